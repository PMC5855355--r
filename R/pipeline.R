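#' Pipeline configuration
#'
#' All thresholds default to the study's stated constants: a 15-CPM filter in
#' at least 4 samples, 5% FDR levels throughout, a log2 fold-change threshold
#' of 2, an equivalence interval of +/-2 log2 units, the top 500 genes for
#' MDS and the top 200 screening genes for the heatmap.
#'
#' @param min_cpm,min_samples low-count filter parameters.
#' @param alpha FDR level used by every testing stage.
#' @param tau_log2 fold-change threshold for the threshold test.
#' @param delta_log2 equivalence interval half-width.
#' @param mds_top,heatmap_top gene counts for MDS and the heatmap selection.
#' @param mds_selection `"pairwise"` (leading log-fold-change) or `"common"`.
#' @param equivalence_universe `"filtered"` (all filtered genes, the default)
#'   or `"screened"` (interaction-screened genes only).
#' @param pool_screening screen the two hypothesis families jointly (one
#'   omnibus test over all 27 contrasts) instead of separately.
#' @param reference_part reference brain part for the design (default: first
#'   level).
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cpm = 15, min_samples = 4, alpha = 0.05,
                            tau_log2 = 2, delta_log2 = 2,
                            mds_top = 500, heatmap_top = 200,
                            mds_selection = "pairwise",
                            equivalence_universe = c("filtered", "screened"),
                            pool_screening = FALSE,
                            reference_part = NULL, seed = 1L) {
  equivalence_universe <- arg_match(equivalence_universe)
  if (any(c(min_cpm, min_samples, alpha, tau_log2, delta_log2, mds_top,
            heatmap_top) <= 0)) {
    abort("all thresholds must be positive")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Filter, TMM-normalize, MDS, fit dispersions, stage-wise testing of both
#' contrast families, fold-change-threshold testing of screened genes,
#' TOST equivalence testing across the interaction contrasts, optional
#' gene-set enrichment, and heatmap data for the top screening genes. All
#' stage outputs are written as TSV under `out_dir` together with a JSON run
#' manifest (config, seed, file checksums, producing stage per file). The
#' analysis is deterministic given inputs and config.
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_table()] covering the count columns.
#' @param gene_sets optional [read_gene_sets()] collection.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param config a [pipeline_config()].
#' @return (Invisibly) a list bundle with every stage result: `filter_mask`,
#'   `factors`, `mds`, `design`, `dispersions`, `stagewise_within`,
#'   `stagewise_interaction`, `threshold`, `equivalence`, `enrichment`,
#'   `heatmap`, `manifest`.
#' @export
run_pipeline <- function(counts, samples, gene_sets = NULL, out_dir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- sample_table(samples)
  if (!setequal(samples$sample_id, counts$sample_ids)) {
    abort("sample table and count matrix disagree on sample ids")
  }
  counts <- subset_counts(counts, samples = samples$sample_id)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(force(expr), error = function(e) {
      abort(paste0("stage ", name, ": ", conditionMessage(e)))
    })
    message(sprintf("[%s] %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    val
  }
  mask <- stage("filter", filter_low_counts(counts, config$min_cpm,
                                            config$min_samples))
  if (!any(mask)) abort("stage filter: no genes pass the low-count filter")
  fcounts <- subset_counts(counts, genes = mask)
  factors <- stage("tmm", tmm_factors(fcounts))
  offsets <- log(factors$eff_lib_size)
  logcpm <- cpm(fcounts, factors = factors, log = TRUE)
  mds <- stage("mds", mds_coordinates(logcpm, top = config$mds_top,
                                      selection = config$mds_selection))
  design <- build_design(samples, reference_part = config$reference_part)
  cw <- within_species_contrasts(design)
  ci <- interaction_contrasts(design)
  disp <- stage("dispersion",
                estimate_dispersion(fcounts, design, offsets))
  if (isTRUE(config$pool_screening)) {
    pooled <- new_contrast_set(cbind(unclass(cw), unclass(ci)),
                               c(attr(cw, "family"), attr(ci, "family")))
    sw_all <- stage("stagewise",
                    stagewise_analysis(fcounts, design, offsets, disp,
                                       pooled, alpha = config$alpha))
    sw <- split_stagewise(sw_all, colnames(cw), "within_species")
    si <- split_stagewise(sw_all, colnames(ci), "interaction")
  } else {
    sw <- stage("stagewise_within",
                stagewise_analysis(fcounts, design, offsets, disp, cw,
                                   alpha = config$alpha))
    si <- stage("stagewise_interaction",
                stagewise_analysis(fcounts, design, offsets, disp, ci,
                                   alpha = config$alpha))
  }
  thr <- stage("threshold",
               threshold_decisions(fcounts, design, offsets, disp, cw, sw,
                                   tau_log2 = config$tau_log2,
                                   alpha = config$alpha))
  eq_genes <- if (config$equivalence_universe == "screened") {
    si$screening$gene_id[si$screening$screened]
  } else NULL
  equivalence <- NULL
  if (is.null(eq_genes) || length(eq_genes) > 0) {
    tost <- stage("equivalence",
                  tost_equivalence(fcounts, design, offsets, disp, ci,
                                   delta_log2 = config$delta_log2,
                                   genes = eq_genes))
    equivalence <- list(
      tost = tost,
      per_contrast = equivalence_per_contrast(tost, alpha = config$alpha),
      global = equivalence_global(tost, alpha = config$alpha)
    )
  }
  enrichment <- NULL
  if (!is.null(gene_sets) &&
      any(sw$confirmation$significant, na.rm = TRUE)) {
    enrichment <- stage("enrichment",
                        enrichment_workflow(sw, gene_sets, logcpm, design,
                                            alpha = config$alpha))
  }
  heat <- stage("heatmap",
                top_gene_heatmap_data(sw, logcpm, top = config$heatmap_top))
  bundle <- list(filter_mask = mask, counts_filtered = fcounts,
                 factors = factors, offsets = offsets, logcpm = logcpm,
                 mds = mds, design = design,
                 contrasts_within = cw, contrasts_interaction = ci,
                 dispersions = disp, stagewise_within = sw,
                 stagewise_interaction = si, threshold = thr,
                 equivalence = equivalence, enrichment = enrichment,
                 heatmap = heat, config = config)
  if (!is.null(out_dir)) {
    bundle$manifest <- write_pipeline_outputs(bundle, out_dir)
  }
  invisible(bundle)
}

# carve one family out of a jointly screened stagewise result
split_stagewise <- function(sw, contrast_names, family) {
  conf <- sw$confirmation[sw$confirmation$contrast %in% contrast_names, ]
  structure(
    list(screening = sw$screening, confirmation = conf,
         alpha = sw$alpha, alpha_adj = sw$alpha_adj,
         n_genes = sw$n_genes, n_screened = sw$n_screened, family = family),
    class = "stagewise_result"
  )
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  emit <- function(tab, name, stage) {
    path <- file.path(out_dir, name)
    write_results_table(tab, path)
    files[[name]] <<- list(stage = stage,
                           md5 = unname(tools::md5sum(path)))
  }
  emit(as.data.frame(bundle$factors), "normalization_factors.tsv", "tmm")
  emit(tidy(bundle$mds), "mds_coordinates.tsv", "mds")
  emit(tibble(gene_id = names(bundle$filter_mask),
              retained = unname(bundle$filter_mask)),
       "filter_mask.tsv", "filter")
  emit(tidy(bundle$dispersions), "dispersions.tsv", "dispersion")
  emit(bundle$stagewise_within$screening, "screening_within.tsv",
       "stagewise_within")
  emit(bundle$stagewise_within$confirmation, "confirmation_within.tsv",
       "stagewise_within")
  emit(bundle$stagewise_interaction$screening, "screening_interaction.tsv",
       "stagewise_interaction")
  emit(bundle$stagewise_interaction$confirmation,
       "confirmation_interaction.tsv", "stagewise_interaction")
  emit(bundle$threshold, "threshold_within.tsv", "threshold")
  if (!is.null(bundle$equivalence)) {
    emit(bundle$equivalence$per_contrast$flags, "equivalence_per_contrast.tsv",
         "equivalence")
    emit(bundle$equivalence$global, "equivalence_global.tsv", "equivalence")
  }
  if (!is.null(bundle$enrichment) && nrow(bundle$enrichment$results)) {
    emit(bundle$enrichment$results, "enrichment.tsv", "enrichment")
  }
  emit(heatmap_long(bundle$heatmap), "heatmap_top_genes.tsv", "heatmap")
  manifest <- list(
    package = "cichlidDE",
    version = as.character(utils::packageVersion("cichlidDE")),
    seed = bundle$config$seed,
    config = unclass(bundle$config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}

#' Heatmap data for the top screening genes
#'
#' Selects the `top` genes with the lowest screening-stage adjusted p-values
#' (ties broken by raw p, then gene id), row-standardizes their log-CPM, and
#' computes hierarchical clustering orders (Euclidean distance, complete
#' linkage) for genes and samples. Emitted as data, not an image.
#'
#' @param stagewise a [stagewise_analysis()] result (screening stage used).
#' @param logcpm log-CPM matrix covering the screened genes.
#' @param top number of genes (default 200); if fewer are available, all are
#'   used with a warning.
#' @return List of class `heatmap_data`: `matrix` (standardized, genes x
#'   samples, input order), `row_order`, `col_order`, `genes`.
#' @export
top_gene_heatmap_data <- function(stagewise, logcpm, top = 200) {
  scr <- stagewise$screening
  if (top > nrow(scr)) {
    warn(paste0("only ", nrow(scr), " genes available; using all"))
    top <- nrow(scr)
  }
  sel <- scr %>%
    arrange(padj_screen, p_screen, gene_id) %>%
    dplyr::slice_head(n = top)
  m <- as.matrix(logcpm)[sel$gene_id, , drop = FALSE]
  mstd <- t(scale(t(m)))
  mstd[!is.finite(mstd)] <- 0
  row_order <- if (nrow(mstd) > 2) hclust(dist(mstd), "complete")$order
               else seq_len(nrow(mstd))
  col_order <- if (ncol(mstd) > 2) hclust(dist(t(mstd)), "complete")$order
               else seq_len(ncol(mstd))
  structure(list(matrix = mstd, row_order = row_order,
                 col_order = col_order, genes = sel$gene_id),
            class = "heatmap_data")
}

heatmap_long <- function(heat) {
  m <- heat$matrix[heat$row_order, heat$col_order, drop = FALSE]
  tibble(gene_id = rep(rownames(m), times = ncol(m)),
         sample_id = rep(colnames(m), each = nrow(m)),
         z = as.numeric(m))
}

#' Candidate-gene report across the within-species contrasts
#'
#' For each requested gene: whether it survived the low-count filter, and per
#' species x brain part the estimated log2 fold change (part vs average of
#' the other parts), the Holm-adjusted confirmation p-value, and the
#' significance flag. Unknown or filtered-out genes yield "not detected"
#' rows with a warning.
#'
#' @param bundle a [run_pipeline()] result (or any list with `filter_mask`
#'   and `stagewise_within`).
#' @param gene_list character vector of gene ids, or a named vector mapping
#'   symbols to ids (names become the `symbol` column).
#' @return Tibble: `symbol`, `gene_id`, `detected`, `contrast`, `log2fc`,
#'   `p_holm`, `significant`.
#' @export
candidate_gene_report <- function(bundle, gene_list) {
  if (length(gene_list) == 0L) {
    return(tibble(symbol = character(), gene_id = character(),
                  detected = logical(), contrast = character(),
                  log2fc = numeric(), p_holm = numeric(),
                  significant = logical()))
  }
  symbols <- names(gene_list)
  if (is.null(symbols)) symbols <- unname(gene_list)
  ids <- unname(gene_list)
  conf <- bundle$stagewise_within$confirmation
  known <- names(bundle$filter_mask)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!id %in% known) {
      warn(paste0("unknown gene id: ", id))
      out[[i]] <- tibble(symbol = symbols[i], gene_id = id, detected = NA,
                         contrast = NA_character_, log2fc = NA_real_,
                         p_holm = NA_real_, significant = NA)
      next
    }
    if (!bundle$filter_mask[[id]]) {
      out[[i]] <- tibble(symbol = symbols[i], gene_id = id, detected = FALSE,
                         contrast = NA_character_, log2fc = NA_real_,
                         p_holm = NA_real_, significant = NA)
      next
    }
    rows <- conf[conf$gene_id == id, ]
    out[[i]] <- tibble(symbol = symbols[i], gene_id = id, detected = TRUE,
                       contrast = rows$contrast, log2fc = rows$log2fc,
                       p_holm = rows$p_holm, significant = rows$significant)
  }
  bind_rows(out)
}
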