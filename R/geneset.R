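#' Inter-gene correlation and variance inflation factor for a gene set
#'
#' Mean pairwise correlation of independence-transformed residuals of the set
#' genes. Log-expression rows are rotated into the residual space of the
#' design (the last n - p components of Q'y from the design QR), unit
#' normalized, and averaged over pairs; the variance inflation factor for the
#' in-set mean statistic is `VIF = 1 + (m - 1) * rho`.
#'
#' @param logcpm numeric gene x sample log-expression matrix covering at
#'   least the set genes.
#' @param design a design matrix (or [build_design()] result).
#' @param set gene ids or row indices of the set (size >= 1).
#' @param floor lower bound for the VIF (default 1).
#' @return List with `rho` (mean inter-gene correlation; `NA` for singleton
#'   sets), `vif`, and `m` (set size).
#' @export
estimate_vif <- function(logcpm, design, set, floor = 1) {
  X <- design_input_matrix(design)
  Y <- as.matrix(logcpm)[set, , drop = FALSE]
  m <- nrow(Y)
  if (m == 0L) abort("empty gene set")
  if (m == 1L) return(list(rho = NA_real_, vif = 1, m = 1L))
  n <- ncol(Y)
  qrX <- qr(X)
  p <- qrX$rank
  if (n - p < 1L) abort("no residual degrees of freedom")
  U <- t(qr.qty(qrX, t(Y))[(p + 1):n, , drop = FALSE])
  nrm <- sqrt(rowSums(U^2))
  U <- U / pmax(nrm, 1e-12)
  U[nrm < 1e-12, ] <- 0
  S <- tcrossprod(U)
  rho <- (sum(S) - sum(diag(S))) / (m * (m - 1))
  list(rho = rho, vif = max(1 + (m - 1) * rho, floor), m = m)
}

#' Competitive gene-set test with correlation correction
#'
#' Compares the mean gene-level statistic inside the set with the mean
#' outside, as a two-sample t-test whose in-set standard error is inflated by
#' the set's VIF: `t = (mean_in - mean_out) / (s_pooled * sqrt(VIF/m1 +
#' 1/m2))` on `G - 2` df, two-tailed.
#'
#' @param gene_stats named numeric vector of per-gene z-equivalent statistics
#'   over the universe.
#' @param in_set logical vector (same length) or character ids marking set
#'   membership.
#' @param vif variance inflation factor (default 1 = no correction).
#' @return One-row tibble: `size`, `vif`, `stat`, `direction` (`"up"`,
#'   `"down"` or `"none"`), `p_value`.
#' @export
camera_test <- function(gene_stats, in_set, vif = 1) {
  G <- length(gene_stats)
  if (is.character(in_set)) {
    in_set <- names(gene_stats) %in% in_set
  }
  stopifnot(length(in_set) == G)
  m1 <- sum(in_set)
  m2 <- G - m1
  if (m1 == 0L) abort("empty set")
  if (m2 == 0L) abort("set equals the universe")
  if (vif <= 0) abort("vif must be positive")
  s_in <- gene_stats[in_set]
  s_out <- gene_stats[!in_set]
  delta <- mean(s_in) - mean(s_out)
  ss <- sum((s_in - mean(s_in))^2) + sum((s_out - mean(s_out))^2)
  df <- G - 2
  s2p <- ss / df
  if (s2p <= 0) {
    return(tibble(size = m1, vif = vif, stat = 0, direction = "none",
                  p_value = 1))
  }
  tstat <- delta / sqrt(s2p * (vif / m1 + 1 / m2))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  dir <- if (delta > 0) "up" else if (delta < 0) "down" else "none"
  tibble(size = m1, vif = vif, stat = tstat, direction = dir, p_value = p)
}

#' GO-style enrichment workflow over stage-wise results
#'
#' For each species and brain part, genes confirmed differentially expressed
#' (DE) in at least one within-species contrast form the universe; the
#' foreground of a part is the set of genes uniquely DE in that part (exactly
#' one significant part-vs-average contrast) in both species. Each gene set
#' is intersected with the part's foreground, its inter-gene correlation is
#' estimated from design residuals, and the competitive test compares the
#' set's normal-equivalent contrast statistics (signed z from the
#' confirmation F-tests) against the rest of the universe. Two-tailed
#' p-values are BH-adjusted per species x part at `alpha`.
#'
#' @param stagewise a [stagewise_analysis()] result for the within-species
#'   contrast family.
#' @param gene_sets a [read_gene_sets()] collection (or named list of id
#'   vectors).
#' @param logcpm log-expression matrix used for the correlation estimate.
#' @param design design matrix or [build_design()] result.
#' @param alpha FDR level per species x part (default 0.05).
#' @param min_set_size smallest set (in foreground) that is formally tested;
#'   smaller sets are reported descriptively with `tested = FALSE`.
#' @param top_k rows of the cross-species top-upregulated table (default 5).
#' @return List with `results` (tibble: species, part, set_id, size, rho,
#'   vif, stat, direction, p_value, padj, significant, tested), `shared`
#'   (sets significant in both species, per part) and `top_up` (top
#'   upregulated shared sets per part).
#' @export
enrichment_workflow <- function(stagewise, gene_sets, logcpm, design,
                                alpha = 0.05, min_set_size = 2, top_k = 5) {
  conf <- stagewise$confirmation
  meta <- parse_within_contrast(conf$contrast)
  conf <- dplyr::bind_cols(conf, meta)
  sig <- conf %>% filter(!is.na(significant) & significant)
  de_genes <- unique(sig$gene_id)
  if (length(de_genes) == 0L) abort("empty universe: no DE genes")
  # uniquely-DE part per gene and species (NA when 0 or >1 parts)
  uniq <- sig %>%
    group_by(gene_id, species) %>%
    summarise(n_parts = n(), part = part[1], .groups = "drop") %>%
    filter(n_parts == 1L)
  species_levels <- unique(meta$species)
  parts <- unique(meta$part)
  res <- list()
  for (s in species_levels) {
    for (p in parts) {
      fg <- foreground_genes(uniq, p, species_levels)
      stats_tab <- conf %>%
        filter(species == s, part == p, gene_id %in% de_genes)
      z <- signed_z(stats_tab$p_value, stats_tab$log2fc)
      names(z) <- stats_tab$gene_id
      z <- z[is.finite(z)]
      for (set_id in names(gene_sets)) {
        members <- intersect(intersect(gene_sets[[set_id]], fg), names(z))
        m <- length(members)
        if (m == 0L) next
        if (m < min_set_size || m >= length(z)) {
          res[[length(res) + 1]] <- tibble(
            species = s, part = p, set_id = set_id, size = m,
            rho = NA_real_, vif = NA_real_, stat = NA_real_,
            direction = NA_character_, p_value = NA_real_, tested = FALSE)
          next
        }
        v <- estimate_vif(logcpm, design, members)
        ct <- camera_test(z, members, vif = v$vif)
        res[[length(res) + 1]] <- tibble(
          species = s, part = p, set_id = set_id, size = m,
          rho = v$rho, vif = ct$vif, stat = ct$stat,
          direction = ct$direction, p_value = ct$p_value, tested = TRUE)
      }
    }
  }
  results <- bind_rows(res)
  if (nrow(results) == 0L) {
    return(list(results = results, shared = results[0, ], top_up = results[0, ]))
  }
  results <- results %>%
    group_by(species, part) %>%
    mutate(padj = {
      v <- rep(NA_real_, n())
      if (any(tested)) v[tested] <- bh_adjust(p_value[tested])
      v
    }) %>%
    ungroup() %>%
    mutate(significant = tested & !is.na(padj) & padj <= alpha)
  shared <- results %>%
    filter(significant) %>%
    group_by(part, set_id) %>%
    filter(dplyr::n_distinct(species) == length(species_levels)) %>%
    ungroup()
  if (nrow(shared) == 0L) {
    return(list(results = results, shared = shared, top_up = shared))
  }
  top_up <- shared %>%
    filter(direction == "up") %>%
    group_by(part, set_id) %>%
    summarise(p_value = max(p_value), size = min(size), .groups = "drop") %>%
    group_by(part) %>%
    arrange(p_value, set_id, .by_group = TRUE) %>%
    dplyr::slice_head(n = top_k) %>%
    ungroup()
  list(results = results, shared = shared, top_up = top_up)
}

foreground_genes <- function(uniq, part, species_levels) {
  per_species <- lapply(species_levels, function(s) {
    uniq$gene_id[uniq$species == s & uniq$part == part]
  })
  Reduce(intersect, per_species)
}

# contrast names of the within-species family: "<part>-avg_<species>"
parse_within_contrast <- function(x) {
  tibble(part = sub("-avg_.*$", "", x),
         species = sub("^.*-avg_", "", x))
}

# normal-equivalent score of a two-sided p with the sign of the estimate
signed_z <- function(p, sign_src) {
  p <- pmin(pmax(p, 1e-300), 1)
  sign(ifelse(sign_src == 0, 1, sign_src)) * qnorm(p / 2, lower.tail = FALSE)
}
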