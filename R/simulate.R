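#' Simulation configuration for the clustered two-species brain design
#'
#' Defaults emulate the study layout: 2 species x 5 individuals x 6 brain
#' parts (60 samples), library sizes log-uniform over roughly 3e5-3e6, about
#' 1e4 genes surviving the low-count filter, gamma-distributed NB dispersions
#' centred near 0.1, per-individual expression effects shared across the six
#' samples of an individual (the clustering the fixed individual effects must
#' absorb), a sparse fraction of genes with brain-part effects shared between
#' species, and a sparser fraction with species-specific (interaction)
#' effects drawn away from the equivalence boundary so truth labels are
#' unambiguous.
#'
#' @param n_genes number of genes.
#' @param individuals_per_species individuals per species (default 5).
#' @param parts brain-part labels (default the six study parts).
#' @param species species labels (default `c("Na", "Ve")`).
#' @param lib_size_range library-size range, sampled log-uniformly.
#' @param baseline_sd SD of gene baseline log abundance (natural log).
#' @param dispersion_shape,dispersion_rate gamma parameters of the per-gene
#'   NB dispersion (defaults give mean 0.1).
#' @param frac_part_de fraction of genes with a brain-part effect (default
#'   0.10).
#' @param part_lfc_range |log2FC| range of part effects (default `c(1, 3)`),
#'   random sign; a single value fixes the magnitude.
#' @param frac_interaction fraction of genes with a species-specific part
#'   effect (default 0.02).
#' @param int_lfc_range |log2FC| range of interaction effects (default
#'   `c(2.5, 4)`, clear of the +/-2 equivalence boundary).
#' @param individual_sd SD of per-gene individual effects (natural log,
#'   default 0.1).
#' @param drop_sample drop one olfactory-bulb sample of the first individual
#'   (the study's low-depth dropout), default `FALSE`.
#' @param seed mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000, individuals_per_species = 5,
                       parts = c("BS", "CE", "DI", "OB", "OT", "TE"),
                       species = c("Na", "Ve"),
                       lib_size_range = c(3e5, 3e6),
                       baseline_sd = 1,
                       dispersion_shape = 4, dispersion_rate = 40,
                       frac_part_de = 0.10, part_lfc_range = c(1, 3),
                       frac_interaction = 0.02, int_lfc_range = c(2.5, 4),
                       individual_sd = 0.1,
                       drop_sample = FALSE, seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  if (n_genes < 1L) abort("need at least one gene")
  if (length(parts) < 2L) abort("need at least two parts")
  fr <- c(frac_part_de, frac_interaction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (any(c(lib_size_range, baseline_sd, dispersion_shape, dispersion_rate,
            individual_sd) < 0)) {
    abort("scale parameters must be non-negative")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a count experiment with known truth
#'
#' Draws NB counts `y ~ NB(mean = exp(log libsize + baseline + individual +
#' part + interaction effects), dispersion phi_g)` under the clustered
#' design. Deterministic given the seed; each gene has its own RNG stream
#' derived from the root seed by counter, so enlarging `n_genes` leaves
#' earlier genes unchanged.
#'
#' @param config a [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `samples` (a
#'   [sample_table()]) and `truth` (class `sim_truth`): per-gene parameters,
#'   true log2 fold changes per contrast of both families, global-null flags
#'   per family, and per-contrast true-equivalence labels at the default
#'   interval half-width 2.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  parts <- cf$parts
  np <- length(parts)
  sp <- cf$species
  ind_ids <- as.vector(t(outer(sp, seq_len(cf$individuals_per_species),
                               paste0)))
  samples <- tidyr::expand_grid(individual = ind_ids, brain_part = parts)
  spec_of_ind <- rep(sp, each = cf$individuals_per_species)
  names(spec_of_ind) <- ind_ids
  samples$species <- spec_of_ind[samples$individual]
  samples$sample_id <- paste0(samples$individual, "_", samples$brain_part)
  samples <- sample_table(samples[, c("sample_id", "individual", "species",
                                      "brain_part")])
  if (isTRUE(cf$drop_sample)) {
    drop_id <- paste0(ind_ids[1], "_OB")
    if (!drop_id %in% samples$sample_id) drop_id <- samples$sample_id[1]
    samples <- sample_table(as_tibble(samples)[samples$sample_id != drop_id, ])
  }
  n <- nrow(samples)
  set.seed(as.integer(cf$seed %% .Machine$integer.max))
  lib <- exp(runif(n, log(cf$lib_size_range[1]), log(cf$lib_size_range[2])))
  # total relative abundance calibrated to a nominal 1e4-gene transcriptome;
  # fixed (not a function of n_genes) so per-gene count laws do not change
  # when the experiment is scaled down
  s0 <- 1e4 * exp(cf$baseline_sd^2 / 2)
  gene_ids <- sprintf("g%05d", seq_len(cf$n_genes))
  counts <- matrix(0L, cf$n_genes, n,
                   dimnames = list(gene_ids, samples$sample_id))
  ind_idx <- match(samples$individual, ind_ids)
  sp2 <- samples$species == sp[2]
  part_idx <- match(samples$brain_part, parts)
  G <- cf$n_genes
  baseline <- numeric(G)
  phi <- numeric(G)
  de_part <- rep(NA_character_, G)
  de_lfc <- numeric(G)
  int_part <- rep(NA_character_, G)
  int_lfc <- numeric(G)
  ln2 <- log(2)
  n_ind <- length(ind_ids)
  for (g in seq_len(G)) {
    set.seed(gene_stream_seed(cf$seed, g))
    baseline[g] <- rnorm(1, 0, cf$baseline_sd)
    phi[g] <- rgamma(1, shape = cf$dispersion_shape, rate = cf$dispersion_rate)
    u <- rnorm(n_ind, 0, cf$individual_sd)
    e_part <- numeric(np)                # shared part effects, log2
    e_int <- numeric(np)                 # extra effect in species 2, log2
    if (runif(1) < cf$frac_part_de) {
      de_part[g] <- parts[sample.int(np, 1)]
      de_lfc[g] <- sample(c(-1, 1), 1) * runif_or_fixed(cf$part_lfc_range)
      e_part[match(de_part[g], parts)] <- de_lfc[g]
    }
    if (length(sp) > 1L && runif(1) < cf$frac_interaction) {
      int_part[g] <- parts[sample.int(np, 1)]
      int_lfc[g] <- sample(c(-1, 1), 1) * runif_or_fixed(cf$int_lfc_range)
      e_int[match(int_part[g], parts)] <- int_lfc[g]
    }
    log2_eff <- e_part[part_idx] + ifelse(sp2, e_int[part_idx], 0)
    mu <- lib / s0 * exp(baseline[g] + u[ind_idx] + ln2 * log2_eff)
    counts[g, ] <- if (phi[g] > 0) {
      rnbinom(n, mu = mu, size = 1 / phi[g])
    } else {
      rpois(n, mu)
    }
  }
  truth <- build_sim_truth(gene_ids, baseline, phi, de_part, de_lfc,
                           int_part, int_lfc, parts, sp)
  list(counts = count_matrix(counts), samples = samples, truth = truth)
}

gene_stream_seed <- function(seed, g) {
  as.integer((as.numeric(seed) * 48271 + g * 1299721) %% 2147483647)
}

runif_or_fixed <- function(range) {
  if (length(range) == 1L || range[1] == range[2]) return(range[1])
  runif(1, range[1], range[2])
}

# derive contrast-level truth from per-gene effects
build_sim_truth <- function(gene_ids, baseline, phi, de_part, de_lfc,
                            int_part, int_lfc, parts, species,
                            delta_log2 = 2) {
  G <- length(gene_ids)
  np <- length(parts)
  e_part <- matrix(0, G, np, dimnames = list(gene_ids, parts))
  hit <- !is.na(de_part)
  e_part[cbind(which(hit), match(de_part[hit], parts))] <- de_lfc[hit]
  e_int <- matrix(0, G, np, dimnames = list(gene_ids, parts))
  hit_i <- !is.na(int_part)
  e_int[cbind(which(hit_i), match(int_part[hit_i], parts))] <- int_lfc[hit_i]
  within <- matrix(0, G, np * length(species))
  wnames <- character(np * length(species))
  k <- 0
  for (s in seq_along(species)) {
    eff <- if (s == 1) e_part else e_part + e_int
    for (p in seq_len(np)) {
      k <- k + 1
      wnames[k] <- paste0(parts[p], "-avg_", species[s])
      within[, k] <- eff[, p] - rowMeans(eff[, -p, drop = FALSE])
    }
  }
  colnames(within) <- wnames
  rownames(within) <- gene_ids
  # put species in the paper's listing order: all parts for species 1 first
  npair <- np * (np - 1) / 2
  inter <- matrix(0, G, npair)
  inames <- character(npair)
  k <- 0
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      k <- k + 1
      inames[k] <- paste0(parts[i], "v", parts[j], "_", species[1], "-",
                          parts[i], "v", parts[j], "_", species[2])
      inter[, k] <- -(e_int[, i] - e_int[, j])
    }
  }
  colnames(inter) <- inames
  rownames(inter) <- gene_ids
  structure(
    list(genes = tibble(gene_id = gene_ids, baseline = baseline,
                        dispersion = phi, de_part = de_part, de_lfc = de_lfc,
                        int_part = int_part, int_lfc = int_lfc),
         within_lfc = within, interaction_lfc = inter,
         null_within = setNames(rowSums(abs(within)) == 0, gene_ids),
         null_interaction = setNames(rowSums(abs(inter)) == 0, gene_ids),
         equivalent = abs(inter) < delta_log2,
         delta_log2 = delta_log2),
    class = "sim_truth"
  )
}

#' @exportS3Method base::print
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", nrow(x$genes), " genes; ",
      sum(!x$null_within), " non-null (within family), ",
      sum(!x$null_interaction), " non-null (interaction family)\n", sep = "")
  invisible(x)
}

#' Score flags against simulation truth
#'
#' Gene-level FDR is the fraction of flagged genes (any significant
#' hypothesis) that are truly globally null in the family; power is the
#' fraction of truly non-null genes flagged. Per-hypothesis rates use the
#' per-contrast truth. Pure function of its inputs.
#'
#' @param result a [stagewise_analysis()] result, or a named logical vector
#'   of per-gene flags.
#' @param truth a `sim_truth` from [simulate_experiment()].
#' @param family `"within"` or `"interaction"`.
#' @return One-row tibble: `n_flagged`, `gene_fdr`, `power`,
#'   `hypothesis_fdr`.
#' @export
evaluate_fdr <- function(result, truth,
                         family = c("within", "interaction")) {
  family <- arg_match(family)
  null_flags <- if (family == "within") truth$null_within else
    truth$null_interaction
  true_lfc <- if (family == "within") truth$within_lfc else
    truth$interaction_lfc
  hyp_fdr <- NA_real_
  if (inherits(result, "stagewise_result")) {
    conf <- result$confirmation
    flagged_tab <- conf %>%
      group_by(gene_id) %>%
      summarise(flag = any(significant, na.rm = TRUE), .groups = "drop")
    flags <- setNames(flagged_tab$flag, flagged_tab$gene_id)
    sig <- conf[!is.na(conf$significant) & conf$significant, ]
    if (nrow(sig)) {
      idx <- cbind(match(sig$gene_id, rownames(true_lfc)),
                   match(sig$contrast, colnames(true_lfc)))
      if (anyNA(idx)) abort("gene/contrast ids do not align with truth")
      hyp_fdr <- mean(true_lfc[idx] == 0)
    } else {
      hyp_fdr <- 0
    }
  } else {
    flags <- result
  }
  if (is.null(names(flags)) || !all(names(flags) %in% names(null_flags))) {
    abort("flag gene ids do not align with truth")
  }
  null_flags <- null_flags[names(flags)]
  n_flag <- sum(flags)
  fdr <- if (n_flag == 0) 0 else sum(flags & null_flags) / n_flag
  pw <- if (sum(!null_flags) == 0) NA_real_ else
    sum(flags & !null_flags) / sum(!null_flags)
  tibble(n_flagged = n_flag, gene_fdr = fdr, power = pw,
         hypothesis_fdr = hyp_fdr)
}

#' Score log2 fold-change recovery against simulation truth
#'
#' Bias and RMSE of estimated log2 fold changes, stratified by the magnitude
#' of the true effect. Pure function of its inputs.
#'
#' @param estimates tibble with columns `gene_id`, `contrast`, `log2fc`.
#' @param truth a `sim_truth`.
#' @param family `"within"` or `"interaction"`.
#' @param breaks magnitude bin edges for the strata (zero effects always form
#'   their own stratum).
#' @return Tibble with one row per stratum: `stratum`, `n`, `bias`, `rmse`.
#' @export
evaluate_recovery <- function(estimates, truth,
                              family = c("within", "interaction"),
                              breaks = c(0, 1, 2, 3, Inf)) {
  family <- arg_match(family)
  true_lfc <- if (family == "within") truth$within_lfc else
    truth$interaction_lfc
  idx <- cbind(match(estimates$gene_id, rownames(true_lfc)),
               match(estimates$contrast, colnames(true_lfc)))
  if (anyNA(idx)) abort("estimate ids do not align with truth")
  tv <- true_lfc[idx]
  err <- estimates$log2fc - tv
  mag <- abs(tv)
  stratum <- ifelse(mag < 1e-12, "0",
                    as.character(cut(mag, breaks = breaks,
                                     include.lowest = FALSE)))
  tibble(stratum = stratum, err = err) %>%
    filter(!is.na(err)) %>%
    group_by(stratum) %>%
    summarise(n = n(), bias = mean(err), rmse = sqrt(mean(err^2)),
              .groups = "drop")
}
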