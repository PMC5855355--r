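#' Fold-change-threshold (TREAT-style) test
#'
#' Tests, per gene and contrast, the null hypothesis |log2FC| <= tau against
#' the alternative that the fold change exceeds the threshold. The p-value
#' combines the two one-sided statistics against the nearer and farther
#' interval boundary — `p = P(T > (|b|-tau)/se) + P(T > (|b|+tau)/se)` with T
#' a t-variable on the quasi-likelihood denominator df — using the QL standard
#' error from the squeezed dispersion. At `tau = 0` this reduces to the
#' ordinary two-sided test.
#'
#' @inheritParams ql_f_test
#' @param tau_log2 fold-change threshold on the log2 scale (default 2).
#' @return Tibble with one row per gene x contrast: `gene_id`, `contrast`,
#'   `log2fc`, `se_log2`, `p_value`.
#' @export
treat_test <- function(counts, design, offsets, dispersions, contrasts,
                       tau_log2 = 2, genes = NULL, tol = 1e-8, maxit = 50) {
  if (tau_log2 < 0) abort("tau_log2 must be non-negative")
  Y <- count_input_matrix(counts)
  X <- design_input_matrix(design)
  Cmat <- contrast_input_matrix(contrasts, X)
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  ids <- rownames(Y)
  phi <- align_by_gene(dispersions$phi_trend, ids)
  s2 <- align_by_gene(dispersions$s2_post, ids)
  df2 <- dispersions$df_prior + dispersions$df_residual
  fit <- .nb_fit_genes_cpp(Y, X, as.numeric(offsets), phi, tol, maxit,
                           FALSE, TRUE)
  uv <- .contrast_unscaled_var_cpp(fit$fitted, X, phi, Cmat)
  b2 <- fit$coefficients %*% Cmat / log(2)
  se2 <- sqrt(uv * s2) / log(2)
  t_near <- (abs(b2) - tau_log2) / se2
  t_far <- (abs(b2) + tau_log2) / se2
  p <- pmin(pt(t_near, df2, lower.tail = FALSE) +
              pt(t_far, df2, lower.tail = FALSE), 1)
  cn <- colnames(Cmat)
  tibble(
    gene_id = rep(ids, times = length(cn)),
    contrast = rep(cn, each = length(ids)),
    log2fc = as.numeric(b2),
    se_log2 = as.numeric(se2),
    p_value = as.numeric(p)
  )
}

#' TOST equivalence test via offset shifting
#'
#' Two one-sided tests of the contrast against the equivalence interval
#' `[-delta, +delta]` (log2 scale). The design is reparametrized so the
#' contrast is a single coefficient; each one-sided null (coefficient at
#' `-delta` or `+delta`) is imposed by shifting the sample-wise offset by the
#' boundary value times the reparametrized column, dropping that column, and
#' refitting. One-sided p-values come from the signed square root of the QL F
#' statistic referred to a t distribution on the QL denominator df; the TOST
#' p-value is the maximum of the two.
#'
#' @inheritParams ql_f_test
#' @param delta_log2 half-width of the equivalence interval in log2 units
#'   (default 2).
#' @return Tibble with one row per gene x contrast: `gene_id`, `contrast`,
#'   `log2fc`, `p_lower`, `p_upper`, `p_tost`.
#' @export
tost_equivalence <- function(counts, design, offsets, dispersions, contrasts,
                             delta_log2 = 2, genes = NULL,
                             tol = 1e-8, maxit = 50) {
  if (delta_log2 <= 0) abort("delta_log2 must be positive")
  Y <- count_input_matrix(counts)
  X <- design_input_matrix(design)
  Cmat <- contrast_input_matrix(contrasts, X)
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  ids <- rownames(Y)
  phi <- align_by_gene(dispersions$phi_trend, ids)
  s2 <- align_by_gene(dispersions$s2_post, ids)
  df2 <- dispersions$df_prior + dispersions$df_residual
  off <- as.numeric(offsets)
  delta_ln <- delta_log2 * log(2)
  full <- .nb_fit_genes_cpp(Y, X, off, phi, tol, maxit, FALSE, FALSE)
  dev_full <- as.numeric(full$deviance)
  out <- vector("list", ncol(Cmat))
  for (j in seq_len(ncol(Cmat))) {
    cvec <- Cmat[, j]
    if (all(cvec == 0)) abort("zero contrast vector")
    # reparametrize: first new coefficient equals c'beta
    a <- cvec / sum(cvec^2)
    K <- null_space_basis(t(cvec))
    x1 <- as.numeric(X %*% a)
    X0 <- X %*% K
    gamma1 <- as.numeric(full$coefficients %*% cvec)
    dev_hi <- .nb_fit_genes_cpp(Y, X0, off + delta_ln * x1, phi, tol, maxit,
                                FALSE, FALSE)$deviance
    dev_lo <- .nb_fit_genes_cpp(Y, X0, off - delta_ln * x1, phi, tol, maxit,
                                FALSE, FALSE)$deviance
    f_hi <- pmax(as.numeric(dev_hi) - dev_full, 0) / s2
    f_lo <- pmax(as.numeric(dev_lo) - dev_full, 0) / s2
    t_hi <- sign(gamma1 - delta_ln) * sqrt(f_hi)
    t_lo <- sign(gamma1 + delta_ln) * sqrt(f_lo)
    p_upper <- pt(t_hi, df2, lower.tail = TRUE)   # H0: gamma1 >= +delta
    p_lower <- pt(t_lo, df2, lower.tail = FALSE)  # H0: gamma1 <= -delta
    out[[j]] <- tibble(
      gene_id = ids, contrast = colnames(Cmat)[j],
      log2fc = gamma1 / log(2),
      p_lower = p_lower, p_upper = p_upper,
      p_tost = pmax(p_lower, p_upper)
    )
  }
  bind_rows(out)
}

#' Per-contrast equivalence calls
#'
#' BH-adjusts TOST p-values within each contrast and flags genes equivalent at
#' FDR `alpha`; reports per-contrast equivalent proportions and their average.
#'
#' @param tost tibble from [tost_equivalence()] (columns `gene_id`,
#'   `contrast`, `p_tost`), or a gene x contrast p-value matrix.
#' @param alpha FDR level per contrast (default 0.05).
#' @return List with `flags` (tibble: gene x contrast with `padj`,
#'   `equivalent`), `by_contrast` (tibble: contrast, `n`, `prop_equivalent`)
#'   and `mean_prop_equivalent`.
#' @export
equivalence_per_contrast <- function(tost, alpha = 0.05) {
  tab <- tost_long(tost)
  if (any(tapply(tab$p_tost, tab$contrast, length) == 0L)) {
    abort("empty contrast column")
  }
  tab <- tab %>%
    group_by(contrast) %>%
    mutate(padj = bh_adjust(p_tost), equivalent = padj <= alpha) %>%
    ungroup()
  by_contrast <- tab %>%
    group_by(contrast) %>%
    summarise(n = n(), prop_equivalent = mean(equivalent), .groups = "drop")
  list(flags = tab, by_contrast = by_contrast,
       mean_prop_equivalent = mean(by_contrast$prop_equivalent))
}

#' Global (all-contrast) equivalence calls
#'
#' Per-gene statistic is the maximum TOST p-value across contrasts (a gene is
#' globally equivalent only if every contrast is); BH across genes on these
#' maxima, flagged at FDR `alpha`. Genes must be tested in every contrast.
#'
#' @inheritParams equivalence_per_contrast
#' @return Tibble: `gene_id`, `p_max`, `padj`, `equivalent`.
#' @export
equivalence_global <- function(tost, alpha = 0.05) {
  tab <- tost_long(tost)
  if (anyNA(tab$p_tost)) abort("NA TOST p-values: every gene must be tested in every contrast")
  counts <- table(tab$gene_id)
  if (length(unique(counts)) != 1L) {
    abort("every gene must be tested in every contrast")
  }
  per_gene <- tab %>%
    group_by(gene_id) %>%
    summarise(p_max = max(p_tost), .groups = "drop")
  per_gene$padj <- bh_adjust(per_gene$p_max)
  per_gene$equivalent <- per_gene$padj <= alpha
  per_gene
}

tost_long <- function(tost) {
  if (is.matrix(tost)) {
    ids <- rownames(tost)
    if (is.null(ids)) ids <- paste0("g", seq_len(nrow(tost)))
    cn <- colnames(tost)
    if (is.null(cn)) cn <- paste0("c", seq_len(ncol(tost)))
    return(tibble(gene_id = rep(ids, times = ncol(tost)),
                  contrast = rep(cn, each = nrow(tost)),
                  p_tost = as.numeric(tost)))
  }
  stopifnot(all(c("gene_id", "contrast", "p_tost") %in% names(tost)))
  as_tibble(tost)[, c("gene_id", "contrast", "p_tost")]
}

#' Threshold-test decisions over screened genes
#'
#' Applies [treat_test()] to the screened genes of a stage-wise result and
#' BH-adjusts within each contrast at `alpha` (the gene-level FDR for the
#' fold-change-threshold decisions).
#'
#' @inheritParams treat_test
#' @param stagewise a [stagewise_analysis()] result supplying the screened
#'   set.
#' @param alpha FDR level (default 0.05).
#' @return Tibble: gene x contrast rows with `log2fc`, `p_value`, `padj`,
#'   `exceeds_threshold`.
#' @export
threshold_decisions <- function(counts, design, offsets, dispersions,
                                contrasts, stagewise, tau_log2 = 2,
                                alpha = 0.05) {
  keep <- stagewise$screening$gene_id[stagewise$screening$screened]
  if (length(keep) == 0L) {
    return(tibble(gene_id = character(), contrast = character(),
                  log2fc = numeric(), se_log2 = numeric(),
                  p_value = numeric(), padj = numeric(),
                  exceeds_threshold = logical()))
  }
  tt <- treat_test(counts, design, offsets, dispersions, contrasts,
                   tau_log2 = tau_log2, genes = keep)
  tt %>%
    group_by(contrast) %>%
    mutate(padj = bh_adjust(p_value), exceeds_threshold = padj <= alpha) %>%
    ungroup()
}
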