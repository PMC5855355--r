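#' Counts per million
#'
#' Scales counts by effective library size (library size times normalization
#' factor) per million. With `log = TRUE`, returns log2-CPM with a prior count
#' scaled by effective library size (the usual convention: the prior added to
#' each count is `prior_count * L_k / mean(L)` so that the offset is constant
#' on the CPM scale).
#'
#' @param counts a [count_matrix()] or a numeric matrix (then `lib_sizes`
#'   must be supplied).
#' @param factors a `tmm_factors` object, a numeric vector of per-sample
#'   factors, or `NULL` for unit factors.
#' @param log return log2 values.
#' @param prior_count prior count used when `log = TRUE` (default 2).
#' @param lib_sizes library sizes when `counts` is a bare matrix.
#' @return Numeric matrix of (log-)CPM values, genes x samples.
#' @export
cpm <- function(counts, factors = NULL, log = FALSE, prior_count = 2,
                lib_sizes = NULL) {
  if (inherits(counts, "count_matrix")) {
    y <- counts$counts
    lib <- counts$lib_sizes
  } else {
    y <- as.matrix(counts)
    if (is.null(lib_sizes)) lib_sizes <- colSums(y)
    lib <- lib_sizes
  }
  f <- norm_factor_vector(factors, colnames(y), ncol(y))
  eff <- lib * f
  if (any(eff <= 0)) abort("zero or negative effective library size")
  if (!log) {
    return(sweep(y, 2, eff / 1e6, "/"))
  }
  # effective-library-scaled prior
  pc <- prior_count * eff / mean(eff)
  logcpm <- log2(sweep(sweep(y, 2, pc, "+"), 2, (eff + 2 * pc) / 1e6, "/"))
  logcpm
}

norm_factor_vector <- function(factors, sample_ids, n) {
  if (is.null(factors)) return(rep(1, n))
  if (inherits(factors, "tmm_factors")) {
    f <- setNames(factors$factor, factors$sample_id)
    if (!is.null(sample_ids)) {
      if (!all(sample_ids %in% names(f))) {
        abort("normalization factors missing for some samples")
      }
      f <- f[sample_ids]
    }
    return(unname(f))
  }
  if (length(factors) != n) abort("factor vector length must match samples")
  as.numeric(factors)
}

#' Low-count gene filter
#'
#' Retains genes with at least `min_cpm` counts per million in at least
#' `min_samples` samples, CPM computed with unit normalization factors (the
#' filter precedes normalization).
#'
#' @param counts a [count_matrix()].
#' @param min_cpm CPM threshold (default 15).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 4).
#' @return Named logical vector, one entry per gene, in input gene order.
#' @export
filter_low_counts <- function(counts, min_cpm = 15, min_samples = 4) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_samples > ncol(counts$counts)) {
    abort("min_samples exceeds the number of samples")
  }
  x <- cpm(counts)
  mask <- rowSums(x >= min_cpm) >= min_samples
  setNames(mask, counts$gene_ids)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors. For each sample against a
#' reference, per-gene log2 expression ratios (M) and average log2 abundances
#' (A) are computed over genes positive in both samples, doubly trimmed by M
#' and A quantiles, and combined in a precision-weighted mean with weights
#' from the asymptotic (binomial) variance of M. Factors are centered to
#' geometric mean one.
#'
#' @param counts a [count_matrix()].
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @param ref reference sample id, or `NULL` to pick the sample whose
#'   upper-quartile CPM is closest to the mean upper-quartile.
#' @return A tibble of class `tmm_factors` with columns `sample_id`, `factor`
#'   and `eff_lib_size`; the reference sample id is stored in
#'   `attr(, "reference")`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  y <- counts$counts
  lib <- counts$lib_sizes
  if (ncol(y) < 2L) abort("TMM needs at least two samples")
  if (any(colSums(y > 0) == 0L)) {
    abort("every sample needs at least one positive count")
  }
  if (is.null(ref)) {
    uq <- apply(cpm(counts), 2, quantile, probs = 0.75)
    if (all(uq == 0)) abort("all upper-quartile CPM are zero")
    ref <- colnames(y)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref %in% colnames(y)) abort(paste0("unknown reference sample: ", ref))
  f <- vapply(colnames(y), function(s) {
    tmm_pair(y[, s], y[, ref], lib[[s]], lib[[ref]], trim_m, trim_a, s, ref)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- tibble(sample_id = colnames(y), factor = unname(f),
                eff_lib_size = unname(lib * f))
  attr(out, "reference") <- ref
  class(out) <- c("tmm_factors", class(out))
  out
}

# single-pair TMM factor (uncentered)
tmm_pair <- function(obs, refc, n_obs, n_ref, trim_m, trim_a, id_obs, id_ref) {
  keep <- obs > 0 & refc > 0
  if (!any(keep)) {
    abort(paste0("samples ", id_obs, " and ", id_ref,
                 " share no positive genes"))
  }
  o <- obs[keep]
  r <- refc[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  if (max(abs(m)) < 1e-6) return(1)
  ng <- length(m)
  lo_m <- floor(ng * trim_m) + 1
  hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1
  hi_a <- ng + 1 - lo_a
  rk_m <- rank(m)
  rk_a <- rank(a)
  sel <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
  if (!any(sel)) return(1)
  f <- 2^(sum(m[sel] / v[sel]) / sum(1 / v[sel]))
  if (!is.finite(f) || f <= 0) f <- 1
  f
}

#' Multidimensional scaling of sample similarity
#'
#' Pairwise sample distances from log-expression profiles, reduced to `k`
#' coordinates by classical MDS (double centering and eigendecomposition).
#' With `selection = "pairwise"` the distance between two samples is the
#' root-mean-square of their `top` largest absolute log-expression
#' differences (the leading-log-fold-change distance); with
#' `selection = "common"` a single set of `top` highest-variance genes is
#' used for every pair (Euclidean distance on that set, RMS-scaled).
#'
#' @param logcpm numeric matrix of log2-CPM values, genes x samples.
#' @param top number of genes per (pair or common) selection, default 500.
#' @param k number of retained dimensions, default 2.
#' @param selection `"pairwise"` or `"common"`.
#' @return An object of class `mds_result`: list with `distance` (sample x
#'   sample matrix), `points` (tibble: `sample_id`, `dim1`, ..., `dimk`), and
#'   `var_explained` (per retained dimension).
#' @export
mds_coordinates <- function(logcpm, top = 500, k = 2,
                            selection = c("pairwise", "common")) {
  selection <- arg_match(selection)
  logcpm <- as.matrix(logcpm)
  ns <- ncol(logcpm)
  if (ns < 3L) abort("MDS needs at least three samples")
  top <- min(top, nrow(logcpm))
  ids <- colnames(logcpm)
  if (is.null(ids)) ids <- paste0("S", seq_len(ns))
  d <- matrix(0, ns, ns, dimnames = list(ids, ids))
  if (selection == "common") {
    v <- apply(logcpm, 1, var)
    sel <- order(v, decreasing = TRUE)[seq_len(top)]
    sub <- logcpm[sel, , drop = FALSE]
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        d[i, j] <- d[j, i] <- sqrt(mean((sub[, i] - sub[, j])^2))
      }
    }
  } else {
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        dif2 <- (logcpm[, i] - logcpm[, j])^2
        d[i, j] <- d[j, i] <-
          sqrt(mean(sort(dif2, decreasing = TRUE)[seq_len(top)]))
      }
    }
  }
  fit <- cmdscale(stats::as.dist(d), k = min(k, ns - 1), eig = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (k > npos) {
    abort(paste0("k = ", k, " exceeds the number of positive eigenvalues (",
                 npos, ")"))
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("dim", seq_len(k))
  points <- as_tibble(pts)
  points$sample_id <- ids
  points <- points[, c("sample_id", paste0("dim", seq_len(k)))]
  pos <- fit$eig[fit$eig > 0]
  structure(
    list(distance = d, points = points,
         var_explained = fit$eig[seq_len(k)] / sum(pos),
         eig = fit$eig, selection = selection, top = top),
    class = "mds_result"
  )
}

#' @exportS3Method base::print
print.mds_result <- function(x, ...) {
  cat("mds_result: ", nrow(x$points), " samples, selection = ", x$selection,
      ", top = ", x$top, "\n", sep = "")
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an MDS result into its coordinate tibble
#'
#' @param x an `mds_result`.
#' @param ... unused.
#' @return The coordinate tibble (`sample_id`, `dim1`, ...).
#' @export
tidy.mds_result <- function(x, ...) x$points
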