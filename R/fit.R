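#' Fit gene-wise negative binomial GLMs
#'
#' Fits, for every gene, an NB GLM with log link, fixed per-gene dispersion
#' and per-sample offsets by iteratively reweighted least squares (relative
#' deviance-change convergence, default tolerance 1e-8, at most 50
#' iterations). Coefficients are on the natural-log scale; fold changes are
#' converted to log2 at reporting time.
#'
#' @param counts numeric gene x sample matrix (or [count_matrix()]).
#' @param design a [build_design()] result or a bare design matrix.
#' @param offsets per-sample offsets, normally `log(effective library size)`.
#' @param dispersion NB dispersion phi: scalar or per-gene vector.
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @param want_fitted keep the fitted-mean matrix (needed for standard errors
#'   and gene-set correlation work).
#' @return An object of class `gene_fit`: list with `coefficients` (gene x
#'   coefficient, natural-log scale), `deviance`, `df_residual`, `converged`,
#'   `degenerate`, `dispersion`, and optionally `fitted`.
#' @export
fit_gene_models <- function(counts, design, offsets, dispersion,
                            tol = 1e-8, maxit = 50, want_fitted = TRUE) {
  Y <- count_input_matrix(counts)
  X <- design_input_matrix(design)
  if (length(offsets) != ncol(Y)) abort("offsets length must match samples")
  phi <- expand_phi(dispersion, nrow(Y))
  if (any(phi < 0)) abort("dispersion must be non-negative")
  res <- .nb_fit_genes_cpp(Y, X, as.numeric(offsets), phi, tol, maxit,
                           FALSE, want_fitted)
  coef <- res$coefficients
  dimnames(coef) <- list(rownames(Y), colnames(X))
  out <- list(coefficients = coef,
              deviance = setNames(as.numeric(res$deviance), rownames(Y)),
              df_residual = ncol(Y) - ncol(X),
              iter = res$iter,
              converged = as.logical(res$converged),
              degenerate = as.logical(res$degenerate),
              dispersion = phi,
              design = X,
              offsets = as.numeric(offsets))
  if (want_fitted) {
    out$fitted <- res$fitted
    dimnames(out$fitted) <- dimnames(Y)
  }
  structure(out, class = "gene_fit")
}

#' @exportS3Method base::print
print.gene_fit <- function(x, ...) {
  cat("gene_fit: ", nrow(x$coefficients), " genes, ",
      ncol(x$coefficients), " coefficients, residual df ",
      x$df_residual, "\n", sep = "")
  invisible(x)
}

#' Fit one gene
#'
#' Single-gene convenience wrapper around [fit_gene_models()]. An all-zero
#' count row yields a degenerate fit (zero fitted means, zero deviance,
#' `degenerate = TRUE`) rather than an error.
#'
#' @param counts_row integer count vector for one gene.
#' @inheritParams fit_gene_models
#' @return List with `coefficients` (named, natural-log scale), `fitted`,
#'   `deviance`, `converged`, `degenerate`.
#' @export
fit_gene <- function(counts_row, design, offsets, dispersion,
                     tol = 1e-8, maxit = 50) {
  Y <- matrix(as.numeric(counts_row), nrow = 1,
              dimnames = list("gene", names(counts_row)))
  fit <- fit_gene_models(Y, design, offsets, dispersion, tol, maxit)
  list(coefficients = fit$coefficients[1, ],
       fitted = fit$fitted[1, ],
       deviance = unname(fit$deviance[1]),
       converged = fit$converged[1],
       degenerate = fit$degenerate[1])
}

count_input_matrix <- function(counts) {
  if (inherits(counts, "count_matrix")) return(counts$counts)
  Y <- as.matrix(counts)
  if (is.null(rownames(Y))) rownames(Y) <- paste0("g", seq_len(nrow(Y)))
  Y
}

design_input_matrix <- function(design) {
  if (inherits(design, "design_matrix")) return(design$matrix)
  as.matrix(design)
}

expand_phi <- function(dispersion, G) {
  if (inherits(dispersion, "dispersion_model")) {
    dispersion <- dispersion$phi_trend
  }
  phi <- as.numeric(dispersion)
  if (length(phi) == 1L) phi <- rep(phi, G)
  if (length(phi) != G) abort("dispersion must be scalar or one value per gene")
  phi
}

#' Estimate NB and quasi-likelihood dispersions
#'
#' Three layers, following the quasi-likelihood workflow: (1) gene-wise NB
#' dispersions by maximizing the Cox-Reid adjusted profile likelihood over a
#' log-spaced grid with quadratic interpolation; (2) an abundance-dispersion
#' trend by robust loess of log gene-wise dispersion on average log2-CPM;
#' (3) per-gene quasi-likelihood dispersions (residual deviance over residual
#' df at the trended NB dispersion), squeezed towards their common value by
#' empirical Bayes moment matching of a scaled inverse chi-square prior.
#'
#' @inheritParams fit_gene_models
#' @param grid_length,grid_range APL evaluation grid (log-spaced).
#' @param span loess span for the abundance trend.
#' @return An object of class `dispersion_model`: list with `gene_ids`,
#'   `abundance` (average log2-CPM), `phi_gene`, `phi_trend`, `s2_raw`,
#'   `s2_post`, `df_prior`, `df_residual`, `s2_prior`.
#' @export
estimate_dispersion <- function(counts, design, offsets,
                                grid_length = 19, grid_range = c(1e-4, 5),
                                span = 0.5, tol = 1e-8, maxit = 50) {
  Y <- count_input_matrix(counts)
  X <- design_input_matrix(design)
  n <- ncol(Y)
  p <- ncol(X)
  if (n - p < 1L) abort("saturated design: no residual degrees of freedom")
  G <- nrow(Y)
  offsets <- as.numeric(offsets)
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_length))
  apl <- matrix(NA_real_, G, grid_length)
  for (k in seq_len(grid_length)) {
    res <- .nb_fit_genes_cpp(Y, X, offsets, rep(grid[k], G), tol, maxit,
                             TRUE, FALSE)
    apl[, k] <- res$apl
  }
  phi_gene <- apl_grid_maximum(apl, log(grid))
  eff_lib <- exp(offsets)
  abundance <- rowMeans(cpm(Y, log = TRUE, lib_sizes = eff_lib))
  ok <- is.finite(phi_gene) & phi_gene > 0 & is.finite(abundance)
  if (sum(ok) >= 20) {
    span_eff <- max(span, min(1, 50 / sum(ok)))
    lo <- loess(log(phi_gene[ok]) ~ abundance[ok], span = span_eff,
                degree = 1, family = "symmetric",
                control = stats::loess.control(surface = "direct"))
    phi_trend <- pmax(exp(predict(lo, abundance)), 1e-6)
  } else {
    # too few genes for a trend: fall back to the common dispersion
    phi_trend <- rep(exp(mean(log(phi_gene[ok]))), G)
  }
  phi_trend[!is.finite(phi_trend)] <- exp(mean(log(phi_gene[ok])))
  fit <- .nb_fit_genes_cpp(Y, X, offsets, phi_trend, tol, maxit, FALSE, FALSE)
  df_res <- n - p
  s2 <- as.numeric(fit$deviance) / df_res
  sq <- squeeze_var(s2, df_res)
  structure(
    list(gene_ids = rownames(Y), abundance = abundance,
         phi_gene = setNames(phi_gene, rownames(Y)),
         phi_trend = setNames(phi_trend, rownames(Y)),
         s2_raw = setNames(s2, rownames(Y)),
         s2_post = setNames(sq$var_post, rownames(Y)),
         s2_prior = sq$var_prior, df_prior = sq$df_prior,
         df_residual = df_res),
    class = "dispersion_model"
  )
}

# per-gene maximizer of a grid of adjusted profile likelihoods, quadratic
# interpolation on the log-dispersion scale around the grid argmax
apl_grid_maximum <- function(apl, log_grid) {
  K <- length(log_grid)
  idx <- max.col(apl, ties.method = "first")
  out <- numeric(nrow(apl))
  for (g in seq_len(nrow(apl))) {
    i <- idx[g]
    if (i == 1L || i == K) {
      out[g] <- exp(log_grid[i])
      next
    }
    x <- log_grid[(i - 1):(i + 1)]
    y <- apl[g, (i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
            x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
            x[1]^2 * (y[2] - y[3])) / denom
    if (a < 0) {
      xv <- -b / (2 * a)
      out[g] <- exp(min(max(xv, x[1]), x[3]))
    } else {
      out[g] <- exp(x[which.max(y)])
    }
  }
  out
}

#' Empirical Bayes squeezing of quasi-likelihood dispersions
#'
#' Moment matching of a scaled inverse chi-square (equivalently scaled F)
#' model on the log sample variances: estimates the prior degrees of freedom
#' `d0` and prior value, and returns the posterior (shrunken) variances
#' `(d0 * s0^2 + df * s2) / (d0 + df)`. With no excess variability across
#' genes, `d0` is infinite and all posterior values equal the prior.
#'
#' @param s2 per-gene variances (QL dispersions), non-negative.
#' @param df residual degrees of freedom (scalar).
#' @return List with `var_post`, `var_prior`, `df_prior`.
#' @export
squeeze_var <- function(s2, df) {
  if (any(s2 < 0)) abort("variances must be non-negative")
  ok <- s2 > 0
  if (sum(ok) < 2L) {
    return(list(var_post = s2, var_prior = mean(s2), df_prior = Inf))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess variability across genes: infinite prior df, no shrinkage
    d0 <- Inf
    s0 <- exp(mean(z))
  }
  var_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + df * s2) / (d0 + df)
  list(var_post = var_post, var_prior = s0, df_prior = d0)
}

# Newton solve of trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' @exportS3Method base::print
print.dispersion_model <- function(x, ...) {
  cat("dispersion_model: ", length(x$phi_gene), " genes\n", sep = "")
  cat("median gene-wise phi ", signif(median(x$phi_gene), 3),
      ", median trended phi ", signif(median(x$phi_trend), 3),
      ", prior df ", signif(x$df_prior, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy per-gene dispersion estimates
#'
#' @param x a `dispersion_model`.
#' @param ... unused.
#' @return Tibble with one row per gene: abundance, gene-wise and trended NB
#'   dispersions, raw and squeezed QL dispersions.
#' @export
tidy.dispersion_model <- function(x, ...) {
  tibble(gene_id = x$gene_ids, abundance = unname(x$abundance),
         phi_gene = unname(x$phi_gene), phi_trend = unname(x$phi_trend),
         s2_raw = unname(x$s2_raw), s2_post = unname(x$s2_post))
}

#' @rdname tidy.dispersion_model
#' @export
glance.dispersion_model <- function(x, ...) {
  tibble(n_genes = length(x$phi_gene), df_residual = x$df_residual,
         df_prior = x$df_prior, s2_prior = x$s2_prior,
         median_phi = unname(median(x$phi_gene)))
}

# orthonormal basis of the null space of M (rows = constraints)
null_space_basis <- function(M) {
  M <- as.matrix(M)
  p <- ncol(M)
  sv <- svd(M, nu = 0, nv = p)
  r <- sum(sv$d > max(dim(M)) * max(sv$d, 0) * .Machine$double.eps)
  if (r >= p) {
    return(matrix(0, p, 0))
  }
  sv$v[, (r + 1):p, drop = FALSE]
}

#' Quasi-likelihood F-test for one or more contrasts
#'
#' Tests the null hypothesis that every contrast in `contrasts` is zero, per
#' gene. The constrained model projects the design onto the orthogonal
#' complement of the contrast space; the statistic is the deviance difference
#' between constrained and full NB fits (at the trended dispersion) divided by
#' `df1` times the squeezed QL dispersion, referred to an F distribution with
#' `df1` and `df_prior + df_residual` degrees of freedom.
#'
#' @inheritParams fit_gene_models
#' @param dispersions a [estimate_dispersion()] result.
#' @param contrasts a `contrast_set` or numeric coefficient x contrast matrix
#'   (a single vector is treated as one contrast).
#' @param genes optional gene-id/index subset to test.
#' @return Tibble with one row per gene: `gene_id`, `f_stat`, `df1`, `df2`,
#'   `p_value`, plus one `log2fc_<contrast>` column per contrast (a plain
#'   `log2fc` column when a single contrast is tested).
#' @export
ql_f_test <- function(counts, design, offsets, dispersions, contrasts,
                      genes = NULL, tol = 1e-8, maxit = 50) {
  Y <- count_input_matrix(counts)
  X <- design_input_matrix(design)
  Cmat <- contrast_input_matrix(contrasts, X)
  if (any(colSums(Cmat != 0) == 0L)) abort("zero contrast vector")
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  ids <- rownames(Y)
  phi <- align_by_gene(dispersions$phi_trend, ids)
  s2 <- align_by_gene(dispersions$s2_post, ids)
  off <- as.numeric(offsets)
  full <- .nb_fit_genes_cpp(Y, X, off, phi, tol, maxit, FALSE, FALSE)
  df1 <- qr(Cmat)$rank
  K <- null_space_basis(t(Cmat))
  X0 <- X %*% K
  null <- .nb_fit_genes_cpp(Y, X0, off, phi, tol, maxit, FALSE, FALSE)
  f_stat <- pmax(as.numeric(null$deviance) - as.numeric(full$deviance), 0) /
    (df1 * s2)
  df2 <- dispersions$df_prior + dispersions$df_residual
  out <- tibble(gene_id = ids, f_stat = f_stat, df1 = df1, df2 = df2,
                p_value = pf(f_stat, df1, df2, lower.tail = FALSE))
  lfc <- full$coefficients %*% Cmat / log(2)
  if (ncol(Cmat) == 1L) {
    out$log2fc <- as.numeric(lfc)
  } else {
    colnames(lfc) <- paste0("log2fc_", colnames(Cmat))
    out <- dplyr::bind_cols(out, as_tibble(lfc))
  }
  out
}

contrast_input_matrix <- function(contrasts, X) {
  if (is.null(dim(contrasts))) {
    contrasts <- matrix(contrasts, ncol = 1,
                        dimnames = list(names(contrasts), "contrast"))
  }
  Cmat <- unclass(contrasts)
  attr(Cmat, "family") <- NULL
  if (nrow(Cmat) != ncol(X)) {
    abort("contrast rows must match design coefficients")
  }
  Cmat
}

align_by_gene <- function(x, ids) {
  if (!is.null(names(x)) && all(ids %in% names(x))) return(unname(x[ids]))
  if (length(x) == length(ids)) return(unname(x))
  abort("per-gene quantities cannot be aligned with the requested genes")
}
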