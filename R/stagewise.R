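#' Benjamini-Hochberg and Holm adjustments
#'
#' Thin, validated wrappers around the standard step-up (BH) and step-down
#' (Holm) adjustments.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "BH")
}

#' @rdname bh_adjust
#' @export
holm_adjust <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "holm")
}

check_pvalues <- function(p) {
  if (length(p) == 0L) abort("empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  invisible(p)
}

#' Screening stage: gene-level BH on omnibus p-values
#'
#' BH-adjusts the per-gene omnibus (global null) p-values, screens genes at
#' FDR level `alpha`, and computes the confirmation-stage level
#' `alpha_adj = alpha * R / G` (R screened genes out of G), the
#' overall-FDR-preserving adjustment used by stage-wise testing.
#'
#' @param omnibus_p named numeric vector: one omnibus p-value per gene.
#' @param alpha gene-level FDR target (default 0.05).
#' @return List with `screening` (tibble: `gene_id`, `p_screen`,
#'   `padj_screen`, `screened`), `alpha`, `alpha_adj`, `n_genes`,
#'   `n_screened`.
#' @export
screen_genes <- function(omnibus_p, alpha = 0.05) {
  check_pvalues(omnibus_p)
  ids <- names(omnibus_p)
  if (is.null(ids)) ids <- paste0("g", seq_along(omnibus_p))
  padj <- bh_adjust(omnibus_p)
  screened <- padj <= alpha
  G <- length(omnibus_p)
  R <- sum(screened)
  list(
    screening = tibble(gene_id = ids, p_screen = unname(omnibus_p),
                       padj_screen = unname(padj),
                       screened = unname(screened)),
    alpha = alpha, alpha_adj = alpha * R / G,
    n_genes = G, n_screened = R
  )
}

#' Confirmation stage: within-gene Holm at the adjusted level
#'
#' For each screened gene, Holm-adjusts its per-hypothesis p-values and flags
#' hypotheses with adjusted p at or below `alpha_adj`.
#'
#' @param per_hypothesis_p numeric matrix, rows = screened genes (rownames =
#'   gene ids), columns = hypotheses.
#' @param alpha_adj confirmation level from [screen_genes()].
#' @param screened_ids gene ids of the screened set; rows must belong to it.
#' @return List with `p_holm` and `significant` matrices of the same shape.
#' @export
confirm_hypotheses <- function(per_hypothesis_p, alpha_adj,
                               screened_ids = rownames(per_hypothesis_p)) {
  P <- as.matrix(per_hypothesis_p)
  if (is.null(rownames(P))) abort("rows must carry gene ids")
  if (!all(rownames(P) %in% screened_ids)) {
    abort("confirmation rows include non-screened gene(s)")
  }
  ph <- t(apply(P, 1, holm_adjust))
  if (ncol(P) == 1L) ph <- matrix(ph, ncol = 1, dimnames = dimnames(P))
  dimnames(ph) <- dimnames(P)
  list(p_holm = ph, significant = ph <= alpha_adj)
}

#' Stage-wise testing of a contrast family
#'
#' The full two-stage procedure for one hypothesis family: (1) screening — a
#' per-gene omnibus QL F-test of the family's stacked contrast matrix,
#' BH-adjusted, screened at FDR `alpha`; (2) confirmation — for screened genes
#' only, per-contrast QL F-tests, Holm-adjusted within gene, flagged at the
#' adjusted level `alpha * R / G`. The procedure controls the gene-level
#' (overall) FDR at `alpha`.
#'
#' @inheritParams ql_f_test
#' @param alpha gene-level FDR target (default 0.05).
#' @return An object of class `stagewise_result`: list with `screening` and
#'   `confirmation` tibbles (the latter has one row per gene x contrast;
#'   confirmation statistics are `NA` for non-screened genes), and scalars
#'   `alpha`, `alpha_adj`, `n_genes`, `n_screened`, `family`.
#' @export
stagewise_analysis <- function(counts, design, offsets, dispersions,
                               contrasts, alpha = 0.05) {
  Y <- count_input_matrix(counts)
  X <- design_input_matrix(design)
  Cmat <- contrast_input_matrix(contrasts, X)
  family <- attr(contrasts, "family")
  omni <- ql_f_test(Y, X, offsets, dispersions, Cmat)
  scr <- screen_genes(setNames(omni$p_value, omni$gene_id), alpha)
  cn <- colnames(Cmat)
  conf <- tidyr::expand_grid(gene_id = omni$gene_id, contrast = cn)
  lfc_cols <- if (ncol(Cmat) == 1L) "log2fc" else paste0("log2fc_", cn)
  lfc_long <- tibble(
    gene_id = rep(omni$gene_id, each = length(cn)),
    contrast = rep(cn, times = nrow(omni)),
    log2fc = as.numeric(t(as.matrix(omni[, lfc_cols])))
  )
  conf <- left_join(conf, lfc_long, by = c("gene_id", "contrast"))
  conf$p_value <- NA_real_
  conf$p_holm <- NA_real_
  conf$significant <- NA
  keep <- scr$screening$gene_id[scr$screening$screened]
  if (length(keep) > 0) {
    P <- matrix(NA_real_, length(keep), ncol(Cmat),
                dimnames = list(keep, cn))
    for (j in seq_len(ncol(Cmat))) {
      tj <- ql_f_test(Y, X, offsets, dispersions,
                      Cmat[, j, drop = FALSE], genes = keep)
      P[, j] <- tj$p_value
    }
    cf <- confirm_hypotheses(P, scr$alpha_adj, keep)
    long_idx <- match(paste(conf$gene_id, conf$contrast),
                      paste(rep(keep, times = ncol(Cmat)),
                            rep(cn, each = length(keep))))
    src <- tibble(p_value = as.numeric(P), p_holm = as.numeric(cf$p_holm),
                  significant = as.logical(cf$significant))
    hit <- !is.na(long_idx)
    conf$p_value[hit] <- src$p_value[long_idx[hit]]
    conf$p_holm[hit] <- src$p_holm[long_idx[hit]]
    conf$significant[hit] <- src$significant[long_idx[hit]]
  }
  structure(
    list(screening = scr$screening, confirmation = conf,
         alpha = alpha, alpha_adj = scr$alpha_adj,
         n_genes = scr$n_genes, n_screened = scr$n_screened,
         family = if (length(family)) family[1] else "custom"),
    class = "stagewise_result"
  )
}

#' @exportS3Method base::print
print.stagewise_result <- function(x, ...) {
  cat("stagewise_result (", x$family, "): ", x$n_screened, " of ",
      x$n_genes, " genes screened at FDR ", x$alpha,
      "; confirmation level ", signif(x$alpha_adj, 4), "\n", sep = "")
  nsig <- sum(x$confirmation$significant, na.rm = TRUE)
  cat(nsig, "significant gene x contrast flags\n")
  invisible(x)
}

#' Tidy a stage-wise result
#'
#' @param x a `stagewise_result`.
#' @param stage `"confirmation"` (default: one row per gene x contrast) or
#'   `"screening"` (one row per gene).
#' @param ... unused.
#' @export
tidy.stagewise_result <- function(x, stage = c("confirmation", "screening"),
                                  ...) {
  stage <- arg_match(stage)
  if (stage == "screening") x$screening else x$confirmation
}

#' @rdname tidy.stagewise_result
#' @export
glance.stagewise_result <- function(x, ...) {
  tibble(family = x$family, n_genes = x$n_genes, n_screened = x$n_screened,
         alpha = x$alpha, alpha_adj = x$alpha_adj,
         n_significant = sum(x$confirmation$significant, na.rm = TRUE))
}
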