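#' Plot MDS sample coordinates
#'
#' @param object an `mds_result`.
#' @param samples optional [sample_table()]; when given, points are coloured
#'   by brain part and shaped by species.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mds_result <- function(object, samples = NULL, ...) {
  pts <- object$points
  lab <- sprintf("dim %d (%.1f%%)", 1:2, 100 * object$var_explained[1:2])
  if (!is.null(samples)) {
    pts <- left_join(pts, as_tibble(samples), by = "sample_id")
    p <- ggplot2::ggplot(pts, ggplot2::aes(.data$dim1, .data$dim2,
                                           colour = .data$brain_part,
                                           shape = .data$species))
  } else {
    p <- ggplot2::ggplot(pts, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Dispersion trend plot (BCV-style)
#'
#' Gene-wise NB dispersions against average log2-CPM with the fitted trend.
#'
#' @param object a `dispersion_model`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dispersion_model <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$abundance)) +
    ggplot2::geom_point(ggplot2::aes(y = sqrt(.data$phi_gene)),
                        size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = sqrt(.data$phi_trend)),
                       colour = "red") +
    ggplot2::labs(x = "average log2-CPM",
                  y = "biological coefficient of variation") +
    ggplot2::theme_minimal()
}

#' P-value histograms of a stage-wise result
#'
#' Screening p-values plus, for screened genes, per-contrast confirmation
#' p-values.
#'
#' @param object a `stagewise_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.stagewise_result <- function(object, ...) {
  tab <- bind_rows(
    tibble(stage = "screening", p = object$screening$p_screen),
    tibble(stage = "confirmation",
           p = object$confirmation$p_value[!is.na(object$confirmation$p_value)])
  )
  ggplot2::ggplot(tab, ggplot2::aes(.data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), boundary = 0,
                            fill = "grey40") +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = "p-value", y = "genes") +
    ggplot2::theme_minimal()
}

#' Heatmap of the top screening genes
#'
#' @param object a `heatmap_data` from [top_gene_heatmap_data()].
#' @param ... unused.
#' @return A ggplot tile plot in the clustering order.
#' @export
autoplot.heatmap_data <- function(object, ...) {
  long <- heatmap_long(object)
  long$gene_id <- factor(long$gene_id,
                         levels = rownames(object$matrix)[object$row_order])
  long$sample_id <- factor(long$sample_id,
                           levels = colnames(object$matrix)[object$col_order])
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}
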