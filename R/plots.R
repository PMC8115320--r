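#' Enrichment scatter plot
#'
#' The conventional NGS ranking view: positive-pool count (x, log10)
#' against the positive/negative frequency ratio (y, log10), one point per
#' unique clone, with dashed lines marking the selection quadrant. Clones
#' absent from the negative pool (infinite ratio) are drawn at the top of
#' the panel with an open shape.
#'
#' @param object An `enrichment_table` from [enrichment_quadrant()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_table <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  finite_max <- max(tab$fold_ratio[is.finite(tab$fold_ratio)], 1)
  tab <- dplyr::mutate(tab,
    ratio_plot = dplyr::if_else(is.finite(.data$fold_ratio),
      .data$fold_ratio, finite_max * 10
    ),
    neg_absent = !is.finite(.data$fold_ratio)
  )
  ggplot2::ggplot(tab, ggplot2::aes(.data$count_pos, .data$ratio_plot)) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$in_quadrant, shape = .data$neg_absent),
      alpha = 0.6
    ) +
    ggplot2::geom_vline(
      xintercept = attr(object, "min_count"),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::geom_hline(
      yintercept = attr(object, "min_fold"),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(
      x = "positive-pool count",
      y = "positive/negative frequency ratio",
      colour = "in quadrant", shape = "absent in negative"
    ) +
    ggplot2::theme_minimal()
}

#' Motif-frequency separation plot for one scored candidate
#'
#' Shows the two motif-frequency samples whose separation the
#' rank-transformed Welch t-test scores: each admissible motif contributes
#' one frequency in the positive and one in the negative pool.
#'
#' @param object A `specificity_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.specificity_score <- function(object, ...) {
  prof <- object$profile
  long <- tidyr::pivot_longer(
    prof[c("cdr", "freq_pos", "freq_neg")],
    cols = c("freq_pos", "freq_neg"),
    names_to = "pool", values_to = "frequency"
  ) |>
    dplyr::mutate(pool = dplyr::if_else(.data$pool == "freq_pos", "positive", "negative"))
  ggplot2::ggplot(long, ggplot2::aes(.data$pool, .data$frequency)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$cdr), width = 0.15, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "motif frequency (unique sequences)",
      subtitle = if (object$unscorable) "unscorable" else sprintf(
        "log10 p = %.1f, d = %.2f", object$log10_p, object$d
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
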