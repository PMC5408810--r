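#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.replicate_variance <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$design_type, y = .data$variance,
                               fill = .data$design_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Probe design type",
                  y = "Beta variance across replicates") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.proportion_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$proportion,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatter plot of per-sample QC medians
#'
#' Plots the median log2 unmethylated against methylated signal per sample,
#' with the flagging cutoff shown as the usual diagonal.
#'
#' @param qc Result of [get_qc()].
#' @return A ggplot object.
#' @export
plot_qc <- function(qc) {
  cutoff <- attr(qc, "cutoff") %||% 10.5
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$m_median, y = .data$u_median,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = 2 * cutoff, slope = -1,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Median log2 methylated signal",
                  y = "Median log2 unmethylated signal",
                  colour = "Flagged") +
    ggplot2::theme_minimal()
}
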