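#' Plot a ROC curve
#'
#' @param object An `exo_roc` from [roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.exo_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc),
      subtitle = sprintf("%d cases vs %d controls", object$n_pos, object$n_neg)
    ) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of a screening contrast
#'
#' Log2 fold change against -log10 p per assay, coloured by pass status —
#' a quick audit of which markers survive the three screening filters.
#'
#' @param screen_result Tibble from [screen_contrast()] (or several
#'   stacked contrasts; the plot facets by contrast).
#' @param alpha Significance line to draw (default 0.05).
#' @return A ggplot.
#' @export
plot_screen <- function(screen_result, alpha = 0.05) {
  check_columns(screen_result, c("assay_id", "contrast", "log2_fc", "p_value", "pass"),
                "screen results")
  ggplot2::ggplot(screen_result,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$pass)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (high vs low group)",
                  y = expression(-log[10]~p), colour = "passes filters") +
    ggplot2::theme_minimal()
}

#' Plot risk scores by class
#'
#' Jittered coded risk scores per sample, split by true class, with the
#' fitted cut-off line — makes the coarse, integer-valued nature of the
#' coded score visible.
#'
#' @param scores Tibble with `sample_id`, `rsf` (e.g. from
#'   [risk_scores()]).
#' @param labels Logical or two-level vector of true classes, aligned with
#'   `scores`.
#' @param cutoff Optional fitted cut-off to draw.
#' @return A ggplot.
#' @export
plot_risk_scores <- function(scores, labels, cutoff = NULL) {
  check_columns(scores, c("sample_id", "rsf"), "risk scores")
  df <- dplyr::mutate(scores,
                      class = ifelse(as_case_logical(labels), "case", "control"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$rsf,
                                        colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.2, height = 0.05, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "risk score (RSF)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
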