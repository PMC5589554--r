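# ggplot2 visualisations for the main result types

#' Plot ROC curves from an evaluation report
#'
#' @param object An `eval_report` from [evaluate_models()].
#' @param ... Unused.
#' @return A ggplot object: one ROC curve per model with AUCs in the
#'   legend.
#' @export
autoplot.eval_report <- function(object, ...) {
  roc <- attr(object, "roc")
  lab <- setNames(sprintf("%s (AUC %.3f)", object$model, object$auc),
                  object$model)
  roc$model <- factor(lab[roc$model], levels = unname(lab))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Forest plot of stratified odds ratios
#'
#' @param object A `stratified_risk_table` from [stratify_risk()].
#' @param ... Unused.
#' @return A ggplot object: per-category OR with 95% CI on a log scale.
#' @export
autoplot.stratified_risk_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (95% CI)", y = NULL,
      subtitle = sprintf("P for trend = %.3g", attr(object, "p_trend"))) +
    ggplot2::theme_minimal()
}

#' Density of the genetic risk score by case status
#'
#' @param scores Score tibble (`sample_id`, `grs`).
#' @param phenotypes Phenotype tibble with `status`.
#' @param cutoff Optional vertical reference line (e.g. a high/low risk
#'   cutoff).
#' @return A ggplot object.
#' @export
plot_grs_distribution <- function(scores, phenotypes, cutoff = NULL) {
  d <- dplyr::inner_join(scores, phenotypes, by = "sample_id")
  d$group <- factor(ifelse(d$status == 1, "cases", "controls"),
                    levels = c("controls", "cases"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$grs, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::labs(x = "Genetic risk score", y = "Density", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}
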