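#' Scatter plot of the HNR-jitter feature space
#'
#' Jitter against HNR, coloured by risk label, with dashed threshold lines
#' at `hnr_min` (vertical) and `jitter_max` (horizontal). The low-risk
#' region is the lower-right quadrant: harmonic-rich voices (high HNR) with
#' stable pitch (low jitter).
#'
#' @param data A labelled tibble (use [assign_labels()] first if needed).
#' @param rule The [label_rule()] that generated the labels.
#' @param path Optional file path; when given the plot is also saved there.
#' @param aliases Alias map locating the rule columns.
#' @return A ggplot object.
#' @export
plot_feature_space <- function(data, rule = label_rule(), path = NULL,
                               aliases = default_aliases()) {
  hnr_col <- resolve_column(data, "hnr", aliases)
  jit_col <- resolve_column(data, "jitter", aliases)
  if (is.na(hnr_col) || is.na(jit_col)) stop_schema("rule columns not locatable")
  if (!"risk_label" %in% names(data)) data <- assign_labels(data, rule, aliases)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[hnr_col]], y = .data[[jit_col]],
                                          colour = factor(.data$risk_label))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = rule$hnr_min, linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = rule$jitter_max, linetype = "dashed",
                        colour = "purple") +
    ggplot2::scale_colour_manual(values = c(`0` = "#d62728", `1` = "#1f77b4"),
                                 labels = c(`0` = "low risk", `1` = "high risk")) +
    ggplot2::labs(x = "HNR (dB)", y = "jitter (fraction)", colour = NULL,
                  title = "HNR-jitter feature space with rule thresholds") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 5)
  p
}

#' Per-label distributions of the two rule features
#'
#' A two-panel histogram layout: HNR and jitter, faceted by feature, filled
#' by simulated risk label.
#'
#' @inheritParams plot_feature_space
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(data, rule = label_rule(), path = NULL,
                                       aliases = default_aliases()) {
  hnr_col <- resolve_column(data, "hnr", aliases)
  jit_col <- resolve_column(data, "jitter", aliases)
  if (is.na(hnr_col) || is.na(jit_col)) stop_schema("rule columns not locatable")
  if (!"risk_label" %in% names(data)) data <- assign_labels(data, rule, aliases)
  long <- tidyr::pivot_longer(
    dplyr::select(data, dplyr::all_of(c(hnr_col, jit_col)), "risk_label"),
    dplyr::all_of(c(hnr_col, jit_col)),
    names_to = "feature", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                          fill = factor(.data$risk_label))) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free", nrow = 1) +
    ggplot2::labs(x = NULL, y = "count", fill = "risk label",
                  title = "Rule-feature distributions by simulated label") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 4)
  p
}
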