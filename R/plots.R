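#' Plot cost-effectiveness acceptability curves
#'
#' One curve per strategy: probability of being the most cost-effective
#' option (highest net monetary benefit) across willingness-to-pay
#' thresholds.
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(
    curve,
    ggplot2::aes(x = .data$wtp, y = .data$probability, colour = .data$arm)
  ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (ZAR per DMFT averted)",
      y = "Probability cost-effective",
      colour = "Strategy",
      title = "Cost-effectiveness acceptability curves"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the joint PSA distribution of incremental cost and DMFT
#' averted (versus do-nothing), one cloud per strategy.
#'
#' @param samples A `psa_samples` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(samples) {
  df <- samples[samples$arm != "Do nothing", ]
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$dmft_averted, y = .data$total_cost, colour = .data$arm)
  ) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::labs(
      x = "DMFT averted vs do nothing",
      y = "Total cost (ZAR)",
      colour = "Strategy",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}
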