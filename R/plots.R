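# Figure helpers. All return ggplot objects; the numbers always come from
# the analysis objects, the plots are presentation only.

#' @importFrom rlang .data
NULL

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param dsa a [run_dsa()] result.
#' @param top number of parameters to display, by descending range.
#' @return a ggplot object.
#' @export
plot_tornado <- function(dsa, top = 10) {
  stopifnot(inherits(dsa, "dsa_result"))
  d <- utils::head(as.data.frame(dsa), top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(dsa, "base_outcome")
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_low,
                                       xend = .data$outcome_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "5-year savings per tested patient (USD)", y = NULL,
                  title = "One-way sensitivity of 5-year savings") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter of the PSA
#'
#' @param psa a [run_psa()] result.
#' @param wtp willingness-to-pay threshold drawn as a reference line
#'   (USD/QALY).
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 100000) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$results,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param curve a [ceac()] result.
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceac_curve"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Cumulative savings over the cost-impact horizon
#'
#' @param impact a [cost_impact()] data frame.
#' @return a ggplot object.
#' @export
plot_cumulative_savings <- function(impact) {
  ggplot2::ggplot(impact, ggplot2::aes(x = .data$year, y = .data$savings)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Year", y = "Cumulative savings per tested patient (USD)",
                  title = "Cumulative savings vs standard of care") +
    ggplot2::theme_minimal()
}
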