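# Optional ggplot2 figures mirroring the standard cost-effectiveness
# graphics: scatter on the CE plane with the 95% ellipse, acceptability
# curves, and the horizontal-bar tornado.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Cost-effectiveness plane with confidence ellipse
#'
#' @param psa A [run_psa()] result.
#' @param level Ellipse confidence level.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, level = 0.95) {
  need_ggplot()
  ell <- confidence_ellipse(psa$samples, level = level)
  ggplot2::ggplot(psa$samples,
                  ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_path(data = ellipse_boundary(ell), colour = "red") +
    ggplot2::labs(x = "Incremental QALY (per patient-year)",
                  y = "Incremental cost (euro per patient-year)",
                  title = sprintf("Cost-effectiveness plane, %d replicates",
                                  psa$n))
}

#' Cost-effectiveness acceptability curves
#'
#' @param curve A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  need_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(x = wtpt, y = acceptance,
                                      colour = scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay threshold (euro/QALY)",
                  y = "Acceptance probability", colour = NULL)
}

#' Tornado diagram of one-way ICER changes
#'
#' @param tornado A [univariate_tornado()] result.
#' @param top Number of most influential parameters shown.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15) {
  need_ggplot()
  df <- utils::head(as.data.frame(tornado), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low,
                                       xend = icer_high,
                                       y = parameter,
                                       yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (euro/QALY)", y = NULL,
                  title = "One-way sensitivity (+/-10%)")
}
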