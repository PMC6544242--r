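#' Plot an accuracy profile
#'
#' The conventional total-error display: relative bias per level (solid
#' line), the beta-expectation tolerance-interval bounds (dashed), and the
#' +/- lambda acceptance limits (dotted), against log10 concentration.
#'
#' @param profile an [accuracy_profile()].
#' @return A ggplot object.
#' @export
plot_accuracy_profile <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  lv <- profile$levels
  ggplot2::ggplot(lv, ggplot2::aes(x = .data$nominal)) +
    ggplot2::geom_hline(yintercept = c(-profile$lambda, profile$lambda),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$trueness - 100),
                       colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$trueness - 100),
                        colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rel_eti_low),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rel_eti_high),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "nominal concentration (ng/mL)",
      y = "relative error (%)",
      title = profile$analyte,
      subtitle = sprintf("beta = %g, lambda = %g%%, LLOQ %.3g, ULOQ %.4g",
                         profile$beta, profile$lambda, profile$lloq,
                         profile$uloq)
    ) +
    ggplot2::theme_minimal()
}
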