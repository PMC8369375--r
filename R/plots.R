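# Figure helpers (ggplot2 is suggested, not required).

#' Correlation and Bland-Altman plots for estimated vs reference pressure
#'
#' @param estimated,reference Paired pressures (mm Hg).
#' @param component Label used in titles.
#' @return A list of two ggplot objects (`correlation`, `bland_altman`).
#' @export
plot_agreement <- function(estimated, reference, component = "DBP") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  a <- agreement_metrics(estimated, reference)
  df <- data.frame(estimated = estimated, reference = reference,
                   mean_bp = (estimated + reference) / 2,
                   diff_bp = estimated - reference)
  corr <- ggplot2::ggplot(df, ggplot2::aes(x = reference, y = estimated)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      title = sprintf("%s: MAD %.2f mm Hg, RMSE %.2f mm Hg", component,
                      a$mad, a$rmse),
      x = "Reference (mm Hg)", y = "Estimated (mm Hg)")
  ba <- ggplot2::ggplot(df, ggplot2::aes(x = mean_bp, y = diff_bp)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = a$bias) +
    ggplot2::geom_hline(yintercept = c(a$loa_low, a$loa_high),
                        linetype = 2) +
    ggplot2::labs(title = sprintf("%s Bland-Altman: bias %.2f [%.2f, %.2f]",
                                  component, a$bias, a$loa_low, a$loa_high),
                  x = "Mean of methods (mm Hg)",
                  y = "Estimated - reference (mm Hg)")
  list(correlation = corr, bland_altman = ba)
}
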