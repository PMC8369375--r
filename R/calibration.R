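# Per-participant calibration of the linear transit-time model
# BP = K1/PTT + K2, fit independently per pressure component.

#' Fit the calibration model for one pressure component
#'
#' Ordinary least squares of the reference pressure on inverse transit
#' time: the slope of the line of best fit is K1 (mm Hg s) and the
#' intercept K2 (mm Hg).
#'
#' @param points data.frame with columns `task`, `ptt_s` and the reference
#'   pressures `DBP`, `MAP`, `SBP` (one row per kept task; at least 4 rows
#'   with at least 2 distinct transit times).
#' @param component `"DBP"`, `"MAP"` or `"SBP"`.
#' @return A `ptt_calibration`: list with `component`, `K1`, `K2`,
#'   `n_points`, `residuals`, `rmse` and the fitted `lm` summary pieces.
#' @export
fit_calibration <- function(points, component = c("DBP", "MAP", "SBP")) {
  component <- match.arg(component)
  if (!all(c("ptt_s", component) %in% names(points))) {
    stop("points must contain ptt_s and ", component)
  }
  if (nrow(points) < 4) {
    stop("insufficient tasks: need at least 4 calibration points, have ",
         nrow(points))
  }
  if (any(points$ptt_s <= 0)) stop("transit times must be positive")
  if (length(unique(round(points$ptt_s, 9))) < 2) {
    stop("degenerate calibration: transit times do not vary")
  }
  inv_ptt <- 1 / points$ptt_s
  fit <- stats::lm(points[[component]] ~ inv_ptt)
  co <- stats::coef(fit)
  structure(
    list(component = component, K1 = unname(co[2]), K2 = unname(co[1]),
         n_points = nrow(points), residuals = unname(stats::resid(fit)),
         rmse = sqrt(mean(stats::resid(fit)^2))),
    class = "ptt_calibration")
}

#' Estimate blood pressure from a transit time
#'
#' Applies the fitted model `BP = K1/PTT + K2`. For `K1 > 0` the estimate
#' decreases monotonically in PTT and tends to K2 as PTT grows.
#'
#' @param model A [fit_calibration()] result.
#' @param ptt_s Transit time(s) in seconds (positive).
#' @return Estimated pressure(s) in mm Hg.
#' @export
estimate_bp <- function(model, ptt_s) {
  if (any(!is.finite(ptt_s)) || any(ptt_s <= 0)) {
    stop("transit time must be positive")
  }
  model$K1 / ptt_s + model$K2
}
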