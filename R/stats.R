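# Agreement metrics, device grading, and the statistical battery for
# demographic and wavelength comparisons.

#' Agreement between estimated and reference pressures
#'
#' Mean absolute difference (MAD), root-mean-square error, Pearson
#' correlation, and Bland-Altman bias with 95% limits of agreement
#' (bias +/- 1.96 SD of the paired differences; both the half-width and the
#' full width are reported since either convention appears in the
#' literature).
#'
#' @param estimated,reference Equal-length paired numeric vectors (n >= 2).
#' @param grade_thresholds Passed to [ieee_grade()].
#' @return A one-row data.frame: `n`, `mad`, `rmse`, `pcc` (`NA` when
#'   either side is constant), `bias`, `loa_low`, `loa_high`, `loa_half`,
#'   `loa_width`, `grade`.
#' @export
agreement_metrics <- function(estimated, reference,
                              grade_thresholds = c(A = 5, B = 6, C = 7)) {
  if (length(estimated) != length(reference)) {
    stop("estimated and reference must have equal length")
  }
  n <- length(estimated)
  if (n < 2) stop("need at least 2 pairs")
  d <- estimated - reference
  mad <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  pcc <- if (stats::sd(estimated) == 0 || stats::sd(reference) == 0) {
    NA_real_   # undefined for a constant margin
  } else {
    stats::cor(estimated, reference)
  }
  sd_d <- stats::sd(d)
  bias <- mean(d)
  data.frame(n = n, mad = mad, rmse = rmse, pcc = pcc, bias = bias,
             loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
             loa_half = 1.96 * sd_d, loa_width = 2 * 1.96 * sd_d,
             grade = ieee_grade(mad, grade_thresholds),
             stringsAsFactors = FALSE)
}

#' Grade a mean absolute difference against the wearable cuffless standard
#'
#' Grading thresholds (configurable) follow the cuffless wearable
#' blood-pressure device standard: A for MAD <= 5 mm Hg, B <= 6, C <= 7,
#' D otherwise.
#'
#' @param mad_mm_hg Mean absolute difference(s), mm Hg (>= 0).
#' @param thresholds Named vector of upper MAD bounds for grades A, B, C.
#' @return Character grade(s) in `{"A","B","C","D"}`.
#' @export
ieee_grade <- function(mad_mm_hg, thresholds = c(A = 5, B = 6, C = 7)) {
  stopifnot(all(mad_mm_hg >= 0), !is.unsorted(thresholds))
  vapply(mad_mm_hg, function(m) {
    i <- which(m <= thresholds)
    if (length(i)) names(thresholds)[i[1]] else "D"
  }, character(1))
}

#' Mann-Whitney U test (Wilcoxon rank-sum), two-sided
#'
#' Exact enumeration p-value for small tie-free samples
#' (`n_x + n_y <= 12`), normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param x,y Non-empty numeric samples (unpaired).
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Wilcoxon signed-rank test on paired differences, two-sided
#'
#' Zero differences are removed; exact sign-pattern p-value for
#' `n <= 12` tie-free magnitudes, normal approximation otherwise. If every
#' difference is zero the test is degenerate and no p-value is produced.
#'
#' @param differences Numeric vector of paired differences.
#' @return List with `W`, `p`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[differences != 0]
  if (!length(d)) {
    return(list(W = NA_real_, p = NA_real_, method = "degenerate",
                degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       degenerate = FALSE)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against a normal law with sample-estimated mean
#' and SD, with the p-value taken from the standard KS distribution (the
#' procedure used throughout the analysis this package reimplements). The
#' estimated parameters make that p-value conservative; a
#' Lilliefors-corrected version is available via `lilliefors = TRUE`.
#'
#' @param x Numeric sample (n >= 4, non-constant).
#' @param alpha Significance level for the `normal` verdict.
#' @param lilliefors Use the Lilliefors correction.
#' @return List with `D`, `p`, `normal` (p >= alpha), `method`.
#' @export
ks_normality <- function(x, alpha = 0.05, lilliefors = FALSE) {
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  if (lilliefors) {
    ht <- nortest::lillie.test(x)
    list(D = unname(ht$statistic), p = ht$p.value,
         normal = ht$p.value >= alpha, method = "lilliefors")
  } else {
    ht <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    list(D = unname(ht$statistic), p = ht$p.value,
         normal = ht$p.value >= alpha, method = "ks_estimated_params")
  }
}

#' Pooled two-sample t test from summary statistics
#'
#' Unpaired two-tailed Student's t with pooled variance, computed from
#' group means, SDs and sizes (identical to the raw-data test, which
#' depends on the data only through these summaries).
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p`.
#' @export
t_test_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) return(list(t = 0, df = df, p = 1))
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare calibration coefficients across demographic groups
#'
#' Stratifies per-participant coefficients by obesity (BMI >= 30), sex,
#' race (black vs other) or age (under 40 vs 40 and over; 40 itself joins
#' the older group), checks normality per group with [ks_normality()] and
#' applies the Mann-Whitney U test (all four groupings are unpaired).
#'
#' @param calibration data.frame with `participant_id`, `component`, `K1`,
#'   `K2` (e.g. the `calibration` table of [run_study()], or the `truth`
#'   table of [simulate_cohort()] after [coefficients_long()]).
#' @param demographics data.frame with `participant_id`, `bmi`, `sex`,
#'   `race`, `age`.
#' @param grouping One of `"obesity"`, `"sex"`, `"race"`, `"age"`.
#' @param coefficient `"K1"` or `"K2"`.
#' @param component Pressure component to compare (default `"DBP"`, the
#'   component anchored to the diastolic foot fiducial).
#' @return A `ptt_group_comparison`: grouping, coefficient, per-group
#'   boxplot-ready summaries, normality outcomes, test used, `U`, `p`.
#' @export
compare_groups <- function(calibration, demographics,
                           grouping = c("obesity", "sex", "race", "age"),
                           coefficient = c("K1", "K2"),
                           component = "DBP") {
  grouping <- match.arg(grouping)
  coefficient <- match.arg(coefficient)
  cal <- calibration[calibration$component == component, ]
  d <- merge(cal, demographics, by = "participant_id")
  grp <- switch(grouping,
    obesity = ifelse(d$bmi >= 30, "obese", "nonobese"),
    sex = d$sex,
    race = ifelse(d$race == "black", "black", "other"),
    age = ifelse(d$age >= 40, "older", "younger"))
  v <- d[[coefficient]]
  lv <- sort(unique(grp))
  if (length(lv) != 2) stop("grouping does not split into two groups")
  g1 <- v[grp == lv[1]]; g2 <- v[grp == lv[2]]
  if (length(g1) < 3 || length(g2) < 3) {
    stop("need at least 3 participants per group")
  }
  normal <- vapply(list(g1, g2), function(g) {
    if (length(g) >= 4 && stats::sd(g) > 0) ks_normality(g)$normal else NA
  }, logical(1))
  mw <- mann_whitney_u(g1, g2)
  summ <- function(g) {
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(g), mean = mean(g), sd = stats::sd(g),
               q1 = q[1], median = q[2], q3 = q[3])
  }
  groups <- cbind(group = lv, rbind(summ(g1), summ(g2)))
  structure(
    list(grouping = grouping, coefficient = coefficient,
         component = component, groups = groups,
         normal = normal,
         test = "mann_whitney_u", U = mw$U, p = mw$p,
         values = split(v, grp)),
    class = "ptt_group_comparison")
}

#' @export
print.ptt_group_comparison <- function(x, ...) {
  cat(sprintf("<group comparison> %s %s by %s: U = %.1f, p = %.4g\n",
              x$component, x$coefficient, x$grouping, x$U, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Reshape a cohort truth table to the long calibration format
#'
#' @param truth `truth` table from [simulate_cohort()] (columns
#'   `K1_DBP`, `K2_DBP`, ...).
#' @return data.frame with `participant_id`, `component`, `K1`, `K2`.
#' @export
coefficients_long <- function(truth) {
  do.call(rbind, lapply(c("DBP", "MAP", "SBP"), function(cc) {
    data.frame(participant_id = truth$participant_id, component = cc,
               K1 = truth[[paste0("K1_", cc)]],
               K2 = truth[[paste0("K2_", cc)]], stringsAsFactors = FALSE)
  }))
}
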