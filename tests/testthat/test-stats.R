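# Agreement metrics, grading, and the statistical test battery.

test_that("agreement metrics: identity, constant offset, hand-computed case", {
  ref <- c(70, 80, 90, 100)
  a <- agreement_metrics(ref, ref)
  expect_equal(a$mad, 0)
  expect_equal(a$rmse, 0)
  expect_equal(a$pcc, 1)
  expect_equal(a$bias, 0)

  b <- agreement_metrics(ref + 2, ref)
  expect_equal(b$mad, 2)
  expect_equal(b$rmse, 2)
  expect_equal(b$bias, 2)
  expect_equal(b$loa_width, 0)

  est <- c(70, 80, 90, 100)
  refx <- c(72, 77, 91, 98)
  h <- agreement_metrics(est, refx)
  expect_equal(h$mad, 2)
  expect_equal(h$rmse, sqrt((4 + 9 + 1 + 4) / 4))
  expect_true(h$loa_low <= h$bias && h$bias <= h$loa_high)

  const <- agreement_metrics(rep(80, 4), refx)
  expect_true(is.na(const$pcc))
})

test_that("MAD never exceeds RMSE; equality only for equal magnitudes", {
  set.seed(41)
  for (i in 1:30) {
    est <- rnorm(20, 90, 8)
    ref <- rnorm(20, 90, 8)
    a <- agreement_metrics(est, ref)
    expect_lte(a$mad, a$rmse + 1e-12)
  }
  eq <- agreement_metrics(c(81, 79), c(80, 80))
  expect_equal(eq$mad, eq$rmse)
})

test_that("device grading matches the anchored examples and is monotone", {
  expect_identical(ieee_grade(2.90), "A")
  expect_identical(ieee_grade(5.36), "B")
  expect_identical(ieee_grade(10.0), "D")
  expect_identical(ieee_grade(c(0, 5, 5.01, 6, 6.5, 7, 7.2)),
                   c("A", "A", "B", "B", "C", "C", "D"))
  grades <- ieee_grade(seq(0, 12, by = 0.25))
  expect_true(!is.unsorted(match(grades, c("A", "B", "C", "D"))))
})

test_that("rank-sum test equals exhaustive enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, enumerate_mwu_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(42)
  for (i in 1:10) {
    x <- sample(seq(1, 40, by = 0.5), sample(3:5, 1))
    y <- sample(seq(0.25, 40, by = 0.5), sample(3:6, 1))
    y <- y[!y %in% x]
    if (length(y) < 2) next
    expect_equal(mann_whitney_u(x, y)$p, enumerate_mwu_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("identical samples give p near 1; approximation tracks enumeration", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_gte(mann_whitney_u(x, x)$p, 0.99)
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(6)
    y <- rnorm(6)
    exact <- enumerate_mwu_p(x, y)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("signed-rank test equals sign-pattern enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p, 0.25)
  expect_equal(r$p, enumerate_wsr_p(c(1, 2, 3)))
  set.seed(44)
  for (i in 1:8) {
    d <- sample(c(-1, 1), 7, TRUE) * sample(seq(0.5, 20, by = 0.5), 7)
    expect_equal(wilcoxon_signed_rank(d)$p, enumerate_wsr_p(d),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(-d)$p)
  }
  z <- wilcoxon_signed_rank(rep(0, 5))
  expect_true(z$degenerate)
  expect_true(is.na(z$p))
})

test_that("KS normality: accepts gaussian data, rejects separated bimodal", {
  set.seed(45)
  verdicts <- vapply(1:20, function(i) ks_normality(rnorm(1000))$normal,
                     logical(1))
  expect_gte(mean(verdicts), 0.9)
  bimodal <- c(rnorm(500, -5, 0.3), rnorm(500, 5, 0.3))
  expect_false(ks_normality(bimodal)$normal)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 4")
  expect_true(is.finite(ks_normality(rnorm(50), lilliefors = TRUE)$p))
})

test_that("pooled t from summaries reproduces the cohort-table p values", {
  height <- t_test_two_sample(173.9, 9.6, 26, 169.6, 11.5, 18)
  expect_equal(round(height$p, 2), 0.19)
  age <- t_test_two_sample(26.7, 3.7, 26, 44.1, 11.7, 18)
  expect_lt(age$p, 0.001)
  same <- t_test_two_sample(10, 2, 5, 10, 2, 5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("group comparison stratifies, tests normality, and routes to rank-sum", {
  co <- simulate_cohort(
    list(group_spec("nonobese", k1_dbp = c(2.4, 0.3), bmi = c(24, 2)),
         group_spec("obese", k1_dbp = c(1.2, 0.3), bmi = c(35, 3))),
    n_per_group = 15, seed = 19, waveforms = FALSE)
  cal <- coefficients_long(co$truth)
  cmp <- compare_groups(cal, co$demographics, "obesity", "K1")
  expect_identical(cmp$test, "mann_whitney_u")
  expect_lt(cmp$p, 0.05)
  expect_identical(nrow(cmp$groups), 2L)
  expect_length(cmp$normal, 2)

  demo40 <- data.frame(participant_id = sprintf("p%03d", 1:8),
                       bmi = 25, sex = "male", race = "other",
                       age = c(30, 35, 39, 40, 40, 45, 50, 55))
  cal40 <- data.frame(participant_id = demo40$participant_id,
                      component = "DBP", K1 = rnorm(8, 2, 0.1),
                      K2 = rnorm(8, 60, 1))
  cmp40 <- compare_groups(cal40, demo40, "age", "K1")
  expect_identical(unname(cmp40$groups$n), c(5L, 3L))  # 40 joins "older"
})
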