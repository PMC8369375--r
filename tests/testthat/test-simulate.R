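# Ground-truth generator: record identities, determinism, law structure.

test_that("ground-truth record identities hold exactly for any seed", {
  law <- default_law()
  for (seed in c(1, 99)) {
    sim <- simulate_session(law, noise_model(hr_sd = 4),
                            schedule = compact_schedule(20), seed = seed)
    b <- sim$truth$beats
    expect_equal(b$ao_time, b$r_time + law$pep_s)
    expect_equal(b$foot_time, b$ao_time + b$ptt_true)
    expect_equal(b$pat_true, b$foot_time - b$r_time)
  }
})

test_that("identical seeds reproduce the session; different seeds do not", {
  law <- default_law()
  nm <- noise_model()
  s1 <- simulate_session(law, nm, compact_schedule(15), seed = 3)
  s2 <- simulate_session(law, nm, compact_schedule(15), seed = 3)
  s3 <- simulate_session(law, nm, compact_schedule(15), seed = 4)
  expect_identical(s1$session$channels$ppg_ir$samples,
                   s2$session$channels$ppg_ir$samples)
  expect_false(identical(s1$session$channels$ppg_ir$samples,
                         s3$session$channels$ppg_ir$samples))
})

test_that("simulator output is always schema-valid", {
  for (seed in 1:3) {
    sim <- simulate_session(default_law(), noise_model(),
                            schedule = compact_schedule(15), seed = seed)
    expect_identical(nrow(validate_session(sim$session)), 0L)
  }
})

test_that("schedules with too few beats per task are rejected", {
  expect_error(
    simulate_session(default_law(), zero_noise(),
                     schedule = compact_schedule(8), seed = 1),
    "fewer than 12 beats")
})

test_that("raising true pressure strictly shortens the generated transit time", {
  K1 <- c(DBP = 2, MAP = 3, SBP = 4.5)
  K2 <- c(DBP = 64, MAP = 75, SBP = 96)
  maps <- c(sit_baseline = 85, stand_baseline = 90, rest = 95,
            mental_arithmetic = 100, cold_pressor = 105,
            recovery_early = 110, recovery_late = 115)
  law <- law_from_map_targets(K1, K2, maps)
  expect_true(all(diff(law$tasks$ptt_s) < 0))
  expect_true(all(law$tasks$DBP <= law$tasks$MAP))
  expect_true(all(law$tasks$MAP <= law$tasks$SBP))
})

test_that("law invariants are enforced", {
  expect_error(bp_law(c(DBP = -1, MAP = 3, SBP = 4.5),
                      c(DBP = 64, MAP = 75, SBP = 96),
                      c(rest = 0.2)), "positive")
  expect_error(bp_law(c(DBP = 2, MAP = 3, SBP = 4.5),
                      c(DBP = 64, MAP = 75, SBP = 96),
                      c(rest = 0.6)), "0.05")
  for (i in 1:20) {
    law <- random_law()
    expect_true(all(law$tasks$ptt_s > 0.05 & law$tasks$ptt_s < 0.5))
    expect_true(all(law$K1 >= 1 & law$K1 <= 3))
    expect_true(all(law$K2 >= 50 & law$K2 <= 75))
    expect_gte(diff(range(law$tasks$MAP)), 25)
  }
})

test_that("cohorts sample demographics per spec and classify obesity by BMI", {
  co <- simulate_cohort(
    list(group_spec("lean", bmi = c(26, 4)),
         group_spec("high_bmi", bmi = c(33, 4))),
    n_per_group = 10, seed = 8, waveforms = FALSE)
  expect_identical(nrow(co$demographics), 20L)
  expect_identical(co$demographics$obesity_class != "nonobese",
                   co$demographics$bmi >= 30)
  expect_identical(nrow(co$truth), 20L)
  expect_true(all(co$truth$K1_DBP > 0))
  expect_error(simulate_cohort(list(), 5), "no groups")
  expect_error(simulate_cohort(list(group_spec("a")), 0), "positive")
})
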