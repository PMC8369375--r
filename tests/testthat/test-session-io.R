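# Session container: schema validation and lossless file round trip.

make_tiny_session <- function(seed = 5) {
  simulate_session(default_law(), zero_noise(),
                   schedule = compact_schedule(15), seed = seed,
                   lag_samples = 40)$session
}

test_that("write/read round trip preserves samples and metadata", {
  ses <- make_tiny_session()
  path <- file.path(tempdir(), "ses-roundtrip")
  write_session(ses, path)
  back <- read_session(path)
  expect_setequal(names(back$channels), names(ses$channels))
  for (nm in names(ses$channels)) {
    a <- ses$channels[[nm]]$samples
    b <- back$channels[[nm]]$samples
    expect_equal(length(a), length(b))
    expect_lt(max(abs(a - b) / pmax(abs(a), 1)), 1e-9)
    expect_identical(back$channels[[nm]]$fs, ses$channels[[nm]]$fs)
  }
  expect_equal(back$channels$ppg_ir$wavelength_nm, 950)
  expect_null(back$channels$abp$wavelength_nm)
  expect_equal(back$annotations, ses$annotations)
  expect_equal(back$demographics$participant_id,
               ses$demographics$participant_id)
  expect_equal(back$demographics$bmi, ses$demographics$bmi,
               tolerance = 1e-12)
  unlink(path, recursive = TRUE)
})

test_that("writing an incomplete session names the missing channel", {
  ses <- make_tiny_session()
  ses$channels$abp <- NULL
  expect_error(write_session(ses, file.path(tempdir(), "ses-bad")), "abp")
})

test_that("two writes of the same session are byte-identical", {
  ses <- make_tiny_session()
  p1 <- file.path(tempdir(), "ses-a")
  p2 <- file.path(tempdir(), "ses-b")
  write_session(ses, p1)
  write_session(ses, p2)
  for (f in list.files(p1)) {
    expect_identical(unname(tools::md5sum(file.path(p1, f))),
                     unname(tools::md5sum(file.path(p2, f))))
  }
  unlink(c(p1, p2), recursive = TRUE)
})

test_that("corrupt channel files and version mismatches are rejected", {
  ses <- make_tiny_session()
  path <- file.path(tempdir(), "ses-corrupt")
  write_session(ses, path)
  f <- file.path(path, "channel-abp.csv")
  lines <- readLines(f)
  writeLines(lines[1:100], f)
  expect_error(read_session(path), "corrupt channel length")
  write_session(ses, path)
  mf <- file.path(path, "meta.json")
  meta <- jsonlite::read_json(mf)
  meta$format_version <- "0.0"
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, null = "null")
  expect_error(read_session(path), "version mismatch")
  expect_error(read_session(file.path(tempdir(), "nope")), "meta.json")
  unlink(path, recursive = TRUE)
})

test_that("unknown extra channels round trip untouched", {
  ses <- make_tiny_session()
  n <- length(ses$channels[[1]]$samples)
  ses$channels$ppg_sternum <- channel("ppg_sternum", sin(seq_len(n) / 50),
                                      wavelength_nm = 950)
  path <- file.path(tempdir(), "ses-extra")
  write_session(ses, path)
  back <- read_session(path)
  expect_true("ppg_sternum" %in% names(back$channels))
  expect_equal(back$channels$ppg_sternum$samples,
               ses$channels$ppg_sternum$samples, tolerance = 1e-12)
  unlink(path, recursive = TRUE)
})

test_that("validate_session flags schema violations and passes simulator output", {
  ses <- make_tiny_session()
  expect_identical(nrow(validate_session(ses)), 0L)

  bad <- ses
  bad$channels$scg_z$fs <- 500
  v <- validate_session(bad)
  expect_true(any(grepl("fs != 1000", v$message)))

  bad <- ses
  bad$annotations$start_s[2] <- bad$annotations$start_s[2] - 10
  v <- validate_session(bad)
  expect_true(any(grepl("overlapping", v$message)))

  bad <- ses
  bad$channels$abp$samples[5] <- NaN
  expect_true(any(grepl("non-finite", validate_session(bad)$message)))

  bad <- ses
  bad$demographics$bmi <- bad$demographics$bmi + 1
  expect_true(any(grepl("bmi", validate_session(bad)$message)))
})

test_that("obesity classes follow the BMI thresholds", {
  expect_identical(obesity_class(c(22, 29.9, 30, 34.9, 35, 39.9, 40, 48)),
                   c("nonobese", "nonobese", "I", "I", "II", "II",
                     "III", "III"))
})
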