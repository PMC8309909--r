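test_that("zero spread returns the configured means; draws are reproducible", {
  cfg <- cohort_config()
  cfg$coef_sd[] <- 0
  expect_equal(sample_subject_coefficients(cfg), cfg$coef_mean)
  expect_equal(sample_subject_coefficients(cfg)["aQRS", "D2front"], 738.9)

  cfg2 <- cohort_config()
  set.seed(99); a <- sample_subject_coefficients(cfg2)
  set.seed(99); b <- sample_subject_coefficients(cfg2)
  expect_identical(a, b)
})

test_that("coefficient draws center on the configured means", {
  cfg <- cohort_config()
  set.seed(123)
  draws <- replicate(1000, sample_subject_coefficients(cfg)["aQRS", "D2front"])
  se <- cfg$coef_sd["aQRS", "D2front"] / sqrt(1000)
  expect_lt(abs(mean(draws) - 738.9), 3 * se)
  draws_p <- replicate(200, sample_subject_coefficients(cfg))
  expect_true(all(draws_p >= 0))
})

test_that("a synthetic record has the requested duration and beat count", {
  set.seed(1)
  co <- reference_coefficients("volunteers")[, "D2front"]
  rec <- synth_record(co, position = 0, hr = 60, duration = 10)
  expect_length(rec$samples, 2500)
  truth <- attr(rec, "truth")
  expect_gte(length(truth$r_peaks), 9)
  expect_lte(length(truth$r_peaks), 11)
})

test_that("the reference position applies no distortion", {
  co <- reference_coefficients("volunteers")[, "D1back"]
  expect_identical(distort_coefficients(co, 0), co)
  set.seed(21)
  r_times <- rr_train(70, 20)
  a <- synth_record(co, 0, 70, 20, lead = "D1", side = "back", r_times = r_times)
  b <- synth_record(co, 0, 70, 20, lead = "D1", side = "back", r_times = r_times)
  expect_identical(a$samples, b$samples)
})

test_that("rendering is linear in the amplitude coefficient set", {
  co <- reference_coefficients("volunteers")[, "D2front"]
  co2 <- c(co, aS = unname(1000 - co[["aQRS"]]))
  co2_scaled <- co2
  co2_scaled[c("aP", "aQRS", "aT", "aS")] <- 2 * co2_scaled[c("aP", "aQRS", "aT", "aS")]
  r_times <- seq(0.5, 9.5, by = 1)
  a <- synth_record(co2, 0, 60, 10, r_times = r_times)
  b <- synth_record(co2_scaled, 0, 60, 10, r_times = r_times)
  expect_equal(b$samples, 2 * a$samples)
})

test_that("distortion grows with position and reproduces the distance ordering", {
  cfg <- cohort_config()
  set.seed(42)
  r_times <- rr_train(72, 60, cfg$rr_cv)
  co <- cfg$coef_mean[, "D2front"]
  r0 <- synth_record(co, 0, 72, 60, cfg, "D2", "front", r_times = r_times)
  p <- detect_r_peaks(remove_baseline(r0))
  ea0 <- compute_ensemble_average(remove_baseline(r0), p)
  d <- vapply(1:6, function(k) {
    rk <- synth_record(co, k, 72, 60, cfg, "D2", "front", r_times = r_times)
    eak <- compute_ensemble_average(remove_baseline(rk), p)
    dtw_align(ea0$mean, eak$mean)$distance
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  # calibrated against the published distance-by-position row for this lead
  target <- reference_dtw_distances("volunteers")["D2front", ]
  expect_true(all(d > 0.5 * target & d < 1.5 * target))
})

test_that("motion artifacts are seeded, scaled to the target SNR, and optional", {
  set.seed(31)
  co <- reference_coefficients("volunteers")[, "D3front"]
  rec <- synth_record(co, 0, 75, 30, lead = "D3")
  expect_identical(add_motion_artifact(rec, snr_db = Inf)$samples, rec$samples)
  set.seed(7); a <- add_motion_artifact(rec, snr_db = 5)
  set.seed(7); b <- add_motion_artifact(rec, snr_db = 5)
  expect_identical(a$samples, b$samples)
  # the clean-vs-contaminated SNR equals the target by construction
  set.seed(8)
  z <- add_motion_artifact(rec, snr_db = 0)
  expect_equal(snr_db(attr(z, "clean"), z$samples), 0, tolerance = 1e-10)
  set.seed(9)
  z10 <- add_motion_artifact(rec, snr_db = 10)
  expect_equal(snr_db(attr(z10, "clean"), z10$samples), 10, tolerance = 1e-10)
})

test_that("a full subject is reproducible from the master seed", {
  cfg <- cohort_config()
  make <- function() {
    set.seed(2024)
    s <- synth_subject(cfg, "sx")
    subject_record(s, "D2", "front", 3L, "rest", duration = 20, cfg = cfg)
  }
  a <- make(); b <- make()
  expect_identical(a$samples, b$samples)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
})

test_that("records round-trip through the CSV interface", {
  set.seed(5)
  co <- reference_coefficients("volunteers")[, "D1front"]
  rec <- synth_record(co, 2, 65, 8, lead = "D1", side = "front")
  tmp <- tempfile(fileext = ".csv")
  write_ecg_csv(rec, tmp)
  back <- read_ecg_csv(tmp)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_identical(back$lead, "D1")
  expect_identical(back$position, 2L)
  expect_equal(back$fs, 250)
})

test_that("overlapping waves are rejected", {
  co <- reference_coefficients("volunteers")[, "D2front"]
  co[c("dP", "dQRS", "dT")] <- c(400, 300, 400)
  expect_error(synth_record(co, 0, 60, 5), "overlap")
})
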