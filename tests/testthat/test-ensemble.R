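test_that("R peaks are found within 20 ms of generator truth on clean records", {
  set.seed(14)
  co <- reference_coefficients("volunteers")[, "D2front"]
  rec <- synth_record(co, position = 0, hr = 72, duration = 60)
  truth <- attr(rec, "truth")$r_peaks
  p <- detect_r_peaks(remove_baseline(rec))
  expect_lte(abs(length(p) - length(truth)), 1)
  m <- length(p)
  expect_lt(max(abs(p - truth[seq_len(m)])) / rec$fs, 0.020)
  expect_true(all(diff(p) >= 0.2 * rec$fs))
})

test_that("a flat record yields no peaks, flagged with a warning attribute", {
  p <- detect_r_peaks(ecg_record(rep(0.5, 1500), 250))
  expect_length(p, 0)
  expect_true(isTRUE(attr(p, "warning")))
  expect_error(detect_r_peaks(ecg_record(rnorm(100), 250)), "3 s")
})

test_that("baseline removal cancels offsets and slow wander, sparing the QRS", {
  set.seed(15)
  co <- reference_coefficients("volunteers")[, "D2front"]
  rec <- synth_record(co, 0, 70, 30)
  clean <- remove_baseline(rec)$samples
  # constant offset is eliminated to within a microvolt
  shifted <- rec; shifted$samples <- rec$samples + 0.8
  expect_lt(max(abs(remove_baseline(shifted)$samples - clean)), 1e-3)
  # 0.3 Hz sinusoidal wander attenuated by at least 20 dB
  t <- (seq_along(rec$samples) - 1) / rec$fs
  wander <- 0.4 * sin(2 * pi * 0.3 * t)
  noisy <- rec; noisy$samples <- rec$samples + wander
  resid <- remove_baseline(noisy)$samples - clean
  expect_lt(10 * log10(sum(resid^2) / sum(wander^2)), -20)
  # the complexes are barely attenuated (peak-to-peak)
  p2p <- function(x) diff(range(x))
  expect_lt(abs(p2p(clean) - p2p(rec$samples)) / p2p(rec$samples), 0.02)
  # a zero-mean clean train passes essentially unchanged away from the
  # record edges (filter start-up transients live there)
  zm <- rec; zm$samples <- rec$samples - mean(rec$samples)
  out <- remove_baseline(zm)$samples
  dev <- abs((out - median(out)) - (zm$samples - median(zm$samples)))
  interior <- (2 * rec$fs):(length(dev) - 2 * rec$fs)
  expect_lt(max(dev[interior]) / max(abs(rec$samples)), 0.02)
})

test_that("identical beats average to themselves with zero spread", {
  fs <- 250
  beat <- sin(pi * seq(0, 1, length.out = fs))^2
  x <- rep(beat, 8)
  rec <- ecg_record(x, fs)
  peaks <- seq(which.max(beat), length(x), by = fs)
  ea <- compute_ensemble_average(rec, peaks)
  expect_equal(max(ea$sd), 0)
  expect_equal(ea$window, fs)
  expect_equal(which.max(ea$mean), ea$fiducial)
  expect_error(compute_ensemble_average(rec, peaks[1]), "2 detected beats")
})

test_that("averaging suppresses i.i.d. noise like the square root of n", {
  set.seed(16)
  fs <- 250
  beat <- sin(pi * seq(0, 1, length.out = fs))^2
  n_beats <- 36
  sigma <- 0.2
  x <- rep(beat, n_beats) + rnorm(n_beats * fs, sd = sigma)
  peaks <- seq(which.max(beat), length(x), by = fs)
  ea <- compute_ensemble_average(ecg_record(x, fs), peaks)
  resid_sd <- sd(ea$mean - beat[(seq_along(ea$mean) + which.max(beat) -
                                   ea$fiducial - 1) %% fs + 1])
  expect_lt(abs(resid_sd - sigma / sqrt(ea$n_beats)), 0.2 * sigma / sqrt(ea$n_beats))
})

test_that("ensemble averaging is linear in the record", {
  set.seed(17)
  co <- reference_coefficients("volunteers")[, "D3back"]
  rec <- synth_record(co, 0, 68, 30, lead = "D3", side = "back")
  peaks <- detect_r_peaks(remove_baseline(rec))
  ea1 <- compute_ensemble_average(rec, peaks)
  rec3 <- rec; rec3$samples <- 3 * rec$samples
  ea3 <- compute_ensemble_average(rec3, peaks)
  expect_equal(ea3$mean, 3 * ea1$mean)
  expect_equal(ea3$sd, 3 * ea1$sd)
})

test_that("the averaged beat keeps the P-QRS-T order of the generator", {
  set.seed(18)
  co <- reference_coefficients("volunteers")[, "D2front"]
  rec <- synth_record(co, 0, 72, 120)
  rb <- remove_baseline(rec)
  ea <- compute_ensemble_average(rb, detect_r_peaks(rb))
  cf <- extract_coefficients(ea)
  expect_length(attr(cf, "missing"), 0)
  # P before R before T inside the window, by construction of the analysis
  expect_true(all(is.finite(cf)))
})

test_that("noiseless coefficients are recovered within five percent", {
  set.seed(19)
  for (ls in c("D2front", "D1back")) {
    lead <- substr(ls, 1, 2); side <- substring(ls, 3)
    co <- reference_coefficients("volunteers")[, ls]
    rec <- synth_record(co, 0, 72, 60, lead = lead, side = side)
    rb <- remove_baseline(rec)
    ea <- compute_ensemble_average(rb, detect_r_peaks(rb))
    got <- extract_coefficients(ea)
    relerr <- abs(as.numeric(got) - co) / co
    expect_lt(max(relerr), 0.05)
  }
})

test_that("normalized coefficients are invariant to amplitude scaling", {
  set.seed(20)
  co <- reference_coefficients("volunteers")[, "D2back"]
  rec <- synth_record(co, 0, 66, 40, lead = "D2", side = "back")
  rb <- remove_baseline(rec)
  peaks <- detect_r_peaks(rb)
  ea1 <- compute_ensemble_average(rb, peaks)
  rb2 <- rb; rb2$samples <- 2 * rb$samples
  ea2 <- compute_ensemble_average(rb2, peaks)
  expect_equal(as.numeric(extract_coefficients(ea2)),
               as.numeric(extract_coefficients(ea1)), tolerance = 1e-9)
})

test_that("durations convert to milliseconds per second of beat period", {
  # a beat period of 1 s with a 0.21 s T wave must report dT = 210 ms/s
  co <- reference_coefficients("volunteers")[, "D2front"]
  co["dT"] <- 210
  rec <- synth_record(co, 0, 60, 30, r_times = seq(0.5, 29, by = 1))
  rb <- remove_baseline(rec)
  ea <- compute_ensemble_average(rb, detect_r_peaks(rb))
  expect_equal(ea$rr_median, 1, tolerance = 0.01)
  cf <- extract_coefficients(ea)
  expect_equal(unname(cf["dT"]), 210, tolerance = 0.03 * 210)
})

test_that("an undetectable wave is flagged missing rather than zeroed", {
  co <- reference_coefficients("volunteers")[, "D2front"]
  co["aP"] <- 0   # no P wave rendered
  set.seed(22)
  rec <- synth_record(co, 0, 72, 40)
  rb <- remove_baseline(rec)
  ea <- compute_ensemble_average(rb, detect_r_peaks(rb))
  cf <- extract_coefficients(ea)
  expect_true("P" %in% attr(cf, "missing"))
  expect_true(is.na(cf["aP"]) && is.na(cf["dP"]) && is.na(cf["tP"]))
})
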