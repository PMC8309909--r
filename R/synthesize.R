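#' Default synthetic-cohort configuration
#'
#' Describes the synthetic volunteer cohort that stands in for ambulatory
#' recordings: 20 subjects sampled at 250 Hz, 5 min at rest and 5 min
#' walking, resting heart rates around 72 bpm with 3% log-normal RR jitter,
#' subject maximum amplitudes around 1.5 mV, and per-lead/side segment
#' coefficients drawn around the published cohort means and SDs.  Records at
#' displaced electrode positions apply the position-distortion model of
#' [distort_coefficients()] plus a beat-locked morphing wave whose
#' amplitudes are calibrated against the published distance-by-position
#' table; walking records receive the additive motion-artifact model of
#' [add_motion_artifact()].
#'
#' @return a nested configuration list.
#' @export
cohort_config <- function() {
  list(
    n_subjects = 20L, fs = 250,
    rest_s = 300, walking_s = 300,
    hr_bpm = c(mean = 72, sd = 8),
    rr_cv = 0.03,
    subject_amp_mV = c(mean = 1.5, sd = 0.2),
    lead_scale = c(D1 = 0.75, D2 = 1.0, D3 = 0.85),
    coef_mean = reference_coefficients("volunteers", "mean"),
    coef_sd = reference_coefficients("volunteers", "sd"),
    r_lobe_share = 0.6,
    distortion = list(
      # peak fractional coefficient drifts reached at position 6 (quadratic
      # growth in the position index)
      gain_max = c(aP = -0.08, aQRS = -0.04, aT = -0.06,
                   dP = 0.04, dQRS = 0.03, dT = 0.02),
      shift_max_ms_per_s = c(tP = 12, tQRS = 8),
      morph_cycles = c(D1 = 2, D2 = 3, D3 = 4),
      morph_mV = .default_morph_mV
    ),
    artifact = list(
      snr_db = c(mean = 8, sd = 3),
      position_cv = 0.2,
      mix = c(wander = 0.5, emg = 0.3, transient = 0.2)
    )
  )
}

#' Sample one subject's segment coefficients
#'
#' Draws the 8 x 6 coefficient matrix (coefficients by lead-side) from
#' independent normals truncated at zero around the configured means and
#' SDs.  With all SDs zero the configured means are returned exactly.
#'
#' @param cfg a [cohort_config()] list.
#' @return an 8 x 6 numeric matrix with the layout of
#'   [reference_coefficients()].
#' @export
sample_subject_coefficients <- function(cfg = cohort_config()) {
  m <- cfg$coef_mean
  s <- cfg$coef_sd
  draw <- m
  pos_sd <- s > 0
  if (any(pos_sd)) {
    # inverse-CDF truncation at zero
    p0 <- stats::pnorm(0, m[pos_sd], s[pos_sd])
    un <- stats::runif(sum(pos_sd), p0, 1)
    draw[pos_sd] <- stats::qnorm(un, m[pos_sd], s[pos_sd])
  }
  draw
}

#' Position-distortion of the segment coefficients
#'
#' Applies the multiplicative amplitude/duration drifts and additive timing
#' shifts of measurement position `k`: each drift grows quadratically from
#' zero at the reference position to its configured maximum at position 6,
#' reflecting that the first displaced position is nearly indistinguishable
#' from the reference while remote positions are strongly distorted.
#'
#' @param coeffs named numeric vector of the 8 coefficients for one
#'   lead/side.
#' @param position measurement position, 0-6.
#' @param cfg a [cohort_config()] list.
#' @return the distorted coefficient vector.
#' @export
distort_coefficients <- function(coeffs, position, cfg = cohort_config()) {
  stopifnot(position %in% 0:6)
  if (position == 0) return(coeffs)
  w <- (position / 6)^2
  g <- cfg$distortion$gain_max
  out <- coeffs
  out[names(g)] <- out[names(g)] * (1 + w * g)
  sh <- cfg$distortion$shift_max_ms_per_s
  out[names(sh)] <- out[names(sh)] + w * sh
  out
}

# beat template: raised-cosine (sin^2) lobes for P, R, S, T placed relative
# to the R peak at time 0.  `tau` is time in seconds relative to the R peak,
# `co` the physical parameters in seconds / mV.
.lobe <- function(tau, t0, d, amp) {
  inside <- tau >= t0 & tau < t0 + d
  y <- numeric(length(tau))
  y[inside] <- amp * sin(pi * (tau[inside] - t0) / d)^2
  y
}

.beat_template <- function(tau, co) {
  r_d <- co$r_share * co$dQRS
  s_d <- (1 - co$r_share) * co$dQRS
  qrs_on <- -r_d / 2
  y <- .lobe(tau, qrs_on, r_d, co$ampR) -
    .lobe(tau, qrs_on + r_d, s_d, co$ampS) +
    .lobe(tau, qrs_on - co$tP - co$dP, co$dP, co$ampP) +
    .lobe(tau, qrs_on + co$dQRS + co$tQRS, co$dT, co$ampT)
  y
}

#' Synthesize one ECG record
#'
#' Renders a parametric ECG from a segment-coefficient set: smooth
#' raised-cosine P and T lobes and a biphasic R/S complex, scaled and placed
#' per the normalized coefficients, concatenated over a log-normally
#' jittered RR train.  At a displaced measurement position the coefficients
#' are drifted by [distort_coefficients()] and a beat-locked morphing wave
#' (an integer number of sinusoid cycles per beat, vanishing at the beat
#' edges) is added with the calibrated per-position amplitude, emulating the
#' far-field waveform change seen when the montage moves away from the
#' reference placement.
#'
#' Amplitudes follow the convention that `aQRS` is the share of the beat's
#' peak-to-peak excursion carried by the R wave: the S trough carries the
#' complement `aS = 1000 - aQRS` unless an explicit `aS` element is present
#' in `coeffs`.  Rendering is linear in the amplitude set
#' (`aP`, `aQRS`, `aS`, `aT`).
#'
#' @param coeffs named vector of the 8 coefficients (optionally plus `aS`).
#' @param position measurement position 0-6 (0 = identity distortion).
#' @param hr heart rate, bpm.
#' @param duration record length, s.
#' @param cfg a [cohort_config()] list.
#' @param lead,side,subject,condition record metadata.
#' @param scale_mV physical scale: peak-to-peak amplitude (mV) the record
#'   attains when `aQRS + aS = 1000`.
#' @param r_times optional fixed R-peak times (s); when `NULL` a jittered
#'   train is drawn.  Records of one subject share a train, so that
#'   position-to-position differences reflect the distortion, not the
#'   rhythm.
#' @return an `ecg_record`; ground truth (R-peak sample indices, the true
#'   distorted coefficients, the nominal RR) is attached as attribute
#'   `truth`.
#' @export
synth_record <- function(coeffs, position = 0L, hr = 72, duration = 60,
                         cfg = cohort_config(), lead = "D2", side = "front",
                         subject = "s01", condition = "rest",
                         scale_mV = 1.5, r_times = NULL) {
  stopifnot(position %in% 0:6)
  fs <- cfg$fs
  co <- distort_coefficients(coeffs, position, cfg)
  aS <- if ("aS" %in% names(co)) co[["aS"]] else 1000 - co[["aQRS"]]
  rr0 <- 60 / hr
  span <- (co[["dP"]] + co[["tP"]] + co[["dQRS"]] + co[["tQRS"]] + co[["dT"]])
  if (span > 950)
    stop("coefficients imply waves overlapping beyond one beat period")
  phys <- list(
    dP = co[["dP"]] / 1000 * rr0, dQRS = co[["dQRS"]] / 1000 * rr0,
    dT = co[["dT"]] / 1000 * rr0, tP = co[["tP"]] / 1000 * rr0,
    tQRS = co[["tQRS"]] / 1000 * rr0,
    ampP = co[["aP"]] / 1000 * scale_mV,
    ampR = co[["aQRS"]] / 1000 * scale_mV,
    ampS = aS / 1000 * scale_mV,
    ampT = co[["aT"]] / 1000 * scale_mV,
    r_share = cfg$r_lobe_share
  )
  n <- round(duration * fs)
  x <- numeric(n)
  if (is.null(r_times)) r_times <- rr_train(hr, duration, cfg$rr_cv)
  r_times <- r_times[r_times < duration - 0.65 * rr0]
  m_cyc <- cfg$distortion$morph_cycles[[lead]]
  morph_amp <- if (position == 0) 0
  else cfg$distortion$morph_mV[paste0(lead, side), position]
  morph_sign <- if (side == "front") 1 else -1
  for (t_r in r_times) {
    i0 <- max(1L, floor((t_r - 0.4 * rr0) * fs) + 1L)
    i1 <- min(n, ceiling((t_r + 0.6 * rr0) * fs))
    if (i0 >= i1) next
    tau <- ((i0:i1) - 1) / fs - t_r
    seg <- .beat_template(tau, phys)
    if (morph_amp != 0) {
      phi <- tau / rr0          # beat phase in [-0.4, 0.6)
      ok <- phi >= -0.4 & phi < 0.6
      seg[ok] <- seg[ok] +
        morph_sign * morph_amp * sin(2 * pi * m_cyc * (phi[ok] + 0.4))
    }
    x[i0:i1] <- x[i0:i1] + seg
  }
  rec <- ecg_record(x, fs, lead = lead, position = position, side = side,
                    subject = subject, condition = condition)
  truth <- list(r_peaks = round(r_times * fs) + 1L,
                coefficients = co[.coef_names], rr0 = rr0,
                scale_mV = scale_mV, morph_mV = morph_amp)
  attr(rec, "truth") <- truth
  rec
}

#' Add motion artifacts to a record
#'
#' Contaminates a record with a three-component additive artifact: baseline
#' wander (sum of low-frequency sinusoids between 0.1 and 0.8 Hz), EMG-like
#' band-limited noise (15-45 Hz), and sparse electrode-motion transients
#' (smooth biphasic bumps at Poisson times).  The components are mixed at
#' the configured power ratios and the total is scaled so that the SNR of
#' the contaminated record against the clean input equals `snr_db` exactly.
#'
#' @param record an `ecg_record`.
#' @param snr_db target signal-to-noise ratio, dB; `Inf` (or a zero
#'   amplitude mix) returns the record unchanged.
#' @param cfg a [cohort_config()] list (mixing ratios).
#' @return the contaminated `ecg_record`; the clean samples are kept in
#'   attribute `clean`.
#' @export
add_motion_artifact <- function(record, snr_db = 8, cfg = cohort_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.finite(snr_db)) return(record)
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  t <- (seq_len(n) - 1) / fs

  nw <- 3L
  f <- stats::runif(nw, 0.1, 0.8)
  ph <- stats::runif(nw, 0, 2 * pi)
  wander <- colSums(matrix(stats::runif(nw, 0.5, 1), nw, n) *
                      sin(outer(2 * pi * f, t) + ph))

  bp <- signal::butter(2, c(15, 45) / (fs / 2), type = "pass")
  emg <- signal::filtfilt(bp, stats::rnorm(n))

  trans <- numeric(n)
  n_ev <- stats::rpois(1, 0.2 * n / fs)
  if (n_ev > 0) {
    at <- stats::runif(n_ev, 0, n / fs)
    for (j in seq_len(n_ev)) {
      w <- stats::runif(1, 0.3, 0.8)
      amp <- stats::rnorm(1)
      tau <- (t - at[j]) / w
      inside <- tau >= 0 & tau < 1
      trans[inside] <- trans[inside] +
        amp * sin(2 * pi * tau[inside]) * sin(pi * tau[inside])^2
    }
  }

  unitize <- function(z) if (sum(z^2) > 0) z / sqrt(mean(z^2)) else z
  mix <- cfg$artifact$mix
  art <- sqrt(mix[["wander"]]) * unitize(wander) +
    sqrt(mix[["emg"]]) * unitize(emg) +
    sqrt(mix[["transient"]]) * unitize(trans)
  p_art <- sum(art^2)
  if (p_art == 0) return(record)
  scale <- sqrt(sum(x^2) / (p_art * 10^(snr_db / 10)))
  out <- record
  out$samples <- x + scale * art
  attr(out, "clean") <- x
  attr(out, "truth") <- attr(record, "truth")
  out
}

#' Draw a jittered R-peak time train
#'
#' Log-normally jittered RR intervals with the configured coefficient of
#' variation, starting half a period into the record.
#'
#' @param hr heart rate, bpm.
#' @param duration train length, s.
#' @param cv coefficient of variation of the RR intervals.
#' @return numeric vector of R-peak times, s.
#' @export
rr_train <- function(hr, duration, cv = 0.03) {
  rr0 <- 60 / hr
  sd_log <- sqrt(log(1 + cv^2))
  out <- c()
  t_r <- 0.5 * rr0
  while (t_r < duration) {
    out <- c(out, t_r)
    t_r <- t_r + rr0 * exp(stats::rnorm(1, -sd_log^2 / 2, sd_log))
  }
  out
}

#' Generate one synthetic subject
#'
#' Draws the subject-level latent quantities: per-lead/side coefficient
#' matrix, heart rate, physical amplitude scale, artifact severity and
#' per-position artifact factors.
#'
#' @param cfg a [cohort_config()] list.
#' @param id subject identifier.
#' @return a list of class `synthetic_subject`; includes the subject's
#'   R-peak train `r_times`, shared by all of the subject's records.
#' @export
synth_subject <- function(cfg = cohort_config(), id = "s01") {
  co <- sample_subject_coefficients(cfg)
  hr <- max(45, stats::rnorm(1, cfg$hr_bpm[["mean"]], cfg$hr_bpm[["sd"]]))
  amp <- max(0.5, stats::rnorm(1, cfg$subject_amp_mV[["mean"]],
                               cfg$subject_amp_mV[["sd"]]))
  snr <- stats::rnorm(1, cfg$artifact$snr_db[["mean"]],
                      cfg$artifact$snr_db[["sd"]])
  pos_factor <- exp(stats::rnorm(7, 0, cfg$artifact$position_cv))
  r_times <- rr_train(hr, max(cfg$rest_s, cfg$walking_s), cfg$rr_cv)
  structure(
    list(id = id, coefficients = co, hr = hr, amp_mV = amp,
         artifact_snr_db = snr, artifact_pos_factor = pos_factor,
         r_times = r_times),
    class = "synthetic_subject"
  )
}

#' Render one record of a synthetic subject
#'
#' @param subj a `synthetic_subject`.
#' @param lead,side,position,condition record coordinates.
#' @param duration record length, s (defaults to the configured rest or
#'   walking duration).
#' @param cfg a [cohort_config()] list.
#' @return an `ecg_record` (with artifacts when `condition = "walking"`).
#' @export
subject_record <- function(subj, lead = "D2", side = "front", position = 0L,
                           condition = "rest", duration = NULL,
                           cfg = cohort_config()) {
  if (is.null(duration))
    duration <- if (condition == "rest") cfg$rest_s else cfg$walking_s
  ls <- paste0(lead, side)
  scale <- subj$amp_mV * cfg$lead_scale[[lead]]
  rec <- synth_record(subj$coefficients[, ls], position = position,
                      hr = subj$hr, duration = duration, cfg = cfg,
                      lead = lead, side = side, subject = subj$id,
                      condition = condition, scale_mV = scale,
                      r_times = subj$r_times)
  if (condition == "walking") {
    snr <- subj$artifact_snr_db -
      20 * log10(subj$artifact_pos_factor[position + 1L])
    rec <- add_motion_artifact(rec, snr_db = snr, cfg = cfg)
  }
  rec
}
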