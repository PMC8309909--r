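#' Construct an ECG record
#'
#' Lightweight container for one sampled lead signal plus its acquisition
#' metadata.
#'
#' @param samples numeric vector, mV.
#' @param fs sampling rate, Hz.
#' @param lead `"D1"`, `"D2"` or `"D3"`.
#' @param position measurement position 0-6.
#' @param side `"front"` or `"back"`.
#' @param subject subject identifier.
#' @param condition `"rest"` or `"walking"`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead = "D2", position = 0L,
                       side = "front", subject = "s01",
                       condition = "rest") {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(
    list(samples = as.numeric(samples), fs = fs, lead = lead,
         position = as.integer(position), side = side, subject = subject,
         condition = condition),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record: %s %s pos %d, %s, %.1f s at %g Hz\n",
              x$lead, x$side, x$position, x$condition,
              length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Detect R peaks
#'
#' Energy-based QRS detector: band-pass (5-25 Hz) to isolate the QRS band,
#' squared derivative, moving-window integration (120 ms), then peak
#' picking over an adaptive threshold with an enforced 200 ms refractory
#' period.  Peak positions are refined to the largest absolute deflection of
#' the band-passed signal near each energy peak, so the fiducial lands on
#' the R wave regardless of polarity.
#'
#' @param record an `ecg_record` (at least 3 s long).
#' @return integer vector of strictly increasing sample indices; empty, with
#'   attribute `warning = TRUE`, when no QRS energy is found.
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < 3 * fs) stop("record must be at least 3 s long")
  if (stats::sd(x) == 0) {
    out <- integer(0)
    attr(out, "warning") <- TRUE
    return(out)
  }
  bp <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  energy <- c(0, diff(xf))^2
  win <- max(3L, round(0.12 * fs))
  integ <- stats::filter(energy, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- 0.2 * stats::quantile(integ, 0.995)
  if (thr <= 0 || max(integ) == 0) {
    out <- integer(0)
    attr(out, "warning") <- TRUE
    return(out)
  }
  # candidate local maxima above threshold
  n <- length(integ)
  ismax <- integ > thr &
    integ >= c(-Inf, integ[-n]) & integ >= c(integ[-1], Inf)
  cand <- which(ismax)
  if (!length(cand)) {
    out <- integer(0)
    attr(out, "warning") <- TRUE
    return(out)
  }
  refr <- round(0.2 * fs)
  cand <- cand[order(integ[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (c0 in cand)
    if (!length(keep) || all(abs(keep - c0) >= refr)) keep <- c(keep, c0)
  keep <- sort(keep)
  # refine to the extreme deflection of the band-passed signal, using one
  # polarity for the whole record so that every beat aligns on the same
  # wave even when R and S are nearly equal
  half <- round(0.06 * fs)
  refine <- function(sgn) vapply(keep, function(p) {
    lo <- max(1L, p - half); hi <- min(length(x), p + half)
    as.integer(lo + which.max(sgn * xf[lo:hi]) - 1L)
  }, integer(1))
  first <- vapply(keep, function(p) {
    lo <- max(1L, p - half); hi <- min(length(x), p + half)
    xf[lo + which.max(abs(xf[lo:hi])) - 1L]
  }, numeric(1))
  sgn <- sign(sum(sign(first)))
  if (sgn == 0) sgn <- 1
  peaks <- refine(sgn)
  peaks <- sort(unique(peaks))
  # re-enforce refractory after refinement
  if (length(peaks) > 1L) {
    out <- peaks[1L]
    for (p in peaks[-1L]) if (p - out[length(out)] >= refr) out <- c(out, p)
    peaks <- out
  }
  peaks
}

#' Remove baseline wander
#'
#' Estimates the baseline with a two-stage running median (200 ms then
#' 600 ms), subtracts it, and removes the sub-hertz ripple the medians
#' leave behind by subtracting a zero-phase 0.5 Hz low-pass of the
#' residual.  Medians track offsets and drift robustly while passing the
#' QRS almost untouched (narrow deflections barely move a median), and the
#' final stage sits well below the cardiac spectrum, so away from the
#' record edges the complexes come through with negligible attenuation and
#' the per-beat median of the output sits at zero.
#'
#' @param record an `ecg_record`.
#' @return the baseline-corrected `ecg_record`.
#' @export
remove_baseline <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  w1 <- .odd(round(0.2 * fs))
  w2 <- .odd(round(0.6 * fs))
  if (length(x) <= w2) {
    record$samples <- x - stats::median(x)
    return(record)
  }
  base <- stats::runmed(stats::runmed(x, w1), w2)
  y <- x - base
  lp <- signal::butter(2, 0.5 / (fs / 2), type = "low")
  record$samples <- y - signal::filtfilt(lp, y)
  record
}

.odd <- function(n) if (n %% 2L == 0L) n + 1L else n

#' Compute the ensemble-average ECG
#'
#' Windows the record into beats of one median RR interval (40% before and
#' 60% after each R peak), aligns them at the fiducial R peak, and averages
#' pointwise.  The per-sample standard deviation envelope quantifies the
#' beat-to-beat variability around the mean waveform.  Beats whose local RR
#' deviates more than 25% from the median are excluded as rhythm outliers.
#'
#' @param record an `ecg_record`.
#' @param peaks R-peak sample indices from [detect_r_peaks()].
#' @return an object of class `ensemble_average`: `mean` and `sd` waveforms
#'   (mV), `fiducial` (sample index of the R peak inside the window),
#'   `window` (samples), `n_beats`, `fs`, `rr_median` (s).
#' @export
compute_ensemble_average <- function(record, peaks = detect_r_peaks(record)) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(peaks) < 2L) stop("at least 2 detected beats are required")
  x <- record$samples
  fs <- record$fs
  rr <- diff(peaks)
  rr_med <- stats::median(rr)
  win <- round(rr_med)
  pre <- round(0.4 * win)
  post <- win - pre
  local_rr <- c(rr[1], pmin(rr, c(rr[-1], rr[length(rr)])))
  usable <- which(peaks - pre >= 1 & peaks + post - 1 <= length(x) &
                    abs(local_rr - rr_med) <= 0.25 * rr_med)
  if (length(usable) < 2L) stop("fewer than 2 usable beats after windowing")
  beats <- vapply(peaks[usable],
                  function(p) x[(p - pre):(p + post - 1L)],
                  numeric(win))
  structure(
    list(mean = rowMeans(beats),
         sd = apply(beats, 1, stats::sd),
         fiducial = pre + 1L, window = win, n_beats = length(usable),
         fs = fs, rr_median = rr_med / fs),
    class = "ensemble_average"
  )
}

#' @export
print.ensemble_average <- function(x, ...) {
  cat(sprintf("ensemble_average: %d beats, window %d samples (%.0f ms), fiducial at %d\n",
              x$n_beats, x$window, 1000 * x$window / x$fs, x$fiducial))
  invisible(x)
}

#' Plot an ensemble-average ECG with its variability envelope
#'
#' @param x an `ensemble_average`.
#' @param ... passed to [plot()].
#' @export
plot.ensemble_average <- function(x, ...) {
  t <- (seq_along(x$mean) - x$fiducial) / x$fs
  plot(t, x$mean, type = "l", col = "blue", lwd = 2,
       xlab = "time from R peak (s)", ylab = "amplitude (mV)", ...)
  graphics::lines(t, x$mean + x$sd, lty = 2, col = "blue")
  graphics::lines(t, x$mean - x$sd, lty = 2, col = "blue")
  invisible(x)
}

# locate a unimodal lobe's support from its 50%-height crossings; exact for
# the raised-cosine (sin^2) lobes used throughout, and robust to noise.
# sign = +1 for positive lobes, -1 for troughs.  Returns NULL if the lobe
# never exceeds `floor_amp`.
.lobe_support <- function(y, fs, peak_at, sign = 1, floor_amp = 0) {
  w <- sign * y
  amp <- w[peak_at]
  if (!is.finite(amp) || amp <= floor_amp) return(NULL)
  half <- amp / 2
  il <- peak_at
  while (il > 1L && w[il - 1L] >= half) il <- il - 1L
  left <- if (il == 1L) 1
  else il - (w[il] - half) / (w[il] - w[il - 1L])
  ir <- peak_at
  n <- length(w)
  while (ir < n && w[ir + 1L] >= half) ir <- ir + 1L
  right <- if (ir == n) n
  else ir + (half - w[ir]) / (w[ir + 1L] - w[ir])
  hw_l <- peak_at - left
  hw_r <- right - peak_at
  list(onset = peak_at - 2 * hw_l, offset = peak_at + 2 * hw_r,
       amplitude = amp, peak = peak_at)
}

#' Extract normalized segment coefficients from an ensemble average
#'
#' Delineates the P wave, QRS complex and T wave of the mean beat and
#' reports the eight normalized segment coefficients: amplitudes `aP`,
#' `aQRS`, `aT` in \eqn{\mu}V per mV of the amplitude normalizer, durations
#' `dP`, `dQRS`, `dT` and inter-segment times `tP` (P offset to QRS onset)
#' and `tQRS` (QRS offset to T onset) in ms per s of beat period.
#'
#' The amplitude normalizer defaults to the peak-to-peak amplitude of the
#' mean beat, so that `aQRS` expresses the share of the excursion carried by
#' the R wave (its complement is the S trough); the beat period defaults to
#' the record's median RR.  Wave boundaries come from 50%-of-peak crossings
#' doubled outwards, which recovers the exact support of the smooth
#' raised-cosine wave shapes and degrades gracefully under noise.
#'
#' @param ea an `ensemble_average`.
#' @param norm amplitude normalizer, mV (default: peak-to-peak of the mean
#'   beat).
#' @param beat_period beat period, s (default: the median RR of the record).
#' @return an object of class `segment_coefficients`: named numeric vector
#'   of the 8 coefficients (`NA` where a wave was undetectable, flagged in
#'   the `missing` attribute), with the normalizer in attribute `norm_mV`.
#' @export
extract_coefficients <- function(ea, norm = NULL, beat_period = NULL) {
  stopifnot(inherits(ea, "ensemble_average"))
  y <- ea$mean
  fs <- ea$fs
  if (is.null(beat_period)) beat_period <- ea$rr_median
  if (is.null(norm)) norm <- diff(range(y))
  if (norm <= 0) stop("amplitude normalizer must be positive")
  base <- stats::median(y)
  yc <- y - base
  n <- length(yc)

  # R: dominant deflection near the fiducial; when the opposite trough is
  # nearly as large (deep-S morphologies) the earlier extreme is the R wave
  zone <- max(1L, ea$fiducial - round(0.08 * fs)):
    min(n, ea$fiducial + round(0.08 * fs))
  z_up <- zone[which.max(yc[zone])]
  z_dn <- zone[which.min(yc[zone])]
  a_up <- yc[z_up]; a_dn <- -yc[z_dn]
  r_at <- if (a_up >= 1.15 * a_dn) z_up
  else if (a_dn >= 1.15 * a_up) z_dn
  else min(z_up, z_dn)
  r_sign <- sign(yc[r_at])
  r <- .lobe_support(yc, fs, r_at, sign = r_sign)
  if (is.null(r)) stop("no identifiable QRS in the ensemble average")

  # S: opposite trough just after the R lobe
  s_zone <- min(n, ceiling(r$offset)):min(n, round(r$offset + 0.1 * fs))
  s_at <- s_zone[which.max(-r_sign * yc[s_zone])]
  s <- .lobe_support(yc, fs, s_at, sign = -r_sign,
                     floor_amp = 0.05 * r$amplitude)
  qrs_on <- r$onset
  qrs_off <- if (!is.null(s)) s$offset else r$offset

  # P: largest same-sign lobe before QRS onset
  missing <- character(0)
  p <- NULL
  p_hi <- floor(qrs_on) - max(1L, round(0.01 * fs))
  if (p_hi > 2L) {
    p_zone <- 1L:p_hi
    p_at <- p_zone[which.max(r_sign * yc[p_zone])]
    p <- .lobe_support(yc, fs, p_at, sign = r_sign,
                       floor_amp = 0.05 * r$amplitude)
    if (!is.null(p) && (p$onset < 1 || p$offset > qrs_on)) p <- NULL
  }
  if (is.null(p)) missing <- c(missing, "P")

  # T: largest same-sign lobe after QRS offset
  tt <- NULL
  t_lo <- ceiling(qrs_off) + max(1L, round(0.01 * fs))
  if (t_lo < n - 2L) {
    t_zone <- t_lo:n
    t_at <- t_zone[which.max(r_sign * yc[t_zone])]
    tt <- .lobe_support(yc, fs, t_at, sign = r_sign,
                        floor_amp = 0.05 * r$amplitude)
    if (!is.null(tt) && (tt$onset < qrs_off || tt$offset > n + 1)) tt <- NULL
  }
  if (is.null(tt)) missing <- c(missing, "T")

  to_ms_per_s <- function(samples) samples / fs / beat_period * 1000
  out <- c(
    aP = if (is.null(p)) NA_real_ else p$amplitude / norm * 1000,
    aQRS = r$amplitude / norm * 1000,
    aT = if (is.null(tt)) NA_real_ else tt$amplitude / norm * 1000,
    dP = if (is.null(p)) NA_real_ else to_ms_per_s(p$offset - p$onset),
    dQRS = to_ms_per_s(qrs_off - qrs_on),
    dT = if (is.null(tt)) NA_real_ else to_ms_per_s(tt$offset - tt$onset),
    tP = if (is.null(p)) NA_real_ else to_ms_per_s(qrs_on - p$offset),
    tQRS = if (is.null(tt)) NA_real_ else to_ms_per_s(tt$onset - qrs_off)
  )
  structure(out, missing = missing, norm_mV = norm,
            beat_period_s = beat_period, class = "segment_coefficients")
}

#' @export
print.segment_coefficients <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, 1))
  m <- attr(x, "missing")
  if (length(m)) cat("undetectable waves:", paste(m, collapse = ", "), "\n")
  invisible(x)
}
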