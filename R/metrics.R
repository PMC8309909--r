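#' Dynamic time warping alignment of two waveforms
#'
#' Aligns a comparison waveform to a reference waveform by dynamic time
#' warping.  The pointwise distance matrix is the squared sample difference
#' \eqn{D(x,y) = (s_{ref}(x) - s_{cmp}(y))^2}; the cumulative cost matrix
#' follows the standard three-neighbour recurrence
#' \eqn{C(x,y) = D(x,y) + \min\{C(x,y-1), C(x-1,y-1), C(x-1,y)\}}, and the
#' warp path is recovered by backtracking from \eqn{(m,n)} towards the
#' adjacent position of lowest accumulated cost (ties prefer the diagonal,
#' then the vertical step).  The warped signals `s1w`/`s2w` replay the two
#' inputs along the path, repeating samples where the path dwells.
#'
#' @param s_ref numeric vector, the reference waveform (mV).
#' @param s_cmp numeric vector, the waveform to compare (mV).
#' @return an object of class `dtw_result` with elements `cost` (the
#'   cumulative cost matrix, m x n), `path` (two-column integer matrix of
#'   (x, y) indices, monotone from (1,1) to (m,n)), `s1w`, `s2w` (the
#'   path-aligned signals, equal length), and `distance` (the scalar
#'   distance of [dtw_distance()], in \eqn{\mu}V when inputs are mV).
#' @seealso [dtw_distance()], [variation_percent()]
#' @export
#' @examples
#' r <- dtw_align(c(0, 1, 0), c(0, 0, 1, 0))
#' r$distance
dtw_align <- function(s_ref, s_cmp) {
  s_ref <- as.numeric(s_ref)
  s_cmp <- as.numeric(s_cmp)
  if (length(s_ref) == 0L || length(s_cmp) == 0L)
    stop("both waveforms must be non-empty")
  if (!all(is.finite(s_ref)) || !all(is.finite(s_cmp)))
    stop("waveforms must be finite")
  core <- .dtw_core(s_ref, s_cmp)
  path <- cbind(x = core$path_x, y = core$path_y)
  s1w <- s_ref[path[, 1L]]
  s2w <- s_cmp[path[, 2L]]
  res <- structure(
    list(cost = core$cost, path = path, s1w = s1w, s2w = s2w,
         m = length(s_ref), n = length(s_cmp)),
    class = "dtw_result"
  )
  res$distance <- dtw_distance(res)
  res
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW alignment: %d x %d samples, path length %d, distance %.4g uV\n",
              x$m, x$n, nrow(x$path), x$distance))
  invisible(x)
}

#' Scalar DTW distance in microvolts
#'
#' Reduces a DTW alignment to the scalar reported in the distance-by-position
#' tables: the mean absolute difference \eqn{mean |S1w - S2w|} between the
#' path-aligned signals, converted from mV to \eqn{\mu}V.  A first-power
#' statistic is used so the scalar carries \eqn{\mu}V units; it is zero iff
#' the aligned signals coincide, and a constant offset between the inputs is
#' reported verbatim (warping cannot reduce it).
#'
#' @param res a `dtw_result` from [dtw_align()], whose inputs were in mV.
#' @return scalar distance in \eqn{\mu}V.
#' @export
dtw_distance <- function(res) {
  stopifnot(inherits(res, "dtw_result"))
  mean(abs(res$s1w - res$s2w)) * 1000
}

#' Signal-to-noise ratio between a test and a reference record
#'
#' \eqn{SNR[dB] = 10 \log_{10}( \sum_i x_r(i)^2 / \sum_i (x_p(i) - x_r(i))^2 )}.
#'
#' @param xr numeric vector, the reference record.
#' @param xp numeric vector, the test record; same length as `xr`.
#' @return SNR in dB.
#' @export
snr_db <- function(xr, xp) {
  if (length(xr) != length(xp)) stop("records must have equal length")
  err <- sum((xp - xr)^2)
  if (err == 0) stop("records are identical: SNR is infinite")
  10 * log10(sum(xr^2) / err)
}

#' Percentage difference between two measures
#'
#' \eqn{\%Difference = |E_1 - E_2| / (\frac{1}{2}(E_1 + E_2)) \times 100}.
#'
#' @param e1,e2 scalar measures (or equal-length vectors, compared
#'   elementwise).
#' @return percentage difference(s).
#' @export
#' @examples
#' percent_difference(70.3, 82.9)  # 16.45
percent_difference <- function(e1, e2) {
  s <- e1 + e2
  if (any(s == 0)) stop("percentage difference undefined when E1 + E2 = 0")
  abs(e1 - e2) / (0.5 * s) * 100
}

#' Percentage similarity between two measures
#'
#' \eqn{\%Similarity = 100\% - \%Difference}.
#'
#' @inheritParams percent_difference
#' @return percentage similarity(-ies).
#' @export
percent_similarity <- function(e1, e2) 100 - percent_difference(e1, e2)

#' DTW variation relative to the reference amplitude
#'
#' The DTW distance between the two waveforms divided by the peak-to-peak
#' amplitude of the reference, in percent.  This is the scalar used to
#' summarize how much a motion-contaminated record at a displaced position
#' deviates from the (equally contaminated) reference-position record,
#' relative to the size of the signal itself.
#'
#' @param s_ref reference waveform (mV).
#' @param s_cmp comparison waveform (mV).
#' @return variation in percent.
#' @export
variation_percent <- function(s_ref, s_cmp) {
  p2p <- diff(range(s_ref))
  if (p2p == 0) stop("reference waveform is flat: variation undefined")
  res <- dtw_align(s_ref, s_cmp)
  (res$distance / 1000) / p2p * 100
}
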