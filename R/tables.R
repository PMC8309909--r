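#' Published reference tables used as inputs
#'
#' The study that this package reproduces printed a small number of summary
#' tables: the cell-model parameters per cardiac subdomain, the passive
#' tissue conductivities, the per-lead model-vs-volunteer similarities, the
#' segment coefficients of the computational model and of the volunteer
#' cohort at the reference electrode position, the DTW distances by
#' displaced position, and the SNR / variation summaries under walking.
#' These printed values are *inputs* to several analyses here (headline
#' scalars, generator defaults, distortion calibration targets), so they are
#' shipped as plain data frames.
#'
#' @name reference-tables
#' @keywords internal
NULL

# Cell-model parameters per heart subdomain (columns) -----------------------
.cell_param_table <- local({
  m <- rbind(
    a      = c(-0.60, 0.13, 0.13, 0.13, 0.13, 0.13, 0.13),
    b      = c(-0.30, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    c1     = c(1000.0, 2.6, 2.6, 2.6, 2.6, 2.6, 2.6),
    c2     = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    d      = c(0.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    e      = c(0.0660, 0.0132, 0.0132, 0.0050, 0.0022, 0.0047, 0.0060),
    k      = c(1000, 1000, 1000, 1000, 1000, 1000, 1000),
    sigma_e = c(0.5, 8.0, 0.5, 10.0, 15.0, 35.0, 8.0),
    sigma_i = c(0.5, 8.0, 0.5, 10.0, 15.0, 35.0, 8.0),
    A      = c(33.0, 140.0, 140.0, 140.0, 140.0, 140.0, 140.0),
    B      = c(-22.0, -85.0, -85.0, -85.0, -85.0, -85.0, -85.0),
    Ve0    = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    Vi0    = c(-65.0, -85.0, -85.0, -85.0, -85.0, -85.0, -85.0),
    u0     = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0)
  )
  colnames(m) <- c("SAN", "ATR", "AVN", "HIS", "BNL", "PKJ", "VTR")
  m
})

# Passive conductivities, mS/m ----------------------------------------------
.passive_conductivity <- c(
  HEART = 50, BLOOD = 700, LUNG = 40, MUSCLE = 200,
  FAT = 40, BONE = 6, TORSO = 200
)

.lead_side_levels <- c("D1front", "D1back", "D2front", "D2back", "D3front", "D3back")
.coef_names <- c("aP", "aQRS", "aT", "dP", "dQRS", "dT", "tP", "tQRS")

.similarity_table <- c(
  D1front = 89.3, D1back = 87.9, D2front = 87.0,
  D2back = 88.1, D3front = 88.2, D3back = 86.9
)

# Segment coefficients of the computational model, reference position.
# Amplitudes in uV per mV of subject maximum; durations/timings in ms per s.
.model_coefficients <- local({
  m <- cbind(
    D1front = c(70.3, 214.6, 233.6, 86.2, 71.8, 192.5, 51.7, 77.6),
    D1back  = c(82.9, 156.1, 165.1, 89.1, 77.6, 204.0, 51.7, 63.2),
    D2front = c(97.0, 873.2, 188.7, 83.3, 83.3, 212.6, 54.6, 34.5),
    D2back  = c(97.2, 852.4, 186.9, 92.0, 83.3, 209.8, 51.7, 43.1),
    D3front = c(112.6, 746.7, 178.6, 89.1, 80.5, 206.9, 40.2, 43.1),
    D3back  = c(109.6, 784.0, 170.6, 103.4, 92.0, 198.3, 31.6, 46.0)
  )
  rownames(m) <- .coef_names
  m
})

# Volunteer-cohort coefficient means and SDs, reference position ------------
.cohort_coefficient_mean <- local({
  m <- cbind(
    D1front = c(92.7, 544.0, 207.3, 95.3, 105.9, 214.6, 93.1, 89.6),
    D1back  = c(92.3, 558.5, 170.2, 107.7, 105.0, 227.5, 99.3, 97.0),
    D2front = c(68.5, 738.9, 93.1, 105.5, 101.2, 248.2, 98.3, 79.1),
    D2back  = c(67.0, 750.6, 93.7, 105.1, 103.1, 243.1, 97.5, 80.3),
    D3front = c(71.2, 735.0, 108.3, 103.9, 101.2, 238.7, 96.9, 73.5),
    D3back  = c(67.4, 743.7, 99.0, 101.8, 108.9, 242.1, 103.7, 88.4)
  )
  rownames(m) <- .coef_names
  m
})

.cohort_coefficient_sd <- local({
  m <- cbind(
    D1front = c(4.5, 8.1, 12.0, 1.6, 2.6, 2.5, 1.2, 2.6),
    D1back  = c(3.8, 10.1, 9.6, 1.5, 1.7, 5.1, 1.9, 3.0),
    D2front = c(3.2, 14.2, 4.4, 1.7, 1.8, 3.9, 1.9, 2.4),
    D2back  = c(2.6, 14.6, 5.6, 1.8, 1.9, 3.7, 2.6, 1.9),
    D3front = c(3.1, 14.8, 6.9, 1.5, 1.6, 3.9, 1.9, 1.6),
    D3back  = c(2.8, 14.7, 5.7, 2.0, 1.8, 7.4, 2.8, 2.3)
  )
  rownames(m) <- .coef_names
  m
})

# DTW distance (uV) by displaced position 1..6, volunteers ------------------
.cohort_dtw_mean <- local({
  m <- rbind(
    D1front = c(8.1, 88.7, 223.7, 271.7, 301.7, 263.5),
    D1back  = c(9.8, 59.0, 152.5, 184.8, 239.3, 196.1),
    D2front = c(1.0, 48.6, 145.8, 162.6, 233.1, 292.0),
    D2back  = c(0.9, 67.8, 140.0, 186.1, 270.7, 313.8),
    D3front = c(1.8, 94.1, 223.2, 389.9, 446.2, 488.9),
    D3back  = c(0.8, 64.3, 189.2, 243.6, 381.6, 453.0)
  )
  colnames(m) <- paste0("pos", 1:6)
  m
})

# DTW distance (uV) by displaced position 1..6, computational model ---------
.model_dtw <- local({
  m <- rbind(
    D1front = c(40.30, 116.41, 111.05, 141.46, 202.18, 141.45),
    D1back  = c(79.07, 135.30, 114.52, 130.26, 197.82, 170.27),
    D2front = c(55.97, 123.44, 275.74, 338.18, 326.10, 372.51),
    D2back  = c(32.15, 61.68, 101.80, 333.50, 361.46, 417.04),
    D3front = c(189.31, 259.32, 368.67, 424.79, 427.49, 583.20),
    D3back  = c(72.94, 150.58, 307.16, 421.65, 463.91, 544.57)
  )
  colnames(m) <- paste0("pos", 1:6)
  m
})

# SNR (dB) and DTW variation (%) under walking, volunteers ------------------
.cohort_snr_mean <- local({
  m <- rbind(
    D1 = c(-1.62, 0.84, 3.96, 4.80, -0.33, 2.19),
    D2 = c(-2.14, 2.72, 3.58, 7.25, 3.72, -1.08),
    D3 = c(1.03, 1.08, 2.68, 6.03, 3.89, 0.59)
  )
  colnames(m) <- paste0("pos", 1:6)
  m
})

.cohort_variation_mean <- local({
  m <- rbind(
    D1 = c(14.3, 18.2, 18.4, 21.1, 19.1, 19.6),
    D2 = c(12.9, 13.2, 13.8, 14.3, 15.3, 19.8),
    D3 = c(23.8, 37.9, 26.1, 25.3, 16.9, 21.7)
  )
  colnames(m) <- paste0("pos", 1:6)
  m
})

#' Reference segment-coefficient tables
#'
#' Returns the published 8 x 6 segment-coefficient table at the reference
#' electrode position, either for the computational volume-conductor model
#' (point values) or for the volunteer cohort (means, with SDs available).
#' Rows are the eight coefficients `aP, aQRS, aT, dP, dQRS, dT, tP, tQRS`
#' (amplitudes in \eqn{\mu}V per mV of subject maximum; durations and
#' timings in ms per s of beat period); columns are lead x side
#' (`D1front` ... `D3back`).
#'
#' @param source `"model"` for the computational-model table or
#'   `"volunteers"` for the cohort table.
#' @param what for `source = "volunteers"`, `"mean"` or `"sd"`.
#' @return a numeric matrix with coefficient rows and lead-side columns.
#' @export
#' @examples
#' reference_coefficients("volunteers")["aQRS", "D2front"]  # 738.9
reference_coefficients <- function(source = c("volunteers", "model"),
                                   what = c("mean", "sd")) {
  source <- match.arg(source)
  what <- match.arg(what)
  if (source == "model") {
    if (what == "sd") stop("the model table is deterministic; no SDs exist")
    return(.model_coefficients)
  }
  if (what == "mean") .cohort_coefficient_mean else .cohort_coefficient_sd
}

#' Reference per-lead model-vs-volunteer similarity percentages
#'
#' @return named numeric vector over the six lead-side series, in percent.
#' @export
reference_similarity <- function() .similarity_table

#' Reference DTW distances by displaced electrode position
#'
#' @param source `"volunteers"` (cohort means) or `"model"` (point values).
#' @return a 6 x 6 numeric matrix, lead-side rows by position 1..6, in
#'   \eqn{\mu}V.
#' @export
reference_dtw_distances <- function(source = c("volunteers", "model")) {
  source <- match.arg(source)
  if (source == "model") .model_dtw else .cohort_dtw_mean
}

#' Reference walking-condition SNR and DTW-variation summaries
#'
#' @param what `"snr"` (dB) or `"variation"` (percent).
#' @return a 3 x 6 numeric matrix, leads D1..D3 by position 1..6.
#' @export
reference_motion_tables <- function(what = c("snr", "variation")) {
  what <- match.arg(what)
  if (what == "snr") .cohort_snr_mean else .cohort_variation_mean
}
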