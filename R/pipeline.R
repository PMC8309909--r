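#' Per-lead similarity between two coefficient tables
#'
#' For every lead-side column, applies the percentage-difference /
#' similarity formulas to each of the 8 coefficients and averages, yielding
#' one similarity percentage per lead and side plus their overall mean.
#'
#' @param t1,t2 8 x 6 coefficient matrices (same layout as
#'   [reference_coefficients()]).
#' @return list with `per_lead` (named vector, percent) and `mean`.
#' @export
coefficient_similarity <- function(t1, t2) {
  stopifnot(identical(dim(t1), dim(t2)))
  per_lead <- vapply(seq_len(ncol(t1)), function(j)
    mean(percent_similarity(t1[, j], t2[, j])), numeric(1))
  names(per_lead) <- colnames(t1)
  list(per_lead = per_lead, mean = mean(per_lead))
}

#' Mean front-vs-back percentage difference of a coefficient table
#'
#' Applies the percentage-difference formula to each of the 24
#' (coefficient x lead) front/back mean pairs and averages.
#'
#' @param tab an 8 x 6 coefficient matrix with `front`/`back` column pairs.
#' @return mean percentage difference.
#' @export
#' @examples
#' front_back_difference(reference_coefficients("volunteers"))  # ~4.94
front_back_difference <- function(tab) {
  leads <- c("D1", "D2", "D3")
  d <- vapply(leads, function(l)
    percent_difference(tab[, paste0(l, "front")], tab[, paste0(l, "back")]),
    numeric(nrow(tab)))
  mean(d)
}

#' Record-level similarity between two waveforms
#'
#' Applies the percentage-difference / similarity formulas to the
#' root-mean-square amplitudes of two waveforms, giving a coefficient-free
#' similarity pathway for comparing ensemble-average beats directly.
#'
#' @param s1,s2 numeric waveforms (mV).
#' @return similarity in percent.
#' @export
waveform_similarity <- function(s1, s2) {
  percent_similarity(sqrt(mean(s1^2)), sqrt(mean(s2^2)))
}

#' Compare a model coefficient table with a cohort coefficient table
#'
#' Produces the headline scalars of the study: the per-lead and mean
#' model-vs-cohort similarity, and the mean front-vs-back percentage
#' difference of each table.
#'
#' @param model 8 x 6 model coefficient matrix.
#' @param cohort 8 x 6 cohort coefficient-mean matrix.
#' @return a list with `similarity` (see [coefficient_similarity()]),
#'   `front_back_model`, `front_back_cohort` (percent).
#' @export
compare_tables <- function(model, cohort) {
  stopifnot(identical(dim(model), dim(cohort)))
  list(similarity = coefficient_similarity(model, cohort),
       front_back_model = front_back_difference(model),
       front_back_cohort = front_back_difference(cohort))
}

# ensemble-average a lead series against a fixed set of fiducials, after
# baseline removal; returns the ensemble_average
.ea_of_series <- function(samples, fs, peaks, ...) {
  rec <- remove_baseline(ecg_record(samples, fs, ...))
  compute_ensemble_average(rec, peaks)
}

#' Run the simulated-model study
#'
#' Builds the volume conductor and electrode layout, runs the forward
#' simulation, and derives the model-side results: the reference-position
#' coefficient table (8 coefficients x 6 lead-sides) and the DTW
#' distance-by-position table (6 lead-sides x positions 1-6), together with
#' the per-series Spearman correlation between position index and distance.
#'
#' @param geometry a `torso_geometry` (default geometry when `NULL`).
#' @param layout an `electrode_layout` (default anthropometry when `NULL`).
#' @param duration,dt,fs,diffusion_scale,conduction_gain passed to
#'   [run_simulation()].
#' @param warmup_s leading simulated time excluded from beat analysis, s.
#' @return a list of class `model_study`: `coefficients`, `dtw`, `spearman`,
#'   `leads` (the long lead data frame) and the run settings.
#' @export
run_model_study <- function(geometry = NULL, layout = NULL,
                            duration = 4.8, dt = 1e-4, fs = 250,
                            diffusion_scale = 170,
                            conduction_gain = .conduction_gain,
                            warmup_s = 1.0) {
  if (is.null(geometry)) geometry <- build_torso_geometry()
  if (is.null(layout)) layout <- place_electrodes(geometry)
  sim <- run_simulation(geometry, layout, duration = duration, dt = dt,
                        fs = fs, diffusion_scale = diffusion_scale,
                        conduction_gain = conduction_gain)
  leads <- extract_leads(sim)
  keep <- leads$time > warmup_s
  leads <- leads[keep, ]

  get_series <- function(lead, pos, side) {
    sel <- leads$position == pos & leads$side == side
    leads[[lead]][sel]
  }
  # common fiducials per side from the reference-position leads
  peaks_of <- function(side) {
    for (lead in c("D2", "D1", "D3")) {
      rec <- remove_baseline(
        ecg_record(get_series(lead, 0, side), fs, lead = lead, side = side))
      p <- detect_r_peaks(rec)
      if (length(p) >= 2) return(p)
    }
    stop("no beats detectable at the reference position (side ", side, ")")
  }
  sides <- c("front", "back")
  peaks <- lapply(stats::setNames(sides, sides), peaks_of)

  coefs <- matrix(NA_real_, 8, 6, dimnames = list(.coef_names, .lead_side_levels))
  dtw <- matrix(NA_real_, 6, 6,
                dimnames = list(.lead_side_levels, paste0("pos", 1:6)))
  rho <- stats::setNames(numeric(6), .lead_side_levels)
  for (side in sides) {
    # amplitude normalizer: peak-to-peak of each lead's own reference EA
    for (lead in c("D1", "D2", "D3")) {
      ls <- paste0(lead, side)
      ea0 <- .ea_of_series(get_series(lead, 0, side), fs, peaks[[side]],
                           lead = lead, side = side)
      coefs[, ls] <- as.numeric(extract_coefficients(ea0))
      for (k in 1:6) {
        eak <- .ea_of_series(get_series(lead, k, side), fs, peaks[[side]],
                             lead = lead, side = side, position = k)
        dtw[ls, k] <- dtw_align(ea0$mean, eak$mean)$distance
      }
      rho[ls] <- stats::cor(1:6, dtw[ls, ], method = "spearman")
    }
  }
  structure(
    list(coefficients = coefs, dtw = dtw, spearman = rho, leads = leads,
         settings = list(duration = duration, dt = dt, fs = fs,
                         diffusion_scale = diffusion_scale,
                         warmup_s = warmup_s)),
    class = "model_study"
  )
}

#' @export
print.model_study <- function(x, ...) {
  cat("model_study\n\nreference-position coefficients:\n")
  print(round(x$coefficients, 1))
  cat("\nDTW distance vs position (uV):\n")
  print(round(x$dtw, 1))
  cat("\nSpearman(position, distance):", round(x$spearman, 3), "\n")
  invisible(x)
}

#' Run the synthetic-cohort study
#'
#' Generates the synthetic cohort with a fixed master seed, processes every
#' record through baseline removal, R-peak detection and ensemble
#' averaging, and assembles the cohort-side tables: reference-position
#' coefficient means and SDs, DTW distance by position (rest), SNR by
#' position and DTW variation by position (walking, front), plus the
#' per-subject recovered-vs-true coefficient errors at the reference
#' position.
#'
#' @param cfg a [cohort_config()] list.
#' @param seed master RNG seed; the full study is a pure function of
#'   (config, seed).
#' @param n_subjects number of subjects (default from config).
#' @param positions displaced positions to process (besides the reference).
#' @param conditions subset of `c("rest", "walking")`.
#' @param rest_s,walking_s record durations, s (default from config).
#' @return a list of class `cohort_study` with elements `coef_mean`,
#'   `coef_sd`, `dtw_mean`, `dtw_sd`, `snr_mean`, `snr_sd`,
#'   `variation_mean`, `variation_sd`, `recovery` (per-subject relative
#'   errors by coefficient), and `seed`.
#' @export
run_synthetic_cohort <- function(cfg = cohort_config(), seed = 1,
                                 n_subjects = cfg$n_subjects,
                                 positions = 1:6,
                                 conditions = c("rest", "walking"),
                                 rest_s = cfg$rest_s,
                                 walking_s = cfg$walking_s) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  fs <- cfg$fs
  leads <- c("D1", "D2", "D3")
  sides <- c("front", "back")
  nls <- length(.lead_side_levels)

  coef_rec <- array(NA_real_, c(8, nls, n_subjects),
                    dimnames = list(.coef_names, .lead_side_levels, NULL))
  coef_true <- coef_rec
  dtw_arr <- array(NA_real_, c(nls, 6, n_subjects),
                   dimnames = list(.lead_side_levels, paste0("pos", 1:6), NULL))
  snr_arr <- array(NA_real_, c(3, 6, n_subjects),
                   dimnames = list(leads, paste0("pos", 1:6), NULL))
  var_arr <- snr_arr

  for (si in seq_len(n_subjects)) {
    subj <- synth_subject(cfg, id = sprintf("s%02d", si))
    for (side in sides) {
      for (lead in leads) {
        ls <- paste0(lead, side)
        if ("rest" %in% conditions) {
          rec0 <- subject_record(subj, lead, side, 0L, "rest", rest_s, cfg)
          peaks <- detect_r_peaks(remove_baseline(rec0))
          ea0 <- .ea_of_series(rec0$samples, fs, peaks, lead = lead, side = side)
          coef_rec[, ls, si] <- as.numeric(extract_coefficients(ea0))
          coef_true[, ls, si] <- attr(rec0, "truth")$coefficients
          for (k in positions) {
            reck <- subject_record(subj, lead, side, k, "rest", rest_s, cfg)
            eak <- .ea_of_series(reck$samples, fs, peaks,
                                 lead = lead, side = side, position = k)
            dtw_arr[ls, k, si] <- dtw_align(ea0$mean, eak$mean)$distance
          }
        }
        if ("walking" %in% conditions && side == "front") {
          w0 <- subject_record(subj, lead, side, 0L, "walking", walking_s, cfg)
          peaks_w <- detect_r_peaks(remove_baseline(w0))
          eaw0 <- if (length(peaks_w) >= 2)
            .ea_of_series(w0$samples, fs, peaks_w, lead = lead, side = side)
          else NULL
          for (k in positions) {
            wk <- subject_record(subj, lead, side, k, "walking", walking_s, cfg)
            snr_arr[lead, k, si] <- snr_db(w0$samples, wk$samples)
            if (!is.null(eaw0)) {
              eawk <- try(.ea_of_series(wk$samples, fs, peaks_w,
                                        lead = lead, side = side,
                                        position = k), silent = TRUE)
              if (!inherits(eawk, "try-error"))
                var_arr[lead, k, si] <-
                  variation_percent(eaw0$mean, eawk$mean)
            }
          }
        }
      }
    }
  }

  msd <- function(a) list(mean = apply(a, 1:2, mean, na.rm = TRUE),
                          sd = apply(a, 1:2, stats::sd, na.rm = TRUE))
  cf <- msd(coef_rec); dt_ <- msd(dtw_arr); sn <- msd(snr_arr); va <- msd(var_arr)
  rel_err <- abs(coef_rec - coef_true) / coef_true * 100
  structure(
    list(coef_mean = cf$mean, coef_sd = cf$sd,
         dtw_mean = dt_$mean, dtw_sd = dt_$sd,
         snr_mean = sn$mean, snr_sd = sn$sd,
         variation_mean = va$mean, variation_sd = va$sd,
         recovery = rel_err, coef_recovered = coef_rec,
         coef_true = coef_true, seed = seed,
         settings = list(n_subjects = n_subjects, rest_s = rest_s,
                         walking_s = walking_s, positions = positions,
                         conditions = conditions)),
    class = "cohort_study"
  )
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("cohort_study: %d subjects (seed %s)\n\ncoefficient means:\n",
              x$settings$n_subjects, format(x$seed)))
  print(round(x$coef_mean, 1))
  if (!all(is.na(x$dtw_mean))) {
    cat("\nDTW distance vs position (uV):\n")
    print(round(x$dtw_mean, 1))
  }
  invisible(x)
}

#' Write a study's tables as CSV files with a JSON manifest
#'
#' @param study a `model_study` or `cohort_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- Filter(function(el) is.matrix(el) && is.numeric(el),
                 study[!(names(study) %in%
                           c("recovery", "coef_recovered", "coef_true"))])
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")))
  manifest <- list(class = class(study), settings = study$settings,
                   seed = study$seed, tables = names(tabs),
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
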