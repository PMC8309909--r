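#' Write an ECG record to CSV
#'
#' Two-column CSV (`time`, `mV`) with the record metadata in a commented
#' header, readable back with [read_ecg_csv()].
#'
#' @param record an `ecg_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g lead=%s position=%d side=%s subject=%s condition=%s",
                     record$fs, record$lead, record$position, record$side,
                     record$subject, record$condition), con)
  utils::write.table(
    data.frame(time = (seq_along(record$samples) - 1) / record$fs,
               mV = record$samples),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' @param path a file written by [write_ecg_csv()], or any two-column
#'   `time`, `mV` CSV (metadata then defaults, with `fs` inferred from the
#'   time column).
#' @return an `ecg_record`.
#' @export
read_ecg_csv <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list(fs = NULL, lead = "D2", position = 0L, side = "front",
               subject = "s01", condition = "rest")
  if (startsWith(first, "#")) {
    kv <- strsplit(trimws(sub("^#", "", first)), " ")[[1]]
    for (item in kv) {
      p <- strsplit(item, "=")[[1]]
      meta[[p[1]]] <- p[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs)
  else 1 / stats::median(diff(df$time))
  ecg_record(df$mV, fs, lead = meta$lead,
             position = as.integer(meta$position), side = meta$side,
             subject = meta$subject, condition = meta$condition)
}
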