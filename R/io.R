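# Plain-text I/O: recording CSVs (time_s + one column per muscle), cohort
# manifest JSON, and the long feature/coherence tables.

#' Write a recording to CSV
#'
#' Columns: `time_s`, then one column per channel (mV), header row, '.'
#' decimal separator.
#'
#' @param rec an [emg_recording].
#' @param path output file.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- nrow(rec$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec$fs)
  for (ch in rec$channels) df[[ch]] <- rec$samples[, ch]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path CSV as written by [write_recording_csv()].
#' @return An [emg_recording]; the sampling rate is inferred from the
#'   `time_s` column.
#' @export
read_recording_csv <- function(path) {
  df <- read.csv(path)
  if (!"time_s" %in% names(df)) stop("CSV lacks a time_s column")
  fs <- 1 / median(diff(df$time_s))
  chans <- setdiff(names(df), "time_s")
  emg_recording(as.matrix(df[, chans, drop = FALSE]), fs = round(fs),
                channels = chans)
}

#' Write a cohort to disk
#'
#' One CSV per trial plus a JSON manifest (participant, condition, phase,
#' file, velocity, seed).
#'
#' @param cohort a `sprint_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sprint_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort$rows))
  for (r in seq_len(nrow(cohort$rows))) {
    f <- sprintf("%s_%s_%s.csv", cohort$rows$participant[r],
                 cohort$rows$condition[r], cohort$rows$phase[r])
    write_recording_csv(cohort$recordings[[r]], file.path(dir, f))
    files[r] <- f
  }
  manifest <- cbind(cohort$rows[, c("participant", "condition", "phase", "velocity")],
                    file = files, seed = cohort$seed)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(mpath)
}

#' Write / read the long feature and coherence tables
#'
#' @param x a data.frame ([extract_features()] / [compute_imc()] output).
#' @param path CSV path.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
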