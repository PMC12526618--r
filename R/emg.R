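# EMG conditioning and per-phase feature extraction: 20-450 Hz band-pass,
# full-wave rectification, 50 ms moving-RMS envelope, and the iEMG / RMS /
# median-frequency features computed per sprint phase.

#' Multichannel surface EMG recording
#'
#' Container for a sampled multichannel sEMG signal with phase markers.
#'
#' @param samples numeric matrix, one column per muscle channel (mV).
#' @param fs sampling rate in Hz.
#' @param channels channel labels; defaults to the column names of
#'   `samples` or `RA`, `BF`, `TA`, `GL`.
#' @param markers integer vector of phase boundary sample indices
#'   (start inclusive, end exclusive, 1-based); defaults to the whole
#'   recording as a single phase.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs,
                          channels = colnames(samples),
                          markers = c(1L, nrow(samples) + 1L)) {
  samples <- as.matrix(samples)
  if (is.null(channels)) channels <- c("RA", "BF", "TA", "GL")[seq_len(ncol(samples))]
  stopifnot(fs > 0, length(channels) == ncol(samples))
  markers <- as.integer(markers)
  if (is.unsorted(markers) || markers[1L] < 1L ||
      markers[length(markers)] > nrow(samples) + 1L) {
    stop("markers must be sorted sample indices within the recording")
  }
  colnames(samples) <- channels
  structure(list(samples = samples, fs = fs, channels = channels,
                 markers = markers),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels (%s), %d samples @ %g Hz (%.2f s)\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, 4th order overall
#' (two poles per band edge), the de-facto sEMG conditioning standard.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 20, high = 450) {
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below the Nyquist frequency ", fs / 2, " Hz")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Full-wave rectification
#'
#' @param x numeric signal.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Moving-RMS envelope
#'
#' Centered moving root-mean-square with a default 50 ms window. Windows
#' shrink at the edges (no padding), so no data is fabricated at phase
#' boundaries.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_ms window length in milliseconds (default 50).
#' @return Envelope of the same length as `x`.
#' @export
rms_smooth <- function(x, fs, window_ms = 50) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  win <- as.integer(round(window_ms / 1000 * fs))
  if (win < 1L) stop("window shorter than one sample at fs = ", fs, " Hz")
  half_lo <- (win - 1L) %/% 2L
  half_hi <- win - 1L - half_lo
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Per-phase EMG features: iEMG, RMS and median frequency
#'
#' Computes the three features over a phase span of a recording channel:
#' integrated EMG (time integral of the rectified signal, mV s), RMS
#' amplitude (mV), and median frequency of the Welch power spectrum within
#' the processing band (Hz). With `preprocess = TRUE` (default) the span is
#' band-pass filtered first; iEMG uses the rectified signal, MF the
#' filtered unrectified signal.
#'
#' @param rec an [emg_recording].
#' @param channel channel label.
#' @param span integer `c(start, end)` sample indices (inclusive); defaults
#'   to the whole recording.
#' @param preprocess band-pass filter the span before feature computation.
#' @param band processing band in Hz (default `c(20, 450)`), also the MF
#'   integration range.
#' @param segment_s Welch segment length (s) for the MF spectrum.
#' @return A one-row data.frame with columns `iemg`, `rms`, `mf`.
#' @export
features_for_phase <- function(rec, channel, span = NULL, preprocess = TRUE,
                               band = c(20, 450), segment_s = 0.5) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!channel %in% rec$channels) stop("unknown channel: ", channel)
  if (is.null(span)) span <- c(1L, nrow(rec$samples))
  span <- as.integer(span)
  if (span[1L] < 1L || span[2L] > nrow(rec$samples) || span[1L] > span[2L]) {
    stop("span outside recording")
  }
  x <- rec$samples[span[1L]:span[2L], channel]
  dur <- length(x) / rec$fs
  if (dur < 0.5) {
    stop(sprintf("phase span of %.3f s is too short for a reliable median frequency (need >= 0.5 s)", dur))
  }
  if (preprocess) x <- bandpass(x, rec$fs, band[1L], band[2L])
  if (all(x == 0)) stop("all-zero span: median frequency undefined")
  iemg <- sum(abs(x)) / rec$fs
  rms <- sqrt(mean(x^2))
  mf <- median_frequency(x, rec$fs, band = band, segment_s = segment_s)
  data.frame(iemg = iemg, rms = rms, mf = mf)
}

# Median frequency: frequency at which the cumulative PSD reaches half the
# total within `band`, linearly interpolated between Welch bins. Falls back
# to a single full-span periodogram when the span is shorter than one
# segment.
median_frequency <- function(x, fs, band = c(20, 450), segment_s = 0.5) {
  ps <- if (length(x) >= floor(segment_s * fs)) {
    welch_psd(x, fs, segment_s = segment_s)
  } else {
    periodogram_psd(x, fs)
  }
  keep <- ps$freqs >= band[1L] & ps$freqs <= band[2L]
  f <- ps$freqs[keep]
  p <- ps$psd[keep]
  if (length(f) < 2L || sum(p) <= 0) stop("no spectral mass in the MF band")
  cum <- cumsum(p)
  half <- cum[length(cum)] / 2
  i <- which(cum >= half)[1L]
  if (i == 1L) return(f[1L])
  f[i - 1L] + (f[i] - f[i - 1L]) * (half - cum[i - 1L]) / (cum[i] - cum[i - 1L])
}

#' Extract the feature table for a synthetic cohort
#'
#' Runs [features_for_phase()] for every (trial, channel) of a cohort.
#'
#' @param cohort a `sprint_cohort` from [generate_cohort()].
#' @param channels channels to extract (default all four muscles).
#' @return Long data.frame: participant, condition, phase, channel, iemg,
#'   rms, mf.
#' @export
extract_features <- function(cohort, channels = NULL) {
  stopifnot(inherits(cohort, "sprint_cohort"))
  out <- vector("list", nrow(cohort$rows))
  for (r in seq_len(nrow(cohort$rows))) {
    rec <- cohort$recordings[[r]]
    chs <- if (is.null(channels)) rec$channels else channels
    fe <- do.call(rbind, lapply(chs, function(ch) {
      cbind(channel = ch, features_for_phase(rec, ch))
    }))
    out[[r]] <- cbind(cohort$rows[r, c("participant", "condition", "phase")],
                      fe, row.names = NULL)
  }
  do.call(rbind, out)
}
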