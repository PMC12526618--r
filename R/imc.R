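# Intermuscular coherence: Welch cross-spectra, magnitude-squared coherence
# |Sxy|^2 / (Sxx Syy), band averages in alpha/beta/gamma, and significance
# thresholds (fixed 0.5 flag and the analytic 95% confidence limit).

#' Frequency band definitions for intermuscular coherence
#'
#' alpha 8-15 Hz, beta 15-30 Hz, gamma 30-50 Hz. Band intervals are
#' half-open `[low, high)` so boundary bins are never double counted.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
imc_bands <- function() {
  list(alpha = c(8, 15), beta = c(15, 30), gamma = c(30, 50))
}

#' Muscle pairs analysed for intermuscular coherence
#' @return Named list of channel pairs.
#' @export
imc_pairs <- function() {
  list(`RA-BF` = c("RA", "BF"), `TA-GL` = c("TA", "GL"))
}

#' Welch-averaged auto- and cross-power spectral densities
#'
#' Hann-windowed, mean-detrended Welch estimate with `segment_s` second
#' segments and fractional overlap `overlap_frac`.
#'
#' @param x,y numeric signals of equal length.
#' @param fs sampling rate (Hz).
#' @param segment_s segment duration in seconds (default 0.5).
#' @param overlap_frac fractional overlap in `[0, 1)` (default 0.5).
#' @return An object of class `cross_spectra`: freqs, sxx, syy, complex
#'   sxy, and the realized segment count `n_segments`.
#' @export
cross_spectra <- function(x, y, fs, segment_s = 0.5, overlap_frac = 0.5) {
  cs <- welch_cross(x, y, fs, segment_s, overlap_frac)
  structure(cs, class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("<cross_spectra> %d bins up to %g Hz, L = %d segments\n",
              length(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' Magnitude-squared coherence spectrum
#'
#' Pointwise `|Sxy|^2 / (Sxx * Syy)`. Bins with zero auto-power map to
#' coherence 0 (with a warning) so band averages are always defined.
#'
#' @param cs a [cross_spectra] object.
#' @return Object of class `coherence_spectrum` with `freqs`, `coh` in
#'   `[0, 1]` and `n_segments`.
#' @export
coherence_spectrum <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  denom <- cs$sxx * cs$syy
  coh <- numeric(length(denom))
  ok <- denom > 0
  if (!all(ok)) warning("zero-power bins mapped to coherence 0")
  coh[ok] <- Mod(cs$sxy[ok])^2 / denom[ok]
  # clip one-ulp overshoots from the ratio
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(freqs = cs$freqs, coh = coh, n_segments = cs$n_segments),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins, L = %d, mean coherence %.3f\n",
              length(x$freqs), x$n_segments, mean(x$coh)))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Unweighted mean of the coherence over frequency bins with
#' `low <= f < high`.
#'
#' @param spec a [coherence_spectrum].
#' @param band numeric `c(low, high)` in Hz.
#' @return Scalar band-mean coherence.
#' @export
band_average <- function(spec, band) {
  stopifnot(inherits(spec, "coherence_spectrum"), length(band) == 2L)
  keep <- spec$freqs >= band[1L] & spec$freqs < band[2L]
  if (!any(keep)) {
    stop("band [", band[1L], ", ", band[2L],
         ") contains no bins of the frequency grid")
  }
  mean(spec$coh[keep])
}

#' Coherence significance threshold
#'
#' Two conventions: the fixed flag threshold 0.5 used in the reporting
#' tables (`mode = "fixed"`), and the analytic 95% confidence limit for an
#' L-segment coherence estimate, `1 - alpha^(1/(L-1))` (`mode =
#' "analytic"`).
#'
#' @param L Welch segment count (needed for the analytic form, `L >= 2`).
#' @param alpha_level significance level for the analytic limit.
#' @param mode `"fixed"` or `"analytic"`.
#' @return Scalar threshold.
#' @export
significance_threshold <- function(L = NULL, alpha_level = 0.05,
                                   mode = c("fixed", "analytic")) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(0.5)
  if (is.null(L) || L < 2L) stop("analytic threshold requires L >= 2 segments")
  1 - alpha_level^(1 / (L - 1))
}

#' Band coherence for one muscle pair of a recording
#'
#' @param rec an [emg_recording].
#' @param pair character vector of two channel labels.
#' @param segment_s,overlap_frac Welch parameters.
#' @param threshold_mode `"fixed"` (0.5) or `"analytic"` per
#'   [significance_threshold()].
#' @return data.frame: pair, band, coherence, n_segments, significant.
#' @export
band_coherence <- function(rec, pair, segment_s = 0.5, overlap_frac = 0.5,
                           threshold_mode = "fixed") {
  stopifnot(inherits(rec, "emg_recording"), all(pair %in% rec$channels))
  cs <- cross_spectra(rec$samples[, pair[1L]], rec$samples[, pair[2L]],
                      rec$fs, segment_s, overlap_frac)
  spec <- coherence_spectrum(cs)
  bands <- imc_bands()
  vals <- vapply(bands, function(b) band_average(spec, b), numeric(1))
  thr <- significance_threshold(spec$n_segments, mode = threshold_mode)
  data.frame(pair = paste(pair, collapse = "-"),
             band = names(bands), coherence = unname(vals),
             n_segments = spec$n_segments,
             significant = unname(vals) > thr,
             row.names = NULL)
}

#' Intermuscular coherence table for a cohort
#'
#' One band-averaged coherence estimate per (trial, muscle pair, band).
#'
#' @param cohort a `sprint_cohort`.
#' @param pairs list of channel pairs (default [imc_pairs()]).
#' @param segment_s,overlap_frac Welch parameters.
#' @param threshold_mode significance convention, see [band_coherence()].
#' @return Long data.frame: participant, condition, phase, pair, band,
#'   coherence, n_segments, significant.
#' @export
compute_imc <- function(cohort, pairs = imc_pairs(), segment_s = 0.5,
                        overlap_frac = 0.5, threshold_mode = "fixed") {
  stopifnot(inherits(cohort, "sprint_cohort"))
  out <- vector("list", nrow(cohort$rows))
  for (r in seq_len(nrow(cohort$rows))) {
    rec <- cohort$recordings[[r]]
    bc <- do.call(rbind, lapply(pairs, function(p) {
      band_coherence(rec, p, segment_s, overlap_frac, threshold_mode)
    }))
    out[[r]] <- cbind(cohort$rows[r, c("participant", "condition", "phase")],
                      bc, row.names = NULL)
  }
  do.call(rbind, out)
}
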