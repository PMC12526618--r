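# Synthetic cohort generator. Common-drive model: per (muscle pair, band) a
# shared band-limited Gaussian source s is mixed into both channels as
#   x = kappa * s + sqrt(1 - kappa^2) * e_x,
# with e_x an independent, identically band-limited unit-variance noise.
# The expected magnitude-squared coherence in the band is then kappa^4, so
# a target coherence c is hit with kappa = c^(1/4). All channels carry
# additional independent 20-450 Hz broadband noise.

#' Mixing coefficient for a target band coherence
#'
#' Inverts the common-drive model: with both channels mixing a shared
#' unit-variance band-limited drive at weight `kappa` against independent
#' identically band-limited noises, expected band coherence is `kappa^4`;
#' hence `kappa = target^(1/4)`.
#'
#' @param target_coherence target band coherence in `[0, 1)`; vectorized.
#' @return Mixing coefficient(s) in `[0, 1)`.
#' @export
calibrate_mixing <- function(target_coherence) {
  if (any(target_coherence < 0 | target_coherence >= 1)) {
    stop("invalid parameter: target coherence must lie in [0, 1); ",
         "perfect coherence is unattainable with independent noise")
  }
  target_coherence^(1 / 4)
}

# Unit-variance band-limited Gaussian noise: white noise colored in the
# frequency domain by the zero-phase (forward-backward) response |H|^2 of
# the 4th-order Butterworth band-pass — spectrally identical to filtering
# with signal::filtfilt but O(n log n) with no edge transients (circular).
band_limited_noise <- function(n, fs, band) {
  nfft <- stats::nextn(n, c(2L, 3L, 5L))  # keep the FFT on composite lengths
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  w <- 2 * pi * seq(0L, nfft - 1L) / nfft
  ew <- exp(-1i * w)
  H <- outer(ew, seq_along(bf$b) - 1L, "^") %*% bf$b /
    (outer(ew, seq_along(bf$a) - 1L, "^") %*% bf$a)
  gain <- Mod(H)^2  # filtfilt's zero-phase amplitude response
  z <- Re(fft(fft(rnorm(nfft)) * gain, inverse = TRUE))[seq_len(n)] / nfft
  s <- sd(z)
  if (s < .Machine$double.eps) return(z)
  z / s
}

# One coherent channel pair for a single band: list(x, y) with expected
# band coherence kappa^4. Exposed for calibration experiments.
#' Simulate one coherent signal pair in a single band
#'
#' Generates two signals sharing a band-limited common drive mixed at
#' `kappa`, each with independent identically band-limited noise, plus
#' optional broadband (20-450 Hz) measurement noise. Expected band
#' coherence is `kappa^4` (slightly diluted by the broadband noise).
#'
#' @param kappa mixing coefficient in `[0, 1]`.
#' @param band `c(low, high)` Hz.
#' @param fs sampling rate (Hz).
#' @param duration_s duration in seconds.
#' @param broadband_sd sd of added 20-450 Hz noise (default 0).
#' @param seed optional integer seed.
#' @return list with elements `x` and `y`.
#' @export
simulate_coherent_pair <- function(kappa, band, fs = 1000, duration_s = 60,
                                   broadband_sd = 0, seed = NULL) {
  stopifnot(kappa >= 0, kappa <= 1)
  gen <- function() {
    n <- as.integer(round(duration_s * fs))
    s <- band_limited_noise(n, fs, band)
    e1 <- band_limited_noise(n, fs, band)
    e2 <- band_limited_noise(n, fs, band)
    x <- kappa * s + sqrt(1 - kappa^2) * e1
    y <- kappa * s + sqrt(1 - kappa^2) * e2
    if (broadband_sd > 0) {
      x <- x + broadband_sd * band_limited_noise(n, fs, c(20, 450))
      y <- y + broadband_sd * band_limited_noise(n, fs, c(20, 450))
    }
    list(x = x, y = y)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

phase_duration <- function(cfg, condition, phase) {
  vp <- cfg$velocity_params
  row <- vp[vp$condition == condition & vp$phase == phase, ]
  if (nrow(row) != 1L) stop("configuration error: unknown condition/phase: ",
                            condition, "/", phase)
  unname(cfg$phase_distances[[phase]]) / row$mean
}

lookup_target <- function(cfg, condition, phase, pair, band) {
  ct <- cfg$coherence_targets
  hit <- ct$condition == condition & ct$phase == phase &
    ct$pair == pair & ct$band == band
  if (!any(hit)) stop("configuration error: no coherence target for ",
                      paste(condition, phase, pair, band))
  ct$target[hit][1L]
}

# one standard normal draw truncated at +/- 3 sd (rejection; seed-stable)
rnorm_trunc3 <- function() {
  repeat {
    z <- rnorm(1)
    if (abs(z) <= 3) return(z)
  }
}

#' Generate one synthetic sprint trial
#'
#' Produces a 4-channel EMG recording for one (participant, condition,
#' phase) cell plus its phase velocity. Recording duration is phase
#' distance divided by the cell's mean velocity. For each muscle pair and
#' band a shared band-limited drive is mixed at the calibrated kappa; all
#' channels carry independent broadband noise.
#'
#' @param participant participant id.
#' @param condition,phase condition and phase labels.
#' @param cfg a [cohort_config()].
#' @param seed integer seed for this trial.
#' @param amp_factor multiplicative EMG amplitude factor (participant gain).
#' @param participant_effect additive participant velocity intercept (m/s).
#' @return list with `recording` ([emg_recording]) and `velocity` (m/s);
#'   in `"formula"` mode the velocity is `NA` and is filled in by
#'   [generate_cohort()] once features exist.
#' @export
generate_trial <- function(participant, condition, phase, cfg,
                           seed = cfg$seed, amp_factor = 1,
                           participant_effect = 0) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!condition %in% cfg$conditions) {
    stop("configuration error: unknown condition label '", condition, "'")
  }
  if (!phase %in% cfg$phases) {
    stop("configuration error: unknown phase label '", phase, "'")
  }
  withr::with_seed(as.integer(seed), {
    dur <- phase_duration(cfg, condition, phase)
    n <- as.integer(round(dur * cfg$fs))
    channels <- c("RA", "BF", "TA", "GL")
    X <- matrix(0, n, 4L, dimnames = list(NULL, channels))
    bands <- imc_bands()
    for (pname in names(imc_pairs())) {
      pr <- imc_pairs()[[pname]]
      for (bname in names(bands)) {
        kap <- calibrate_mixing(lookup_target(cfg, condition, phase, pname, bname))
        s <- band_limited_noise(n, cfg$fs, bands[[bname]])
        e1 <- band_limited_noise(n, cfg$fs, bands[[bname]])
        e2 <- band_limited_noise(n, cfg$fs, bands[[bname]])
        X[, pr[1L]] <- X[, pr[1L]] +
          cfg$band_amplitude * (kap * s + sqrt(1 - kap^2) * e1)
        X[, pr[2L]] <- X[, pr[2L]] +
          cfg$band_amplitude * (kap * s + sqrt(1 - kap^2) * e2)
      }
    }
    for (ch in channels) {
      X[, ch] <- X[, ch] + cfg$broadband_sd * band_limited_noise(n, cfg$fs, c(20, 450))
    }
    X <- X * amp_factor
    velocity <- NA_real_
    if (cfg$velocity_mode == "table") {
      vp <- cfg$velocity_params
      row <- vp[vp$condition == condition & vp$phase == phase, ]
      # residual sd carved so total SD reproduces the configured per-cell SD
      sd_resid <- sqrt(max(row$sd^2 - cfg$participant_sd^2, 1e-6))
      velocity <- row$mean + participant_effect + sd_resid * rnorm_trunc3()
    }
    list(recording = emg_recording(X, cfg$fs), velocity = velocity)
  })
}

trial_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + index) %% 2147483629)
}

#' Generate the full synthetic cohort
#'
#' Every (participant, condition, phase) cell gets a 4-channel recording
#' and a phase velocity. In `"table"` mode velocities are drawn from the
#' configured per-cell (mean, sd) with a shared participant intercept; in
#' `"formula"` mode the packaged reference equation is evaluated on the
#' features extracted from the generated signals, plus Gaussian noise of
#' sd `noise_sd_velocity`.
#'
#' @param cfg a [cohort_config()].
#' @return Object of class `sprint_cohort`: `rows` (data.frame with
#'   participant, condition, phase, velocity, duration_s, n_samples),
#'   `recordings` (list of [emg_recording]), `config`, `seed`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  validate_cohort_config(cfg)
  parts <- sprintf("P%02d", seq_len(cfg$n_participants))
  grid <- expand.grid(stringsAsFactors = FALSE,
                      phase = cfg$phases, condition = cfg$conditions,
                      participant = parts)
  grid <- grid[, c("participant", "condition", "phase")]
  grid <- grid[order(match(grid$participant, parts),
                     match(grid$condition, cfg$conditions),
                     match(grid$phase, cfg$phases)), ]
  rownames(grid) <- NULL
  peff <- withr::with_seed(cfg$seed, rnorm(cfg$n_participants, 0, cfg$participant_sd))
  pamp <- withr::with_seed(cfg$seed + 1L,
                           exp(rnorm(cfg$n_participants, 0, cfg$participant_amp_sd)))
  names(peff) <- names(pamp) <- parts
  recs <- vector("list", nrow(grid))
  vel <- numeric(nrow(grid))
  dur <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    tr <- generate_trial(grid$participant[r], grid$condition[r], grid$phase[r],
                         cfg, seed = trial_seed(cfg$seed, r),
                         amp_factor = pamp[[grid$participant[r]]],
                         participant_effect = peff[[grid$participant[r]]])
    recs[[r]] <- tr$recording
    vel[r] <- tr$velocity
    dur[r] <- nrow(tr$recording$samples) / cfg$fs
  }
  rows <- cbind(grid, velocity = vel, duration_s = dur,
                n_samples = vapply(recs, function(x) nrow(x$samples), integer(1)))
  cohort <- structure(list(rows = rows, recordings = recs, config = cfg,
                           seed = cfg$seed), class = "sprint_cohort")
  if (cfg$velocity_mode == "formula") {
    fm <- feature_matrix(cohort)
    noise <- withr::with_seed(trial_seed(cfg$seed, nrow(rows) + 1L),
                              rnorm(nrow(rows), 0, cfg$noise_sd_velocity))
    cohort$rows$velocity <-
      generate_velocity_from_formula(as.matrix(fm[, paste0("x", 1:9)]),
                                     noise_sd = 0) + noise
  }
  cohort
}

#' @export
print.sprint_cohort <- function(x, ...) {
  cat(sprintf("<sprint_cohort> %d rows (%d participants x %d conditions x %d phases), seed %d\n",
              nrow(x$rows), x$config$n_participants,
              length(x$config$conditions), length(x$config$phases), x$seed))
  invisible(x)
}

#' Velocity from the packaged reference equation
#'
#' Evaluates the packaged closed-form sprint-velocity equation (see
#' [reference_sprint_equation()]) on a feature vector or matrix and adds
#' Gaussian noise. Used as generative ground truth for model-recovery
#' experiments.
#'
#' @param features numeric vector of length 9 or matrix with 9 columns
#'   (x1..x9).
#' @param noise_sd Gaussian noise sd in m/s (default 0).
#' @param seed optional seed for the noise.
#' @return Velocity (m/s), one value per row.
#' @export
generate_velocity_from_formula <- function(features, noise_sd = 0, seed = NULL) {
  eqn <- reference_sprint_equation()
  y <- predict_symbolic(eqn, features)
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(length(y), 0, noise_sd) else
      withr::with_seed(as.integer(seed), rnorm(length(y), 0, noise_sd))
    y <- y + eps
  }
  y
}
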