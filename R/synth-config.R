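# Cohort configuration: study dimensions, per-cell velocity (mean, sd) and
# per-cell band-coherence targets for the common-drive simulator.

#' Default per-cell band-coherence targets
#'
#' Long table of target band-averaged coherence for each
#' (condition, phase, pair, band) cell of the study design. Targets above
#' `clamp` are clamped (magnitude-squared coherence cannot exceed 1, and a
#' noisy common-drive model cannot reach 1).
#'
#' @param clamp upper clamp for targets (default 0.95).
#' @return data.frame: condition, phase, pair, band, target.
#' @export
default_coherence_targets <- function(clamp = 0.95) {
  g <- expand.grid(stringsAsFactors = FALSE,
                   band = c("alpha", "beta", "gamma"),
                   pair = c("RA-BF", "TA-GL"),
                   phase = c("p0_30", "p30_60", "p60_100"))
  # columns: sham, m1_tdcs, dlpfc_tdcs; row order matches g
  vals <- rbind(
    c(0.20, 0.25, 0.18),  # p0_30  RA-BF alpha
    c(0.41, 0.48, 0.39),  #              beta
    c(0.88, 0.95, 0.82),  #              gamma
    c(0.12, 0.15, 0.10),  # p0_30  TA-GL alpha
    c(0.25, 0.30, 0.22),  #              beta
    c(0.68, 0.75, 0.65),  #              gamma
    c(0.24, 0.32, 0.20),  # p30_60 RA-BF alpha
    c(0.44, 0.55, 0.40),  #              beta
    c(0.55, 0.70, 0.50),  #              gamma
    c(0.09, 0.12, 0.08),  # p30_60 TA-GL alpha
    c(0.08, 0.11, 0.07),  #              beta
    c(0.34, 0.45, 0.30),  #              gamma
    c(0.23, 0.20, 0.25),  # p60_100 RA-BF alpha
    c(0.53, 0.60, 0.50),  #               beta
    c(0.15, 0.12, 0.16),  #               gamma
    c(0.22, 0.25, 0.20),  # p60_100 TA-GL alpha
    c(0.51, 0.58, 0.48),  #               beta
    c(0.98, 1.10, 0.90))  #               gamma (clamped)
  out <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(condition = c("sham", "m1_tdcs", "dlpfc_tdcs")[j],
               phase = g$phase, pair = g$pair, band = g$band,
               target = pmin(vals[, j], clamp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default per-cell phase velocities
#'
#' Mean and SD of phase velocity (m/s) for every (condition, phase) cell.
#'
#' @return data.frame: condition, phase, mean, sd.
#' @export
default_velocity_params <- function() {
  conds <- c("sham", "m1_tdcs", "dlpfc_tdcs")
  phases <- c("p0_30", "p30_60", "p60_100")
  means <- rbind(sham = c(9.26, 11.12, 10.08),
                 m1_tdcs = c(9.35, 11.59, 9.88),
                 dlpfc_tdcs = c(8.97, 11.32, 9.85))
  sds <- rbind(sham = c(0.44, 0.60, 0.32),
               m1_tdcs = c(0.40, 0.67, 0.34),
               dlpfc_tdcs = c(0.49, 0.59, 0.40))
  out <- expand.grid(stringsAsFactors = FALSE, phase = phases, condition = conds)
  out$mean <- mapply(function(cd, ph) means[cd, match(ph, phases)],
                     out$condition, out$phase)
  out$sd <- mapply(function(cd, ph) sds[cd, match(ph, phases)],
                   out$condition, out$phase)
  out[, c("condition", "phase", "mean", "sd")]
}

#' Cohort configuration
#'
#' All knobs of the synthetic sprint cohort. Defaults encode the study
#' conditions: 30 participants x 3 conditions (sham, motor-cortex tDCS,
#' DLPFC tDCS) x 3 sprint phases (0-30, 30-60, 60-100 m), 4 muscles at
#' 1000 Hz, per-cell coherence targets and phase velocities.
#'
#' @param n_participants number of participants (default 30).
#' @param conditions ordered condition labels.
#' @param phases ordered phase labels.
#' @param fs sampling rate (Hz).
#' @param phase_distances named distances (m) per phase.
#' @param coherence_targets long data.frame as
#'   [default_coherence_targets()].
#' @param velocity_params long data.frame as [default_velocity_params()].
#' @param velocity_mode `"table"` (draw from velocity_params; default) or
#'   `"formula"` (evaluate the packaged reference equation on the extracted
#'   features plus Gaussian noise).
#' @param noise_sd_velocity velocity noise sd (m/s) used in `"formula"`
#'   mode (default 0.15).
#' @param participant_sd sd (m/s) of the participant-level random
#'   intercept shared across cells (default 0.2); in `"table"` mode the
#'   residual sd is reduced so the total per-cell SD matches
#'   `velocity_params$sd`.
#' @param band_amplitude RMS amplitude (mV) of each band-limited common
#'   drive component per channel.
#' @param broadband_sd RMS amplitude (mV) of the independent 20-450 Hz
#'   broadband noise on every channel.
#' @param participant_amp_sd log-sd of the per-participant EMG amplitude
#'   factor (physiological gain variability).
#' @param seed integer seed; the cohort is bit-reproducible given
#'   (config, seed).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 30,
                          conditions = c("sham", "m1_tdcs", "dlpfc_tdcs"),
                          phases = c("p0_30", "p30_60", "p60_100"),
                          fs = 1000,
                          phase_distances = c(p0_30 = 30, p30_60 = 30, p60_100 = 40),
                          coherence_targets = default_coherence_targets(),
                          velocity_params = default_velocity_params(),
                          velocity_mode = c("table", "formula"),
                          noise_sd_velocity = 0.15,
                          participant_sd = 0.2,
                          band_amplitude = 1.0,
                          broadband_sd = 0.3,
                          participant_amp_sd = 0.2,
                          seed = 1L) {
  velocity_mode <- match.arg(velocity_mode)
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    conditions = conditions, phases = phases, fs = fs,
    phase_distances = phase_distances,
    coherence_targets = coherence_targets,
    velocity_params = velocity_params,
    velocity_mode = velocity_mode,
    noise_sd_velocity = noise_sd_velocity,
    participant_sd = participant_sd,
    band_amplitude = band_amplitude,
    broadband_sd = broadband_sd,
    participant_amp_sd = participant_amp_sd,
    seed = as.integer(seed)), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop("config error: n_participants must be >= 1")
  if (any(cfg$coherence_targets$target < 0 | cfg$coherence_targets$target >= 1)) {
    stop("config error: coherence targets must lie in [0, 1)")
  }
  top <- max(vapply(imc_bands(), max, numeric(1)))
  if (cfg$fs <= 2 * top) {
    stop("config error: fs must exceed twice the highest band edge (", top, " Hz)")
  }
  if (any(cfg$velocity_params$sd <= 0)) stop("config error: velocity sd must be > 0")
  if (!all(cfg$phases %in% names(cfg$phase_distances))) {
    stop("config error: every phase needs a distance")
  }
  miss <- setdiff(
    paste(rep(cfg$conditions, each = length(cfg$phases)), cfg$phases),
    paste(cfg$velocity_params$condition, cfg$velocity_params$phase))
  if (length(miss)) stop("config error: velocity params missing for: ",
                         paste(miss, collapse = ", "))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d participants x %d conditions x %d phases ",
                     "(%d cells), fs %g Hz, velocity mode '%s', seed %d\n"),
              x$n_participants, length(x$conditions), length(x$phases),
              x$n_participants * length(x$conditions) * length(x$phases),
              x$fs, x$velocity_mode, x$seed))
  invisible(x)
}

#' Read a cohort configuration from YAML
#'
#' Reads a YAML file with the [cohort_config()] fields; missing fields take
#' the defaults. The packaged default lives at
#' `system.file("extdata", "default_cohort.yaml", package = "sprintkan")`.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_participants", "conditions", "phases", "fs",
               "velocity_mode", "noise_sd_velocity", "participant_sd",
               "band_amplitude", "broadband_sd", "participant_amp_sd", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$phase_distances)) {
    args$phase_distances <- unlist(y$phase_distances)
  }
  if (!is.null(y$velocity_params)) {
    vp <- do.call(rbind, lapply(y$velocity_params, as.data.frame))
    args$velocity_params <- vp
  }
  if (!is.null(y$coherence_targets)) {
    ct <- do.call(rbind, lapply(y$coherence_targets, as.data.frame))
    args$coherence_targets <- ct
  }
  do.call(cohort_config, args)
}

#' Write a cohort configuration to YAML
#'
#' @param cfg a `cohort_config`.
#' @param path output file.
#' @export
write_cohort_config <- function(cfg, path) {
  y <- list(
    n_participants = cfg$n_participants,
    conditions = cfg$conditions, phases = cfg$phases, fs = cfg$fs,
    phase_distances = as.list(cfg$phase_distances),
    velocity_mode = cfg$velocity_mode,
    noise_sd_velocity = cfg$noise_sd_velocity,
    participant_sd = cfg$participant_sd,
    band_amplitude = cfg$band_amplitude,
    broadband_sd = cfg$broadband_sd,
    participant_amp_sd = cfg$participant_amp_sd,
    seed = cfg$seed,
    velocity_params = unname(split(cfg$velocity_params,
                                   seq_len(nrow(cfg$velocity_params)))),
    coherence_targets = unname(split(cfg$coherence_targets,
                                     seq_len(nrow(cfg$coherence_targets)))))
  y$velocity_params <- lapply(y$velocity_params, as.list)
  y$coherence_targets <- lapply(y$coherence_targets, as.list)
  yaml::write_yaml(y, path)
  invisible(path)
}
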