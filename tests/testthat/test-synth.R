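# Synthetic cohort generator: mixing calibration, trial structure,
# determinism, and the common-drive coherence levels.

test_that("calibrate_mixing inverts the common-drive model", {
  expect_equal(calibrate_mixing(0), 0)
  expect_equal(calibrate_mixing(0.70), 0.9147, tolerance = 1e-4)
  expect_equal(calibrate_mixing(0.45), 0.8191, tolerance = 1e-4)
  expect_error(calibrate_mixing(1), "invalid parameter")
  expect_error(calibrate_mixing(1.2), "invalid parameter")
})

test_that("simulated pairs hit their coherence targets in every band", {
  bands <- imc_bands()
  targets <- list(alpha = 0.12, beta = 0.44, gamma = 0.70)
  for (bn in names(bands)) {
    est <- vapply(1:5, function(s) {
      p <- simulate_coherent_pair(calibrate_mixing(targets[[bn]]),
                                  bands[[bn]], fs = 1000, duration_s = 60,
                                  broadband_sd = 0.3, seed = s)
      spec <- coherence_spectrum(cross_spectra(p$x, p$y, 1000))
      band_average(spec, bands[[bn]])
    }, numeric(1))
    expect_lt(abs(mean(est) - targets[[bn]]), 0.05)
  }
})

test_that("estimated band coherence is monotone in the mixing coefficient", {
  kappas <- c(0, 0.3, 0.6, 0.8, 0.95)
  est <- vapply(kappas, function(k) {
    mean(vapply(1:3, function(s) {
      p <- simulate_coherent_pair(k, c(30, 50), fs = 1000, duration_s = 20,
                                  seed = s)
      band_average(coherence_spectrum(cross_spectra(p$x, p$y, 1000)),
                   c(30, 50))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("independent channels stay below the analytic significance limit", {
  hits <- vapply(1:5, function(s) {
    p <- simulate_coherent_pair(0, c(30, 50), fs = 1000, duration_s = 10,
                                seed = s)
    spec <- coherence_spectrum(cross_spectra(p$x, p$y, 1000))
    thr <- significance_threshold(spec$n_segments, mode = "analytic")
    band_average(spec, c(30, 50)) < thr
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("trial duration follows phase distance over mean velocity", {
  cfg <- tiny_cohort_config()
  tr <- generate_trial("P01", "m1_tdcs", "p30_60", cfg, seed = 1)
  expect_equal(nrow(tr$recording$samples), round(30 / 11.59 * 1000))
  expect_identical(ncol(tr$recording$samples), 4L)
  tr2 <- generate_trial("P01", "sham", "p0_30", cfg, seed = 1)
  expect_equal(nrow(tr2$recording$samples) / 1000, 30 / 9.26, tolerance = 1e-3)
  expect_error(generate_trial("P01", "anodal", "p0_30", cfg),
               "unknown condition")
  expect_error(generate_trial("P01", "sham", "p10_20", cfg), "unknown phase")
})

test_that("cohort cardinality equals the product of the factor sizes", {
  coh <- generate_cohort(tiny_cohort_config(n = 2))
  expect_identical(nrow(coh$rows), 2L * 3L * 3L)
  cfg1 <- cohort_config(n_participants = 2, conditions = "sham",
                        phases = "p0_30", seed = 3)
  coh1 <- generate_cohort(cfg1)
  expect_identical(nrow(coh1$rows), 2L)
  expect_true(all(vapply(coh1$recordings, function(r)
    ncol(r$samples) == 4L, logical(1))))
})

test_that("generation is bit-reproducible given (config, seed)", {
  cfg <- cohort_config(n_participants = 2, conditions = c("sham", "m1_tdcs"),
                       phases = "p30_60", seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$rows, c2$rows)
  expect_identical(c1$recordings, c2$recordings)
})

test_that("table-mode velocities track the configured cell means and SDs", {
  cfg <- cohort_config(n_participants = 30, conditions = "sham",
                       phases = "p30_60", seed = 9)
  coh <- generate_cohort(cfg)
  v <- coh$rows$velocity
  # mean 11.12, total sd 0.60 at n = 30
  expect_lt(abs(mean(v) - 11.12), 0.4)
  expect_lt(abs(sd(v) - 0.60), 0.35)
  # truncation at 3 sd about the cell mean (participant effect included)
  expect_true(all(abs(v - 11.12) < 3 * 0.6 + 3 * 0.2 + 0.1))
})

test_that("formula velocities evaluate the reference equation", {
  expect_equal(generate_velocity_from_formula(rep(0, 9)), 11.08502,
               tolerance = 1e-5)
  x <- rep(0, 9); x[7] <- 1
  expect_equal(generate_velocity_from_formula(x) -
                 generate_velocity_from_formula(rep(0, 9)), 0.2996)
  expect_identical(generate_velocity_from_formula(rep(0.5, 9)),
                   generate_velocity_from_formula(rep(0.5, 9)))
  set.seed(1)
  noisy <- generate_velocity_from_formula(matrix(0, 50, 9), noise_sd = 0.15,
                                          seed = 4)
  expect_gt(sd(noisy), 0.05)
})

test_that("config validation rejects impossible parameters", {
  bad <- default_coherence_targets()
  bad$target[1] <- 1.2
  expect_error(cohort_config(coherence_targets = bad), "config error")
  expect_error(cohort_config(fs = 90), "config error")
  vp <- default_velocity_params()
  vp$sd[2] <- 0
  expect_error(cohort_config(velocity_params = vp), "config error")
  # the packaged defaults clamp the impossible printed gamma targets
  expect_true(all(default_coherence_targets()$target <= 0.95))
})

test_that("the packaged YAML config mirrors the in-code defaults", {
  path <- system.file("extdata", "default_cohort.yaml", package = "sprintkan")
  cfg <- read_cohort_config(path)
  ref <- cohort_config()
  expect_identical(cfg$n_participants, ref$n_participants)
  expect_identical(cfg$conditions, ref$conditions)
  expect_identical(cfg$phases, ref$phases)
  expect_equal(cfg$velocity_params$mean, ref$velocity_params$mean)
  expect_equal(cfg$coherence_targets$target, ref$coherence_targets$target)
})

test_that("recording CSV and cohort manifest round-trip", {
  rec <- sine_recording(duration = 0.6)
  tmp <- tempfile(fileext = ".csv")
  write_recording_csv(rec, tmp)
  back <- read_recording_csv(tmp)
  expect_equal(back$fs, rec$fs)
  expect_equal(unname(back$samples), unname(rec$samples), tolerance = 1e-12)
  cfg1 <- cohort_config(n_participants = 1, conditions = "sham",
                        phases = "p0_30", seed = 2)
  coh <- generate_cohort(cfg1)
  dir <- tempfile()
  write_cohort(coh, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(nrow(man), 1L)
  expect_true(file.exists(file.path(dir, man$file[1])))
})
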