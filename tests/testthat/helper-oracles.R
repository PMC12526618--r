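# Independent oracles and small fixture builders used across the suite.

# Brute-force Welch coherence: explicit DFT sums per segment (no fft),
# explicit averaging. Mirrors the estimator's contract, not its code.
brute_force_cross_spectra <- function(x, y, fs, segment_s = 0.5,
                                      overlap_frac = 0.5) {
  n <- length(x)
  nseg <- floor(segment_s * fs)
  step <- floor(nseg * (1 - overlap_frac))
  L <- floor((n - nseg) / step) + 1
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)))
  nb <- nseg %/% 2 + 1
  # explicit DFT matrix
  k <- 0:(nb - 1)
  t <- 0:(nseg - 1)
  W <- exp(-2i * pi * outer(k, t) / nseg)
  sxx <- numeric(nb); syy <- numeric(nb); sxy <- complex(nb)
  for (s in seq_len(L)) {
    i0 <- (s - 1) * step
    xs <- x[(i0 + 1):(i0 + nseg)]; ys <- y[(i0 + 1):(i0 + nseg)]
    X <- as.vector(W %*% ((xs - mean(xs)) * w))
    Y <- as.vector(W %*% ((ys - mean(ys)) * w))
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  dbl <- rep(2, nb); dbl[1] <- 1; if (nseg %% 2 == 0) dbl[nb] <- 1
  sc <- dbl / (fs * sum(w^2) * L)
  list(freqs = k * fs / nseg, sxx = sxx * sc, syy = syy * sc, sxy = sxy * sc,
       n_segments = L)
}

brute_force_coherence <- function(x, y, fs, ...) {
  cs <- brute_force_cross_spectra(x, y, fs, ...)
  coh <- numeric(length(cs$freqs))
  ok <- cs$sxx * cs$syy > 0
  coh[ok] <- Mod(cs$sxy[ok])^2 / (cs$sxx[ok] * cs$syy[ok])
  list(freqs = cs$freqs, coh = coh, n_segments = cs$n_segments)
}

# Explicit sums-of-squares RM-ANOVA oracle (loops over cell means).
brute_force_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(Y[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(Y[i, ]) - grand)^2
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err, f = f,
       eta = ss_cond / (ss_cond + ss_err))
}

# long table from a wide matrix of condition scores
wide_to_long <- function(Y) {
  data.frame(participant = rep(rownames(Y), times = ncol(Y)),
             condition = rep(colnames(Y), each = nrow(Y)),
             value = as.vector(Y))
}

random_long_table <- function(n = 6, k = 3, seed = 1) {
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * k), n, k,
                dimnames = list(paste0("P", seq_len(n)), paste0("c", seq_len(k))))
    wide_to_long(Y)
  })
}

# small deterministic recording: sum of sines per channel
sine_recording <- function(freqs = c(50, 80, 110, 140), fs = 1000,
                           duration = 2) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  X <- vapply(freqs, function(f) sin(2 * pi * f * t), numeric(length(t)))
  emg_recording(X, fs, channels = c("RA", "BF", "TA", "GL"))
}

# tiny cohort config for structural tests (fast to generate)
tiny_cohort_config <- function(n = 2, seed = 1, ...) {
  cohort_config(n_participants = n, seed = seed, ...)
}
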