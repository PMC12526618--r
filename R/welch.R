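# Welch segment-averaged spectra. Internal engine shared by the coherence
# estimator and the median-frequency feature. One-sided densities; Hann
# window; per-segment mean removal.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq(0L, n - 1L) / (n - 1L)))
}

# Number of Welch segments for a signal of length n: floor((n - nseg)/step) + 1
welch_n_segments <- function(n, nseg, step) {
  if (n < nseg) 0L else as.integer(floor((n - nseg) / step) + 1L)
}

welch_cross <- function(x, y, fs, segment_s = 0.5, overlap = 0.5) {
  stopifnot(length(x) == length(y), fs > 0, segment_s > 0,
            overlap >= 0, overlap < 1)
  n <- length(x)
  nseg <- as.integer(floor(segment_s * fs))
  if (nseg < 2L) stop("Welch segment shorter than 2 samples")
  if (n < nseg) {
    stop("signal of ", n, " samples is shorter than one Welch segment (",
         nseg, " samples)")
  }
  step <- max(1L, as.integer(floor(nseg * (1 - overlap))))
  L <- welch_n_segments(n, nseg, step)
  w <- hann_window(nseg)
  nb <- nseg %/% 2L + 1L
  sxx <- numeric(nb)
  syy <- numeric(nb)
  sxy <- complex(nb)
  for (s in seq_len(L)) {
    i0 <- (s - 1L) * step
    xs <- x[(i0 + 1L):(i0 + nseg)]
    ys <- y[(i0 + 1L):(i0 + nseg)]
    xs <- (xs - mean(xs)) * w
    ys <- (ys - mean(ys)) * w
    X <- fft(xs)[seq_len(nb)]
    Y <- fft(ys)[seq_len(nb)]
    sxx <- sxx + Re(X * Conj(X))
    syy <- syy + Re(Y * Conj(Y))
    sxy <- sxy + X * Conj(Y)
  }
  # one-sided scaling; DC (and Nyquist for even nseg) are not doubled
  dbl <- rep(2, nb)
  dbl[1L] <- 1
  if (nseg %% 2L == 0L) dbl[nb] <- 1
  sc <- dbl / (fs * sum(w^2) * L)
  list(freqs = seq(0L, nb - 1L) * fs / nseg,
       sxx = sxx * sc, syy = syy * sc, sxy = sxy * sc,
       n_segments = L, segment_samples = nseg, step = step)
}

welch_psd <- function(x, fs, segment_s = 0.5, overlap = 0.5) {
  cs <- welch_cross(x, x, fs, segment_s, overlap)
  list(freqs = cs$freqs, psd = cs$sxx, n_segments = cs$n_segments)
}

# Single full-span periodogram, used when a span is shorter than one Welch
# segment (median frequency of short phases).
periodogram_psd <- function(x, fs) {
  n <- length(x)
  w <- hann_window(n)
  xs <- (x - mean(x)) * w
  nb <- n %/% 2L + 1L
  X <- fft(xs)[seq_len(nb)]
  dbl <- rep(2, nb)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[nb] <- 1
  list(freqs = seq(0L, nb - 1L) * fs / n,
       psd = Re(X * Conj(X)) * dbl / (fs * sum(w^2)),
       n_segments = 1L)
}
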