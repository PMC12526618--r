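# Uniform cubic B-spline basis on a clamped interval. Grid parameter G =
# number of knot intervals on [lo, hi]; the knot vector is extended by 3
# uniform knots on each side, giving G + 3 basis functions that form a
# partition of unity on [lo, hi] and are C2 at interior knots.

#' Uniform cubic B-spline grid
#'
#' @param n_intervals number of knot intervals G on the domain.
#' @param lo,hi domain endpoints (default `[0, 1]`).
#' @return Object of class `spline_grid`: knots (extended by 3 each side),
#'   spacing `h`, `n_basis = G + 3`, degree 3.
#' @export
spline_grid <- function(n_intervals, lo = 0, hi = 1) {
  stopifnot(n_intervals >= 1, hi > lo)
  G <- as.integer(n_intervals)
  h <- (hi - lo) / G
  structure(list(n_intervals = G, degree = 3L, lo = lo, hi = hi, h = h,
                 knots = lo + ((-3L):(G + 3L)) * h, n_basis = G + 3L),
            class = "spline_grid")
}

# Cardinal cubic B-spline N(t) supported on [0, 4], N(2) = 2/3.
cubic_cardinal <- function(t) {
  r <- numeric(length(t))
  i <- t >= 0 & t < 1
  r[i] <- t[i]^3 / 6
  i <- t >= 1 & t < 2
  v <- t[i] - 1
  r[i] <- (-3 * v^3 + 3 * v^2 + 3 * v + 1) / 6
  i <- t >= 2 & t < 3
  v <- t[i] - 2
  r[i] <- (3 * v^3 - 6 * v^2 + 4) / 6
  i <- t >= 3 & t <= 4
  r[i] <- (4 - t[i])^3 / 6
  r
}

cubic_cardinal_deriv <- function(t) {
  r <- numeric(length(t))
  i <- t >= 0 & t < 1
  r[i] <- t[i]^2 / 2
  i <- t >= 1 & t < 2
  v <- t[i] - 1
  r[i] <- (-9 * v^2 + 6 * v + 3) / 6
  i <- t >= 2 & t < 3
  v <- t[i] - 2
  r[i] <- (9 * v^2 - 12 * v) / 6
  i <- t >= 3 & t <= 4
  r[i] <- -(4 - t[i])^2 / 2
  r
}

# basis (and optionally derivative d/dx) matrices for a vector x on a
# grid. Outside [lo, hi] the design either clamps to the boundary value
# (mode "clamp", derivative zero) or continues linearly with the edge's
# average (secant) slope over the domain (mode "extrapolate", used inside
# the network so held-out inputs beyond the training range keep a robust
# global trend rather than a flat plateau or a noisy boundary tangent).
spline_design <- function(x, grid, deriv = FALSE, warn = FALSE,
                          mode = c("extrapolate", "clamp")) {
  mode <- match.arg(mode)
  u_raw <- (x - grid$lo) / grid$h
  G <- grid$n_intervals
  out_of_domain <- u_raw < 0 | u_raw > G
  if (warn && any(out_of_domain)) {
    warning(sum(out_of_domain), " evaluation point(s) outside [",
            grid$lo, ", ", grid$hi, "] clamped to the domain")
  }
  u <- pmin(pmax(u_raw, 0), G)
  m <- grid$n_basis
  n <- length(x)
  B <- matrix(0, n, m)
  for (j in seq_len(m)) B[, j] <- cubic_cardinal(u - j + 4)
  Bp <- NULL
  if (deriv) {
    Bp <- matrix(0, n, m)
    for (j in seq_len(m)) Bp[, j] <- cubic_cardinal_deriv(u - j + 4)
    Bp <- Bp / grid$h
  }
  if (any(out_of_domain)) {
    idx <- which(out_of_domain)
    if (mode == "extrapolate") {
      b_lo <- cubic_cardinal(0 - seq_len(m) + 4)
      b_hi <- cubic_cardinal(G - seq_len(m) + 4)
      secant <- (b_hi - b_lo) / (grid$hi - grid$lo)
      dx <- (u_raw - u) * grid$h  # signed distance beyond the boundary
      B[idx, ] <- B[idx, , drop = FALSE] +
        dx[idx] %o% secant
      if (deriv) Bp[idx, ] <- rep(secant, each = length(idx))
    } else if (deriv) {
      Bp[idx, ] <- 0
    }
  }
  if (!deriv) return(list(B = B))
  list(B = B, Bp = Bp)
}

#' Evaluate the cubic B-spline basis
#'
#' Evaluates basis function `i` (or the full basis matrix when `i` is
#' `NULL`) at points `x`. Points outside the domain are clamped with a
#' warning. The basis functions form a partition of unity on the domain.
#'
#' @param x evaluation points.
#' @param grid a [spline_grid()].
#' @param i basis index in `1..n_basis`, or `NULL` for the full matrix.
#' @return Numeric vector (single basis) or matrix `length(x) x n_basis`.
#' @export
bspline_basis <- function(x, grid, i = NULL) {
  stopifnot(inherits(grid, "spline_grid"))
  B <- spline_design(x, grid, warn = TRUE, mode = "clamp")$B
  if (is.null(i)) return(B)
  stopifnot(i >= 1L, i <= grid$n_basis)
  B[, i]
}

# least-squares fit of spline coefficients to samples (x, y); used by
# single-edge construction in tests and examples.
fit_edge_lsq <- function(grid, x, y) {
  B <- spline_design(x, grid)$B
  qr.coef(qr(B), y)
}
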