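# Kolmogorov-Arnold network with cubic B-spline edge functions. Every edge
# (i, j) of layer l carries a univariate spline Phi_ij(x) = sum_k c_ijk
# B_k(x); node j of the next layer is the plain sum of its incoming edge
# outputs. No residual or base activation: edges are pure splines.

#' Construct an untrained KAN
#'
#' @param widths layer widths, input first (default `c(9, 5, 3, 1)`).
#' @param grid spline grid parameter G: number of knot intervals per edge
#'   domain (default 5); each edge has `G + 3` basis functions.
#' @param seed seed for the coefficient initialization.
#' @param init `"ramp"` (default) initializes every edge as a random
#'   linear function (spline coefficients set along the Greville abscissae
#'   with slope ~ Normal(0, 1/sqrt(n_in)) plus jitter `coef_sd/10`), which
#'   gives the depth-wise gradient flow that residual base activations
#'   provide in other KAN variants while keeping edges pure splines;
#'   `"normal"` draws white coefficients ~ Normal(0, `coef_sd`).
#' @param coef_sd coefficient sd for `init = "normal"` (default 0.1).
#' @return Object of class `kan`. Input-feature and target scalers are
#'   unfitted until [kan_fit_scaler()] or [kan_train()] is called.
#' @export
kan_new <- function(widths = c(9, 5, 3, 1), grid = 5, seed = 1L,
                    init = c("ramp", "normal"), coef_sd = 0.1) {
  stopifnot(length(widths) >= 2L, all(widths >= 1L), grid >= 1L)
  init <- match.arg(init)
  widths <- as.integer(widths)
  G <- as.integer(grid)
  m <- G + 3L
  layers <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(length(widths) - 1L), function(l) {
      n_in <- widths[l]
      n_out <- widths[l + 1L]
      dom <- if (l == 1L) c(0, 1) else c(-1, 1)
      lo <- rep(dom[1L], n_in)
      hi <- rep(dom[2L], n_in)
      coef <- array(0, dim = c(n_in, n_out, m))
      if (init == "normal") {
        coef[] <- rnorm(n_in * n_out * m, 0, coef_sd)
      } else {
        for (i in seq_len(n_in)) {
          g <- spline_grid(G, lo[i], hi[i])
          kn <- g$knots
          grev <- (kn[seq_len(m) + 1L] + kn[seq_len(m) + 2L] +
                     kn[seq_len(m) + 3L]) / 3
          for (j in seq_len(n_out)) {
            slope <- rnorm(1, 0, 1 / sqrt(n_in))
            coef[i, j, ] <- slope * grev + rnorm(m, 0, coef_sd / 10)
          }
        }
      }
      list(coef = coef, mask = matrix(TRUE, n_in, n_out), lo = lo, hi = hi)
    })
  })
  structure(list(widths = widths, grid = G, n_basis = m,
                 layers = layers, scaler = NULL,
                 y_center = 0, y_scale = 1, seed = as.integer(seed)),
            class = "kan")
}

#' @export
print.kan <- function(x, ...) {
  act <- sum(vapply(x$layers, function(l) sum(l$mask), numeric(1)))
  tot <- sum(vapply(x$layers, function(l) length(l$mask), numeric(1)))
  cat(sprintf("<kan> widths [%s], grid %d (%d basis/edge), %d/%d active edges, scaler %s\n",
              paste(x$widths, collapse = ","), x$grid, x$n_basis, act, tot,
              if (is.null(x$scaler)) "unfitted" else "fitted"))
  invisible(x)
}

#' Fit the input (and optionally target) scaler
#'
#' Min-max scales every feature to `[0, 1]` (the representation domain of
#' the first layer) and z-scores the target for optimization; both are
#' fitted on training data only and stored in the model.
#'
#' @param model a `kan`.
#' @param X training feature matrix.
#' @param y optional training target.
#' @return The model with fitted scalers.
#' @export
kan_fit_scaler <- function(model, X, y = NULL) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == model$widths[1L])
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  deg <- mx - mn < 1e-12
  mn[deg] <- mn[deg] - 0.5
  mx[deg] <- mx[deg] + 0.5
  model$scaler <- list(min = mn, max = mx)
  if (!is.null(y)) {
    model$y_center <- mean(y)
    s <- sd(y)
    model$y_scale <- if (is.finite(s) && s > 1e-12) s else 1
  }
  model
}

scale_features <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(model$scaler)) stop("unfitted scaler: call kan_fit_scaler() or kan_train() first")
  stopifnot(ncol(X) == model$widths[1L])
  # no hard clamp: out-of-range values are handled by the spline design's
  # secant extrapolation
  sweep(sweep(X, 2, model$scaler$min), 2, model$scaler$max - model$scaler$min, "/")
}

masked_coef <- function(layer, i, m) {
  Ci <- array(layer$coef[i, , ], dim = c(dim(layer$coef)[2L], m))
  Ci[!layer$mask[i, ], ] <- 0
  Ci
}

# forward pass on scaled inputs; optional cache for backprop / pruning.
# l1_designs: precomputed layer-1 basis matrices (the first layer's inputs
# are fixed during optimization, so its design never changes). The first
# layer's derivative is never needed (no gradient flows to raw inputs).
kan_forward_raw <- function(model, U, cache = FALSE, l1_designs = NULL) {
  N <- nrow(U)
  A <- U
  caches <- if (cache) vector("list", length(model$layers)) else NULL
  m <- model$n_basis
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    n_in <- model$widths[l]
    n_out <- model$widths[l + 1L]
    out <- matrix(0, N, n_out)
    designs <- if (cache) vector("list", n_in) else NULL
    for (i in seq_len(n_in)) {
      if (l == 1L && !is.null(l1_designs)) {
        d <- l1_designs[[i]]
      } else {
        g <- spline_grid(model$grid, lay$lo[i], lay$hi[i])
        d <- spline_design(A[, i], g, deriv = cache && l > 1L)
      }
      Ci <- masked_coef(lay, i, m)
      out <- out + d$B %*% t(Ci)
      if (cache) designs[[i]] <- d
    }
    if (cache) caches[[l]] <- list(A = A, designs = designs)
    A <- out
  }
  if (cache) list(z = A[, 1L], cache = caches) else A[, 1L]
}

# precompute layer-1 designs for fixed scaled inputs
layer1_designs <- function(model, U) {
  lay <- model$layers[[1L]]
  lapply(seq_len(model$widths[1L]), function(i) {
    g <- spline_grid(model$grid, lay$lo[i], lay$hi[i])
    spline_design(U[, i], g, deriv = FALSE)
  })
}

#' KAN forward pass
#'
#' Predicts the outcome (m/s) for raw feature rows: features are min-max
#' scaled to `[0, 1]`, pushed through the spline layers, and the
#' standardized network output is mapped back to outcome units. Pruned
#' edges contribute exactly zero.
#'
#' @param model a fitted `kan`.
#' @param X feature matrix (rows) or a single feature vector.
#' @return Numeric predictions.
#' @export
kan_forward <- function(model, X) {
  stopifnot(inherits(model, "kan"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  U <- scale_features(model, X)
  kan_forward_raw(model, U) * model$y_scale + model$y_center
}
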