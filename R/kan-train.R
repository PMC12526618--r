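# Regularized KAN training. Objective on the standardized target:
#   L = mean (z_n - f(u_n))^2 + lambda * (mu1 * sum_edges ||c||_1
#                                         + mu2 * sum_edges S(c)),
# with per-edge entropy S(c) = -sum_k p_k log p_k, p_k = c_k^2 / sum c^2.
# Optimized with L-BFGS using analytic spline gradients.

#' Training configuration
#'
#' @param lambda overall regularization weight (default 0.01).
#' @param mu1 L1 weight (default 1).
#' @param mu2 entropy weight (default 10).
#' @param iterations training iterations (default 20); each iteration is
#'   one L-BFGS cycle of `inner_iterations` line-search steps.
#' @param inner_iterations L-BFGS steps per training iteration
#'   (default 10).
#' @param prune_threshold edge-importance threshold for [kan_prune()]
#'   (default 0.2).
#' @param seed seed for coefficient initialization.
#' @param adapt two-phase schedule: unregularized warm start for the first
#'   quarter of the iterations, hidden-layer spline domains refreshed from
#'   the observed activations, then the regularized run (default TRUE).
#' @return Object of class `kan_config`.
#' @export
kan_config <- function(lambda = 0.01, mu1 = 1, mu2 = 10, iterations = 20,
                       inner_iterations = 10, prune_threshold = 0.2,
                       seed = 1L, adapt = TRUE) {
  stopifnot(lambda >= 0, mu1 >= 0, mu2 >= 0, iterations >= 1,
            inner_iterations >= 1)
  structure(list(lambda = lambda, mu1 = mu1, mu2 = mu2,
                 iterations = as.integer(iterations),
                 inner_iterations = as.integer(inner_iterations),
                 prune_threshold = prune_threshold,
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "kan_config")
}

edge_entropy <- function(c_k) {
  T2 <- sum(c_k^2)
  if (T2 <= 0) return(0)
  p <- c_k^2 / T2
  pos <- p > 0
  -sum(p[pos] * log(pmax(p[pos], 1e-12)))
}

edge_entropy_grad <- function(c_k) {
  T2 <- sum(c_k^2)
  if (T2 <= 0) return(rep(0, length(c_k)))
  p <- c_k^2 / T2
  S <- edge_entropy(c_k)
  lp <- log(pmax(p, 1e-12))
  -(2 * c_k / T2) * (lp + S)
}

# pack/unpack all spline coefficients (masked entries carried but frozen)
kan_get_par <- function(model) {
  unlist(lapply(model$layers, function(l) as.numeric(l$coef)))
}

kan_set_par <- function(model, par) {
  pos <- 0L
  for (l in seq_along(model$layers)) {
    k <- length(model$layers[[l]]$coef)
    model$layers[[l]]$coef <- array(par[pos + seq_len(k)],
                                    dim = dim(model$layers[[l]]$coef))
    pos <- pos + k
  }
  model
}

# value and gradient of the training objective at the current coefficients
kan_objective <- function(model, U, z, cfg, l1_designs = NULL) {
  N <- nrow(U)
  m <- model$n_basis
  fw <- kan_forward_raw(model, U, cache = TRUE, l1_designs = l1_designs)
  resid <- fw$z - z
  mse <- mean(resid^2)
  reg <- 0
  grads <- lapply(model$layers, function(l) array(0, dim = dim(l$coef)))
  # delta: d(mse)/d(node outputs) for the current layer, backwards
  delta <- matrix(2 * resid / N, N, 1L)
  for (l in rev(seq_along(model$layers))) {
    lay <- model$layers[[l]]
    ch <- fw$cache[[l]]
    n_in <- model$widths[l]
    n_out <- model$widths[l + 1L]
    delta_prev <- matrix(0, N, n_in)
    for (i in seq_len(n_in)) {
      G <- crossprod(ch$designs[[i]]$B, delta)        # m x n_out
      grads[[l]][i, , ] <- t(G)
      Ci <- masked_coef(lay, i, m)                     # n_out x m
      if (l > 1L) {
        slope <- ch$designs[[i]]$Bp %*% t(Ci)          # N x n_out
        delta_prev[, i] <- rowSums(slope * delta)
      }
    }
    # regularization on active edges
    for (i in seq_len(n_in)) for (j in seq_len(n_out)) {
      if (!lay$mask[i, j]) {
        grads[[l]][i, j, ] <- 0
        next
      }
      ck <- lay$coef[i, j, ]
      reg <- reg + cfg$lambda * (cfg$mu1 * sum(abs(ck)) +
                                   cfg$mu2 * edge_entropy(ck))
      grads[[l]][i, j, ] <- grads[[l]][i, j, ] +
        cfg$lambda * (cfg$mu1 * sign(ck) + cfg$mu2 * edge_entropy_grad(ck))
    }
    delta <- delta_prev
  }
  list(value = mse + reg, mse = mse, reg = reg,
       grad = unlist(lapply(grads, as.numeric)))
}

refresh_hidden_domains <- function(model, U) {
  if (length(model$layers) < 2L) return(model)
  fw <- kan_forward_raw(model, U, cache = TRUE)
  for (l in 2:length(model$layers)) {
    A <- fw$cache[[l]]$A
    for (i in seq_len(ncol(A))) {
      rng <- range(A[, i])
      span <- max(rng[2L] - rng[1L], 1e-3)
      model$layers[[l]]$lo[i] <- rng[1L] - 0.1 * span
      model$layers[[l]]$hi[i] <- rng[2L] + 0.1 * span
    }
  }
  model
}

run_lbfgs <- function(model, U, z, cfg, maxit) {
  par0 <- kan_get_par(model)
  l1d <- layer1_designs(model, U)
  env <- new.env()
  env$model <- model
  fn <- function(p) {
    env$model <- kan_set_par(env$model, p)
    ob <- kan_objective(env$model, U, z, cfg, l1_designs = l1d)
    env$last <- ob
    env$last_p <- p
    ob$value
  }
  gr <- function(p) {
    if (is.null(env$last_p) || !identical(p, env$last_p)) fn(p)
    env$last$grad
  }
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  model <- kan_set_par(model, opt$par)
  list(model = model, value = opt$value)
}

#' Train a KAN
#'
#' Fits the spline coefficients by L-BFGS on the regularized objective
#' (prediction MSE on the standardized target plus L1 and entropy terms on
#' every active edge). Scalers are fitted on the supplied data if absent.
#' Training uses a two-phase schedule within the iteration budget: the
#' first quarter of the iterations runs unregularized (a warm start that
#' lets weak edges emerge before the entropy term concentrates
#' coefficients), the hidden-layer spline domains are refreshed from the
#' observed activations, and the remaining iterations run with the full
#' objective. Set `adapt = FALSE` in the config for a single regularized
#' run.
#'
#' @param model a `kan` from [kan_new()].
#' @param X training feature matrix.
#' @param y training outcome (m/s).
#' @param cfg a [kan_config()].
#' @return The trained model; `$loss_history` holds per-phase
#'   (initial, final) objective values, `$objective` the final value.
#' @export
kan_train <- function(model, X, y, cfg = kan_config()) {
  stopifnot(inherits(model, "kan"))
  X <- as.matrix(X)
  if (is.null(model$scaler)) model <- kan_fit_scaler(model, X, y)
  U <- scale_features(model, X)
  z <- (y - model$y_center) / model$y_scale
  it <- cfg$iterations * cfg$inner_iterations
  hist <- list()
  if (cfg$adapt && it > 4L) {
    ph1 <- max(1L, it %/% 4L)
    cfg_warm <- cfg
    cfg_warm$lambda <- 0
    v0 <- kan_objective(model, U, z, cfg_warm)$value
    r1 <- run_lbfgs(model, U, z, cfg_warm, ph1)
    model <- refresh_hidden_domains(r1$model, U)
    hist$warm <- c(v0, r1$value)
    v1 <- kan_objective(model, U, z, cfg)$value
    r2 <- run_lbfgs(model, U, z, cfg, it - ph1)
    model <- r2$model
    hist$regularized <- c(v1, r2$value)
  } else {
    v0 <- kan_objective(model, U, z, cfg)$value
    r <- run_lbfgs(model, U, z, cfg, it)
    model <- r$model
    hist$regularized <- c(v0, r$value)
  }
  fin <- hist$regularized[length(hist$regularized)]
  if (!all(is.finite(unlist(hist)))) {
    stop("non-finite training loss; check inputs and scaling")
  }
  model$loss_history <- hist
  model$objective <- fin
  model
}

#' Loss breakdown for a model on a dataset
#'
#' Reports the components of the training criterion in outcome units:
#' prediction MSE, the summed per-edge L1 norm, the summed per-edge
#' coefficient entropy, and `total = mse + lambda * (mu1 * l1 + mu2 *
#' entropy)`.
#'
#' @param model a `kan` with fitted scaler.
#' @param X,y data.
#' @param cfg a [kan_config()] supplying lambda, mu1, mu2.
#' @return Object of class `kan_loss` with fields `mse`, `l1_term`,
#'   `entropy_term`, `total`.
#' @export
kan_loss <- function(model, X, y, cfg = kan_config()) {
  pred <- kan_forward(model, X)
  mse <- mean((y - pred)^2)
  l1 <- 0
  ent <- 0
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    for (i in seq_len(dim(lay$coef)[1L])) for (j in seq_len(dim(lay$coef)[2L])) {
      if (!lay$mask[i, j]) next
      ck <- lay$coef[i, j, ]
      l1 <- l1 + sum(abs(ck))
      ent <- ent + edge_entropy(ck)
    }
  }
  structure(list(mse = mse, l1_term = l1, entropy_term = ent,
                 total = mse + cfg$lambda * (cfg$mu1 * l1 + cfg$mu2 * ent)),
            class = "kan_loss")
}

#' @export
print.kan_loss <- function(x, ...) {
  cat(sprintf("<kan_loss> mse %.5g | l1 %.5g | entropy %.5g | total %.5g\n",
              x$mse, x$l1_term, x$entropy_term, x$total))
  invisible(x)
}
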