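# KAN forward pass, loss, training, pruning, serialization.

test_that("forward pass is linear in coefficients and zero for zero models", {
  m <- kan_new(c(3, 2, 1), grid = 4, seed = 1)
  X <- matrix(runif(30), 10, 3)
  m <- kan_fit_scaler(m, X)
  m0 <- m
  for (l in seq_along(m0$layers)) m0$layers[[l]]$coef[] <- 0
  expect_identical(unname(kan_forward(m0, X)), rep(0, 10))
  # doubling the last-layer coefficients doubles the output
  m2 <- m
  m2$layers[[length(m2$layers)]]$coef <-
    2 * m2$layers[[length(m2$layers)]]$coef
  expect_equal(kan_forward(m2, X), 2 * kan_forward(m, X), tolerance = 1e-12)
  # unfitted scaler errors
  expect_error(kan_forward(kan_new(c(3, 1)), X), "unfitted scaler")
})

test_that("a single edge fitted by least squares represents the identity", {
  g <- spline_grid(5)
  x <- seq(0, 1, length.out = 50)
  cf <- sprintkan:::fit_edge_lsq(g, x, x)
  m <- kan_new(c(1, 1), grid = 5, seed = 1)
  m$layers[[1]]$coef[1, 1, ] <- cf
  m$scaler <- list(min = 0, max = 1)
  xx <- seq(0.05, 0.95, length.out = 100)
  expect_lt(max(abs(kan_forward(m, matrix(xx)) - xx)), 1e-3)
})

test_that("loss breakdown follows the printed decomposition", {
  ent <- sprintkan:::edge_entropy
  expect_identical(ent(c(0, 2, 0, 0)), 0)
  expect_equal(ent(c(1, -1, 1, 1)), log(4))
  expect_identical(ent(rep(0, 6)), 0)
  m <- kan_new(c(2, 1), grid = 3, seed = 2)
  X <- matrix(runif(40), 20, 2)
  y <- rnorm(20)
  m <- kan_fit_scaler(m, X, y)
  cfg <- kan_config(lambda = 0.05, mu1 = 2, mu2 = 3)
  lb <- kan_loss(m, X, y, cfg)
  expect_equal(lb$total,
               lb$mse + cfg$lambda * (cfg$mu1 * lb$l1_term +
                                        cfg$mu2 * lb$entropy_term))
  expect_gte(lb$mse, 0)
  # zero-coefficient model on centered targets: mse = mean(y^2)
  m0 <- m
  for (l in seq_along(m0$layers)) m0$layers[[l]]$coef[] <- 0
  yc <- y - mean(y)
  m0$y_center <- 0; m0$y_scale <- 1
  lb0 <- kan_loss(m0, X, yc, cfg)
  expect_equal(lb0$mse, mean(yc^2))
  expect_identical(lb0$l1_term, 0)
})

test_that("the analytic gradient matches finite differences", {
  m <- kan_new(c(3, 2, 1), grid = 4, seed = 3)
  X <- matrix(runif(36), 12, 3)
  y <- rnorm(12)
  m <- kan_fit_scaler(m, X, y)
  U <- sprintkan:::scale_features(m, X)
  z <- (y - m$y_center) / m$y_scale
  cfg <- kan_config(lambda = 0.01, mu1 = 1, mu2 = 10)
  ob <- sprintkan:::kan_objective(m, U, z, cfg)
  p0 <- sprintkan:::kan_get_par(m)
  withr::with_seed(9, idx <- sample(length(p0), 25))
  h <- 1e-6
  num <- vapply(idx, function(k) {
    pp <- p0; pp[k] <- p0[k] + h
    v1 <- sprintkan:::kan_objective(sprintkan:::kan_set_par(m, pp), U, z, cfg)$value
    pp[k] <- p0[k] - h
    v0 <- sprintkan:::kan_objective(sprintkan:::kan_set_par(m, pp), U, z, cfg)$value
    (v1 - v0) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - ob$grad[idx])), 1e-6)
})

test_that("training fits a noiseless affine map and is reproducible", {
  withr::with_seed(5, x <- matrix(runif(100), 100, 1))
  y <- 2 * x[, 1]
  cfg <- kan_config(lambda = 0, iterations = 20)
  m1 <- kan_train(kan_new(c(1, 1), 5, seed = 1), x, y, cfg)
  expect_lt(mean((kan_forward(m1, x) - y)^2), 1e-4)
  m2 <- kan_train(kan_new(c(1, 1), 5, seed = 1), x, y, cfg)
  expect_identical(m1$layers, m2$layers)
  # regularization trades fit: unregularized mse <= regularized mse
  m3 <- kan_train(kan_new(c(1, 1), 5, seed = 1), x, y,
                  kan_config(lambda = 0.01, iterations = 20))
  expect_lte(mean((kan_forward(m1, x) - y)^2),
             mean((kan_forward(m3, x) - y)^2) + 1e-10)
})

test_that("the objective is non-increasing over each optimization phase", {
  withr::with_seed(6, {
    X <- matrix(runif(60), 30, 2)
    y <- X[, 1] - 2 * X[, 2] + rnorm(30, 0, 0.05)
  })
  m <- kan_train(kan_new(c(2, 2, 1), 5, seed = 2), X, y, kan_config())
  for (ph in m$loss_history) expect_lte(ph[length(ph)], ph[1] + 1e-10)
})

test_that("pruning masks weak edges and recovers planted inputs", {
  # trivials
  withr::with_seed(7, {
    X <- matrix(runif(200), 50, 4)
    y <- X[, 1] + rnorm(50, 0, 0.05)
  })
  m <- kan_train(kan_new(c(4, 1), 5, seed = 1), X, y, kan_config())
  p0 <- kan_prune(m, X, threshold = 0)
  expect_identical(p0$layers[[1]]$mask, m$layers[[1]]$mask)
  expect_error(kan_prune(m, X, threshold = Inf), "lower the threshold")
  # planted recovery: y depends only on x1 (nonlinear) and x7 (linear)
  hits <- 0
  for (s in 1:10) {
    withr::with_seed(s, {
      Xs <- matrix(runif(270 * 9), 270, 9)
      ys <- sin(3 * Xs[, 1]) + 2 * Xs[, 7] + rnorm(270, 0, 0.05)
    })
    ms <- kan_train(kan_new(c(9, 1), 5, seed = s), Xs, ys,
                    kan_config(seed = s))
    ms <- tryCatch(kan_prune(ms, Xs, threshold = 0.2, refit = TRUE, y = ys,
                             cfg = kan_config(seed = s, adapt = FALSE)),
                   error = function(e) NULL)
    ai <- if (is.null(ms)) integer() else kan_active_inputs(ms)
    if (all(c(1, 7) %in% ai) && length(ai) <= 4) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("a pruned forward pass equals the masked-coefficient forward pass", {
  withr::with_seed(8, {
    X <- matrix(runif(120), 40, 3)
    y <- X[, 1] + rnorm(40, 0.1)
  })
  m <- kan_train(kan_new(c(3, 2, 1), 5, seed = 3), X, y, kan_config())
  p <- kan_prune(m, X, threshold = 0.05, fallback = "backbone")
  # manual masking of the unpruned model
  mm <- m
  for (l in seq_along(mm$layers)) {
    mm$layers[[l]]$mask <- p$layers[[l]]$mask
  }
  expect_identical(kan_forward(p, X), kan_forward(mm, X))
})

test_that("models serialize to JSON and back without changing predictions", {
  withr::with_seed(9, {
    X <- matrix(runif(90), 30, 3)
    y <- rowSums(X) + rnorm(30, 0, 0.1)
  })
  m <- kan_train(kan_new(c(3, 2, 1), 4, seed = 4), X, y,
                 kan_config(iterations = 5))
  tmp <- tempfile(fileext = ".json")
  kan_save(m, tmp)
  m2 <- kan_load(tmp)
  expect_equal(kan_forward(m2, X), kan_forward(m, X), tolerance = 1e-12)
  expect_identical(m2$widths, m$widths)
})

test_that("r_squared follows the printed definition", {
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(0, 2, 4, 6)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  # residuals twice the size of y's deviations give -3:
  # y = (0, 2), yhat = y + 2*(y - mean(y)) = (-2, 4)
  y2 <- c(0, 2)
  expect_equal(r_squared(c(-2, 4), y2), -3)
  expect_error(r_squared(c(1, 2), c(5, 5)), "zero variance")
})
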