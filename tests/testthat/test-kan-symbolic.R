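# Symbolic compression: family fitting, network symbolization, flattening,
# and the packaged reference equation.

test_that("each library family is recovered from its own data", {
  gens <- list(
    x = function(x) 1.5 * x - 0.3,
    x2 = function(x) 2 * (x - 0.4)^2 + 0.1,
    exp = function(x) 0.8 * exp(2 * x) - 1,
    log = function(x) 1.2 * log(6 * x + 0.1),
    sin = function(x) sin(3 * x + 1))
  for (fam in names(gens)) {
    hits <- 0
    for (s in 1:10) {
      withr::with_seed(s, {
        x <- runif(200)
        y <- gens[[fam]](x) + rnorm(200, 0, 0.02)
      })
      if (fit_edge_family(x, y)$family == fam) hits <- hits + 1
    }
    expect_gte(hits, 9)
  }
})

test_that("sin parameters are recovered to grid-search-plus-refine accuracy", {
  withr::with_seed(1, {
    x <- runif(200)
    y <- sin(3 * x + 1) + rnorm(200, 0, 0.02)
  })
  f <- fit_edge_family(x, y)
  expect_identical(f$family, "sin")
  expect_lt(abs(f$a - 3), 0.1)
  expect_lt(abs(f$b - 1), 0.1)
})

test_that("the quadratic family beats the linear one on quadratic data", {
  withr::with_seed(2, {
    x <- runif(200)
    y <- (x - 0.3)^2 + rnorm(200, 0, 0.01)
  })
  fx <- sprintkan:::fit_family("x", x, y)
  fq <- sprintkan:::fit_family("x2", x, y)
  n <- length(x); vy <- mean((y - mean(y))^2)
  score <- function(f, fam) f$rss / (n * vy) +
    0.002 * sprintkan:::sym_complexity(fam)
  expect_lt(score(fq, "x2"), score(fx, "x"))
  expect_identical(fit_edge_family(x, y)$family, "x2")
})

test_that("degenerate constant edges select the const family", {
  f <- fit_edge_family(runif(50), rep(2.5, 50))
  expect_identical(f$family, "const")
  expect_equal(f$d, 2.5)
})

test_that("the packaged reference equation evaluates as printed", {
  eq <- reference_sprint_equation()
  expect_equal(round(predict_symbolic(eq, rep(0, 9)), 3), 11.085)
  x7 <- rep(0, 9); x7[7] <- 1
  expect_equal(predict_symbolic(eq, x7) - predict_symbolic(eq, rep(0, 9)),
               0.2996, tolerance = 1e-12)
  expect_match(equation_string(eq), "exp")
  # matrix evaluation, one prediction per row
  X <- rbind(rep(0, 9), x7)
  expect_length(predict_symbolic(eq, X), 2)
})

test_that("symbolic models guard their domains and reject empty models", {
  empty <- symbolic_model(data.frame(family = character(), input = integer(),
                                     a = numeric(), b = numeric(),
                                     c = numeric(), d = numeric()),
                          intercept = 0)
  expect_error(predict_symbolic(empty, rep(0, 9)), "empty symbolic model")
  logm <- symbolic_model(data.frame(family = "log", input = 1, a = 1, b = 0,
                                    c = 1, d = 0), intercept = 0)
  expect_error(predict_symbolic(logm, -1), "domain error")
})

test_that("symbolizing a trained model reproduces its edges closely", {
  withr::with_seed(4, {
    X <- matrix(runif(540), 270, 2)
    y <- sin(3 * X[, 1]) + 2 * X[, 2] + rnorm(270, 0, 0.02)
  })
  m <- kan_train(kan_new(c(2, 1), 5, seed = 4), X, y, kan_config(seed = 4))
  sym <- kan_symbolize(m, X)
  expect_s3_class(sym, "kan_symbolic")
  pred_spline <- kan_forward(m, X)
  pred_sym <- predict_kan_symbolic(sym, X)
  expect_lt(sqrt(mean((pred_sym - pred_spline)^2)) / sd(y), 0.15)
  # single-layer networks always flatten
  expect_false(is.null(sym$flat))
  expect_equal(predict_symbolic(sym$flat, X), pred_sym, tolerance = 1e-8)
})

test_that("affine deeper layers flatten to an additive closed form", {
  sym <- structure(list(
    widths = c(2L, 2L, 1L),
    edges = list(
      data.frame(input = c(1L, 2L), output = c(1L, 2L),
                 family = c("x2", "exp"), a = c(1, 2), b = c(-0.5, 0),
                 c = c(2, 0.3), d = c(0.1, -0.2), nmse = 0),
      data.frame(input = c(1L, 2L), output = c(1L, 1L),
                 family = c("x", "x"), a = c(1, 1), b = c(0, 0),
                 c = c(3, -1), d = c(0.5, 0), nmse = 0)),
    scaler = list(min = c(0, 0), max = c(1, 1)),
    y_center = 0, y_scale = 1), class = "kan_symbolic")
  flat <- sprintkan:::flatten_symbolic(sym)
  X <- matrix(runif(40), 20, 2)
  expect_equal(predict_symbolic(flat, X), predict_kan_symbolic(sym, X),
               tolerance = 1e-10)
  # a non-affine deep edge blocks flattening
  sym$edges[[2]]$family[1] <- "sin"
  expect_error(sprintkan:::flatten_symbolic(sym), "cannot be flattened")
})

test_that("symbolic models round-trip through JSON", {
  eq <- reference_sprint_equation()
  tmp <- tempfile(fileext = ".json")
  write_symbolic_model(eq, tmp)
  back <- read_symbolic_model(tmp)
  expect_equal(back$intercept, eq$intercept)
  expect_equal(back$terms$c, eq$terms$c)
  X <- matrix(runif(18), 2, 9)
  expect_equal(predict_symbolic(back, X), predict_symbolic(eq, X))
})
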