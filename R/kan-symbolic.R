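# Symbolic compression: every surviving spline edge is replaced by the
# best closed form c * g(a*x + b) + d with g drawn from the library
# {x, x^2, exp, log, sin, const}, selected by a complexity-penalized fit.
# A symbolic network flattens to an additive closed-form model whenever
# all edges past the first layer are affine.

SYM_FAMILIES <- c("x", "x2", "exp", "log", "sin", "const")

sym_complexity <- function(family) {
  switch(family, const = 1, x = 2, x2 = 3, exp = 3, log = 4, sin = 4,
         stop("unknown family: ", family))
}

sym_eval_term <- function(family, x, a, b, c, d) {
  z <- a * x + b
  inner <- switch(family,
                  x = z,
                  x2 = z^2,
                  exp = exp(z),
                  log = {
                    if (any(z <= 0)) stop("domain error: log of non-positive argument")
                    log(z)
                  },
                  sin = sin(z),
                  const = rep(1, length(x)),
                  stop("unknown family: ", family))
  c * inner + d
}

# inner linear solve for (c, d) given a transformed regressor
lin_cd <- function(g, y) {
  vg <- sum((g - mean(g))^2)
  if (!all(is.finite(g)) || vg < 1e-14) {
    return(list(c = 0, d = mean(y), rss = sum((y - mean(y))^2)))
  }
  cc <- sum((g - mean(g)) * (y - mean(y))) / vg
  dd <- mean(y) - cc * mean(g)
  list(c = cc, d = dd, rss = sum((y - cc * g - dd)^2))
}

fit_family <- function(family, x, y) {
  n <- length(x)
  rng <- range(x)
  span <- max(rng[2L] - rng[1L], 1e-9)
  if (family == "const") {
    return(list(family = family, a = 0, b = 0, c = 0, d = mean(y),
                rss = sum((y - mean(y))^2)))
  }
  if (family == "x") {
    f <- lin_cd(x, y)
    return(list(family = family, a = 1, b = 0, c = f$c, d = f$d, rss = f$rss))
  }
  if (family == "x2") {
    X <- cbind(1, x, x^2)
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf)) || abs(cf[3L]) < 1e-12) {
      f <- lin_cd(x^2, y)
      return(list(family = family, a = 1, b = 0, c = f$c, d = f$d, rss = f$rss))
    }
    cq <- cf[3L]
    b <- cf[2L] / (2 * cq)
    d <- cf[1L] - cq * b^2
    rss <- sum((y - X %*% cf)^2)
    return(list(family = family, a = 1, b = b, c = cq, d = d, rss = rss))
  }
  if (family == "exp") {
    amax <- 20 / max(abs(rng))
    agrid <- setdiff(seq(-6, 6, by = 0.5), 0)
    agrid <- agrid[abs(agrid) <= amax]
    if (!length(agrid)) agrid <- c(-amax, amax) / 2
    rss_a <- function(a) lin_cd(exp(a * x), y)$rss
    r <- vapply(agrid, rss_a, numeric(1))
    a0 <- agrid[which.min(r)]
    oa <- optimize(rss_a, interval = c(a0 - 0.6, a0 + 0.6))
    a <- oa$minimum
    f <- lin_cd(exp(a * x), y)
    return(list(family = family, a = a, b = 0, c = f$c, d = f$d, rss = f$rss))
  }
  if (family == "log") {
    cand <- list()
    for (a in c(-4, -2, -1, -0.5, 0.5, 1, 2, 4) / span) {
      for (delta in c(0.05, 0.2, 0.5, 1, 2) * abs(a) * span) {
        b <- delta - min(a * rng)
        z <- a * x + b
        if (any(z <= 0)) next
        f <- lin_cd(log(z), y)
        cand[[length(cand) + 1L]] <- c(a, b, f$rss)
      }
    }
    if (!length(cand)) {
      return(list(family = family, a = 0, b = 1, c = 0, d = mean(y),
                  rss = sum((y - mean(y))^2)))
    }
    cb <- do.call(rbind, cand)
    best <- cb[which.min(cb[, 3L]), ]
    ob <- function(p) {
      z <- p[1L] * x + p[2L]
      if (any(z <= 0)) return(1e12)
      lin_cd(log(z), y)$rss
    }
    op <- optim(best[1:2], ob, method = "Nelder-Mead",
                control = list(maxit = 300))
    a <- op$par[1L]
    b <- op$par[2L]
    if (any(a * x + b <= 0)) {
      a <- best[1L]
      b <- best[2L]
    }
    f <- lin_cd(log(a * x + b), y)
    return(list(family = family, a = a, b = b, c = f$c, d = f$d, rss = f$rss))
  }
  if (family == "sin") {
    agrid <- seq(0.5, 15, by = 0.5) / span
    bgrid <- seq(0, 2 * pi - pi / 4, by = pi / 4)
    best <- NULL
    for (a in agrid) for (b in bgrid) {
      f <- lin_cd(sin(a * x + b), y)
      if (is.null(best) || f$rss < best[3L]) best <- c(a, b, f$rss)
    }
    ob <- function(p) lin_cd(sin(p[1L] * x + p[2L]), y)$rss
    op <- optim(best[1:2], ob, method = "Nelder-Mead",
                control = list(maxit = 400))
    a <- op$par[1L]
    b <- op$par[2L]
    f <- lin_cd(sin(a * x + b), y)
    # canonical form: positive amplitude, frequency, phase in [0, 2*pi)
    cc <- f$c
    if (a < 0) {
      a <- -a
      b <- pi - b
    }
    if (cc < 0) {
      cc <- -cc
      b <- b + pi
    }
    b <- b %% (2 * pi)
    return(list(family = family, a = a, b = b, c = cc, d = f$d, rss = f$rss))
  }
  stop("unknown family: ", family)
}

#' Fit the best library family to one edge
#'
#' Selects `argmin` over the function library of
#' `mse / var(y) + lambda_c * C(g)` where `C(g)` counts the family's free
#' parameters. Degenerate (constant-output) edges select `const`.
#'
#' @param x,y edge input and output samples.
#' @param lambda_c complexity penalty weight (default 0.002).
#' @param families subset of the library to consider.
#' @return list: family, a, b, c, d, score, nmse.
#' @export
fit_edge_family <- function(x, y, lambda_c = 0.002, families = SYM_FAMILIES) {
  n <- length(x)
  vy <- mean((y - mean(y))^2)
  if (vy < 1e-14) {
    return(list(family = "const", a = 0, b = 0, c = 0, d = mean(y),
                score = lambda_c, nmse = 0))
  }
  best <- NULL
  for (fam in families) {
    f <- tryCatch(fit_family(fam, x, y), error = function(e) NULL)
    if (is.null(f) || !all(is.finite(unlist(f[c("a", "b", "c", "d", "rss")])))) next
    nmse <- f$rss / (n * vy)
    score <- nmse + lambda_c * sym_complexity(fam)
    if (is.null(best) || score < best$score) {
      best <- c(f[c("family", "a", "b", "c", "d")],
                list(score = score, nmse = nmse))
    }
  }
  if (is.null(best)) stop("no admissible family fit for edge")
  best
}

#' Symbolically compress a pruned KAN
#'
#' Replaces every active spline edge with the best closed form from the
#' library (see [fit_edge_family()]), giving a symbolic network with the
#' same topology. When all edges past the first layer come out affine
#' (`x`/`const`), the network is flattened to an additive closed-form
#' [symbolic_model()] over the raw input features.
#'
#' @param model a trained (typically pruned) `kan`.
#' @param X training feature matrix (edge samples are taken from its
#'   activations).
#' @param lambda_c complexity penalty weight.
#' @param families library subset.
#' @return Object of class `kan_symbolic`; if flattening succeeded its
#'   `$flat` field holds the additive `symbolic_model`.
#' @export
kan_symbolize <- function(model, X, lambda_c = 0.002, families = SYM_FAMILIES) {
  stopifnot(inherits(model, "kan"))
  X <- as.matrix(X)
  U <- scale_features(model, X)
  fw <- kan_forward_raw(model, U, cache = TRUE)
  m <- model$n_basis
  layers <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    edges <- list()
    for (i in seq_len(nrow(lay$mask))) {
      d <- fw$cache[[l]]$designs[[i]]
      for (j in seq_len(ncol(lay$mask))) {
        if (!lay$mask[i, j]) next
        ys <- as.numeric(d$B %*% lay$coef[i, j, ])
        f <- fit_edge_family(fw$cache[[l]]$A[, i], ys, lambda_c, families)
        edges[[length(edges) + 1L]] <-
          data.frame(input = i, output = j, family = f$family,
                     a = f$a, b = f$b, c = f$c, d = f$d,
                     nmse = f$nmse, stringsAsFactors = FALSE)
      }
    }
    layers[[l]] <- if (length(edges)) do.call(rbind, edges) else
      data.frame(input = integer(), output = integer(), family = character(),
                 a = numeric(), b = numeric(), c = numeric(), d = numeric(),
                 nmse = numeric())
  }
  sym <- structure(list(widths = model$widths, edges = layers,
                        scaler = model$scaler,
                        y_center = model$y_center, y_scale = model$y_scale),
                   class = "kan_symbolic")
  sym$flat <- tryCatch(flatten_symbolic(sym), error = function(e) NULL)
  sym
}

#' @export
print.kan_symbolic <- function(x, ...) {
  n_edges <- sum(vapply(x$edges, nrow, integer(1)))
  fams <- table(unlist(lapply(x$edges, function(e) e$family)))
  cat(sprintf("<kan_symbolic> widths [%s], %d symbolic edges (%s); %s\n",
              paste(x$widths, collapse = ","), n_edges,
              paste(names(fams), fams, sep = ":", collapse = ", "),
              if (is.null(x$flat)) "not flattenable" else "flattened form available"))
  if (!is.null(x$flat)) cat("  ", equation_string(x$flat), "\n")
  invisible(x)
}

#' Predict from a symbolic network
#'
#' @param sym a `kan_symbolic`.
#' @param X raw feature matrix or vector.
#' @return Predictions in outcome units.
#' @export
predict_kan_symbolic <- function(sym, X) {
  stopifnot(inherits(sym, "kan_symbolic"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  A <- sweep(sweep(X, 2, sym$scaler$min), 2, sym$scaler$max - sym$scaler$min, "/")
  for (l in seq_along(sym$edges)) {
    out <- matrix(0, nrow(A), sym$widths[l + 1L])
    e <- sym$edges[[l]]
    for (r in seq_len(nrow(e))) {
      out[, e$output[r]] <- out[, e$output[r]] +
        sym_eval_term(e$family[r], A[, e$input[r]], e$a[r], e$b[r], e$c[r], e$d[r])
    }
    A <- out
  }
  A[, 1L] * sym$y_scale + sym$y_center
}

# Flatten a symbolic network to an additive model over raw inputs.
# Requires every edge past layer 1 to be affine (family x or const).
flatten_symbolic <- function(sym) {
  L <- length(sym$edges)
  if (L > 1L) {
    for (l in 2:L) {
      if (!all(sym$edges[[l]]$family %in% c("x", "const"))) {
        stop("deeper edges are non-affine; network cannot be flattened")
      }
    }
  }
  # weight[j] = d(output)/d(node j of layer l), built backwards
  wts <- rep(1, sym$widths[L + 1L])
  const <- 0
  if (L > 1L) {
    for (l in L:2) {
      e <- sym$edges[[l]]
      w_in <- rep(0, sym$widths[l])
      for (r in seq_len(nrow(e))) {
        slope <- if (e$family[r] == "x") e$c[r] * e$a[r] else 0
        intercept <- if (e$family[r] == "x") e$c[r] * e$b[r] + e$d[r] else
          e$c[r] + e$d[r]
        w_in[e$input[r]] <- w_in[e$input[r]] + slope * wts[e$output[r]]
        const <- const + intercept * wts[e$output[r]]
      }
      wts <- w_in
    }
  }
  e1 <- sym$edges[[1L]]
  terms <- list()
  intercept <- const
  for (r in seq_len(nrow(e1))) {
    w <- wts[e1$output[r]]
    if (w == 0) next
    i <- e1$input[r]
    # fold the [0,1] feature scaling into the inner affine map
    scl <- 1 / (sym$scaler$max[i] - sym$scaler$min[i])
    a2 <- e1$a[r] * scl
    b2 <- e1$b[r] - e1$a[r] * scl * sym$scaler$min[i]
    if (e1$family[r] == "const") {
      intercept <- intercept + w * (e1$c[r] + e1$d[r])
      next
    }
    terms[[length(terms) + 1L]] <-
      data.frame(family = e1$family[r], input = i, a = a2, b = b2,
                 c = w * e1$c[r], d = 0, stringsAsFactors = FALSE)
    intercept <- intercept + w * e1$d[r]
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(family = character(), input = integer(), a = numeric(),
               b = numeric(), c = numeric(), d = numeric())
  # map back to outcome units
  terms$c <- terms$c * sym$y_scale
  terms$d <- terms$d * sym$y_scale
  intercept <- intercept * sym$y_scale + sym$y_center
  symbolic_model(terms, intercept)
}

#' Additive closed-form model
#'
#' A sum of terms `c * g(a * x_i + b) + d` over raw input features plus an
#' intercept, with `g` from the library {x, x^2, exp, log, sin, const}.
#'
#' @param terms data.frame with columns family, input, a, b, c, d.
#' @param intercept scalar intercept.
#' @return Object of class `symbolic_model`.
#' @export
symbolic_model <- function(terms, intercept = 0) {
  stopifnot(is.data.frame(terms),
            all(c("family", "input", "a", "b", "c", "d") %in% names(terms)),
            all(terms$family %in% SYM_FAMILIES))
  structure(list(terms = terms, intercept = intercept),
            class = "symbolic_model")
}

#' @export
print.symbolic_model <- function(x, ...) {
  cat("<symbolic_model>", equation_string(x), "\n")
  invisible(x)
}

#' Evaluate an additive symbolic model
#'
#' @param sym a [symbolic_model()].
#' @param features numeric vector (one row) or matrix of raw features.
#' @return Predicted outcome per row.
#' @export
predict_symbolic <- function(sym, features) {
  stopifnot(inherits(sym, "symbolic_model"))
  if (nrow(sym$terms) == 0L && identical(sym$intercept, 0)) {
    stop("empty symbolic model")
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  needed <- if (nrow(sym$terms)) max(sym$terms$input) else 0L
  if (ncol(features) < needed) {
    stop("feature matrix has ", ncol(features), " columns but the model ",
         "references x", needed)
  }
  y <- rep(sym$intercept, nrow(features))
  for (r in seq_len(nrow(sym$terms))) {
    tm <- sym$terms[r, ]
    y <- y + sym_eval_term(tm$family, features[, tm$input],
                           tm$a, tm$b, tm$c, tm$d)
  }
  y
}

#' Human-readable equation string
#'
#' @param sym a [symbolic_model()].
#' @param digits significant digits for coefficients.
#' @return A single string such as `"y = 11.085 + 0.2996*x7 + ..."`.
#' @export
equation_string <- function(sym, digits = 4) {
  stopifnot(inherits(sym, "symbolic_model"))
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  parts <- character()
  for (r in seq_len(nrow(sym$terms))) {
    tm <- sym$terms[r, ]
    inner <- if (tm$b == 0) sprintf("%s*x%d", fmt(tm$a), tm$input) else
      sprintf("%s*x%d %s %s", fmt(tm$a), tm$input,
              if (tm$b >= 0) "+" else "-", fmt(abs(tm$b)))
    if (tm$family == "x" && tm$a == 1 && tm$b == 0) inner <- sprintf("x%d", tm$input)
    core <- switch(tm$family,
                   x = inner,
                   x2 = sprintf("(%s)^2", inner),
                   exp = sprintf("exp(%s)", inner),
                   log = sprintf("log(%s)", inner),
                   sin = sprintf("sin(%s)", inner),
                   const = "1")
    term <- sprintf("%s*%s", fmt(abs(tm$c)), core)
    parts <- c(parts, sprintf("%s %s", if (tm$c >= 0) "+" else "-", term))
    if (tm$d != 0) {
      parts <- c(parts, sprintf("%s %s", if (tm$d >= 0) "+" else "-",
                                fmt(abs(tm$d))))
    }
  }
  paste("y =", paste(c(fmt(sym$intercept), parts), collapse = " "))
}

#' The packaged reference sprint-velocity equation
#'
#' Loads the closed-form equation mapping the nine neuromuscular features
#' (x1-x3: RA-BF alpha/beta/gamma coherence; x4-x6: TA-GL alpha/beta/gamma
#' coherence; x7-x9: rectus femoris iEMG, RMS, MF) to sprint phase
#' velocity (m/s) that ships with the package. It serves as the worked
#' example of a compressed model and as generative ground truth for
#' recovery experiments.
#'
#' @return A [symbolic_model()].
#' @export
reference_sprint_equation <- function() {
  path <- system.file("extdata", "reference_sprint_equation.json",
                      package = "sprintkan")
  if (path == "") stop("packaged reference equation not found")
  read_symbolic_model(path)
}

#' Read an additive symbolic model from JSON
#' @param path JSON file as written by [write_symbolic_model()].
#' @return A [symbolic_model()].
#' @export
read_symbolic_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- do.call(rbind, lapply(obj$terms, function(t) {
    data.frame(family = t$family, input = as.integer(t$input),
               a = as.numeric(t$a), b = as.numeric(t$b),
               c = as.numeric(t$c), d = as.numeric(t$d),
               stringsAsFactors = FALSE)
  }))
  symbolic_model(terms, intercept = as.numeric(obj$intercept))
}

#' Write an additive symbolic model to JSON
#' @param sym a [symbolic_model()].
#' @param path output file.
#' @export
write_symbolic_model <- function(sym, path) {
  stopifnot(inherits(sym, "symbolic_model"))
  obj <- list(intercept = sym$intercept,
              equation = equation_string(sym),
              terms = unname(lapply(seq_len(nrow(sym$terms)), function(r) {
                as.list(sym$terms[r, ])
              })))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
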