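# Evaluation and serialization.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum (y - yhat)^2 / sum (y - mean(y))^2`; may be negative for
#' predictions worse than the mean.
#'
#' @param predictions,truths numeric vectors of equal length (n >= 2).
#' @return Scalar R-squared.
#' @export
r_squared <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) >= 2L)
  ss_tot <- sum((truths - mean(truths))^2)
  if (ss_tot <= 0) stop("truths have zero variance: R^2 undefined")
  1 - sum((truths - predictions)^2) / ss_tot
}

#' Serialize a KAN to JSON
#'
#' Widths, grid, knot domains, coefficient arrays, edge masks and scalers
#' round-trip exactly through [kan_load()].
#'
#' @param model a `kan`.
#' @param path output JSON file.
#' @export
kan_save <- function(model, path) {
  stopifnot(inherits(model, "kan"))
  obj <- list(widths = model$widths, grid = model$grid,
              n_basis = model$n_basis,
              y_center = model$y_center, y_scale = model$y_scale,
              seed = model$seed,
              scaler = model$scaler,
              layers = lapply(model$layers, function(l) {
                list(dim = dim(l$coef), coef = as.numeric(l$coef),
                     mask = as.logical(l$mask), lo = l$lo, hi = l$hi)
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a KAN from JSON
#'
#' @param path JSON file written by [kan_save()].
#' @return A `kan`.
#' @export
kan_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(obj$layers, function(l) {
    d <- as.integer(unlist(l$dim))
    list(coef = array(as.numeric(unlist(l$coef)), dim = d),
         mask = matrix(as.logical(unlist(l$mask)), d[1L], d[2L]),
         lo = as.numeric(unlist(l$lo)), hi = as.numeric(unlist(l$hi)))
  })
  scaler <- if (is.null(obj$scaler)) NULL else
    list(min = as.numeric(unlist(obj$scaler$min)),
         max = as.numeric(unlist(obj$scaler$max)))
  structure(list(widths = as.integer(unlist(obj$widths)),
                 grid = as.integer(obj$grid),
                 n_basis = as.integer(obj$n_basis), layers = layers,
                 scaler = scaler, y_center = as.numeric(obj$y_center),
                 y_scale = as.numeric(obj$y_scale),
                 seed = as.integer(obj$seed)),
            class = "kan")
}
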