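# Edge pruning. Importance of an edge is the standard deviation of its
# output over the training inputs (on the standardized-target scale), so
# the |w| > 0.2 keep-rule reads as "the edge moves the prediction by more
# than 0.2 standardized units". Nodes left without active incoming or
# outgoing edges are removed by masking their remaining edges.

# per-edge output sd on training inputs; returns list of n_in x n_out mats
edge_importance <- function(model, U) {
  fw <- kan_forward_raw(model, U, cache = TRUE)
  m <- model$n_basis
  lapply(seq_along(model$layers), function(l) {
    lay <- model$layers[[l]]
    n_in <- model$widths[l]
    n_out <- model$widths[l + 1L]
    W <- matrix(0, n_in, n_out)
    for (i in seq_len(n_in)) {
      Ci <- masked_coef(lay, i, m)
      outs <- fw$cache[[l]]$designs[[i]]$B %*% t(Ci)   # N x n_out
      W[i, ] <- apply(outs, 2, sd)
    }
    W[!lay$mask] <- 0
    W
  })
}

#' Prune a trained KAN
#'
#' Masks edges whose importance (output standard deviation on the training
#' inputs, standardized-target scale) does not exceed `threshold`, then
#' removes nodes with no active incoming or outgoing edges. Optionally
#' refits the surviving coefficients.
#'
#' @param model a trained `kan`.
#' @param X training feature matrix (importance is data dependent).
#' @param threshold importance threshold; edges with `w > threshold` are
#'   kept (default 0.2).
#' @param refit retrain surviving edges after masking (requires `y`).
#' @param y training outcome, needed when `refit = TRUE`.
#' @param cfg a [kan_config()] for the refit.
#' @param fallback what to do when thresholding would disconnect the
#'   output: `"error"` (default) stops with guidance; `"backbone"`
#'   additionally keeps the maximum-importance path from the output back
#'   to an input, so a connected predictor always survives (used by the
#'   cross-validation pipeline).
#' @return The pruned (and optionally refitted) model; `$importance`
#'   holds the importance matrices.
#' @export
kan_prune <- function(model, X, threshold = 0.2, refit = FALSE, y = NULL,
                      cfg = kan_config(), fallback = c("error", "backbone")) {
  stopifnot(inherits(model, "kan"))
  fallback <- match.arg(fallback)
  X <- as.matrix(X)
  U <- scale_features(model, X)
  W <- edge_importance(model, U)
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$mask <- model$layers[[l]]$mask & (W[[l]] > threshold)
  }
  if (fallback == "backbone") {
    need <- 1L
    for (l in rev(seq_along(model$layers))) {
      i_best <- which.max(W[[l]][, need])
      model$layers[[l]]$mask[i_best, need] <- TRUE
      need <- i_best
    }
  }
  # propagate: a node with no active input edges outputs a constant 0, so
  # its outgoing edges are constant and masked; a node feeding nothing is
  # masked backwards. Iterate to a fixed point.
  repeat {
    changed <- FALSE
    for (l in seq_along(model$layers)) {
      msk <- model$layers[[l]]$mask
      if (l > 1L) {
        dead_in <- colSums(model$layers[[l - 1L]]$mask) == 0L
        if (any(dead_in & rowSums(msk) > 0L)) {
          msk[dead_in, ] <- FALSE
          changed <- TRUE
        }
      }
      if (l < length(model$layers)) {
        dead_out <- rowSums(model$layers[[l + 1L]]$mask) == 0L
        if (any(dead_out & colSums(msk) > 0L)) {
          msk[, dead_out] <- FALSE
          changed <- TRUE
        }
      }
      model$layers[[l]]$mask <- msk
    }
    if (!changed) break
  }
  last <- model$layers[[length(model$layers)]]
  if (sum(last$mask) == 0L) {
    stop("pruning removed every edge into the output; lower the threshold ",
         "(current ", threshold, ")")
  }
  # masked coefficients are frozen at zero
  for (l in seq_along(model$layers)) {
    msk <- model$layers[[l]]$mask
    for (i in seq_len(nrow(msk))) {
      model$layers[[l]]$coef[i, !msk[i, ], ] <- 0
    }
  }
  model$importance <- W
  if (refit) {
    if (is.null(y)) stop("refit = TRUE requires y")
    model <- kan_train(model, X, y, cfg)
  }
  model
}

#' Surviving input features of a pruned model
#'
#' @param model a `kan`.
#' @return Integer indices of inputs with at least one active outgoing
#'   edge.
#' @export
kan_active_inputs <- function(model) {
  which(rowSums(model$layers[[1L]]$mask) > 0L)
}
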