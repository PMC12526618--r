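# Orchestration: feature-matrix assembly, grouped cross-validation, grid
# sweep, and the end-to-end run (simulate -> features -> coherence ->
# model -> statistics -> report).

#' Assemble the 9-feature model matrix
#'
#' Joins the EMG feature table and the coherence table into one row per
#' (participant, condition, phase) with the canonical feature order:
#' x1-x3 RA-BF alpha/beta/gamma coherence, x4-x6 TA-GL alpha/beta/gamma
#' coherence, x7-x9 rectus femoris iEMG, RMS, MF. The outcome `y` is the
#' phase velocity.
#'
#' @param features long feature table from [extract_features()].
#' @param imc long coherence table from [compute_imc()].
#' @param velocities data.frame with participant, condition, phase,
#'   velocity (e.g. `cohort$rows`); optional — without it `y` is `NA`.
#' @return data.frame: participant, condition, phase, x1..x9, y.
#' @export
build_feature_matrix <- function(features, imc, velocities = NULL) {
  key <- function(d) paste(d$participant, d$condition, d$phase, sep = "|")
  fk <- unique(key(features))
  ik <- unique(key(imc))
  miss <- c(setdiff(fk, ik), setdiff(ik, fk))
  if (length(miss)) {
    stop("feature and coherence tables cover different cells: ",
         paste(unique(miss), collapse = ", "))
  }
  extra <- setdiff(unique(features$channel), c("RA", "BF", "TA", "GL"))
  if (length(extra)) warning("ignoring extra channels: ", paste(extra, collapse = ", "))
  cells <- unique(features[, c("participant", "condition", "phase")])
  rownames(cells) <- NULL
  bands <- c("alpha", "beta", "gamma")
  X <- matrix(NA_real_, nrow(cells), 9L,
              dimnames = list(NULL, paste0("x", 1:9)))
  ck <- key(cells)
  ikey <- key(imc)
  fkey <- key(features)
  for (r in seq_len(nrow(cells))) {
    sel_i <- imc[ikey == ck[r], ]
    for (b in 1:3) {
      X[r, b] <- sel_i$coherence[sel_i$pair == "RA-BF" & sel_i$band == bands[b]][1L]
      X[r, b + 3L] <- sel_i$coherence[sel_i$pair == "TA-GL" & sel_i$band == bands[b]][1L]
    }
    sel_f <- features[fkey == ck[r] & features$channel == "RA", ]
    X[r, 7L] <- sel_f$iemg[1L]
    X[r, 8L] <- sel_f$rms[1L]
    X[r, 9L] <- sel_f$mf[1L]
  }
  if (anyNA(X)) stop("missing feature cells; check pair/band/channel coverage")
  out <- cbind(cells, as.data.frame(X))
  out$y <- NA_real_
  if (!is.null(velocities)) {
    vk <- key(velocities)
    miss_v <- setdiff(ck, vk)
    if (length(miss_v)) stop("velocities missing for cells: ",
                             paste(miss_v, collapse = ", "))
    out$y <- velocities$velocity[match(ck, vk)]
  }
  out
}

#' Feature matrix straight from a cohort
#'
#' Convenience wrapper: [extract_features()] + [compute_imc()] +
#' [build_feature_matrix()].
#'
#' @param cohort a `sprint_cohort`.
#' @param segment_s,overlap_frac Welch parameters for the coherence stage.
#' @return data.frame as from [build_feature_matrix()].
#' @export
feature_matrix <- function(cohort, segment_s = 0.5, overlap_frac = 0.5) {
  fe <- extract_features(cohort)
  ic <- compute_imc(cohort, segment_s = segment_s, overlap_frac = overlap_frac)
  build_feature_matrix(fe, ic, cohort$rows)
}

# deterministic grouped fold assignment: participants shuffled by seed and
# dealt round-robin into folds
grouped_folds <- function(participants, folds, seed) {
  ids <- unique(participants)
  if (length(ids) < folds) {
    stop("grouped CV needs at least as many participants (", length(ids),
         ") as folds (", folds, ")")
  }
  ord <- withr::with_seed(as.integer(seed), sample(ids))
  fold_of <- setNames(rep(seq_len(folds), length.out = length(ord)), ord)
  unname(fold_of[as.character(participants)])
}

#' Grouped cross-validation of the KAN pipeline
#'
#' Participants are partitioned into folds (no participant appears in two
#' folds unless `grouped = FALSE`, which splits rows instead). Per fold:
#' fit scalers on the training split, train, optionally prune (with
#' refit), and evaluate R-squared on the held-out rows.
#'
#' @param fm feature matrix from [build_feature_matrix()].
#' @param cfg a [kan_config()].
#' @param folds number of folds (default 3).
#' @param widths,grid network architecture.
#' @param seed seed controlling fold assignment and initialization.
#' @param prune prune (+refit) before evaluation (default TRUE).
#' @param grouped participant-grouped split (default TRUE).
#' @return list: `per_fold` (fold, r2, n_test), `mean_r2`, `folds`
#'   (row assignment), `models`.
#' @export
cross_validate <- function(fm, cfg = kan_config(), folds = 3,
                           widths = c(9, 5, 3, 1), grid = 5,
                           seed = cfg$seed, prune = TRUE, grouped = TRUE) {
  xcols <- paste0("x", seq_len(widths[1L]))
  stopifnot(all(xcols %in% names(fm)), "y" %in% names(fm))
  fold_id <- if (grouped) {
    grouped_folds(fm$participant, folds, seed)
  } else {
    withr::with_seed(as.integer(seed),
                     sample(rep(seq_len(folds), length.out = nrow(fm))))
  }
  per <- vector("list", folds)
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fm[fold_id != f, ]
    te <- fm[fold_id == f, ]
    Xtr <- as.matrix(tr[, xcols])
    Xte <- as.matrix(te[, xcols])
    mod <- kan_new(widths, grid, seed = trial_seed(seed, f))
    mod <- kan_train(mod, Xtr, tr$y, cfg)
    if (prune) {
      mod <- kan_prune(mod, Xtr, threshold = cfg$prune_threshold,
                       refit = TRUE, y = tr$y, cfg = cfg,
                       fallback = "backbone")
    }
    r2 <- r_squared(kan_forward(mod, Xte), te$y)
    per[[f]] <- data.frame(fold = f, r2 = r2, n_test = nrow(te))
    models[[f]] <- mod
  }
  per <- do.call(rbind, per)
  list(per_fold = per, mean_r2 = mean(per$r2), folds = fold_id,
       models = models)
}

#' Sweep the spline grid parameter
#'
#' Cross-validated train/validation MSE per grid value; selection is the
#' argmin of validation loss, ties broken toward the smaller grid.
#'
#' @param fm feature matrix.
#' @param grids grid values to evaluate (default `c(3, 5, 10, 20, 50,
#'   100)`: the sweep values plus the headline grid 5).
#' @param cfg a [kan_config()].
#' @param folds CV folds (default 3).
#' @param widths architecture.
#' @param seed seed.
#' @return data.frame (grid, train_mse, val_mse) with attribute
#'   `selected`.
#' @export
grid_sweep <- function(fm, grids = c(3, 5, 10, 20, 50, 100),
                       cfg = kan_config(), folds = 3,
                       widths = c(9, 5, 3, 1), seed = cfg$seed) {
  xcols <- paste0("x", seq_len(widths[1L]))
  fold_id <- grouped_folds(fm$participant, folds, seed)
  res <- lapply(grids, function(g) {
    tr_mse <- val_mse <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fm[fold_id != f, ]
      te <- fm[fold_id == f, ]
      mod <- kan_new(widths, g, seed = trial_seed(seed, f))
      mod <- kan_train(mod, as.matrix(tr[, xcols]), tr$y, cfg)
      tr_mse[f] <- mean((kan_forward(mod, as.matrix(tr[, xcols])) - tr$y)^2)
      val_mse[f] <- mean((kan_forward(mod, as.matrix(te[, xcols])) - te$y)^2)
    }
    data.frame(grid = g, train_mse = mean(tr_mse), val_mse = mean(val_mse))
  })
  res <- do.call(rbind, res)
  ord <- order(res$val_mse, res$grid)
  attr(res, "selected") <- res$grid[ord[1L]]
  res
}

run_anova_tables <- function(fm, imc) {
  vel <- lapply(split(fm, fm$phase), function(d) {
    a <- rm_anova(d, outcome = "y")
    list(phase = d$phase[1L], outcome = "velocity", anova = unclass_anova(a))
  })
  keys <- unique(imc[, c("phase", "pair", "band")])
  coh <- lapply(seq_len(nrow(keys)), function(r) {
    d <- imc[imc$phase == keys$phase[r] & imc$pair == keys$pair[r] &
               imc$band == keys$band[r], ]
    a <- rm_anova(d, outcome = "coherence")
    list(phase = keys$phase[r], pair = keys$pair[r], band = keys$band[r],
         outcome = "coherence", anova = unclass_anova(a))
  })
  list(velocity = unname(vel), coherence = unname(coh))
}

unclass_anova <- function(a) {
  a <- unclass(a)
  a$means <- as.list(a$means)
  a$posthoc <- as.list(a$posthoc)
  a
}

#' Run configuration for the full pipeline
#'
#' @param synth a [cohort_config()].
#' @param kan a [kan_config()].
#' @param widths network widths.
#' @param folds CV folds.
#' @param grids grid-sweep values.
#' @param seed master seed (propagates to cohort, folds, inits).
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = cohort_config(), kan = kan_config(),
                       widths = c(9, 5, 3, 1), folds = 3,
                       grids = c(3, 5, 10, 20, 50, 100), seed = 42L) {
  stopifnot(folds >= 2)
  synth$seed <- as.integer(seed)
  kan$seed <- as.integer(seed)
  structure(list(synth = synth, kan = kan, widths = widths, folds = folds,
                 grids = grids, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' simulate -> EMG features -> intermuscular coherence -> feature matrix
#' -> grid sweep -> grouped CV -> fit on all data -> prune -> symbolic
#' compression -> repeated-measures ANOVA tables -> report. Deterministic
#' given (config, seed).
#'
#' @param cfg a [run_config()].
#' @param outdir optional directory; when given, the report is written as
#'   `report.json` and `report.md`.
#' @return Object of class `run_report`.
#' @export
run_full <- function(cfg = run_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- generate_cohort(cfg$synth)
  feats <- extract_features(cohort)
  imc <- compute_imc(cohort)
  fm <- build_feature_matrix(feats, imc, cohort$rows)
  sweep <- grid_sweep(fm, grids = cfg$grids, cfg = cfg$kan,
                      folds = cfg$folds, widths = cfg$widths, seed = cfg$seed)
  sel_grid <- attr(sweep, "selected")
  cv <- cross_validate(fm, cfg = cfg$kan, folds = cfg$folds,
                       widths = cfg$widths, grid = sel_grid, seed = cfg$seed)
  xcols <- paste0("x", seq_len(cfg$widths[1L]))
  final <- kan_new(cfg$widths, sel_grid, seed = cfg$seed)
  final <- kan_train(final, as.matrix(fm[, xcols]), fm$y, cfg$kan)
  final_pruned <- kan_prune(final, as.matrix(fm[, xcols]),
                            threshold = cfg$kan$prune_threshold,
                            refit = TRUE, y = fm$y, cfg = cfg$kan,
                            fallback = "backbone")
  sym <- kan_symbolize(final_pruned, as.matrix(fm[, xcols]))
  anova_tables <- run_anova_tables(fm, imc)
  report <- structure(list(
    provenance = list(seed = cfg$seed, config_hash = config_hash(cfg),
                      n_rows = nrow(fm),
                      package_version = as.character(utils::packageVersion("sprintkan"))),
    grid_sweep = as.list(as.data.frame(sweep)),
    selected_grid = sel_grid,
    cv = list(per_fold = as.list(cv$per_fold), mean_r2 = cv$mean_r2),
    pruned_model = list(
      active_inputs = kan_active_inputs(final_pruned),
      active_edges = vapply(final_pruned$layers,
                            function(l) sum(l$mask), numeric(1)),
      train_r2 = r_squared(kan_forward(final_pruned, as.matrix(fm[, xcols])),
                           fm$y)),
    symbolic = list(
      edge_families = lapply(sym$edges, function(e) as.list(e)),
      equation = if (!is.null(sym$flat)) equation_string(sym$flat) else NA),
    anova = anova_tables), class = "run_report")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d rows | selected grid %d | mean CV R^2 %.3f | %d active inputs\n",
              x$provenance$n_rows, x$selected_grid, x$cv$mean_r2,
              length(x$pruned_model$active_inputs)))
  invisible(x)
}

#' Write a run report as JSON and Markdown
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  md <- c("# Pipeline report", "",
          sprintf("- rows: %d", report$provenance$n_rows),
          sprintf("- selected grid: %d", report$selected_grid),
          sprintf("- mean CV R^2: %.4f", report$cv$mean_r2),
          sprintf("- equation: %s",
                  if (is.na(report$symbolic$equation)) "(nested; not flattenable)"
                  else report$symbolic$equation),
          "", "## Velocity ANOVA by phase", "")
  for (v in report$anova$velocity) {
    a <- v$anova
    md <- c(md, sprintf("- %s: F(%g, %g) = %.2f, p = %.4f, partial eta^2 = %.3f",
                        v$phase, a$df_effect, a$df_error, a$f_value,
                        a$p_selected, a$partial_eta_sq))
  }
  md <- c(md, "", "## Coherence ANOVA by phase/pair/band", "")
  for (v in report$anova$coherence) {
    a <- v$anova
    md <- c(md, sprintf("- %s %s %s: F(%g, %g) = %.2f, p = %.4f, partial eta^2 = %.3f",
                        v$phase, v$pair, v$band, a$df_effect, a$df_error,
                        a$f_value, a$p_selected, a$partial_eta_sq))
  }
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}
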