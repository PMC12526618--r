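# Inferential stage: Shapiro-Wilk normality screen, one-way
# repeated-measures ANOVA with Mauchly's sphericity test and
# Greenhouse-Geisser correction, Bonferroni-corrected paired post hocs,
# and partial eta-squared effect sizes.

check_long_table <- function(table, outcome, condition, participant) {
  for (nm in c(outcome, condition, participant)) {
    if (!nm %in% names(table)) stop("column '", nm, "' not found")
  }
  tab <- table(table[[participant]], table[[condition]])
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    cells <- apply(bad, 1L, function(ix) {
      paste0(rownames(tab)[ix[1L]], ":", colnames(tab)[ix[2L]])
    })
    stop("unbalanced table; cells not observed exactly once: ",
         paste(cells, collapse = ", "))
  }
  invisible(TRUE)
}

long_to_wide <- function(table, outcome, condition, participant) {
  conds <- unique(as.character(table[[condition]]))
  parts <- unique(as.character(table[[participant]]))
  Y <- matrix(NA_real_, length(parts), length(conds),
              dimnames = list(parts, conds))
  for (r in seq_len(nrow(table))) {
    Y[as.character(table[[participant]][r]),
      as.character(table[[condition]][r])] <- table[[outcome]][r]
  }
  Y
}

#' Shapiro-Wilk normality screen per condition
#'
#' Advisory screen: the analysis proceeds regardless, but violations are
#' worth knowing about before interpreting the ANOVA.
#'
#' @param table long data.frame.
#' @param outcome,condition column names (defaults `"value"`,
#'   `"condition"`).
#' @return data.frame: condition, n, statistic, p_value.
#' @export
shapiro_screen <- function(table, outcome = "value", condition = "condition") {
  if (!outcome %in% names(table) || !condition %in% names(table)) {
    stop("outcome/condition columns not found")
  }
  sp <- split(table[[outcome]], table[[condition]])
  out <- lapply(names(sp), function(cd) {
    x <- sp[[cd]]
    if (length(x) < 3L) stop("condition '", cd, "' has fewer than 3 observations")
    if (diff(range(x)) < .Machine$double.eps) {
      stop("condition '", cd, "' is degenerate (all values identical)")
    }
    sw <- shapiro.test(x)
    data.frame(condition = cd, n = length(x),
               statistic = unname(sw$statistic), p_value = sw$p.value)
  })
  do.call(rbind, out)
}

# Greenhouse-Geisser epsilon from the covariance of condition scores
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  if (k < 3L) return(1)
  S <- stats::cov(Y)
  # orthonormal contrasts orthogonal to the unit vector
  C <- stats::contr.helmert(k)
  C <- t(qr.Q(qr(C)))
  A <- C %*% S %*% t(C)
  eps <- sum(diag(A))^2 / ((k - 1) * sum(A^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition with Mauchly's sphericity test,
#' Greenhouse-Geisser corrected p-value, partial eta-squared, and
#' Bonferroni-corrected paired post hocs. The GG-corrected p is reported
#' alongside the uncorrected one; `p_selected` applies the conventional
#' rule (use GG when Mauchly p < 0.05).
#'
#' @param table balanced long data.frame: one row per
#'   (participant, condition).
#' @param outcome,condition,participant column names.
#' @return Object of class `rm_anova`: f_value, df_effect, df_error,
#'   p_value, gg_epsilon, p_gg, p_selected, partial_eta_sq, mauchly_w,
#'   mauchly_p, means, posthoc.
#' @export
rm_anova <- function(table, outcome = "value", condition = "condition",
                     participant = "participant") {
  check_long_table(table, outcome, condition, participant)
  Y <- long_to_wide(table, outcome, condition, participant)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L) stop("need at least 2 conditions")
  if (n < 2L) stop("need at least 2 participants")
  grand <- mean(Y)
  m_cond <- colMeans(Y)
  m_subj <- rowMeans(Y)
  ss_cond <- n * sum((m_cond - grand)^2)
  ss_subj <- k * sum((m_subj - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- if (ss_err <= 0) {
    if (ss_cond <= 0) 0 else Inf
  } else {
    (ss_cond / df1) / (ss_err / df2)
  }
  p <- if (is.finite(f)) pf(f, df1, df2, lower.tail = FALSE) else 0
  eps <- gg_epsilon(Y)
  p_gg <- if (is.finite(f)) pf(f, eps * df1, eps * df2, lower.tail = FALSE) else 0
  eta <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0
  mw <- mp <- NA_real_
  if (k >= 3L && ss_err > 0) {
    ml <- lm(Y ~ 1)
    idata <- data.frame(condition = factor(colnames(Y), levels = colnames(Y)))
    mt <- tryCatch(
      mauchly.test(ml, M = ~condition, X = ~1, idata = idata),
      error = function(e) NULL)
    if (!is.null(mt)) {
      mw <- unname(mt$statistic)
      mp <- mt$p.value
    }
  }
  sphericity_violated <- !is.na(mp) && mp < 0.05
  ph <- bonferroni_posthoc(table, outcome, condition, participant)
  res <- list(f_value = f, df_effect = df1, df_error = df2, p_value = p,
              gg_epsilon = eps, p_gg = p_gg,
              p_selected = if (sphericity_violated) p_gg else p,
              sphericity_violated = sphericity_violated,
              partial_eta_sq = eta, mauchly_w = mw, mauchly_p = mp,
              ss_effect = ss_cond, ss_error = ss_err, ss_subject = ss_subj,
              n = n, k = k,
              means = data.frame(condition = colnames(Y),
                                 mean = unname(m_cond),
                                 sd = apply(Y, 2, sd)),
              posthoc = ph)
  structure(res, class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.3f, p = %.4f (GG eps = %.3f, p_GG = %.4f), partial eta^2 = %.3f\n",
              x$df_effect, x$df_error, x$f_value, x$p_value, x$gg_epsilon,
              x$p_gg, x$partial_eta_sq))
  if (!is.na(x$mauchly_p)) {
    cat(sprintf("Mauchly W = %.3f, p = %.4f%s\n", x$mauchly_w, x$mauchly_p,
                if (x$sphericity_violated) " (sphericity violated; GG applied)" else ""))
  }
  invisible(x)
}

#' Partial eta-squared from an F statistic
#'
#' Back-computation identity
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, monotone increasing in F.
#'
#' @param f F statistic (>= 0).
#' @param df_effect,df_error degrees of freedom (>= 1).
#' @return Effect size in `[0, 1)`.
#' @export
partial_eta_from_f <- function(f, df_effect, df_error) {
  stopifnot(all(f >= 0), all(df_effect >= 1), all(df_error >= 1))
  f * df_effect / (f * df_effect + df_error)
}

#' Bonferroni-corrected paired post hocs
#'
#' Paired t-tests for every condition pair; corrected p is the raw p times
#' the number of pairs, capped at 1.
#'
#' @param table balanced long data.frame.
#' @param outcome,condition,participant column names.
#' @return data.frame: pair, mean_diff, t, df, p_raw, p_bonferroni,
#'   significant.
#' @export
bonferroni_posthoc <- function(table, outcome = "value",
                               condition = "condition",
                               participant = "participant") {
  check_long_table(table, outcome, condition, participant)
  Y <- long_to_wide(table, outcome, condition, participant)
  conds <- colnames(Y)
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  np <- length(pairs)
  out <- lapply(pairs, function(pr) {
    d <- Y[, pr[1L]] - Y[, pr[2L]]
    tt <- t.test(d)
    data.frame(pair = paste(pr, collapse = " vs "),
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * np))
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_bonferroni < 0.05
  out
}
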