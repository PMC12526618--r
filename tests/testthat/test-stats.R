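# Repeated-measures statistics stage.

test_that("shapiro screen accepts normal and flags skewed samples", {
  norm_pass <- vapply(1:20, function(s) {
    tab <- withr::with_seed(s, data.frame(participant = 1:30, condition = "a",
                                          value = rnorm(30)))
    shapiro_screen(tab)$p_value > 0.05
  }, logical(1))
  expect_gte(sum(norm_pass), 18 - 3)  # type-I error ~5%
  skew_flag <- vapply(1:20, function(s) {
    tab <- withr::with_seed(s + 100, data.frame(participant = 1:30,
                                                condition = "a",
                                                value = rexp(30)))
    shapiro_screen(tab)$p_value < 0.05
  }, logical(1))
  expect_gte(sum(skew_flag), 15)
  expect_error(shapiro_screen(data.frame(participant = 1:2, condition = "a",
                                         value = c(1, 2))), "fewer than 3")
  expect_error(shapiro_screen(data.frame(participant = 1:5, condition = "a",
                                         value = rep(1, 5))), "degenerate")
})

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  for (s in 1:5) {
    tab <- random_long_table(n = 6, k = 3, seed = s)
    a <- rm_anova(tab)
    Y <- withr::with_seed(s, matrix(rnorm(18), 6, 3,
                                    dimnames = list(paste0("P", 1:6),
                                                    paste0("c", 1:3))))
    o <- brute_force_rm_anova(Y)
    expect_equal(a$f_value, o$f, tolerance = 1e-10)
    expect_equal(a$partial_eta_sq, o$eta, tolerance = 1e-10)
    expect_equal(a$ss_effect, o$ss_cond, tolerance = 1e-10)
    expect_equal(a$ss_error, o$ss_err, tolerance = 1e-10)
  }
})

test_that("rm_anova agrees with the multivariate-model route (anova.mlm)", {
  tab <- random_long_table(n = 10, k = 4, seed = 11)
  a <- rm_anova(tab)
  Y <- withr::with_seed(11, matrix(rnorm(40), 10, 4,
                                   dimnames = list(paste0("P", 1:10),
                                                   paste0("c", 1:4))))
  fit <- lm(Y ~ 1)
  idata <- data.frame(condition = factor(colnames(Y)))
  av <- anova(fit, M = ~condition, X = ~1, idata = idata, test = "Spherical")
  expect_equal(a$f_value, av$F[1], tolerance = 1e-8)
  expect_equal(a$p_value, av$`Pr(>F)`[1], tolerance = 1e-8)
  expect_equal(a$p_gg, av$`G-G Pr`[1], tolerance = 1e-8)
})

test_that("two-condition F equals the squared paired t statistic", {
  Y <- matrix(c(4.1, 5.0, 3.2, 4.8, 5.5,
                4.6, 5.4, 3.1, 5.6, 5.9), 5, 2,
              dimnames = list(paste0("P", 1:5), c("a", "b")))
  a <- rm_anova(wide_to_long(Y))
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(a$f_value, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-8)
})

test_that("identical condition profiles give F = 0 and zero effect size", {
  Y <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3,
              dimnames = list(paste0("P", 1:4), c("a", "b", "c")))
  a <- rm_anova(wide_to_long(Y))
  expect_identical(a$f_value, 0)
  expect_identical(a$partial_eta_sq, 0)
})

test_that("GG epsilon is bounded and 1 for compound-symmetric covariance", {
  for (s in 1:5) {
    tab <- random_long_table(n = 8, k = 4, seed = s + 40)
    a <- rm_anova(tab)
    expect_gte(a$gg_epsilon, 1 / 3)
    expect_lte(a$gg_epsilon, 1)
  }
  # construct data whose sample covariance is exactly compound symmetric
  withr::with_seed(3, Z <- matrix(rnorm(60), 20, 3))
  Z <- scale(Z, center = TRUE, scale = FALSE)
  S_emp <- crossprod(Z) / (nrow(Z) - 1)
  W <- Z %*% solve(chol(S_emp))
  target <- 0.3 + diag(0.7, 3)
  Y <- W %*% chol(target)
  colnames(Y) <- c("a", "b", "c"); rownames(Y) <- paste0("P", 1:20)
  a <- rm_anova(wide_to_long(Y))
  expect_equal(a$gg_epsilon, 1, tolerance = 1e-8)
})

test_that("a planted condition shift is detected with GG-corrected power", {
  hits <- vapply(1:20, function(s) {
    Y <- withr::with_seed(s, {
      base <- matrix(rnorm(90), 30, 3)
      base[, 2] <- base[, 2] + 1
      base
    })
    colnames(Y) <- c("a", "b", "c"); rownames(Y) <- paste0("P", 1:30)
    rm_anova(wide_to_long(Y))$p_gg < 0.05
  }, logical(1))
  expect_gte(sum(hits), 17)
})

test_that("partial eta squared identity is monotone and matches reports", {
  expect_equal(round(partial_eta_from_f(4.62, 2, 27), 3), 0.255)
  expect_equal(round(partial_eta_from_f(6.11, 2, 27), 2), 0.31)
  expect_equal(round(partial_eta_from_f(4.24, 2, 27), 2), 0.24)
  expect_identical(partial_eta_from_f(0, 2, 27), 0)
  fs <- seq(0, 20, by = 0.5)
  etas <- partial_eta_from_f(fs, 2, 27)
  expect_true(all(diff(etas) > 0))
  expect_true(all(etas >= 0 & etas < 1))
})

test_that("Bonferroni post hocs report all pairs with capped p-values", {
  tab <- random_long_table(n = 8, k = 3, seed = 21)
  ph <- bonferroni_posthoc(tab)
  expect_identical(nrow(ph), 3L)
  expect_true(all(ph$p_bonferroni <= 1))
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  # a raw p of 0.4 with 3 pairs caps at 1
  expect_true(all(pmin(1, ph$p_raw * 3) == ph$p_bonferroni))
  # only pairs involving the shifted condition reach significance
  hits <- vapply(1:20, function(s) {
    Y <- withr::with_seed(s + 500, {
      base <- matrix(rnorm(90), 30, 3)
      base[, 2] <- base[, 2] + 1
      base
    })
    colnames(Y) <- c("a", "b", "c"); rownames(Y) <- paste0("P", 1:30)
    ph <- bonferroni_posthoc(wide_to_long(Y))
    with_b <- grepl("b", ph$pair)
    all(ph$p_bonferroni[with_b] < 0.05) && ph$p_bonferroni[!with_b] >= 0.05
  }, logical(1))
  # the selectivity rate of this design is ~0.76 (measured over 200
  # simulations), so a majority of seeds must succeed
  expect_gte(sum(hits), 11)
})

test_that("unbalanced tables are rejected with the missing cells named", {
  tab <- random_long_table(n = 5, k = 3, seed = 31)
  tab <- tab[-2, ]
  expect_error(rm_anova(tab), "unbalanced")
  expect_error(rm_anova(tab), "P2")
})
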