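test_that("with no group variance the mixed model matches the OLS slope", {
  d <- simulate_lmm_table(50, 6, beta_std = 0.3, icc = 0, seed = 101)
  fit <- suppressWarnings(fit_lmm(d, "y", "x", "g"))
  ols <- unname(coef(lm(y ~ x, d))[2])
  expect_lt(abs(fit$fixed_slope - ols), 1e-4)
  expect_equal(fit$random_intercept_variance, 0)
})

test_that("a planted standardized slope is recovered within 3 SE", {
  d <- simulate_lmm_table(164, 6, beta_std = 0.25, icc = 0.3, seed = 23)
  fit <- fit_lmm(d, "y", "x", "g")
  se_std <- fit$slope_se * fit$sd_predictor / fit$sd_outcome
  expect_lt(abs(fit$standardized_beta - 0.25), 3 * se_std)
  expect_true(fit$converged)
  expect_equal(fit$n_groups, 164)
  expect_equal(fit$n_observations, 984)
  expect_true(fit$std_ci[1] <= fit$standardized_beta &&
                fit$standardized_beta <= fit$std_ci[2])
  expect_true(fit$marginal_r2 <= fit$conditional_r2)
  expect_true(fit$conditional_r2 <= 1)
})

test_that("post-hoc standardization rescales estimate and CI together", {
  std <- standardize_beta(list(estimate = 0.5, ci = c(0.1, 0.9)),
                          sd_predictor = 2, sd_outcome = 4)
  expect_equal(std$estimate, 0.25)
  expect_equal(std$ci, c(0.05, 0.45))
  # already-standardized data: no change
  ident <- standardize_beta(list(estimate = 0.3, ci = c(0.2, 0.4)), 1, 1)
  expect_equal(ident$estimate, 0.3)
  expect_error(standardize_beta(list(estimate = 1, ci = c(0, 2)), 0, 1),
               "positive")

  # rescaling the predictor's units leaves the standardized slope unchanged
  d <- simulate_lmm_table(60, 4, beta_std = 0.3, seed = 31)
  d2 <- d; d2$x <- d$x * 2
  f1 <- fit_lmm(d, "y", "x", "g")
  f2 <- fit_lmm(d2, "y", "x", "g")
  expect_equal(f2$fixed_slope, f1$fixed_slope / 2, tolerance = 1e-6)
  expect_equal(f2$standardized_beta, f1$standardized_beta, tolerance = 1e-6)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  d <- simulate_lmm_table(80, 6, beta_std = 0.3, seed = 41)
  fit <- fit_lmm(d, "y", "x", "g")
  # formula arithmetic through the override argument
  expect_equal(unname(lmm_r2(fit, fixed_effects_variance = NULL) -
                        lmm_r2(fit)), c(0, 0))
  manual <- mindfc:::nakagawa_r2(1, 1, 2)
  expect_equal(unname(manual), c(0.25, 0.5))

  # null slope: marginal R2 near zero
  d0 <- simulate_lmm_table(80, 6, beta_std = 0, seed = 43)
  fit0 <- fit_lmm(d0, "y", "x", "g")
  expect_lt(fit0$marginal_r2, 0.02)

  # no group variance: marginal equals conditional
  dg <- simulate_lmm_table(40, 8, beta_std = 0.3, icc = 0, seed = 45)
  fitg <- suppressWarnings(fit_lmm(dg, "y", "x", "g"))
  expect_equal(fitg$marginal_r2, fitg$conditional_r2, tolerance = 0.02)
})

test_that("Wald slope test is calibrated under the null", {
  n_sims <- 120
  p_vals <- vapply(seq_len(n_sims), function(i) {
    d <- simulate_lmm_table(60, 4, beta_std = 0, seed = 5000 + i)
    fit_lmm(d, "y", "x", "g")$slope_p
  }, 1.0)
  rate <- mean(p_vals < 0.05)
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_sims)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(51)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p), bh_oracle(p))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  adj <- fdr_bh(c(0.1, 0.01), family_label = "demo")
  expect_equal(attr(adj, "family"), "demo")
})

test_that("CCA with a univariate outcome equals the multiple correlation", {
  set.seed(61)
  X <- matrix(rnorm(200 * 12), 200, 12)
  y <- X %*% rnorm(12) * 0.1 + rnorm(200)
  cca <- cca_univariate_outcome(X, y)
  r_lm <- sqrt(summary(lm(y ~ X))$r.squared)
  expect_equal(cca$canonical_correlation, r_lm, tolerance = 1e-8)
  # and the first canonical correlation from the classical algorithm
  expect_equal(cca$canonical_correlation,
               cancor(X, matrix(y))$cor[1], tolerance = 1e-8)
  # loadings are correlations with the variate
  expect_true(all(abs(cca$loadings) <= 1))
  expect_equal(cca$loadings, drop(cor(X, cca$cv_scores)), tolerance = 1e-10)
  # sign convention: variate correlates positively with the outcome
  expect_gt(cor(cca$cv_scores, y), 0)
  # affine rescaling of a predictor changes nothing
  X2 <- X; X2[, 3] <- X2[, 3] * 100 + 7
  expect_equal(cca_univariate_outcome(X2, y)$canonical_correlation,
               cca$canonical_correlation, tolerance = 1e-10)
})

test_that("CCA degenerate and deficient cases behave as documented", {
  set.seed(63)
  x <- rnorm(50)
  y <- -0.6 * x + rnorm(50)
  one <- cca_univariate_outcome(matrix(x), y)
  expect_equal(one$canonical_correlation, abs(cor(x, y)), tolerance = 1e-10)

  X <- matrix(rnorm(60 * 3), 60, 3)
  y_in_span <- X %*% c(1, -2, 0.5)
  expect_equal(cca_univariate_outcome(X, y_in_span)$canonical_correlation, 1,
               tolerance = 1e-8)

  # duplicated column: reduced-rank warning, result matches the reduced set
  Xd <- cbind(X, X[, 1])
  yr <- X %*% c(0.3, 0.2, 0.1) + rnorm(60)
  expect_warning(dup <- cca_univariate_outcome(Xd, yr), "rank-deficient")
  expect_equal(dup$canonical_correlation,
               cca_univariate_outcome(X, yr)$canonical_correlation,
               tolerance = 1e-6)

  expect_error(cca_univariate_outcome(matrix(rnorm(100), 50, 2), rep(1, 50)),
               "constant")
  expect_error(cca_univariate_outcome(matrix(rnorm(12 * 36), 12, 36), rnorm(12)),
               "n > p")
})

test_that("canonical-variate scores are standardized linear combinations", {
  set.seed(71)
  X <- matrix(rnorm(40 * 5), 40, 5)
  expect_equal(cv_scores(X, rep(0, 5)), rep(0, 40))
  expect_equal(cv_scores(X[, 1, drop = FALSE], 1), as.numeric(scale(X[, 1])))
  # duplicated subjects receive identical scores
  Xdup <- X[c(1:40, 1), ]
  s <- cv_scores(Xdup, runif(5))
  expect_equal(s[41], s[1])
  expect_error(cv_scores(X, rep(1, 4)), "length")
  expect_error(cv_scores(X, rep(1, 5), mode = "magic"), "'arg'")
})

test_that("mediation satisfies the least-squares path identity exactly", {
  set.seed(81)
  for (i in 1:5) {
    d <- simulate_mediation_data(60, runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                                 runif(1, -0.4, 0.4), seed = 900 + i)
    med <- mediate(d$x, d$m, d$y, n_boot = 50, seed = i)
    expect_lt(abs(med$path_c - med$path_c_prime - med$indirect), 1e-10)
  }
})

test_that("planted full mediation is recovered and the bootstrap is reproducible", {
  d <- simulate_mediation_data(500, a = 0.5, b = 0.5, cprime = 0, seed = 97)
  med <- mediate(d$x, d$m, d$y, n_boot = 1000, seed = 7)
  expect_lt(abs(med$path_c_prime), 3 * med$path_c_prime_se)
  expect_gt(med$bootstrap_ci[1], 0)   # indirect clearly positive
  expect_true(med$significant)
  expect_equal(med$path_a, 0.5, tolerance = 0.15)
  expect_equal(med$ci_type, "percentile")

  med2 <- mediate(d$x, d$m, d$y, n_boot = 1000, seed = 7)
  expect_identical(med$bootstrap_ci, med2$bootstrap_ci)
  med3 <- mediate(d$x, d$m, d$y, n_boot = 1000, seed = 8)
  expect_false(identical(med$bootstrap_ci, med3$bootstrap_ci))

  expect_error(mediate(d$x, rep(1, 500), d$y), "constant")
  expect_error(mediate(1:5, 1:5, 1:5), "at least 10")
})

test_that("a disconnected mediator yields CIs covering zero almost always", {
  covers <- vapply(1:60, function(i) {
    set.seed(2000 + i)
    x <- rnorm(300); m <- rnorm(300); y <- 0.3 * x + rnorm(300)
    med <- mediate(x, m, y, n_boot = 300, seed = i)
    !med$significant
  }, TRUE)
  expect_gte(mean(covers), 0.9)
})

test_that("phenotype gate is inclusive at exactly 90% valid data", {
  behavior <- data.frame(subject = sprintf("s%03d", 1:100),
                         full = rnorm(100),
                         at_gate = c(rnorm(90), rep(NA, 10)),
                         below_gate = c(rnorm(89), rep(NA, 11)))
  inc <- phenotype_inclusion(behavior, threshold = 0.90)
  expect_true("full" %in% inc)
  expect_true("at_gate" %in% inc)      # 90% valid: kept ("at least 90%")
  expect_false("below_gate" %in% inc)  # 89% valid: excluded
  expect_equal(unname(attr(inc, "valid_fraction")["at_gate"]), 0.90)
  expect_error(phenotype_inclusion(data.frame()), "non-empty")
})
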