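test_that("configuration invariants are enforced with the field named", {
  expect_error(tiny_config(n_runs = 2), "n_runs")
  expect_error(tiny_config(n_subjects = 0), "n_subjects")
  expect_error(tiny_config(missing_fraction = 1), "missing_fraction")
  expect_error(tiny_config(noise_sds = list(state = 0, item = 0.3, edge = 0.04)),
               "noise_sds\\$state")
  expect_error(tiny_config(behavior_path_a = Inf), "behavior_path_a")
  expect_error(tiny_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(tiny_config(summary_networks = c(1, 1)), "summary_networks")
  expect_error(tiny_config(state_loading_matrix = matrix(1, 3, 3)),
               "state_loading_matrix")
  # paths too large to standardize the behavioral outcome
  expect_error(generate_dataset(tiny_config(behavior_path_b = 0.9,
                                            behavior_path_cprime = 0.9)),
               "explained variance")
})

test_that("zero planted paths give a zero expected indirect effect", {
  cfg <- tiny_config(behavior_path_a = 0, behavior_path_b = 0)
  gt <- generate_dataset(cfg)$ground_truth
  expect_equal(gt$phenotypes$expected_indirect[gt$phenotypes$name == "mediated"],
               0)
  expect_equal(gt$path_a, 0)
})

test_that("generation is bit-identical under a fixed config", {
  cfg <- tiny_config(seed = 99, n_timepoints = 40, n_nodes = 8,
                     fc_mode = "timeseries")
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$snycq, d2$snycq)
  expect_identical(d1$behavior, d2$behavior)
  expect_identical(d1$timeseries[["sub-003"]][["run-2"]]$data,
                   d2$timeseries[["sub-003"]][["run-2"]]$data)
  expect_identical(d1$ground_truth, d2$ground_truth)

  # a different seed changes the draw
  d3 <- generate_dataset(tiny_config(seed = 100, n_timepoints = 40,
                                     n_nodes = 8, fc_mode = "timeseries"))
  expect_false(identical(d1$snycq, d3$snycq))
})

test_that("a 164 x 4 design yields 656 runs and questionnaire rows", {
  cfg <- synthetic_config(n_subjects = 164, n_runs = 4, n_nodes = 10,
                          n_networks = 2, n_timepoints = 30, seed = 2)
  ds <- suppressWarnings(generate_dataset(cfg))
  expect_equal(length(unlist(ds$timeseries, recursive = FALSE)), 656)
  expect_equal(nrow(ds$snycq), 656)
  expect_s3_class(ds$timeseries[[1]][[1]], "parcellated_ts")
  expect_equal(nrow(ds$behavior), 164)
})

test_that("questionnaire scores always lie on the 0-100 grid in steps of 5", {
  ds <- generate_dataset(tiny_config(seed = 13, n_subjects = 25))
  scores <- unlist(ds$snycq[, snycq_items()])
  expect_true(all(scores >= 0 & scores <= 100))
  expect_true(all(scores %% 5 == 0))
})

test_that("missingness is applied at the configured MCAR rate", {
  ds <- generate_dataset(tiny_config(seed = 4, n_subjects = 400,
                                     missing_fraction = 0.2))
  frac <- mean(is.na(ds$behavior$mediated))
  expect_gt(frac, 0.13)
  expect_lt(frac, 0.27)
  none <- generate_dataset(tiny_config(seed = 4, missing_fraction = 0))
  expect_false(anyNA(none$behavior))
})

test_that("simulated timeseries reproduce their target cross-correlation", {
  n <- 6
  # identity target: off-diagonal correlations within sampling error
  ts0 <- simulate_timeseries(diag(n), 5000, ar_coefficient = 0, seed = 8)
  r0 <- cor(t(ts0$data))
  expect_lt(max(abs(r0[lower.tri(r0)])), 0.1)

  # single planted r = 0.8 recovered within Fisher-z sampling error
  target <- diag(4)
  target[1, 2] <- target[2, 1] <- 0.8
  ts1 <- simulate_timeseries(target, 20000, ar_coefficient = 0.3, seed = 9)
  r1 <- cor(t(ts1$data))
  expect_gt(r1[1, 2], 0.75)
  expect_lt(r1[1, 2], 0.85)
  expect_lt(max(abs(r1[3, 1:2])), 0.06)

  # white noise has no lag-1 autocorrelation
  ac <- acf(ts0$data[1, ], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 0.05)
  # while an AR(1) draw does
  ts_ar <- simulate_timeseries(diag(2), 5000, ar_coefficient = 0.5, seed = 8)
  ac_ar <- acf(ts_ar$data[1, ], lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(ac_ar, 0.5, tolerance = 0.1)

  expect_identical(simulate_timeseries(diag(3), 50, 0.2, seed = 3)$data,
                   simulate_timeseries(diag(3), 50, 0.2, seed = 3)$data)
})

test_that("non-positive-definite targets raise a ridge-repair hint", {
  bad <- matrix(0.9, 3, 3)
  bad[1, 2] <- bad[2, 1] <- -0.9
  diag(bad) <- 1
  expect_error(simulate_timeseries(bad, 100), "ridge")
  fixed <- make_positive_definite(bad)
  expect_equal(diag(fixed), rep(1, 3))
  expect_true(min(eigen(fixed, symmetric = TRUE)$values) > 0)
  expect_silent(simulate_timeseries(fixed, 50))

  # an already positive-definite matrix is returned unchanged
  good <- diag(4)
  good[lower.tri(good)] <- good[upper.tri(good)] <- 0.2
  expect_equal(make_positive_definite(good), good)
})

test_that("simulated LMM tables carry the planted standardized slope", {
  d <- simulate_lmm_table(400, 6, beta_std = 0.3, icc = 0.3, seed = 5)
  expect_equal(nrow(d), 2400)
  expect_equal(var(d$y), 1, tolerance = 0.1)
  expect_lt(abs(unname(coef(lm(y ~ x, d))[2]) - 0.3), 0.08)
})

test_that("simulated mediation data have the planted standardized paths", {
  d <- simulate_mediation_data(20000, a = 0.4, b = 0.4, cprime = 0.3, seed = 6)
  expect_equal(cor(d$x, d$m), 0.4, tolerance = 0.03)
  expect_equal(sd(d$y), 1, tolerance = 0.03)
  fit <- coef(lm(y ~ x + m, d))
  expect_lt(abs(unname(fit["m"]) - 0.4), 0.05)
  expect_lt(abs(unname(fit["x"]) - 0.3), 0.05)
  expect_error(simulate_mediation_data(50, 0.9, 0.9, 0.9), "explained")
})

test_that("the analysis chain recovers the planted indirect effect without material bias", {
  # analytic FC mode for replicate speed; planted a = b = 0.4 -> 0.16
  n_rep <- 40
  est <- rep(NA_real_, n_rep)
  detected <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ds <- generate_dataset(synthetic_config(seed = 20000 + i,
                                            fc_mode = "analytic"))
    h3 <- suppressWarnings(run_hypothesis3(ds, n_boot = 400, seed = i))
    r <- h3$results[h3$results$phenotype == "mediated", ]
    if (nrow(r) == 1) {
      est[i] <- r$indirect
      detected[i] <- r$indirect_significant
    }
  }
  est <- est[!is.na(est)]
  # estimates attenuate through questionnaire rounding and canonical-variate
  # measurement error, but stay within the replicate spread of the target
  expect_lt(abs(mean(est) - 0.16), 3 * sd(est))
  expect_gte(mean(detected), 0.9)
})

test_that("zero state-to-edge coupling gives a calibrated null similarity test", {
  n_rep <- 150
  n_nodes <- 16
  W0 <- matrix(0, n_nodes * (n_nodes - 1) / 2, 2)
  rejections <- vapply(seq_len(n_rep), function(i) {
    ds <- generate_dataset(tiny_config(seed = 30000 + i, n_subjects = 30,
                                       n_nodes = n_nodes,
                                       state_to_edge_weights = W0))
    fcv <- lapply(ds$timeseries, function(runs) lapply(runs, vectorize_fc))
    ct <- build_contrast_table(fcv, ds$snycq)
    suppressWarnings(
      fit_lmm(ct, "mad_fc", "mad_snycq_full", "subject")$slope_p) < 0.05
  }, TRUE)
  rate <- mean(rejections)
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})
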