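test_that("mean absolute difference follows its defining arithmetic", {
  v <- rnorm(20)
  expect_equal(mad_diff(v, v), 0)
  expect_equal(mad_diff(c(0, 0), c(1, 3)), 2)
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mad_diff(a, b), mad_diff(b, a))
  expect_error(mad_diff(1:3, 1:4), "length mismatch")
  expect_error(mad_diff(c(1, NA), c(1, 2)), "finite")
})

make_fcv <- function(values) {
  vectorize_fc(sym_from_lower(4, values))
}

test_that("contrast table contains one record per unique run pair", {
  snycq <- flat_snycq(c("s1", "s2"), paste0("run-", 1:4))
  # vary one item so predictors are not constant
  snycq$vigilance <- rep(c(0, 30, 60, 100), 2)
  fcv <- list(
    s1 = stats::setNames(lapply(1:4, function(i) make_fcv(rnorm(6))),
                         paste0("run-", 1:4)),
    s2 = stats::setNames(lapply(1:3, function(i) make_fcv(rnorm(6))),
                         paste0("run-", 1:3))
  )
  ct <- build_contrast_table(fcv, snycq)
  expect_equal(sum(ct$subject == "s1"), 6)   # C(4,2)
  expect_equal(sum(ct$subject == "s2"), 3)   # C(3,2)
  expect_true(all(ct$run_a < ct$run_b))
  expect_true(all(ct$mad_fc >= 0))
  expect_true(all(ct$vigilance_absdiff %in% abs(outer(c(0, 30, 60, 100),
                                                      c(0, 30, 60, 100), "-"))))

  # identical fingerprints give exactly zero FC dissimilarity
  same <- list(s1 = stats::setNames(rep(list(make_fcv(1:6)), 3),
                                    paste0("run-", 1:3)))
  ct0 <- build_contrast_table(same, flat_snycq("s1", paste0("run-", 1:3)))
  expect_equal(ct0$mad_fc, rep(0, 3))
})

test_that("cohort-level record count follows subject run mix", {
  # 153 subjects with 4 runs and 11 with 3 runs -> 153*6 + 11*3 records
  subjects <- sprintf("s%03d", 1:164)
  n_runs <- c(rep(4, 153), rep(3, 11))
  fcv <- lapply(seq_along(subjects), function(i)
    stats::setNames(rep(list(make_fcv(1:6)), n_runs[i]),
                    paste0("run-", seq_len(n_runs[i]))))
  names(fcv) <- subjects
  snycq <- do.call(rbind, lapply(seq_along(subjects), function(i)
    flat_snycq(subjects[i], paste0("run-", seq_len(n_runs[i])))))
  ct <- build_contrast_table(fcv, snycq)
  expect_equal(nrow(ct), 153 * 6 + 11 * 3)
  expect_equal(nrow(ct), 951)
})

test_that("runs without questionnaire rows are dropped with a warning", {
  fcv <- list(s1 = stats::setNames(rep(list(make_fcv(1:6)), 4),
                                   paste0("run-", 1:4)))
  snycq <- flat_snycq("s1", paste0("run-", 1:3))  # run-4 missing
  expect_warning(ct <- build_contrast_table(fcv, snycq), "run-4")
  expect_equal(nrow(ct), 3)

  # below the minimum-run threshold the subject is dropped entirely
  snycq2 <- flat_snycq("s1", paste0("run-", 1:2))
  expect_warning(expect_error(build_contrast_table(fcv, snycq2),
                              "enough valid runs"))
})

test_that("record set is invariant to run labeling order", {
  set.seed(7)
  vals <- lapply(1:4, function(i) rnorm(6))
  runs <- paste0("run-", 1:4)
  fcv1 <- list(s1 = stats::setNames(lapply(vals, make_fcv), runs))
  fcv2 <- list(s1 = stats::setNames(lapply(vals[c(3, 1, 4, 2)], make_fcv),
                                    runs[c(3, 1, 4, 2)]))
  snycq <- flat_snycq("s1", runs)
  ct1 <- build_contrast_table(fcv1, snycq)
  ct2 <- build_contrast_table(fcv2, snycq)
  key <- function(ct) ct[order(ct$run_a, ct$run_b),
                         c("run_a", "run_b", "mad_fc")]
  expect_equal(key(ct1), key(ct2), ignore_attr = TRUE)
})

test_that("non-overlapping subset keeps disjoint pairs per subject", {
  fcv <- list(
    s1 = stats::setNames(rep(list(make_fcv(1:6)), 4), paste0("run-", 1:4)),
    s2 = stats::setNames(rep(list(make_fcv(1:6)), 3), paste0("run-", 1:3))
  )
  snycq <- rbind(flat_snycq("s1", paste0("run-", 1:4)),
                 flat_snycq("s2", paste0("run-", 1:3)))
  ct <- build_contrast_table(fcv, snycq)

  sub <- nonoverlapping_subset(ct)
  expect_equal(sum(sub$subject == "s1"), 2)   # run1-run2 and run3-run4
  expect_equal(sum(sub$subject == "s2"), 1)   # the two earliest runs
  for (s in unique(sub$subject)) {
    used <- c(sub$run_a[sub$subject == s], sub$run_b[sub$subject == s])
    expect_false(anyDuplicated(used) > 0)
  }
  expect_equal(sort(c(sub$run_a[sub$subject == "s2"],
                      sub$run_b[sub$subject == "s2"])),
               c("run-1", "run-2"))

  # alternative declared scheme {1-3, 2-4}
  alt <- nonoverlapping_subset(ct, scheme = function(runs) {
    if (length(runs) == 4) list(runs[c(1, 3)], runs[c(2, 4)]) else
      list(runs[1:2])
  })
  expect_equal(sum(alt$subject == "s1"), 2)
  expect_setequal(paste(alt$run_a[alt$subject == "s1"],
                        alt$run_b[alt$subject == "s1"]),
                  c("run-1 run-3", "run-2 run-4"))

  # overlapping scheme is rejected
  expect_error(nonoverlapping_subset(ct, scheme = function(runs)
    list(runs[1:2], runs[c(2, 3)])), "more than one pair")
})

test_that("across-run questionnaire averages are item-wise means", {
  snycq <- flat_snycq("s1", paste0("run-", 1:3))
  snycq$vigilance <- c(10, 20, 60)
  snycq$positive <- c(0, 100, 50)
  avg <- average_snycq(snycq)
  expect_equal(avg$vigilance, 30)
  expect_equal(avg$positive, 50)
  expect_equal(avg$n_runs, 3)
  expect_equal(avg$myself, 50)  # constant items average to themselves
})

test_that("planted state excursions enlarge FC dissimilarity (rank association)", {
  cfg <- tiny_config(seed = 77, n_subjects = 30, fingerprint_sd = 0.02,
                     noise_sds = list(state = 1, item = 0.3, edge = 0.01))
  ds <- generate_dataset(cfg)
  fcv <- lapply(ds$timeseries, function(runs) lapply(runs, vectorize_fc))
  ct <- build_contrast_table(fcv, ds$snycq)
  # ground-truth state-1 excursion difference per run pair
  gt <- ds$ground_truth
  subjects <- names(ds$timeseries)
  dev <- gt$run_states[, , 1] - gt$subject_state_means[, 1]
  state_diff <- mapply(function(s, ra, rb) {
    i <- match(s, subjects)
    abs(dev[i, as.integer(sub("run-", "", ra))] -
          dev[i, as.integer(sub("run-", "", rb))])
  }, ct$subject, ct$run_a, ct$run_b)
  expect_gt(cor(state_diff, ct$mad_fc, method = "spearman"), 0)
})
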