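# per-run fingerprint vectors for a dataset; accepts runs stored either as
# parcellated timeseries (FC measured here) or as ready fc_matrix objects
dataset_fc_vectors <- function(dataset) {
  lapply(dataset$timeseries, function(runs) {
    lapply(runs, function(run) {
      fc <- if (inherits(run, "fc_matrix")) run else compute_fc(run)
      vectorize_fc(fc)
    })
  })
}

# subject-level FNC edge matrix (subjects x unique edges) from concatenated
# runs (timeseries mode) or from the run-averaged Fisher-z FC (analytic mode)
dataset_subject_fnc <- function(dataset) {
  subjects <- names(dataset$timeseries)
  rows <- lapply(subjects, function(s) {
    runs <- dataset$timeseries[[s]]
    fc <- if (inherits(runs[[1]], "fc_matrix")) {
      mats <- lapply(runs, function(r) r$values)
      avg <- Reduce(`+`, mats) / length(mats)
      structure(list(values = avg, node_labels = runs[[1]]$node_labels,
                     network_assignment = runs[[1]]$network_assignment),
                class = "fc_matrix")
    } else {
      compute_fc(concatenate_runs(runs))
    }
    fnc_edges(aggregate_fnc(fc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- subjects
  out
}

lmm_row <- function(fit) {
  data.frame(beta_std = fit$standardized_beta, ci_lo = fit$std_ci[1],
             ci_hi = fit$std_ci[2], p = fit$slope_p,
             marginal_r2 = fit$marginal_r2,
             conditional_r2 = fit$conditional_r2,
             n_obs = fit$n_observations, n_groups = fit$n_groups,
             converged = fit$converged)
}

#' Hypothesis 1: thought-content similarity predicts fingerprint similarity
#'
#' Builds the within-subject run-pair contrast table and fits
#' random-intercept mixed models with the FC-fingerprint MAD as outcome:
#' one full-scale model (questionnaire MAD over all items as predictor) and
#' one model per item (raw absolute item difference as predictor). The 12
#' item-level p-values form one BH-FDR family. A sensitivity rerun on
#' non-overlapping run pairs is included by default.
#'
#' @param dataset A `mindfc_dataset` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param items Item column names (default [snycq_items()]).
#' @param min_runs Minimum valid runs per subject (default 3).
#' @param nonoverlapping Also rerun on the non-overlapping contrast subset
#'   (default `TRUE`).
#'
#' @return Object of class `h1_result`: `results` (13 rows: `full_scale`
#'   plus one per item, with standardized beta, CI, p, item-family
#'   `p_fdr`, R2), `nonoverlapping` (same shape or `NULL`),
#'   `contrast_table`, `n_subjects`.
#' @export
run_hypothesis1 <- function(dataset, items = snycq_items(), min_runs = 3,
                            nonoverlapping = TRUE) {
  fcv <- dataset_fc_vectors(dataset)
  ct <- build_contrast_table(fcv, dataset$snycq, items = items,
                             min_runs = min_runs)
  if (length(unique(ct$subject)) < 2L) {
    stop("fewer than 2 subjects survive filtering", call. = FALSE)
  }
  fit_block <- function(tab) {
    fits <- c(list(full_scale = fit_lmm(tab, "mad_fc", "mad_snycq_full",
                                        "subject")),
              stats::setNames(lapply(items, function(it)
                fit_lmm(tab, "mad_fc", paste0(it, "_absdiff"), "subject")),
                items))
    res <- cbind(data.frame(model = names(fits)),
                 do.call(rbind, lapply(fits, lmm_row)))
    rownames(res) <- NULL
    res$p_fdr <- NA_real_
    item_rows <- res$model != "full_scale"
    res$p_fdr[item_rows] <- fdr_bh(res$p[item_rows], "item_level")
    res
  }
  out <- list(results = fit_block(ct),
              nonoverlapping = if (nonoverlapping)
                fit_block(nonoverlapping_subset(ct)) else NULL,
              contrast_table = ct,
              n_subjects = length(unique(ct$subject)))
  class(out) <- "h1_result"
  out
}

#' @export
print.h1_result <- function(x, ...) {
  cat(sprintf("<h1_result> %d subjects, %d contrasts\n", x$n_subjects,
              nrow(x$contrast_table)))
  print(x$results[, c("model", "beta_std", "ci_lo", "ci_hi", "p", "p_fdr")],
        digits = 3)
  invisible(x)
}

#' Hypothesis 2: network-pair connectivity correlates of each item
#'
#' Aggregates each valid run's FC matrix into a network-by-network (FNC)
#' matrix and fits one random-intercept mixed model per (unique FNC edge,
#' questionnaire item) pair, with the edge value as outcome and the item
#' score as predictor. With the default 8 networks and 12 items this is
#' 36 x 12 = 432 models. BH-FDR is applied within each item's family of
#' edge tests (36 per family), never across items.
#'
#' @inheritParams run_hypothesis1
#'
#' @return Object of class `h2_result`: `results` with one row per
#'   (item, edge) model and columns `item`, `edge`, `network_a`,
#'   `network_b`, standardized beta, CI, `p`, `p_fdr`, R2.
#' @export
run_hypothesis2 <- function(dataset, items = snycq_items(), min_runs = 3) {
  check_snycq(dataset$snycq, items)
  subjects <- names(dataset$timeseries)
  rows <- list()
  for (s in subjects) {
    for (r in names(dataset$timeseries[[s]])) {
      q <- dataset$snycq[dataset$snycq$subject == s & dataset$snycq$run == r, ,
                         drop = FALSE]
      if (!nrow(q)) next
      run <- dataset$timeseries[[s]][[r]]
      fc <- if (inherits(run, "fc_matrix")) run else compute_fc(run)
      edges <- fnc_edges(suppressWarnings(aggregate_fnc(fc)))
      row <- data.frame(subject = s, run = r)
      row[names(edges)] <- as.list(edges)
      row[items] <- q[1, items]
      rows[[length(rows) + 1L]] <- row
    }
  }
  long <- do.call(rbind, rows)
  run_counts <- table(long$subject)
  long <- long[long$subject %in% names(run_counts)[run_counts >= min_runs], ,
               drop = FALSE]
  if (length(unique(long$subject)) < 2L) {
    stop("fewer than 2 subjects survive filtering", call. = FALSE)
  }
  edge_names <- setdiff(names(long), c("subject", "run", items))
  res <- list()
  for (item in items) {
    for (edge in edge_names) {
      fit <- fit_lmm(long, edge, item, "subject")
      nets <- strsplit(edge, "..", fixed = TRUE)[[1]]
      res[[length(res) + 1L]] <- cbind(
        data.frame(item = item, edge = edge, network_a = nets[1],
                   network_b = nets[2]), lmm_row(fit))
    }
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$p_fdr <- NA_real_
  for (item in items) {
    sel <- res$item == item
    res$p_fdr[sel] <- fdr_bh(res$p[sel], paste0("edges_", item))
  }
  out <- list(results = res, n_subjects = length(unique(long$subject)),
              n_edges = length(edge_names), long_table = long)
  class(out) <- "h2_result"
  out
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("<h2_result> %d models (%d edges x %d items), %d subjects; %d FDR-significant\n",
              nrow(x$results), x$n_edges,
              length(unique(x$results$item)), x$n_subjects,
              sum(x$results$p_fdr < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Hypothesis 3: thought content mediates FC-behavior associations
#'
#' Cross-sectional chain per behavioral phenotype: (1) subject-level
#' predictors — unique FNC edges from run-concatenated FC and across-run
#' questionnaire item means; (2) phenotype gate — keep phenotypes with at
#' least `inclusion_threshold` valid subjects, then listwise-complete
#' subjects per phenotype; (3) two CCAs against the (univariate) phenotype,
#' one for the item set and one for the FNC edge set, each yielding a
#' canonical variate scored by matrix-multiplying the standardized
#' variables with the canonical loadings (`cv_mode = "coefficients"`
#' switches to textbook coefficient scoring); (4) correlations of each CV
#' with the phenotype (one BH-FDR family per CV across phenotypes); (5)
#' bootstrap mediation with the FNC variate as predictor, the item variate
#' as mediator, and the phenotype as outcome, with BH-FDR across the
#' indirect-effect p-values.
#'
#' @inheritParams run_hypothesis1
#' @param inclusion_threshold Minimum valid-data fraction for a phenotype
#'   (default 0.90, inclusive).
#' @param n_boot Bootstrap replicates for each mediation (default 5000).
#' @param seed Base seed; phenotype `k` uses `seed + k`.
#' @param cv_mode `"loadings"` (default) or `"coefficients"`.
#'
#' @return Object of class `h3_result`: `results` (one row per included
#'   phenotype: CV-behavior correlations with FDR, standardized mediation
#'   paths, indirect effect with percentile CI, bootstrap p and FDR,
#'   significance flags, `n`, `n_boot`, `seed`), `loadings` (per-phenotype
#'   item and edge loadings), `mediations` (the full
#'   [mediate()] objects), `excluded_phenotypes`.
#' @export
run_hypothesis3 <- function(dataset, items = snycq_items(),
                            inclusion_threshold = 0.90, n_boot = 5000,
                            seed = 1, cv_mode = c("loadings", "coefficients")) {
  cv_mode <- match.arg(cv_mode)
  x_fnc <- dataset_subject_fnc(dataset)
  x_fnc <- x_fnc[, colSums(is.na(x_fnc)) == 0, drop = FALSE]
  snycq_avg <- average_snycq(dataset$snycq, items = items)
  behavior <- dataset$behavior
  included <- phenotype_inclusion(behavior, threshold = inclusion_threshold)
  if (!length(included)) {
    stop("no phenotype passes the inclusion gate", call. = FALSE)
  }
  subjects <- intersect(rownames(x_fnc), snycq_avg$subject)
  subjects <- intersect(subjects, behavior$subject)
  x_items <- as.matrix(snycq_avg[match(subjects, snycq_avg$subject), items])
  x_edges <- x_fnc[subjects, , drop = FALSE]

  rows <- list()
  loadings <- list()
  mediations <- list()
  for (k in seq_along(included)) {
    pheno <- included[k]
    y_all <- behavior[[pheno]][match(subjects, behavior$subject)]
    ok <- !is.na(y_all)
    y <- y_all[ok]
    cca_items <- cca_univariate_outcome(x_items[ok, , drop = FALSE], y)
    cca_fnc <- cca_univariate_outcome(x_edges[ok, , drop = FALSE], y)
    w_items <- if (cv_mode == "loadings") cca_items$loadings else
      cca_items$coefficients
    w_fnc <- if (cv_mode == "loadings") cca_fnc$loadings else
      cca_fnc$coefficients
    cv_snycq <- cv_scores(x_items[ok, , drop = FALSE], w_items, mode = cv_mode)
    cv_fnc <- cv_scores(x_edges[ok, , drop = FALSE], w_fnc, mode = cv_mode)
    cor_snycq <- stats::cor.test(cv_snycq, y)
    cor_fnc <- stats::cor.test(cv_fnc, y)
    med <- mediate(cv_fnc, cv_snycq, y, n_boot = n_boot, seed = seed + k)
    loadings[[pheno]] <- list(items = cca_items$loadings,
                              fnc = cca_fnc$loadings)
    mediations[[pheno]] <- med
    rows[[k]] <- data.frame(
      phenotype = pheno, n = length(y),
      r_cv_fnc = unname(cor_fnc$estimate), p_cv_fnc = cor_fnc$p.value,
      r_cv_snycq = unname(cor_snycq$estimate),
      p_cv_snycq = cor_snycq$p.value,
      path_a = med$path_a, path_b = med$path_b, path_c = med$path_c,
      path_c_prime = med$path_c_prime, indirect = med$indirect,
      indirect_ci_lo = med$bootstrap_ci[1],
      indirect_ci_hi = med$bootstrap_ci[2],
      indirect_p = med$indirect_p,
      indirect_significant = med$significant,
      n_boot = n_boot, seed = seed + k)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_cv_fnc_fdr <- fdr_bh(res$p_cv_fnc, "cv_fnc_behavior")
  res$p_cv_snycq_fdr <- fdr_bh(res$p_cv_snycq, "cv_snycq_behavior")
  res$indirect_p_fdr <- fdr_bh(res$indirect_p, "indirect_effects")
  res$indirect_significant_fdr <- res$indirect_significant &
    res$indirect_p_fdr < 0.05
  out <- list(results = res, loadings = loadings, mediations = mediations,
              excluded_phenotypes = setdiff(setdiff(names(behavior), "subject"),
                                            included),
              cv_mode = cv_mode)
  class(out) <- "h3_result"
  out
}

#' @export
print.h3_result <- function(x, ...) {
  cat(sprintf("<h3_result> %d phenotypes (%d excluded by gate); %d significant indirect effects after FDR\n",
              nrow(x$results), length(x$excluded_phenotypes),
              sum(x$results$indirect_significant_fdr)))
  print(x$results[, c("phenotype", "n", "r_cv_fnc", "r_cv_snycq",
                      "indirect", "indirect_ci_lo", "indirect_ci_hi",
                      "indirect_p_fdr")], digits = 3)
  invisible(x)
}

#' Monte-Carlo power for the package's analyses
#'
#' Estimates power by repeated simulation at explicitly supplied generative
#' parameters (no defaults are claimed to reproduce any particular study).
#' `analysis = "similarity"` simulates random-intercept long tables
#' ([simulate_lmm_table()]) and counts significant Wald slope tests;
#' `analysis = "mediation"` simulates subject-level mediation data
#' ([simulate_mediation_data()]) and counts bootstrap CIs excluding zero.
#'
#' @param analysis `"similarity"` or `"mediation"`.
#' @param n_sims Number of simulations (default 1000). Fewer than 50 draws
#'   a Monte-Carlo-error warning.
#' @param n_subjects Subjects (groups) per simulated dataset.
#' @param n_per_group Rows per group (similarity analysis; default 6, the
#'   contrast count of a 4-run subject).
#' @param beta_std Planted standardized slope (similarity).
#' @param paths Length-3 vector `c(a, b, cprime)` (mediation).
#' @param icc Group-intercept share of residual variance (similarity).
#' @param n_boot Bootstrap replicates per mediation simulation
#'   (default 500).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; simulation `i` uses `seed + i`.
#'
#' @return Object of class `power_report`: `power`, binomial `se`,
#'   `n_sims`, `n_significant`, `analysis`, `params`, `seed`.
#' @export
run_power_simulation <- function(analysis = c("similarity", "mediation"),
                                 n_sims = 1000, n_subjects = 164,
                                 n_per_group = 6, beta_std = 0.25,
                                 paths = c(a = 0.4, b = 0.4, cprime = 0.3),
                                 icc = 0.3, n_boot = 500, alpha = 0.05,
                                 seed = 1) {
  analysis <- match.arg(analysis)
  if (n_sims < 50) {
    warning("fewer than 50 simulations: Monte-Carlo error will be large",
            call. = FALSE)
  }
  sig <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    if (analysis == "similarity") {
      d <- simulate_lmm_table(n_subjects, n_per_group, beta_std, icc = icc,
                              seed = seed + i)
      fit <- fit_lmm(d, "y", "x", "g")
      sig[i] <- fit$slope_p < alpha
    } else {
      d <- simulate_mediation_data(n_subjects, paths[1], paths[2], paths[3],
                                   seed = seed + i)
      med <- mediate(d$x, d$m, d$y, n_boot = n_boot, seed = seed + i,
                     conf_level = 1 - alpha)
      sig[i] <- med$significant
    }
  }
  power <- mean(sig)
  params <- if (analysis == "similarity") {
    list(n_subjects = n_subjects, n_per_group = n_per_group,
         beta_std = beta_std, icc = icc, alpha = alpha)
  } else {
    list(n_subjects = n_subjects, paths = paths, n_boot = n_boot,
         alpha = alpha)
  }
  structure(
    list(analysis = analysis, power = power,
         se = sqrt(power * (1 - power) / n_sims),
         n_sims = n_sims, n_significant = sum(sig), params = params,
         seed = seed),
    class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("<power_report> %s: power %.3f (SE %.3f) from %d simulations (seed %d)\n",
              x$analysis, x$power, x$se, x$n_sims, x$seed))
  invisible(x)
}
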