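#' Configuration for the synthetic multi-run dataset generator
#'
#' Collects every parameter of the generative model in one validated
#' object. The model plants the causal structure the analysis pipeline
#' assumes: each subject has a stable FC fingerprint; run-level latent
#' thought states perturb FC edges; questionnaire items are noisy readouts
#' of the states on the 0-100 grid; and behavior is generated jointly from
#' a declared FC-fingerprint contrast (direct path c') and the subject's
#' mean first state (mediated path a then b), so the planted indirect
#' effect is `a * b`.
#'
#' @param n_subjects Number of subjects (default 164).
#' @param n_runs Runs per subject (default 4, minimum 3).
#' @param n_nodes Nodes per parcellation (default 50; 219 at full scale).
#' @param n_networks Number of networks nodes are split into (default 8).
#' @param n_items Questionnaire items (default 12).
#' @param n_states Latent thought-state dimensions (default 2).
#' @param n_timepoints Timepoints per run (default 657).
#' @param sampling_interval Sampling interval in seconds (default 1.4).
#' @param ar_coefficient Temporal AR(1) coefficient of the simulated BOLD
#'   series, in (-1, 1) (default 0.4).
#' @param fingerprint_sd SD of the stable per-subject, per-edge Fisher-z
#'   fingerprint deviations (default 0.1).
#' @param state_loading_matrix `n_items x n_states` map from states to
#'   questionnaire items; default loads the `vigilance` item almost
#'   entirely on state 1 and spreads the remaining items across both
#'   states.
#' @param state_to_edge_weights `n_edges x n_states` per-edge effect of
#'   each state on Fisher-z FC, edges in the package's lower-triangle
#'   row-major order. Default: state 1 shifts all within-network edges
#'   (weight 0.05), state 2 shifts edges between networks outside the
#'   behavior-summary pair.
#' @param behavior_path_a Standardized path from the FC summary to the
#'   subject mean state (default 0.4).
#' @param behavior_path_b Standardized path from the subject mean state to
#'   behavior (default 0.4).
#' @param behavior_path_cprime Standardized direct path from the FC summary
#'   to behavior (default 0.3).
#' @param phenotypes Data frame (`name`, `b`, `cprime`) describing the
#'   behavior columns to generate; all share path `a`. Default: a
#'   `mediated` phenotype with the configured paths, a `direct_only`
#'   phenotype (`b = 0`), and a `null` phenotype (both 0).
#' @param noise_sds List of residual scales: `state` (run-level state
#'   noise, default 0.5), `item` (questionnaire readout noise, default
#'   0.3), `edge` (per-run FC measurement noise used only in
#'   `fc_mode = "analytic"`, default 0.04). Behavioral residual variance is
#'   set automatically so the planted paths are standardized.
#' @param missing_fraction MCAR fraction of behavior cells masked
#'   (default 0.05).
#' @param summary_networks Length-2 network indices whose between-network
#'   FNC block mean is the declared behavioral FC summary (default 1, 2).
#' @param fc_mode `"timeseries"` (default): per-run node-by-time series are
#'   simulated and FC is measured from them downstream; `"analytic"`:
#'   per-run Fisher-z FC matrices are emitted directly with `edge` noise,
#'   for replicate-heavy simulation studies (e.g. power analysis).
#' @param seed Master RNG seed; drives a per-subject-run seed sequence.
#'
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 164, n_runs = 4, n_nodes = 50,
                             n_networks = 8, n_items = 12, n_states = 2,
                             n_timepoints = 657, sampling_interval = 1.4,
                             ar_coefficient = 0.4, fingerprint_sd = 0.1,
                             state_loading_matrix = NULL,
                             state_to_edge_weights = NULL,
                             behavior_path_a = 0.4, behavior_path_b = 0.4,
                             behavior_path_cprime = 0.3, phenotypes = NULL,
                             noise_sds = list(state = 0.5, item = 0.3,
                                              edge = 0.04),
                             missing_fraction = 0.05,
                             summary_networks = c(1, 2),
                             fc_mode = c("timeseries", "analytic"),
                             seed = 1) {
  fc_mode <- match.arg(fc_mode)
  counts <- list(n_subjects = n_subjects, n_runs = n_runs, n_nodes = n_nodes,
                 n_networks = n_networks, n_items = n_items,
                 n_states = n_states, n_timepoints = n_timepoints)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop(sprintf("invalid config: `%s` must be a count >= 1", nm),
           call. = FALSE)
    }
  }
  if (n_runs < 3) stop("invalid config: `n_runs` must be at least 3",
                       call. = FALSE)
  if (n_networks > n_nodes) {
    stop("invalid config: `n_networks` cannot exceed `n_nodes`", call. = FALSE)
  }
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("invalid config: `sampling_interval` must be positive", call. = FALSE)
  }
  if (abs(ar_coefficient) >= 1) {
    stop("invalid config: `ar_coefficient` must lie in (-1, 1)", call. = FALSE)
  }
  if (!is.finite(fingerprint_sd) || fingerprint_sd < 0) {
    stop("invalid config: `fingerprint_sd` must be a finite non-negative scale",
         call. = FALSE)
  }
  for (path in c("behavior_path_a", "behavior_path_b",
                 "behavior_path_cprime")) {
    if (!is.finite(get(path))) {
      stop(sprintf("invalid config: `%s` must be finite", path), call. = FALSE)
    }
  }
  for (nm in c("state", "item", "edge")) {
    if (is.null(noise_sds[[nm]]) || !is.finite(noise_sds[[nm]]) ||
        noise_sds[[nm]] <= 0) {
      stop(sprintf("invalid config: `noise_sds$%s` must be > 0", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(missing_fraction) || missing_fraction < 0 ||
      missing_fraction >= 1) {
    stop("invalid config: `missing_fraction` must lie in [0, 1)",
         call. = FALSE)
  }
  if (length(summary_networks) != 2L ||
      any(summary_networks < 1 | summary_networks > n_networks) ||
      summary_networks[1] == summary_networks[2]) {
    stop("invalid config: `summary_networks` must be 2 distinct network indices",
         call. = FALSE)
  }
  if (is.null(state_loading_matrix)) {
    state_loading_matrix <- default_state_loadings(n_items, n_states)
  }
  state_loading_matrix <- as.matrix(state_loading_matrix)
  if (!all(dim(state_loading_matrix) == c(n_items, n_states)) ||
      !all(is.finite(state_loading_matrix))) {
    stop("invalid config: `state_loading_matrix` must be a finite n_items x n_states matrix",
         call. = FALSE)
  }
  if (is.null(phenotypes)) {
    phenotypes <- data.frame(
      name = c("mediated", "direct_only", "null"),
      b = c(behavior_path_b, 0, 0),
      cprime = c(behavior_path_cprime, behavior_path_cprime, 0)
    )
  }
  if (!all(c("name", "b", "cprime") %in% names(phenotypes)) ||
      !all(is.finite(phenotypes$b)) || !all(is.finite(phenotypes$cprime))) {
    stop("invalid config: `phenotypes` needs finite columns name, b, cprime",
         call. = FALSE)
  }
  networks <- network_partition(n_nodes, n_networks)
  if (is.null(state_to_edge_weights)) {
    state_to_edge_weights <- default_state_edge_weights(
      networks, n_states, summary_networks)
  }
  state_to_edge_weights <- as.matrix(state_to_edge_weights)
  n_edges <- n_nodes * (n_nodes - 1) / 2
  if (!all(dim(state_to_edge_weights) == c(n_edges, n_states)) ||
      !all(is.finite(state_to_edge_weights))) {
    stop("invalid config: `state_to_edge_weights` must be a finite n_edges x n_states matrix",
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("invalid config: `seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         n_nodes = as.integer(n_nodes), n_networks = as.integer(n_networks),
         n_items = as.integer(n_items), n_states = as.integer(n_states),
         n_timepoints = as.integer(n_timepoints),
         sampling_interval = sampling_interval,
         ar_coefficient = ar_coefficient, fingerprint_sd = fingerprint_sd,
         state_loading_matrix = state_loading_matrix,
         state_to_edge_weights = state_to_edge_weights,
         behavior_path_a = behavior_path_a,
         behavior_path_b = behavior_path_b,
         behavior_path_cprime = behavior_path_cprime,
         phenotypes = phenotypes, noise_sds = noise_sds,
         missing_fraction = missing_fraction,
         summary_networks = as.integer(summary_networks),
         network_assignment = networks, fc_mode = fc_mode,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_config> %d subjects x %d runs, %d nodes / %d networks, ",
    "%d items, %d states\n  paths a = %.2f, b = %.2f, c' = %.2f ",
    "(planted indirect %.3f); fc_mode = %s; seed %d\n"),
    x$n_subjects, x$n_runs, x$n_nodes, x$n_networks, x$n_items, x$n_states,
    x$behavior_path_a, x$behavior_path_b, x$behavior_path_cprime,
    x$behavior_path_a * x$behavior_path_b, x$fc_mode, x$seed))
  invisible(x)
}

# split nodes as evenly as possible into labelled networks
network_partition <- function(n_nodes, n_networks) {
  sizes <- rep(floor(n_nodes / n_networks), n_networks)
  extra <- n_nodes - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(paste0("net_", seq_len(n_networks)), times = sizes)
}

# default item loadings: `vigilance` is the pure state-1 readout, the other
# items mix both states with smaller weights
default_state_loadings <- function(n_items, n_states) {
  items <- if (n_items == 12L) snycq_items() else paste0("item_", seq_len(n_items))
  L <- matrix(0, n_items, n_states, dimnames = list(items, NULL))
  w1 <- 0.35 * (1 + (seq_len(n_items) %% 3)) / 3  # 0.23 .. 0.7, varied
  L[, 1] <- w1
  if (n_states >= 2) {
    L[, 2] <- rev(w1) * 0.8
  }
  vig <- if ("vigilance" %in% items) which(items == "vigilance") else 1L
  L[vig, ] <- 0
  L[vig, 1] <- 1
  L
}

# default per-edge state weights (lower-tri row-major edge order): state 1
# (the vigilance-like arousal state) shifts within-network edges everywhere
# and is the dominant FC perturber; state 2 shifts between-network edges
# outside the behavior-summary pair more weakly. Neither state moves the
# declared behavioral FC contrast block.
default_state_edge_weights <- function(networks, n_states, summary_networks,
                                       weight = c(0.05, 0.02)) {
  n_nodes <- length(networks)
  map <- lower_tri_index_map(n_nodes)
  net_i <- networks[map$node_i]
  net_j <- networks[map$node_j]
  W <- matrix(0, nrow(map), n_states)
  W[net_i == net_j, 1] <- weight[1]
  if (n_states >= 2) {
    summary_labels <- unique(networks)[summary_networks]
    outside <- net_i != net_j & !(net_i %in% summary_labels) &
      !(net_j %in% summary_labels)
    W[outside, 2] <- weight[2]
  }
  W
}

#' Simulate a stationary timeseries with a target cross-correlation
#'
#' Cholesky-colored AR(1) process: node-wise independent AR(1) innovations
#' with unit stationary variance are mixed by the Cholesky factor of the
#' target correlation matrix. Because every channel carries the identical
#' temporal filter, the population cross-sectional correlation equals the
#' target exactly, and the empirical correlation converges to it as the
#' run lengthens.
#'
#' @param target_fc Node-by-node target correlation matrix (symmetric; unit
#'   diagonal is enforced). Must be positive definite.
#' @param n_timepoints Run length.
#' @param ar_coefficient AR(1) coefficient in (-1, 1); 0 gives white noise.
#' @param seed RNG seed.
#' @param sampling_interval Sampling interval in seconds (default 1.4).
#' @param subject_id,run_id,network_assignment Passed to the returned
#'   [parcellated_ts()].
#' @param burn_in Initial samples discarded so the process is stationary
#'   from the first retained frame (default 100).
#'
#' @return A [parcellated_ts()].
#' @export
simulate_timeseries <- function(target_fc, n_timepoints, ar_coefficient = 0,
                                seed = 1, sampling_interval = 1.4,
                                subject_id = "sub-01", run_id = "run-01",
                                network_assignment = NULL, burn_in = 100) {
  C <- as.matrix(target_fc)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("`target_fc` must be a symmetric square matrix", call. = FALSE)
  }
  diag(C) <- 1
  if (abs(ar_coefficient) >= 1) {
    stop("`ar_coefficient` must lie in (-1, 1)", call. = FALSE)
  }
  L <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (is.null(L)) {
    stop(paste("target correlation matrix is not positive definite;",
               "repair it with a small diagonal ridge, e.g.",
               "(C + eps * I) / (1 + eps)"), call. = FALSE)
  }
  n <- nrow(C)
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  total <- n_timepoints + burn_in
  innov_sd <- sqrt(1 - ar_coefficient^2)
  E <- matrix(stats::rnorm(n * total, sd = innov_sd), n, total)
  X <- if (ar_coefficient == 0) E else {
    t(apply(E, 1, function(e)
      stats::filter(e, ar_coefficient, method = "recursive")))
  }
  X <- X[, (burn_in + 1):total, drop = FALSE]
  parcellated_ts(L %*% X, sampling_interval = sampling_interval,
                 subject_id = subject_id, run_id = run_id,
                 network_assignment = network_assignment)
}

#' Nearest positive-definite repair of a correlation matrix
#'
#' Clips eigenvalues below `min_eig` times the largest eigenvalue,
#' reconstructs, and renormalizes to unit diagonal. Edge-wise perturbations
#' of a correlation matrix (as planted by the synthetic fingerprints) are
#' not guaranteed to stay positive definite; this repair preserves the
#' dominant (block/fingerprint) structure while shrinking only the
#' offending noise directions.
#'
#' @param C Symmetric matrix with unit diagonal intended as a correlation
#'   matrix.
#' @param min_eig Relative eigenvalue floor (default 1e-4).
#' @return A positive-definite correlation matrix.
#' @export
make_positive_definite <- function(C, min_eig = 1e-4) {
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  floor_val <- min_eig * max(eig$values)
  if (min(eig$values) >= floor_val) return(C)
  vals <- pmax(eig$values, floor_val)
  out <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Generate a complete synthetic multi-run dataset
#'
#' Draws subject fingerprints, run-level thought states, questionnaire
#' scores and behavioral phenotypes from the planted generative model in
#' `config`, and records every latent quantity in a `ground_truth` object.
#' With the same config (including seed) the output is bit-identical across
#' calls.
#'
#' @param config A [synthetic_config()].
#'
#' @return Object of class `mindfc_dataset`: list with
#'   \describe{
#'     \item{timeseries}{`timeseries[[subject]][[run]]`: a
#'       [parcellated_ts()] (or an `fc_matrix` when
#'       `config$fc_mode == "analytic"`).}
#'     \item{snycq}{questionnaire table (`subject`, `run`, 12 item columns
#'       on the 0-100 grid in steps of 5).}
#'     \item{behavior}{subject-by-phenotype table with MCAR missingness.}
#'     \item{ground_truth}{latents and planted parameters (class
#'       `ground_truth`).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(cfg$seed)

  subjects <- sprintf("sub-%03d", seq_len(cfg$n_subjects))
  runs <- sprintf("run-%d", seq_len(cfg$n_runs))
  networks <- cfg$network_assignment
  map <- lower_tri_index_map(cfg$n_nodes)
  n_edges <- nrow(map)

  # group-mean Fisher-z FC: stronger within than between networks
  net_i <- networks[map$node_i]
  net_j <- networks[map$node_j]
  mu_edges <- ifelse(net_i == net_j, 0.35, 0.10)

  # the declared behavioral FC summary: the between-network block of the
  # two summary networks; its fingerprint part has known SD so the latent
  # predictor can be standardized exactly
  summary_labels <- unique(networks)[cfg$summary_networks]
  summary_block <- (net_i == summary_labels[1] & net_j == summary_labels[2]) |
    (net_i == summary_labels[2] & net_j == summary_labels[1])
  if (!any(summary_block)) stop("summary networks share no edges", call. = FALSE)

  # subject-level latents
  fingerprints <- matrix(stats::rnorm(cfg$n_subjects * n_edges,
                                      sd = cfg$fingerprint_sd),
                         cfg$n_subjects, n_edges)
  block_sd <- cfg$fingerprint_sd / sqrt(sum(summary_block))
  predictor <- rowMeans(fingerprints[, summary_block, drop = FALSE]) / block_sd

  a <- cfg$behavior_path_a
  state_means <- matrix(stats::rnorm(cfg$n_subjects * cfg$n_states),
                        cfg$n_subjects, cfg$n_states)
  state_means[, 1] <- a * predictor + sqrt(max(0, 1 - a^2)) * state_means[, 1]

  # run-level states
  run_states <- array(stats::rnorm(cfg$n_subjects * cfg$n_runs * cfg$n_states,
                                   sd = cfg$noise_sds$state),
                      c(cfg$n_subjects, cfg$n_runs, cfg$n_states))
  for (k in seq_len(cfg$n_states)) {
    run_states[, , k] <- run_states[, , k] + state_means[, k]
  }

  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 cfg$n_subjects * cfg$n_runs),
                      cfg$n_subjects, cfg$n_runs)

  # questionnaire scores: linear readout of states, rank-preservingly
  # mapped onto the 0-100 grid in steps of 5 through the normal quantile
  L <- cfg$state_loading_matrix
  state_var <- 1 + cfg$noise_sds$state^2
  item_sd <- sqrt(rowSums(L^2) * state_var + cfg$noise_sds$item^2)
  items <- rownames(L)
  if (is.null(items)) items <- paste0("item_", seq_len(cfg$n_items))

  snycq_rows <- vector("list", cfg$n_subjects * cfg$n_runs)
  ts_list <- stats::setNames(vector("list", cfg$n_subjects), subjects)
  for (s in seq_len(cfg$n_subjects)) {
    ts_list[[s]] <- stats::setNames(vector("list", cfg$n_runs), runs)
    for (r in seq_len(cfg$n_runs)) {
      state <- run_states[s, r, ]
      # FC responds to the run-specific state excursion around the subject
      # mean: fingerprints stay subject-stable and the run-pair (MAD)
      # analyses difference out subject means anyway, while the
      # questionnaire reads out the full state
      state_dev <- state - state_means[s, ]
      latent_items <- drop(L %*% state) +
        stats::rnorm(cfg$n_items, sd = cfg$noise_sds$item)
      scores <- 5 * round(20 * stats::pnorm(latent_items / item_sd))
      row <- data.frame(subject = subjects[s], run = runs[r])
      row[items] <- as.list(scores)
      snycq_rows[[(s - 1) * cfg$n_runs + r]] <- row

      z_edges <- mu_edges + fingerprints[s, ] +
        drop(cfg$state_to_edge_weights %*% state_dev)
      if (cfg$fc_mode == "timeseries") {
        z_full <- matrix(0, cfg$n_nodes, cfg$n_nodes)
        z_full[cbind(map$node_i, map$node_j)] <- z_edges
        z_full[cbind(map$node_j, map$node_i)] <- z_edges
        target_r <- tanh(z_full)
        diag(target_r) <- 1
        target_r <- make_positive_definite(target_r)
        ts_list[[s]][[r]] <- simulate_timeseries(
          target_r, cfg$n_timepoints, cfg$ar_coefficient,
          seed = run_seeds[s, r], sampling_interval = cfg$sampling_interval,
          subject_id = subjects[s], run_id = runs[r],
          network_assignment = networks)
      } else {
        noisy <- z_edges + stats::rnorm(n_edges, sd = cfg$noise_sds$edge)
        z_full <- matrix(NA_real_, cfg$n_nodes, cfg$n_nodes)
        z_full[cbind(map$node_i, map$node_j)] <- noisy
        z_full[cbind(map$node_j, map$node_i)] <- noisy
        labels <- paste0("node_", seq_len(cfg$n_nodes))
        dimnames(z_full) <- list(labels, labels)
        ts_list[[s]][[r]] <- structure(
          list(values = z_full, node_labels = labels,
               network_assignment = stats::setNames(networks, labels)),
          class = "fc_matrix")
      }
    }
  }
  snycq <- do.call(rbind, snycq_rows)
  rownames(snycq) <- NULL

  # behavior: standardized planted paths, residual variance chosen so each
  # phenotype has unit marginal variance
  phen <- cfg$phenotypes
  behavior <- data.frame(subject = subjects)
  resid_sds <- numeric(nrow(phen))
  for (p in seq_len(nrow(phen))) {
    b <- phen$b[p]; cp <- phen$cprime[p]
    explained <- b^2 + cp^2 + 2 * a * b * cp
    if (explained >= 1) {
      stop(sprintf("invalid config: paths for phenotype `%s` imply explained variance >= 1",
                   phen$name[p]), call. = FALSE)
    }
    resid_sds[p] <- sqrt(1 - explained)
    y <- cp * predictor + b * state_means[, 1] +
      stats::rnorm(cfg$n_subjects, sd = resid_sds[p])
    if (cfg$missing_fraction > 0) {
      y[stats::runif(cfg$n_subjects) < cfg$missing_fraction] <- NA_real_
    }
    behavior[[phen$name[p]]] <- y
  }

  ground_truth <- structure(
    list(subject_predictor = stats::setNames(predictor, subjects),
         subject_state_means = state_means,
         run_states = run_states,
         path_a = a,
         phenotypes = cbind(phen, expected_indirect = a * phen$b,
                            residual_sd = resid_sds),
         state_loading_matrix = L,
         state_to_edge_weights = cfg$state_to_edge_weights,
         summary_block_edges = which(summary_block),
         mu_edges = mu_edges,
         fingerprints = fingerprints,
         run_seeds = run_seeds,
         seed = cfg$seed),
    class = "ground_truth")

  structure(
    list(timeseries = ts_list, snycq = snycq, behavior = behavior,
         ground_truth = ground_truth, config = cfg),
    class = "mindfc_dataset")
}

#' @export
print.mindfc_dataset <- function(x, ...) {
  cat(sprintf("<mindfc_dataset> %d subjects x %d runs (%s mode), %d phenotypes, seed %d\n",
              x$config$n_subjects, x$config$n_runs, x$config$fc_mode,
              nrow(x$config$phenotypes), x$config$seed))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> path a = %.3f; phenotypes:\n", x$path_a))
  print(x$phenotypes[, c("name", "b", "cprime", "expected_indirect")])
  invisible(x)
}

#' Simulate a long table from the random-intercept model
#'
#' Direct draws from `y = beta * x + u_g + e` with `x ~ N(0, 1)`,
#' `u_g ~ N(0, icc * (1 - beta^2))` and
#' `e ~ N(0, (1 - icc) * (1 - beta^2))`, so the marginal outcome variance
#' is 1 and `beta` is the standardized slope. Used for slope-recovery,
#' calibration, and power simulations.
#'
#' @param n_groups Number of groups (subjects).
#' @param n_per_group Rows per group.
#' @param beta_std Planted standardized slope, `|beta_std| < 1`.
#' @param icc Share of residual variance attributed to the group intercept
#'   (default 0.3).
#' @param seed RNG seed.
#' @return Data frame with columns `g`, `x`, `y`.
#' @export
simulate_lmm_table <- function(n_groups, n_per_group, beta_std, icc = 0.3,
                               seed = 1) {
  stopifnot(abs(beta_std) < 1, icc >= 0, icc < 1)
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  n <- n_groups * n_per_group
  g <- rep(seq_len(n_groups), each = n_per_group)
  x <- stats::rnorm(n)
  resid_var <- 1 - beta_std^2
  u <- stats::rnorm(n_groups, sd = sqrt(icc * resid_var))[g]
  e <- stats::rnorm(n, sd = sqrt((1 - icc) * resid_var))
  data.frame(g = factor(g), x = x, y = beta_std * x + u + e)
}

#' Simulate subject-level mediation data
#'
#' Draws `(x, m, y)` with standardized planted paths: `m = a x + e_m` and
#' `y = cprime x + b m + e_y`, residual variances chosen so all three
#' variables have unit variance. The planted indirect effect is `a * b`.
#'
#' @param n Number of subjects.
#' @param a,b,cprime Standardized paths.
#' @param seed RNG seed.
#' @return Data frame with columns `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, a, b, cprime, seed = 1) {
  explained <- b^2 + cprime^2 + 2 * a * b * cprime
  if (abs(a) >= 1 || explained >= 1) {
    stop("paths imply explained variance >= 1", call. = FALSE)
  }
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- a * x + stats::rnorm(n, sd = sqrt(1 - a^2))
  y <- cprime * x + b * m + stats::rnorm(n, sd = sqrt(1 - explained))
  data.frame(x = x, m = m, y = y)
}
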