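# small fixtures shared across tests; everything is generated in code

# a fast reduced-scale configuration (analytic FC mode unless stated)
tiny_config <- function(seed = 1, ...) {
  args <- list(n_subjects = 12, n_runs = 4, n_nodes = 16, n_networks = 4,
               n_timepoints = 80, fc_mode = "analytic", seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# symmetric matrix with unit diagonal and given off-diagonal entries
sym_from_lower <- function(n, values) {
  m <- diag(n)
  m[lower.tri(m)] <- NA
  idx <- mindfc:::lower_tri_index_map(n)
  m[cbind(idx$node_i, idx$node_j)] <- values
  m[cbind(idx$node_j, idx$node_i)] <- values
  m
}

# an fc_matrix with hand-set edge values (Fisher-z scale)
fc_fixture <- function(values, networks) {
  n <- length(networks)
  z <- sym_from_lower(n, values)
  diag(z) <- NA_real_
  labels <- paste0("node_", seq_len(n))
  dimnames(z) <- list(labels, labels)
  structure(list(values = z, node_labels = labels,
                 network_assignment = stats::setNames(networks, labels)),
            class = "fc_matrix")
}

# questionnaire table with constant grid scores for the given subjects/runs
flat_snycq <- function(subjects, runs, score = 50) {
  grid <- data.frame(subject = rep(subjects, each = length(runs)),
                     run = rep(runs, times = length(subjects)))
  grid[snycq_items()] <- score
  grid
}

# independent step-up BH implementation used as the FDR oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(prev, p[ord[k]] * m / k)
    adj[ord[k]] <- val
    prev <- val
  }
  adj
}
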