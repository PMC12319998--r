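#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlations between node timeseries, clamped to
#' `[-0.999999, 0.999999]` and atanh-transformed (Fisher z), giving a
#' symmetric node-by-node connectivity matrix with a finite value on every
#' edge. The diagonal is set to `NA` and excluded from all downstream
#' statistics.
#'
#' @param ts A [parcellated_ts()] object with at least 3 timepoints.
#' @param clamp Absolute correlation bound applied before the atanh
#'   transform (default 0.999999), keeping z finite for degenerate inputs.
#'
#' @return An object of class `fc_matrix`: list with `values` (node x node
#'   Fisher-z matrix), `node_labels` and `network_assignment`.
#' @export
compute_fc <- function(ts, clamp = 0.999999) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (ncol(ts$data) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(ts$data, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance node(s): %s",
                 paste(ts$node_labels[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- stats::cor(t(ts$data))
  r <- pmin(pmax(r, -clamp), clamp)
  z <- atanh(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(ts$node_labels, ts$node_labels)
  structure(
    list(values = z, node_labels = ts$node_labels,
         network_assignment = ts$network_assignment),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d nodes, %d networks; mean off-diagonal z = %.3f\n",
              nrow(x$values), length(unique(x$network_assignment)),
              mean(x$values[lower.tri(x$values)])))
  invisible(x)
}

# row-major lower-triangle index map: (2,1), (3,1), (3,2), (4,1), ...
lower_tri_index_map <- function(n, labels = NULL) {
  i <- rep(2:n, times = 1:(n - 1))
  j <- unlist(lapply(2:n, function(k) seq_len(k - 1)))
  out <- data.frame(pos = seq_along(i), node_i = i, node_j = j)
  if (!is.null(labels)) {
    out$label_i <- labels[i]
    out$label_j <- labels[j]
  }
  out
}

#' Half-vectorize an FC matrix into a fingerprint vector
#'
#' Extracts the lower triangle (excluding the diagonal) of a symmetric FC
#' matrix into a single column of length `n(n-1)/2` — the run's FC
#' fingerprint. The order is fixed and package-wide: row-major over the
#' lower triangle with 1-based node indices, recorded in `index_map` so the
#' matrix can be reassembled exactly.
#'
#' @param fc An `fc_matrix` (or plain symmetric matrix).
#' @param tol Symmetry tolerance (default 1e-8).
#'
#' @return An object of class `fc_vector`: `values`, `index_map`
#'   (pos, node_i, node_j with node_i > node_j), `node_labels`,
#'   `network_assignment`.
#' @export
vectorize_fc <- function(fc, tol = 1e-8) {
  if (inherits(fc, "fc_matrix")) {
    m <- fc$values
    labels <- fc$node_labels
    networks <- fc$network_assignment
  } else {
    m <- as.matrix(fc)
    labels <- rownames(m)
    networks <- NULL
  }
  if (nrow(m) != ncol(m)) stop("FC matrix must be square", call. = FALSE)
  off <- abs(m - t(m))
  if (max(off[lower.tri(off)]) > tol) {
    stop("FC matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  n <- nrow(m)
  map <- lower_tri_index_map(n, labels)
  values <- m[cbind(map$node_i, map$node_j)]
  structure(
    list(values = values, index_map = map, node_labels = labels,
         network_assignment = networks),
    class = "fc_vector"
  )
}

#' Reassemble an FC matrix from a fingerprint vector
#'
#' Inverse of [vectorize_fc()]: rebuilds the symmetric off-diagonal matrix
#' (diagonal `NA`).
#'
#' @param fcv An `fc_vector`.
#' @return An `fc_matrix`.
#' @export
fc_from_vector <- function(fcv) {
  stopifnot(inherits(fcv, "fc_vector"))
  map <- fcv$index_map
  n <- max(map$node_i)
  m <- matrix(NA_real_, n, n)
  m[cbind(map$node_i, map$node_j)] <- fcv$values
  m[cbind(map$node_j, map$node_i)] <- fcv$values
  if (!is.null(fcv$node_labels)) dimnames(m) <- list(fcv$node_labels, fcv$node_labels)
  structure(
    list(values = m, node_labels = fcv$node_labels,
         network_assignment = fcv$network_assignment),
    class = "fc_matrix"
  )
}

#' Aggregate an FC matrix into a network-by-network (FNC) matrix
#'
#' Averages FC edges within their network-to-network groupings. The
#' off-diagonal entry (A, B) is the mean of all edges with one endpoint in
#' network A and the other in B; the diagonal entry (A, A) is the mean over
#' distinct node pairs within A (self-pairs excluded) and represents
#' within-network connectivity. A K-network FNC matrix has `K^2` entries of
#' which `K(K+1)/2` are unique (36 for the default 8 networks). Networks
#' with fewer than 2 nodes have no within-network edge; their diagonal entry
#' is `NA` and flagged.
#'
#' @param fc An `fc_matrix` with a network assignment covering `K >= 2`
#'   networks.
#' @param network_order Optional character vector fixing the row/column
#'   order of the result; defaults to first appearance order.
#'
#' @return An object of class `fnc_matrix`: `values` (K x K), `n_nodes`
#'   (per-network node counts), `flagged_networks` (single-node networks).
#' @export
aggregate_fnc <- function(fc, network_order = NULL) {
  stopifnot(inherits(fc, "fc_matrix"))
  networks <- fc$network_assignment
  if (is.null(networks)) stop("FC matrix carries no network assignment",
                              call. = FALSE)
  if (is.null(network_order)) network_order <- unique(networks)
  if (length(network_order) < 2L) {
    stop("need at least 2 networks to aggregate", call. = FALSE)
  }
  k <- length(network_order)
  out <- matrix(NA_real_, k, k, dimnames = list(network_order, network_order))
  idx <- split(seq_along(networks), factor(networks, levels = network_order))
  for (a in seq_len(k)) {
    for (b in seq_len(a)) {
      ia <- idx[[a]]; ib <- idx[[b]]
      if (a == b) {
        if (length(ia) < 2L) next  # single-node network: no within edge
        block <- fc$values[ia, ia]
        out[a, a] <- mean(block[lower.tri(block)])
      } else {
        out[a, b] <- out[b, a] <- mean(fc$values[ia, ib])
      }
    }
  }
  flagged <- network_order[vapply(idx, length, 1L) < 2L]
  if (length(flagged)) {
    warning(sprintf("network(s) with < 2 nodes, within-network entry undefined: %s",
                    paste(flagged, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(values = out, n_nodes = vapply(idx, length, 1L),
         flagged_networks = flagged),
    class = "fnc_matrix"
  )
}

#' @export
print.fnc_matrix <- function(x, ...) {
  cat(sprintf("<fnc_matrix> %d networks (%d entries, %d unique)\n",
              nrow(x$values), nrow(x$values)^2,
              nrow(x$values) * (nrow(x$values) + 1) / 2))
  print(round(x$values, 3))
  invisible(x)
}

#' Unique FNC edges as a named vector
#'
#' Lower triangle plus diagonal of an FNC matrix in fixed row-major order,
#' named `A..B`. Undefined (flagged) entries are dropped.
#'
#' @param fnc An `fnc_matrix`.
#' @return Named numeric vector of length at most `K(K+1)/2`.
#' @export
fnc_edges <- function(fnc) {
  stopifnot(inherits(fnc, "fnc_matrix"))
  v <- fnc$values
  k <- nrow(v)
  nm <- rownames(v)
  i <- rep(seq_len(k), times = seq_len(k))
  j <- unlist(lapply(seq_len(k), seq_len))
  out <- v[cbind(i, j)]
  names(out) <- paste0(nm[i], "..", nm[j])
  out[!is.na(out)]
}

#' Concatenate runs of a subject
#'
#' Z-scores each node series within run (preventing inter-run mean or scale
#' offsets from inflating correlations), then joins the runs along time.
#' All runs must share the same node set and ordering.
#'
#' @param runs List of [parcellated_ts()] objects from one subject.
#' @return A single `parcellated_ts` whose length is the sum of run lengths.
#' @export
concatenate_runs <- function(runs) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, TRUE, "parcellated_ts")))
  ref <- runs[[1]]$node_labels
  bad <- vapply(runs, function(r) !identical(r$node_labels, ref), TRUE)
  if (any(bad)) {
    stop(sprintf("node labels differ from run 1 in run(s): %s",
                 paste(vapply(runs[bad], function(r) r$run_id, ""), collapse = ", ")),
         call. = FALSE)
  }
  zscored <- lapply(runs, function(r) {
    m <- r$data
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0)) {
      stop(sprintf("zero-variance node in %s/%s", r$subject_id, r$run_id),
           call. = FALSE)
    }
    (m - mu) / sdv
  })
  out <- runs[[1]]
  out$data <- do.call(cbind, zscored)
  out$run_id <- paste(vapply(runs, function(r) r$run_id, ""), collapse = "+")
  out
}
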