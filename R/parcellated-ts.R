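#' Construct a parcellated timeseries object
#'
#' Container for one subject-run of node-level BOLD data: a node-by-time
#' numeric matrix plus the sampling interval and a node-to-network map.
#' All preprocessing and connectivity functions in the package operate on
#' this class.
#'
#' @param data Numeric matrix, nodes in rows and timepoints in columns.
#' @param sampling_interval Sampling interval (repetition time) in seconds.
#' @param subject_id,run_id Labels identifying the subject and run.
#' @param node_labels Character vector of node names; defaults to
#'   `node_1 ... node_n`.
#' @param network_assignment Vector (same length as the node count) mapping
#'   each node to a network label. Every node must be assigned exactly once.
#'
#' @return An object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, sampling_interval, subject_id = "sub-01",
                           run_id = "run-01", node_labels = NULL,
                           network_assignment = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("`data` must be a finite numeric matrix (nodes x time)", call. = FALSE)
  }
  n_nodes <- nrow(data)
  if (is.null(node_labels)) {
    node_labels <- paste0("node_", seq_len(n_nodes))
  }
  if (length(node_labels) != n_nodes || anyDuplicated(node_labels)) {
    stop("`node_labels` must give one unique label per node", call. = FALSE)
  }
  if (is.null(network_assignment)) {
    network_assignment <- rep("network_1", n_nodes)
  }
  if (length(network_assignment) != n_nodes || anyNA(network_assignment)) {
    stop("`network_assignment` must cover every node exactly once",
         call. = FALSE)
  }
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval <= 0) {
    stop("`sampling_interval` must be a positive scalar (seconds)",
         call. = FALSE)
  }
  if (ncol(data) < 2L * n_nodes) {
    warning(sprintf(
      "timeseries has %d timepoints for %d nodes (< 2x); estimates may be unstable",
      ncol(data), n_nodes), call. = FALSE)
  }
  names(network_assignment) <- node_labels
  rownames(data) <- node_labels
  structure(
    list(subject_id = subject_id, run_id = run_id, data = data,
         sampling_interval = sampling_interval, node_labels = node_labels,
         network_assignment = network_assignment),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("<parcellated_ts> %s / %s: %d nodes x %d timepoints (TR %.3gs, %d networks)\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data),
              x$sampling_interval, length(unique(x$network_assignment))))
  invisible(x)
}

n_timepoints <- function(ts) ncol(ts$data)
n_nodes <- function(ts) nrow(ts$data)
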