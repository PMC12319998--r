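#' Write a dataset to a directory of delimited text files
#'
#' Layout: one `<subject>_<run>_timeseries.tsv` (nodes x timepoints, row
#' names are node labels) per run — or `<subject>_<run>_fc.tsv` Fisher-z
#' matrices when the dataset was generated in analytic FC mode — plus
#' `nodes.tsv` (node, network), `snycq.tsv`, `behavior.tsv`, and
#' `ground_truth.json` / `meta.json` (sampling interval, mode, seed).
#'
#' @param dataset A `mindfc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mindfc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  first <- dataset$timeseries[[1]][[1]]
  analytic <- inherits(first, "fc_matrix")
  nodes <- data.frame(node = first$node_labels,
                      network = unname(first$network_assignment))
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in names(dataset$timeseries)) {
    for (r in names(dataset$timeseries[[s]])) {
      run <- dataset$timeseries[[s]][[r]]
      suffix <- if (analytic) "fc" else "timeseries"
      mat <- if (analytic) run$values else run$data
      utils::write.table(mat,
                         file.path(dir, sprintf("%s_%s_%s.tsv", s, r, suffix)),
                         sep = "\t", row.names = TRUE, col.names = FALSE,
                         quote = FALSE)
    }
  }
  utils::write.table(dataset$snycq, file.path(dir, "snycq.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(subjects = names(dataset$timeseries),
               runs = names(dataset$timeseries[[1]]),
               sampling_interval = if (analytic) NA else
                 first$sampling_interval,
               fc_mode = if (analytic) "analytic" else "timeseries",
               seed = dataset$config$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(dataset$ground_truth)) {
    gt <- unclass(dataset$ground_truth)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         digits = NA, matrix = "rowmajor")
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory produced by [write_dataset()].
#' @return A `mindfc_dataset` (without the original `config`; the ground
#'   truth, when present, is re-read as a plain list).
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  networks <- stats::setNames(nodes$network, nodes$node)
  analytic <- identical(meta$fc_mode, "analytic")
  ts_list <- list()
  for (s in meta$subjects) {
    ts_list[[s]] <- list()
    for (r in meta$runs) {
      suffix <- if (analytic) "fc" else "timeseries"
      path <- file.path(dir, sprintf("%s_%s_%s.tsv", s, r, suffix))
      raw <- utils::read.table(path, sep = "\t", row.names = 1,
                               header = FALSE)
      mat <- as.matrix(raw)
      colnames(mat) <- NULL
      ts_list[[s]][[r]] <- if (analytic) {
        colnames(mat) <- rownames(mat)
        structure(list(values = mat, node_labels = rownames(mat),
                       network_assignment = networks[rownames(mat)]),
                  class = "fc_matrix")
      } else {
        parcellated_ts(mat, sampling_interval = meta$sampling_interval,
                       subject_id = s, run_id = r,
                       node_labels = rownames(mat),
                       network_assignment = unname(networks[rownames(mat)]))
      }
    }
  }
  snycq <- utils::read.table(file.path(dir, "snycq.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  item_cols <- setdiff(names(snycq), c("subject", "run"))
  snycq[item_cols] <- lapply(snycq[item_cols], as.numeric)
  behavior <- utils::read.table(file.path(dir, "behavior.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  structure(list(timeseries = ts_list, snycq = snycq, behavior = behavior,
                 ground_truth = gt, config = NULL),
            class = "mindfc_dataset")
}
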