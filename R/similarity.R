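#' Mean absolute difference between two vectors
#'
#' The package's run-pair (dis)similarity statistic: element-wise absolute
#' differences averaged over positions. Symmetric in its arguments and zero
#' iff the vectors are identical.
#'
#' @param vec_a,vec_b Equal-length finite numeric vectors.
#' @return Scalar `mean(|vec_a - vec_b|)`.
#' @export
mad_diff <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) {
    stop(sprintf("length mismatch: %d vs %d", length(vec_a), length(vec_b)),
         call. = FALSE)
  }
  if (!all(is.finite(vec_a)) || !all(is.finite(vec_b))) {
    stop("inputs must be finite", call. = FALSE)
  }
  mean(abs(vec_a - vec_b))
}

#' Questionnaire item names
#'
#' The 12 thought-content dimensions assessed after each resting-state run
#' (SNYCQ short names). Used as default item columns throughout.
#'
#' @return Character vector of length 12.
#' @export
snycq_items <- function() {
  c("positive", "negative", "future", "past", "myself", "people",
    "surroundings", "vigilance", "images", "words", "specific", "intrusive")
}

# validate a questionnaire table: subject, run, then item columns
check_snycq <- function(snycq, items) {
  missing_cols <- setdiff(c("subject", "run", items), names(snycq))
  if (length(missing_cols)) {
    stop(sprintf("questionnaire table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  scores <- as.matrix(snycq[, items, drop = FALSE])
  if (any(scores < 0 | scores > 100, na.rm = TRUE)) {
    stop("questionnaire scores must lie in [0, 100]", call. = FALSE)
  }
  off_grid <- scores[!is.na(scores)] %% 5 != 0
  if (any(off_grid)) {
    warning(sprintf("%d questionnaire score(s) off the {0,5,...,100} grid",
                    sum(off_grid)), call. = FALSE)
  }
  invisible(snycq)
}

#' Within-subject run-pair contrast table
#'
#' For every unique unordered pair of valid runs within a subject, records
#' the mean absolute difference (MAD) of the two runs' FC fingerprint
#' vectors, the MAD over the questionnaire items (full-scale), and the raw
#' per-item absolute differences. A subject with r valid runs contributes
#' `choose(r, 2)` rows; subjects with fewer than `min_runs` valid runs are
#' dropped. FC runs without a matching questionnaire row are dropped with a
#' warning.
#'
#' @param fc_vectors Named list: `fc_vectors[[subject]][[run]]` is the
#'   `fc_vector` of that run.
#' @param snycq Data frame with columns `subject`, `run`, and one column per
#'   item (scores 0-100).
#' @param items Item column names (default [snycq_items()]).
#' @param min_runs Minimum valid runs per retained subject (default 3).
#'
#' @return Long data frame of class `contrast_table`: `subject`, `run_a`,
#'   `run_b` (run_a < run_b in run order), `mad_fc`, `mad_snycq_full`, and
#'   `<item>_absdiff` columns.
#' @export
build_contrast_table <- function(fc_vectors, snycq, items = snycq_items(),
                                 min_runs = 3) {
  check_snycq(snycq, items)
  rows <- list()
  dropped <- character(0)
  for (subject in names(fc_vectors)) {
    runs <- names(fc_vectors[[subject]])
    has_q <- vapply(runs, function(r)
      any(snycq$subject == subject & snycq$run == r), TRUE)
    if (any(!has_q)) {
      dropped <- c(dropped, paste0(subject, "/", runs[!has_q]))
      runs <- runs[has_q]
    }
    if (length(runs) < min_runs) next
    runs <- sort(runs)
    for (a in seq_len(length(runs) - 1L)) {
      for (b in (a + 1L):length(runs)) {
        fa <- fc_vectors[[subject]][[runs[a]]]$values
        fb <- fc_vectors[[subject]][[runs[b]]]$values
        qa <- as.numeric(snycq[snycq$subject == subject & snycq$run == runs[a],
                               items][1, ])
        qb <- as.numeric(snycq[snycq$subject == subject & snycq$run == runs[b],
                               items][1, ])
        rec <- data.frame(subject = subject, run_a = runs[a], run_b = runs[b],
                          mad_fc = mad_diff(fa, fb),
                          mad_snycq_full = mad_diff(qa, qb))
        item_diffs <- as.list(abs(qa - qb))
        names(item_diffs) <- paste0(items, "_absdiff")
        rows[[length(rows) + 1L]] <- cbind(rec, as.data.frame(item_diffs))
      }
    }
  }
  if (length(dropped)) {
    warning(sprintf("run(s) without questionnaire data dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (!length(rows)) stop("no subject has enough valid runs", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_table", class(out))
  out
}

#' Restrict a contrast table to non-overlapping run pairs
#'
#' Sensitivity variant in which each run enters at most one retained
#' contrast per subject, removing the dependence between contrasts that
#' share a run. The default scheme pairs consecutive runs in run order
#' (run1-run2, run3-run4); subjects with an odd number of runs contribute
#' the pairs among their first `2*floor(r/2)` runs, i.e. a 3-run subject
#' keeps the pair of its two earliest runs.
#'
#' @param table A `contrast_table`.
#' @param scheme Either `"consecutive"` (default) or a function
#'   `function(runs)` returning a list of length-2 run vectors forming a
#'   partial pairing of the subject's sorted runs. Overlapping pairings are
#'   rejected.
#'
#' @return The filtered `contrast_table`.
#' @export
nonoverlapping_subset <- function(table, scheme = "consecutive") {
  stopifnot(inherits(table, "contrast_table") || is.data.frame(table))
  pair_fun <- if (is.function(scheme)) scheme else if (identical(scheme, "consecutive")) {
    function(runs) {
      n_pair <- floor(length(runs) / 2)
      lapply(seq_len(n_pair), function(k) runs[c(2 * k - 1, 2 * k)])
    }
  } else stop("`scheme` must be \"consecutive\" or a pairing function",
              call. = FALSE)
  keep <- logical(nrow(table))
  for (subject in unique(table$subject)) {
    rows <- which(table$subject == subject)
    runs <- sort(unique(c(table$run_a[rows], table$run_b[rows])))
    pairs <- pair_fun(runs)
    used <- unlist(pairs)
    if (anyDuplicated(used)) {
      stop("pairing scheme assigns a run to more than one pair", call. = FALSE)
    }
    for (p in pairs) {
      p <- sort(p)
      keep[rows[table$run_a[rows] == p[1] & table$run_b[rows] == p[2]]] <- TRUE
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Across-run questionnaire averages
#'
#' Item-wise arithmetic mean of each subject's valid-run questionnaire
#' profiles, used as the subject-level thought-content summary in the
#' cross-sectional analyses. Subjects with no valid rows are dropped with a
#' warning.
#'
#' @param snycq Questionnaire table (`subject`, `run`, item columns).
#' @param items Item column names (default [snycq_items()]).
#' @param subjects Optional subject subset/order; defaults to all subjects
#'   present.
#'
#' @return Data frame: `subject`, `n_runs`, then one mean column per item.
#' @export
average_snycq <- function(snycq, items = snycq_items(), subjects = NULL) {
  check_snycq(snycq, items)
  if (is.null(subjects)) subjects <- unique(snycq$subject)
  rows <- lapply(subjects, function(s) {
    sub <- snycq[snycq$subject == s, items, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cbind(data.frame(subject = s, n_runs = nrow(sub)),
          as.data.frame(as.list(colMeans(sub))))
  })
  empty <- subjects[vapply(rows, is.null, TRUE)]
  if (length(empty)) {
    warning(sprintf("subject(s) with no valid questionnaire runs dropped: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
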