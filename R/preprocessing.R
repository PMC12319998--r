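#' Mean RMS displacement and motion-based run exclusion
#'
#' Summarizes head motion for one run as the mean frame-to-frame root mean
#' squared displacement and flags the run for exclusion when it exceeds the
#' threshold. Displacement per frame transition combines the translation
#' increments with rotation increments converted to arc length at a nominal
#' brain radius:
#' \deqn{d_t = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2 +
#'   r^2(\Delta\alpha^2 + \Delta\beta^2 + \Delta\gamma^2)}}
#' Exclusion uses a strict inequality: a run at exactly the threshold is
#' retained.
#'
#' @param motion_parameters Matrix or data frame with 6 columns: three
#'   translations (mm) then three rotations (radians), one row per timepoint.
#' @param brain_radius Radius (mm) used to convert rotation angles to arc
#'   displacement. Default 50 mm, the common convention.
#' @param threshold Exclusion threshold in mm (default 0.25).
#' @param run_id Label carried into the summary.
#'
#' @return A list of class `motion_summary` with `run_id`,
#'   `mean_rms_displacement` (mm) and `excluded`.
#' @export
mean_rms_displacement <- function(motion_parameters, brain_radius = 50,
                                  threshold = 0.25, run_id = "run-01") {
  mp <- as.matrix(motion_parameters)
  if (ncol(mp) != 6L) {
    stop(sprintf("motion table must have 6 columns (3 translations, 3 rotations), got %d",
                 ncol(mp)), call. = FALSE)
  }
  if (!all(is.finite(mp))) stop("motion parameters contain non-finite values",
                                call. = FALSE)
  if (nrow(mp) < 2L) {
    d <- 0
  } else {
    diffs <- diff(mp)
    diffs[, 4:6] <- diffs[, 4:6] * brain_radius
    d <- mean(sqrt(rowSums(diffs^2)))
  }
  structure(
    list(run_id = run_id, mean_rms_displacement = d,
         excluded = d > threshold, threshold = threshold),
    class = "motion_summary"
  )
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> %s: mean RMS displacement %.4f mm (%s)\n",
              x$run_id, x$mean_rms_displacement,
              if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}

#' Cosine basis for slow drift
#'
#' Discrete cosine (DCT-II) regressors spanning periods at or above
#' `cutoff_period`, the standard drift basis used in fMRI nuisance models.
#' The number of columns is `floor(2 * n * TR / cutoff_period)`; columns are
#' unit-normalized and exactly mutually orthogonal.
#'
#' @param n_timepoints Number of timepoints.
#' @param sampling_interval Sampling interval in seconds.
#' @param cutoff_period Slowest period (seconds) to be treated as signal;
#'   drift slower than this is captured by the basis. Default 128 s.
#'
#' @return Matrix with `n_timepoints` rows; zero columns when the run is too
#'   short for any drift term.
#' @export
build_cosine_basis <- function(n_timepoints, sampling_interval,
                               cutoff_period = 128) {
  if (n_timepoints < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (cutoff_period <= 2 * sampling_interval) {
    stop("`cutoff_period` must exceed twice the sampling interval",
         call. = FALSE)
  }
  n_basis <- floor(2 * n_timepoints * sampling_interval / cutoff_period)
  t_idx <- seq_len(n_timepoints) - 0.5
  basis <- matrix(0, n_timepoints, max(n_basis, 0))
  for (k in seq_len(n_basis)) {
    col <- cos(pi * k * t_idx / n_timepoints)
    basis[, k] <- col / sqrt(sum(col^2))
  }
  colnames(basis) <- if (n_basis > 0) paste0("cosine_", seq_len(n_basis))
  basis
}

#' Assemble a confound design
#'
#' Combines motion parameters, tissue signals (white matter, CSF, global),
#' optionally their first-difference derivatives, and a cosine drift basis
#' into one regressor matrix. Rank-deficient column sets are reduced by
#' dropping aliased columns (detected by pivoted QR).
#'
#' @param motion_parameters Optional 6-column motion table.
#' @param tissue_signals Optional matrix/data frame of tissue signals.
#' @param derivatives Add first differences (zero-padded at the first frame)
#'   of motion and tissue columns. Default `TRUE`.
#' @param cosine_basis Optional drift basis (from [build_cosine_basis()]).
#'
#' @return A numeric matrix of confound regressors (possibly 0 columns), of
#'   class `confound_set`.
#' @export
confound_set <- function(motion_parameters = NULL, tissue_signals = NULL,
                         derivatives = TRUE, cosine_basis = NULL) {
  parts <- list()
  if (!is.null(motion_parameters)) {
    mp <- as.matrix(motion_parameters)
    if (ncol(mp) != 6L) stop("motion table must have 6 columns", call. = FALSE)
    colnames(mp) <- paste0("motion_", 1:6)
    parts$motion <- mp
  }
  if (!is.null(tissue_signals)) {
    tsg <- as.matrix(tissue_signals)
    if (is.null(colnames(tsg))) colnames(tsg) <- paste0("tissue_", seq_len(ncol(tsg)))
    parts$tissue <- tsg
  }
  if (derivatives && length(parts)) {
    base <- do.call(cbind, parts)
    deriv <- rbind(0, diff(base))
    colnames(deriv) <- paste0(colnames(base), "_deriv")
    parts$deriv <- deriv
  }
  if (!is.null(cosine_basis) && ncol(as.matrix(cosine_basis)) > 0) {
    parts$cosine <- as.matrix(cosine_basis)
  }
  x <- if (length(parts)) do.call(cbind, parts) else
    matrix(0, 0, 0)
  if (length(x) && !all(is.finite(x))) {
    stop("confound regressors contain non-finite values", call. = FALSE)
  }
  n_len <- vapply(parts, nrow, 1L)
  if (length(unique(n_len)) > 1L) {
    stop("all confound blocks must have the same number of timepoints",
         call. = FALSE)
  }
  if (ncol(x) > 1L) {
    qrx <- qr(cbind(1, x))
    if (qrx$rank < ncol(x) + 1L) {
      keep <- sort(qrx$pivot[seq_len(qrx$rank)]) - 1L
      keep <- keep[keep > 0L]
      warning(sprintf("confound design is rank-deficient; keeping %d of %d columns",
                      length(keep), ncol(x)), call. = FALSE)
      x <- x[, keep, drop = FALSE]
    }
  }
  class(x) <- c("confound_set", class(x))
  x
}

#' Regress confounds out of a parcellated timeseries
#'
#' Replaces each node series with its least-squares residual against the
#' confound design plus an intercept, so output series are mean-centered and
#' numerically orthogonal to every confound column. Applying the same
#' regression twice is a no-op.
#'
#' @param ts A [parcellated_ts()] object.
#' @param confounds A [confound_set()] or plain numeric matrix with one row
#'   per timepoint (may have zero columns, giving pure demeaning).
#'
#' @return The denoised `parcellated_ts`.
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "parcellated_ts"))
  x <- as.matrix(unclass(confounds))
  if (length(x) == 0L) x <- matrix(numeric(0), ncol(ts$data), 0L)
  if (nrow(x) != ncol(ts$data)) {
    stop(sprintf("confounds have %d rows but timeseries has %d timepoints",
                 nrow(x), ncol(ts$data)), call. = FALSE)
  }
  if (length(x) && !all(is.finite(x))) {
    stop("confound regressors contain non-finite values", call. = FALSE)
  }
  design <- cbind(intercept = 1, x)
  resid <- t(stats::lm.fit(design, t(ts$data))$residuals)
  dimnames(resid) <- dimnames(ts$data)
  ts$data <- resid
  ts
}

#' Zero-phase low-pass filter
#'
#' Fourth-order Butterworth low-pass applied forward and backward
#' ([signal::filtfilt()]), giving zero phase shift so that lag structure and
#' hence cross-correlations are not distorted. DC is preserved.
#'
#' @param ts A [parcellated_ts()] object.
#' @param cutoff_hz Cutoff frequency in Hz; default 0.1. Must be below the
#'   Nyquist frequency implied by the sampling interval.
#' @param order Filter order per pass (default 4).
#'
#' @return The filtered `parcellated_ts`.
#' @export
lowpass_filter <- function(ts, cutoff_hz = 0.1, order = 4) {
  stopifnot(inherits(ts, "parcellated_ts"))
  nyquist <- 1 / (2 * ts$sampling_interval)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop(sprintf("`cutoff_hz` must lie in (0, %.4f Hz), the Nyquist limit",
                 nyquist), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  filtered <- t(apply(ts$data, 1, function(row) {
    m <- mean(row)
    # filter the demeaned series and restore the mean: keeps DC exact even
    # for short runs where edge transients would otherwise bias the level
    signal::filtfilt(bf, row - m) + m
  }))
  dimnames(filtered) <- dimnames(ts$data)
  ts$data <- filtered
  ts
}

#' Denoise one run: confound regression then low-pass filtering
#'
#' Convenience wrapper fixing the pipeline order (regression first, then
#' filtering) used throughout the package.
#'
#' @inheritParams regress_confounds
#' @inheritParams lowpass_filter
#' @return The denoised `parcellated_ts`.
#' @export
denoise_run <- function(ts, confounds, cutoff_hz = 0.1) {
  lowpass_filter(regress_confounds(ts, confounds), cutoff_hz = cutoff_hz)
}
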