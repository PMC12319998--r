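#' Random-intercept mixed model with standardized slope
#'
#' Fits `outcome ~ predictor + (1 | group)` by REML (via [lme4::lmer()]) and
#' returns the quantities the pipeline reports: fixed effects, variance
#' components, Wald test of the slope, the standardized coefficient
#' `beta * sd(x) / sd(y)` with its 95% confidence interval, and
#' Nakagawa-Schielzeth marginal/conditional R-squared. Confidence intervals
#' use the normal approximation by default, with residual-df t as an option.
#'
#' @param data Data frame in long format.
#' @param outcome,predictor,group Column names (strings).
#' @param ci_method `"normal"` (default) or `"t"` (residual df).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return Object of class `lmm_fit` with fields `fixed_intercept`,
#'   `fixed_slope`, `slope_se`, `slope_p`, `random_intercept_variance`,
#'   `residual_variance`, `standardized_beta`, `std_ci` (length-2),
#'   `marginal_r2`, `conditional_r2`, `n_observations`, `n_groups`,
#'   `converged`, `singular` (boundary fit with zero group variance, a
#'   legitimate converged solution), plus the underlying `model`.
#' @export
fit_lmm <- function(data, outcome, predictor, group,
                    ci_method = c("normal", "t"), conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  cols <- c(outcome, predictor, group)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  d <- data.frame(y = data[[outcome]], x = data[[predictor]],
                  g = factor(data[[group]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$g)) < 2L) stop("need at least 2 groups", call. = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | g), data = d, REML = TRUE)
  ))
  msgs <- fit@optinfo$conv$lme4$messages
  singular <- any(grepl("boundary (singular)", msgs, fixed = TRUE))
  # a boundary (zero-variance) fit is a legitimate converged solution;
  # only genuine optimizer failures are flagged
  real_problems <- msgs[!grepl("boundary (singular)", msgs, fixed = TRUE)]
  converged <- length(real_problems) == 0L
  if (!converged) {
    warning(sprintf("mixed-model fit did not converge cleanly: %s",
                    paste(real_problems, collapse = "; ")), call. = FALSE)
  }
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_u <- vc$vcov[vc$grp == "g"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["x"]]
  alpha <- 1 - conf_level
  crit <- if (ci_method == "normal") stats::qnorm(1 - alpha / 2) else
    stats::qt(1 - alpha / 2, df = nrow(d) - nlevels(droplevels(d$g)) - 1L)
  wald_z <- beta[["x"]] / se
  slope_p <- if (ci_method == "normal") 2 * stats::pnorm(-abs(wald_z)) else
    2 * stats::pt(-abs(wald_z), df = nrow(d) - nlevels(droplevels(d$g)) - 1L)
  sd_x <- stats::sd(d$x)
  sd_y <- stats::sd(d$y)
  std <- standardize_beta(
    list(estimate = beta[["x"]],
         ci = beta[["x"]] + c(-1, 1) * crit * se),
    sd_predictor = sd_x, sd_outcome = sd_y
  )
  # fixed-effects variance for Nakagawa R2: variance of the fitted fixed part
  var_f <- stats::var(beta[["x"]] * d$x)
  r2 <- nakagawa_r2(var_f, var_u, var_e)
  structure(
    list(fixed_intercept = unname(beta[["(Intercept)"]]),
         fixed_slope = unname(beta[["x"]]),
         slope_se = se, slope_p = unname(slope_p),
         random_intercept_variance = var_u, residual_variance = var_e,
         standardized_beta = std$estimate, std_ci = std$ci,
         sd_predictor = sd_x, sd_outcome = sd_y,
         fixed_effects_variance = var_f,
         marginal_r2 = r2[["marginal"]], conditional_r2 = r2[["conditional"]],
         n_observations = nrow(d), n_groups = nlevels(droplevels(d$g)),
         converged = converged, singular = singular,
         ci_method = ci_method, model = fit),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<lmm_fit> %d obs in %d groups%s\n",
    "  slope %.4f (SE %.4f, p = %.3g); std beta %.4f [%.4f, %.4f]\n",
    "  var(u) %.4g, var(e) %.4g; R2 marginal %.3f / conditional %.3f\n"),
    x$n_observations, x$n_groups, if (x$converged) "" else " [NOT CONVERGED]",
    x$fixed_slope, x$slope_se, x$slope_p, x$standardized_beta,
    x$std_ci[1], x$std_ci[2], x$random_intercept_variance,
    x$residual_variance, x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' Standardize a regression coefficient post hoc
#'
#' Rescales a fitted slope (and its confidence interval) to standardized
#' units, `beta * sd(x) / sd(y)`, without refitting on z-scored data. Both
#' CI endpoints are transformed identically.
#'
#' @param fit An `lmm_fit`, or a list with `estimate` and `ci` (length 2).
#' @param sd_predictor,sd_outcome Positive standard deviations.
#' @return List with standardized `estimate` and `ci`.
#' @export
standardize_beta <- function(fit, sd_predictor, sd_outcome) {
  if (!is.numeric(sd_predictor) || !is.numeric(sd_outcome) ||
      sd_predictor <= 0 || sd_outcome <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  est <- if (inherits(fit, "lmm_fit")) fit$fixed_slope else fit$estimate
  ci <- if (inherits(fit, "lmm_fit"))
    fit$fixed_slope + c(-1, 1) * stats::qnorm(0.975) * fit$slope_se else fit$ci
  scale <- sd_predictor / sd_outcome
  list(estimate = est * scale, ci = sort(ci * scale))
}

# Nakagawa-Schielzeth R2 for a random-intercept model
nakagawa_r2 <- function(var_fixed, var_random, var_residual) {
  total <- var_fixed + var_random + var_residual
  if (total <= 0) {
    warning("zero total variance: R2 undefined", call. = FALSE)
    return(c(marginal = NA_real_, conditional = NA_real_))
  }
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Nakagawa-Schielzeth decomposition for a random-intercept model:
#' marginal `= var_f / (var_f + var_u + var_e)` (fixed effects only) and
#' conditional `= (var_f + var_u) / (var_f + var_u + var_e)` (fixed plus
#' random).
#'
#' @param fit An `lmm_fit`.
#' @param fixed_effects_variance Optional override of the fixed-effects
#'   variance component (defaults to the value stored in the fit).
#' @return Named vector `c(marginal, conditional)`.
#' @export
lmm_r2 <- function(fit, fixed_effects_variance = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) warning("fit did not converge; R2 may be unreliable",
                              call. = FALSE)
  var_f <- if (is.null(fixed_effects_variance)) fit$fixed_effects_variance
           else fixed_effects_variance
  nakagawa_r2(var_f, fit$random_intercept_variance, fit$residual_variance)
}

#' Benjamini-Hochberg FDR adjustment for a declared family
#'
#' Step-up adjusted p-values for one caller-declared family of tests
#' (monotone, capped at 1). Families are always declared explicitly by the
#' caller — e.g. the 36 network-edge tests of one questionnaire item, the 12
#' item-level fingerprint tests, or the per-phenotype canonical-correlation
#' and indirect-effect families.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   passed through).
#' @param family_label Optional label recorded as an attribute.
#' @return Adjusted p-values, same length and order as the input.
#' @export
fdr_bh <- function(p_values, family_label = NULL) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "BH")
  if (!is.null(family_label)) attr(adj, "family") <- family_label
  adj
}

#' Canonical correlation analysis against a univariate outcome
#'
#' First (and only) canonical pair between a multivariate predictor set X
#' and a single outcome y, used as a per-outcome dimension-reduction: the
#' canonical variate is the linear combination of X maximally correlated
#' with y. Computed from the whitened cross-covariance; with a univariate
#' second set the canonical correlation equals the multiple correlation R of
#' y on X, and significance is the overall regression F test on
#' (rank, n - rank - 1) degrees of freedom. The variate's sign is fixed so
#' it correlates positively with y. Loadings (structure coefficients) are
#' the correlations of each X column with the variate. Rank-deficient X is
#' handled by pseudo-inverse whitening with a warning.
#'
#' @param X Numeric matrix/data frame, subjects in rows (n > p + 1).
#' @param y Numeric outcome vector.
#' @param tol Relative eigenvalue tolerance for the rank decision.
#'
#' @return Object of class `cca_result`: `canonical_correlation`,
#'   `loadings`, `coefficients` (canonical weights on standardized X),
#'   `cv_scores` (unit-variance), `p_value`, `n`, `rank`.
#' @export
cca_univariate_outcome <- function(X, y, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1L) {
    stop(sprintf("need n > p + 1 (n = %d, p = %d)", n, p), call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0) || stats::sd(y) == 0) {
    stop("constant column in X or constant outcome", call. = FALSE)
  }
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  Rxx <- stats::cor(X)
  rxy <- as.numeric(stats::cor(X, y))
  eig <- eigen(Rxx, symmetric = TRUE)
  keep <- eig$values > tol * eig$values[1]
  rank <- sum(keep)
  if (rank < p) {
    warning(sprintf("predictor set is rank-deficient (rank %d of %d); using pseudo-inverse whitening",
                    rank, p), call. = FALSE)
  }
  # Rxx^{-1} via the retained eigenspace
  v <- eig$vectors[, keep, drop = FALSE]
  rxx_inv <- v %*% (t(v) / eig$values[keep])
  r2 <- drop(crossprod(rxy, rxx_inv %*% rxy))
  r2 <- min(max(r2, 0), 1)
  cancor_r <- sqrt(r2)
  w <- drop(rxx_inv %*% rxy)
  scores <- drop(Xs %*% w)
  if (stats::sd(scores) > 0) {
    w <- w / stats::sd(scores)
    scores <- scores / stats::sd(scores)
  }
  if (sum(scores * ys) < 0) {  # sign convention: CV correlates positively with y
    w <- -w
    scores <- -scores
  }
  loadings <- drop(stats::cor(X, scores))
  df2 <- n - rank - 1L
  f_stat <- (r2 / rank) / ((1 - r2) / df2)
  p_value <- stats::pf(f_stat, rank, df2, lower.tail = FALSE)
  structure(
    list(canonical_correlation = cancor_r, loadings = loadings,
         coefficients = w, cv_scores = scores, p_value = p_value,
         n = n, rank = rank),
    class = "cca_result"
  )
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> n = %d, p(rank) = %d: canonical r = %.4f (p = %.3g)\n",
              x$n, x$rank, x$canonical_correlation, x$p_value))
  invisible(x)
}

#' Canonical-variate scores from a weight vector
#'
#' Per-subject summary scores: the column-standardized predictor matrix
#' multiplied by a weight vector. The default `"loadings"` mode uses
#' structure loadings as weights (the convention mirrored by this
#' pipeline's cross-sectional analyses); `"coefficients"` mode uses the
#' canonical coefficients, the textbook CCA scoring.
#'
#' @param X Numeric matrix/data frame, subjects in rows.
#' @param weights Weight vector of length `ncol(X)` (loadings or
#'   coefficients, per `mode`).
#' @param mode `"loadings"` (default) or `"coefficients"`; semantic tag
#'   validated against the allowed values.
#' @return Numeric vector of per-subject scores.
#' @export
cv_scores <- function(X, weights, mode = c("loadings", "coefficients")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (length(weights) != ncol(X)) {
    stop(sprintf("weights have length %d but X has %d columns",
                 length(weights), ncol(X)), call. = FALSE)
  }
  drop(scale(X) %*% as.numeric(weights))
}

# standardized mediation paths from a 3-column (x, m, y) matrix via the
# correlation closed form; used for both the point fit and the bootstrap
mediation_paths <- function(xmy) {
  r <- stats::cor(xmy)
  r_xm <- r[1, 2]; r_xy <- r[1, 3]; r_my <- r[2, 3]
  det <- 1 - r_xm^2
  c(a = r_xm,
    b = (r_my - r_xm * r_xy) / det,
    c = r_xy,
    c_prime = (r_xy - r_xm * r_my) / det)
}

#' Bootstrap mediation of a predictor-outcome association
#'
#' Single-mediator model on standardized variables: path A (mediator on
#' predictor), paths B and C' (outcome on predictor + mediator), path C
#' (outcome on predictor). The indirect effect is `A * B`; on any one sample
#' the least-squares identity `C = C' + A * B` holds exactly. Its
#' percentile confidence interval comes from case-resampled bootstrap
#' replicates (seeded and reproducible); a two-sided bootstrap p-value
#' (twice the smaller tail fraction of replicates on either side of zero)
#' is also reported so indirect effects can enter an FDR family.
#'
#' @param predictor,mediator,outcome Aligned finite numeric vectors,
#'   `n >= 10`.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed RNG seed for the resampling.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return Object of class `mediation_result`: standardized `path_a`,
#'   `path_b`, `path_c`, `path_c_prime` (each with `_se` and `_p`),
#'   `indirect`, `bootstrap_ci`, `indirect_p`, `significant` (CI excludes
#'   0), `n`, `n_boot`, `seed`, `ci_type = "percentile"`.
#' @export
mediate <- function(predictor, mediator, outcome, n_boot = 5000, seed = 1,
                    conf_level = 0.95) {
  xmy <- cbind(x = as.numeric(predictor), m = as.numeric(mediator),
               y = as.numeric(outcome))
  xmy <- xmy[stats::complete.cases(xmy), , drop = FALSE]
  n <- nrow(xmy)
  if (n < 10L) stop("need at least 10 complete observations", call. = FALSE)
  if (any(apply(xmy, 2, stats::sd) == 0)) {
    stop("constant predictor, mediator, or outcome", call. = FALSE)
  }
  paths <- mediation_paths(xmy)
  # SEs and p-values from the two standardized least-squares fits
  zs <- as.data.frame(scale(xmy))
  sm <- stats::coef(summary(stats::lm(m ~ x, data = zs)))
  sy <- stats::coef(summary(stats::lm(y ~ x + m, data = zs)))
  sc <- stats::coef(summary(stats::lm(y ~ x, data = zs)))
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("a", "b", "c", "c_prime")))
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[i, ] <- tryCatch(mediation_paths(xmy[idx, , drop = FALSE]),
                          error = function(e) rep(NA_real_, 4))
  }
  boot_ind <- boot[, "a"] * boot[, "b"]
  boot_ind <- boot_ind[is.finite(boot_ind)]
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(boot_ind, c(alpha / 2, 1 - alpha / 2)))
  p_lo <- mean(boot_ind <= 0)
  p_hi <- mean(boot_ind >= 0)
  indirect_p <- min(1, 2 * min(p_lo, p_hi))
  structure(
    list(path_a = unname(paths["a"]), path_a_se = sm["x", 2],
         path_a_p = sm["x", 4],
         path_b = unname(paths["b"]), path_b_se = sy["m", 2],
         path_b_p = sy["m", 4],
         path_c = unname(paths["c"]), path_c_se = sc["x", 2],
         path_c_p = sc["x", 4],
         path_c_prime = unname(paths["c_prime"]),
         path_c_prime_se = sy["x", 2],
         path_c_prime_p = sy["x", 4],
         indirect = unname(paths["a"] * paths["b"]),
         bootstrap_ci = ci, indirect_p = indirect_p,
         significant = ci[1] > 0 || ci[2] < 0,
         n = n, n_boot = n_boot, seed = seed, conf_level = conf_level,
         ci_type = "percentile"),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<mediation_result> n = %d, %d bootstrap replicates (seed %s)\n",
    "  A = %.4f (SE %.4f)  B = %.4f (SE %.4f)\n",
    "  C = %.4f  C' = %.4f\n",
    "  indirect A*B = %.4f, 95%% CI [%.4f, %.4f] -> %s\n"),
    x$n, x$n_boot, format(x$seed), x$path_a, x$path_a_se, x$path_b,
    x$path_b_se, x$path_c, x$path_c_prime, x$indirect, x$bootstrap_ci[1],
    x$bootstrap_ci[2],
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Phenotype inclusion by data completeness
#'
#' Keeps a behavioral phenotype iff at least `threshold` of subjects have
#' valid (non-missing) data for it; the boundary is inclusive ("at least").
#' Downstream per-phenotype analyses then use listwise-complete subjects.
#'
#' @param behavior Data frame with a `subject` column and one column per
#'   phenotype (missingness as `NA`).
#' @param threshold Minimum valid fraction (default 0.90).
#' @param id_col Subject identifier column name (default `"subject"`).
#'
#' @return Character vector of included phenotype names, with the per-
#'   phenotype valid fractions as the `valid_fraction` attribute.
#' @export
phenotype_inclusion <- function(behavior, threshold = 0.90,
                                id_col = "subject") {
  if (!is.data.frame(behavior) || !nrow(behavior)) {
    stop("`behavior` must be a non-empty data frame", call. = FALSE)
  }
  phenos <- setdiff(names(behavior), id_col)
  if (!length(phenos)) stop("no phenotype columns found", call. = FALSE)
  frac <- vapply(phenos, function(p) mean(!is.na(behavior[[p]])), 1.0)
  included <- phenos[frac >= threshold]
  attr(included, "valid_fraction") <- frac
  included
}

# preserve the caller's RNG state around seeded internals
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
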