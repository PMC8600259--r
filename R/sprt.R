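#' SPRT configuration
#'
#' Parameters of the truncated, two-stage voxelwise sequential probability
#' ratio test. During the first stage no decisions are made; at its end the
#' alternative hypothesis \eqn{\theta_1} is calibrated per voxel from the
#' first-stage variance so that \eqn{\theta_1 / \sqrt{\widehat{var}}} equals
#' `z_threshold`, and thereafter the Wald statistic is compared to the
#' boundaries implied by the target error levels.
#'
#' @param alpha_e Target type-I error level (default 0.001).
#' @param beta_e Target type-II error level (default 0.1).
#' @param z_threshold Calibration z-score for the alternative (default 3.10,
#'   the upper-tail standard normal quantile for one-sided p = 0.001).
#' @param first_stage_scans Scans withheld from decision-making while
#'   variance estimates stabilise (common presets: 78 = 2 blocks per level,
#'   154 = 4 blocks per level of the packaged protocol).
#' @param max_scans Truncation horizon.
#' @param theta0 Null contrast value (default 0).
#' @param sided `"one"` (activation = positive contrast; default) or `"two"`.
#' @param bonferroni Divide `alpha_e` by `n_comparisons` before computing
#'   boundaries (off by default).
#' @param n_comparisons Number of simultaneous voxel tests, used only when
#'   `bonferroni = TRUE`.
#' @return Object of class `sprt_config`.
#' @export
sprt_config <- function(alpha_e = 0.001, beta_e = 0.1, z_threshold = 3.10,
                        first_stage_scans = 154, max_scans = 238,
                        theta0 = 0, sided = c("one", "two"),
                        bonferroni = FALSE, n_comparisons = 1L) {
  sided <- match.arg(sided)
  if (alpha_e <= 0 || alpha_e >= 1 || beta_e <= 0 || beta_e >= 1)
    stop("error levels must lie in (0, 1)", call. = FALSE)
  if (alpha_e + beta_e >= 1)
    stop("alpha_e + beta_e must be < 1", call. = FALSE)
  if (first_stage_scans >= max_scans)
    stop("first_stage_scans must be < max_scans", call. = FALSE)
  if (z_threshold <= 0) stop("z_threshold must be > 0", call. = FALSE)
  structure(list(alpha_e = alpha_e, beta_e = beta_e, z_threshold = z_threshold,
                 first_stage_scans = as.integer(first_stage_scans),
                 max_scans = as.integer(max_scans), theta0 = theta0,
                 sided = sided, bonferroni = isTRUE(bonferroni),
                 n_comparisons = as.integer(n_comparisons)),
            class = "sprt_config")
}

#' @export
print.sprt_config <- function(x, ...) {
  b <- sprt_boundaries(x)
  cat(sprintf(paste0("SPRT config: alpha_E = %g, beta_E = %g (A = %.4f, B = %.4f)\n",
                     "  z_threshold = %g, first stage %d of %d scans, %s-sided\n"),
              x$alpha_e, x$beta_e, b[1], b[2], x$z_threshold,
              x$first_stage_scans, x$max_scans, x$sided))
  invisible(x)
}

#' Wald stopping boundaries
#'
#' \eqn{A = \log((1-\beta_E)/\alpha_E)} and
#' \eqn{B = \log(\beta_E/(1-\alpha_E))}; sampling continues while
#' \eqn{B < \Lambda_t < A}, the null is accepted when \eqn{\Lambda_t \le B}
#' and the alternative when \eqn{\Lambda_t \ge A}.
#'
#' @param alpha_e,beta_e Target type-I and type-II error levels.
#' @return Named numeric vector `c(A = ..., B = ...)` with `A > 0 > B`.
#' @examples
#' stopping_boundaries(0.001, 0.1)
#' @export
stopping_boundaries <- function(alpha_e, beta_e) {
  if (alpha_e <= 0 || beta_e <= 0 || alpha_e + beta_e >= 1)
    stop("need alpha_e > 0, beta_e > 0 and alpha_e + beta_e < 1", call. = FALSE)
  c(A = log((1 - beta_e) / alpha_e), B = log(beta_e / (1 - alpha_e)))
}

# Boundaries for a config, with optional Bonferroni adjustment of alpha.
sprt_boundaries <- function(config) {
  a <- config$alpha_e
  if (config$bonferroni) a <- a / max(1L, config$n_comparisons)
  stopping_boundaries(a, config$beta_e)
}

#' Calibrate the alternative hypothesis from first-stage variance
#'
#' Solves \eqn{\theta_1 / \sqrt{\widehat{var}[c\hat\beta]} = z_t} for the
#' alternative contrast value, i.e. \eqn{\theta_1 = z_t \sqrt{\widehat{var}}}.
#' Once set, \eqn{\theta_1} is held fixed for all later scans, so the
#' activation magnitude targeted by the alternative hypothesis does not move
#' as the variance shrinks.
#'
#' @param first_stage_variance Variance estimate(s) at the end of the first
#'   stage; non-positive or non-finite entries yield `NA` (degenerate voxel).
#' @param z_threshold Calibration z-score (> 0).
#' @return `theta1`, same length as `first_stage_variance`.
#' @export
set_alternative <- function(first_stage_variance, z_threshold) {
  if (z_threshold <= 0) stop("z_threshold must be > 0", call. = FALSE)
  bad <- !is.finite(first_stage_variance) | first_stage_variance <= 0
  th <- z_threshold * sqrt(pmax(first_stage_variance, 0))
  th[bad] <- NA_real_
  th
}

#' Wald log-likelihood-ratio statistic
#'
#' Log ratio of the normal density of the current contrast estimate under
#' the alternative versus the null, conditioning on the current variance
#' estimate:
#' \deqn{\Lambda_t = \frac{(c\hat\beta_t - \theta_0)^2 -
#'   (c\hat\beta_t - \theta_1)^2}{2\,\widehat{var}[c\hat\beta_t]}.}
#' The statistic is recomputed from the current estimate and variance at
#' every scan (estimator-plug-in form), not accumulated over increments.
#' In two-sided mode the alternative is the symmetric two-point mixture
#' \eqn{\pm\theta_1}, which makes the statistic invariant to a sign flip of
#' the data.
#'
#' @param cb_hat Current contrast estimate(s).
#' @param variance Current variance estimate(s) (> 0; others yield `NA`).
#' @param theta0 Null contrast value.
#' @param theta1 Alternative contrast value(s) (`theta1 != theta0`).
#' @param sided `"one"` or `"two"`.
#' @return `lambda_t`, same length as the inputs (recycled).
#' @export
wald_statistic <- function(cb_hat, variance, theta0, theta1,
                           sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (sided == "one") {
    lam <- ((cb_hat - theta0)^2 - (cb_hat - theta1)^2) / (2 * variance)
  } else {
    lp <- ((cb_hat - theta0)^2 - (cb_hat - theta1)^2) / (2 * variance)
    lm <- ((cb_hat - theta0)^2 - (cb_hat + theta1)^2) / (2 * variance)
    m <- pmax(lp, lm)
    lam <- m + log(0.5 * (exp(lp - m) + exp(lm - m)))
  }
  bad <- !is.finite(variance) | variance <= 0 | !is.finite(theta1)
  lam[bad] <- NA_real_
  lam
}

#' Per-voxel SPRT decision state
#'
#' Tracks, for each voxel, the calibrated alternative `theta1`, the current
#' Wald statistic `lambda`, the classification `status` and the scan at
#' which a decision was reached. Status transitions are monotone
#' (`estimating` -> `undecided` -> `active`/`nonactive`) and decided states
#' are absorbing; `degenerate` marks voxels excluded from classification.
#'
#' @param n_voxels Number of voxels.
#' @return Object of class `sprt_state`: list of vectors `theta1`, `lambda`,
#'   `status` (character), `decision_scan`.
#' @export
sprt_state_init <- function(n_voxels) {
  structure(list(theta1 = rep(NA_real_, n_voxels),
                 lambda = rep(NA_real_, n_voxels),
                 status = rep("estimating", n_voxels),
                 decision_scan = rep(NA_integer_, n_voxels)),
            class = "sprt_state")
}

#' @export
print.sprt_state <- function(x, ...) {
  tab <- table(factor(x$status,
                      levels = c("estimating", "undecided", "active",
                                 "nonactive", "degenerate")))
  cat("SPRT state:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Mark first-stage completion and calibrate alternatives
#'
#' Moves voxels from `estimating` to `undecided`, sets each voxel's
#' `theta1` from its first-stage variance via [set_alternative()], and flags
#' voxels with unusable variance as `degenerate`.
#'
#' @param state An [sprt_state_init()] state.
#' @param first_stage_variance Per-voxel variance at the end of the first stage.
#' @param config An [sprt_config()].
#' @return The updated `sprt_state`.
#' @export
sprt_start_testing <- function(state, first_stage_variance, config) {
  stopifnot(inherits(state, "sprt_state"))
  th <- set_alternative(first_stage_variance, config$z_threshold)
  est <- state$status == "estimating"
  state$theta1[est] <- th[est]
  state$status[est & is.na(th)] <- "degenerate"
  state$status[est & !is.na(th)] <- "undecided"
  state
}

#' Classify voxels against the stopping boundaries
#'
#' Applies the three-way decision rule to every still-undecided voxel:
#' accept the alternative (`active`) when \eqn{\Lambda_t \ge A}, accept the
#' null (`nonactive`) when \eqn{\Lambda_t \le B}, continue otherwise.
#' Decided voxels are never revisited. At the truncation horizon
#' still-undecided voxels keep the `undecided` label by default; an optional
#' post-hoc labelling by the sign of \eqn{\Lambda} is available.
#'
#' @param state An [sprt_state_init()] state past the first stage.
#' @param lambda Per-voxel Wald statistics at this scan (`NA` entries flag
#'   degenerate voxels).
#' @param scan Current scan index (must exceed the first stage).
#' @param config An [sprt_config()].
#' @param truncation_label At `scan == max_scans`, label leftover undecided
#'   voxels by `sign(lambda)` when `TRUE` (default `FALSE`).
#' @return The updated `sprt_state`.
#' @export
sprt_classify <- function(state, lambda, scan, config, truncation_label = FALSE) {
  stopifnot(inherits(state, "sprt_state"), inherits(config, "sprt_config"))
  if (scan <= config$first_stage_scans)
    stop("no classification during the first stage", call. = FALSE)
  b <- sprt_boundaries(config)
  live <- state$status == "undecided"
  state$lambda[live] <- lambda[live]
  newly_bad <- live & !is.finite(lambda)
  state$status[newly_bad] <- "degenerate"
  live <- live & !newly_bad
  up <- live & lambda >= b["A"]
  dn <- live & lambda <= b["B"]
  state$status[up] <- "active"
  state$status[dn] <- "nonactive"
  state$decision_scan[up | dn] <- as.integer(scan)
  if (truncation_label && scan >= config$max_scans) {
    left <- state$status == "undecided"
    state$status[left & state$lambda > 0] <- "active"
    state$status[left & state$lambda <= 0] <- "nonactive"
    state$decision_scan[left] <- as.integer(scan)
  }
  state
}

#' z-score equivalent at a later scan count
#'
#' Holding the alternative effect \eqn{\theta_1} fixed, the z-score that a
#' given early-scan threshold corresponds to at a later scan count, using the
#' design-based variance proxy \eqn{c(X'X)^{-1}c'} of the truncated designs:
#' \deqn{z_{late} = z_{early}
#'   \sqrt{\frac{c(X'X)^{-1}c'\,\big|_{t_{early}}}{c(X'X)^{-1}c'\,\big|_{t_{late}}}}.}
#' Because the variance shrinks with more scans, a fixed activation magnitude
#' corresponds to an increasing z-score as the run lengthens.
#'
#' @param X_full Full design matrix (`design_matrix` or plain matrix) with at
#'   least `t_late` rows.
#' @param t_early,t_late Scan counts, `p <= t_early <= t_late`.
#' @param c A [contrast()] or numeric weight vector.
#' @param z_early z-score at `t_early`.
#' @return The equivalent z-score at `t_late`.
#' @examples
#' X <- build_design_matrix(make_paper_protocol(), design_spec())
#' rescale_z_equivalent(X, 154, 238, contrast(X, "easy"), 3.1)
#' @export
rescale_z_equivalent <- function(X_full, t_early, t_late, c, z_early) {
  Xm <- .design_mat(X_full)
  p <- ncol(Xm)
  if (t_early < p || t_early > t_late || t_late > nrow(Xm))
    stop("need p <= t_early <= t_late <= nrow(X_full)", call. = FALSE)
  v_early <- contrast_design_variance(Xm[seq_len(t_early), , drop = FALSE], c)
  v_late <- contrast_design_variance(Xm[seq_len(t_late), , drop = FALSE], c)
  z_early * sqrt(v_early / v_late)
}
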