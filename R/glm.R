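#' Incremental voxelwise GLM state
#'
#' Holds the running regression state for a set of voxels sharing one design
#' matrix: the observed signal history, the cross-product accumulators
#' \eqn{X'X} and \eqn{X'Y}, and per-voxel degeneracy flags. The state is an
#' environment so that per-scan updates are in-place; all voxels are solved
#' in one batched linear-algebra call, with results identical to per-voxel
#' solves.
#'
#' @param p Number of design columns.
#' @param n_voxels Number of voxels (columns of the signal matrix).
#' @param max_scans Number of rows to preallocate.
#' @return Object of class `glm_stream`.
#' @seealso [glm_update()], [glm_fit()], [glm_contrast_inference()]
#' @export
glm_stream_init <- function(p, n_voxels, max_scans) {
  st <- new.env(parent = emptyenv())
  st$p <- as.integer(p)
  st$n_voxels <- as.integer(n_voxels)
  st$max_scans <- as.integer(max_scans)
  st$t <- 0L
  st$X <- matrix(NA_real_, max_scans, p)
  st$Y <- matrix(NA_real_, max_scans, n_voxels)
  st$xtx <- matrix(0, p, p)
  st$xty <- matrix(0, p, n_voxels)
  st$degenerate <- rep(FALSE, n_voxels)
  class(st) <- "glm_stream"
  st
}

#' @export
print.glm_stream <- function(x, ...) {
  cat(sprintf("Incremental GLM: %d voxel(s), p = %d, %d/%d scan(s) observed\n",
              x$n_voxels, x$p, x$t, x$max_scans))
  invisible(x)
}

#' Add one scan to an incremental GLM
#'
#' Updates the accumulators with the new design row and observed signals in
#' constant work per voxel. Voxels delivering a non-finite value are flagged
#' degenerate (and their value replaced by zero) rather than raising an
#' error, so a real-time loop never halts on a corrupt voxel.
#'
#' @param state A [glm_stream_init()] state (modified in place).
#' @param design_row Numeric `p`-vector: row `t + 1` of the design.
#' @param y_new Numeric vector of length `n_voxels` (a scalar is accepted for
#'   a single-voxel stream).
#' @return The state, invisibly.
#' @export
glm_update <- function(state, design_row, y_new) {
  stopifnot(inherits(state, "glm_stream"))
  design_row <- as.numeric(design_row)
  if (length(design_row) != state$p)
    stop("design_row must have length p = ", state$p, call. = FALSE)
  y_new <- as.numeric(y_new)
  if (length(y_new) != state$n_voxels)
    stop("y_new must have length n_voxels = ", state$n_voxels, call. = FALSE)
  if (state$t >= state$max_scans)
    stop("stream already holds max_scans = ", state$max_scans, " scans", call. = FALSE)
  bad <- !is.finite(y_new)
  if (any(bad)) {
    state$degenerate[bad] <- TRUE
    y_new[bad] <- 0
  }
  i <- state$t + 1L
  state$X[i, ] <- design_row
  state$Y[i, ] <- y_new
  state$xtx <- state$xtx + tcrossprod(design_row)
  state$xty <- state$xty + design_row %o% y_new
  state$t <- i
  invisible(state)
}

#' Solve the accumulated normal equations
#'
#' Refreshes the coefficient estimates from the accumulators via a Cholesky
#' solve shared across voxels. Estimates are undefined while `t < p` or while
#' the accumulated \eqn{X'X} is numerically singular.
#'
#' @param state A [glm_stream_init()] state.
#' @return List with `beta` (`p x n_voxels`), `residuals` (`t x n_voxels`),
#'   `ok` (logical: estimates defined) and `t`.
#' @export
glm_fit <- function(state) {
  stopifnot(inherits(state, "glm_stream"))
  t <- state$t
  if (t < state$p)
    return(list(beta = NULL, residuals = NULL, ok = FALSE, t = t))
  ch <- tryCatch(chol(state$xtx), error = function(e) NULL)
  if (is.null(ch) || any(abs(diag(ch)) < sqrt(.Machine$double.eps) * max(abs(diag(ch)))))
    return(list(beta = NULL, residuals = NULL, ok = FALSE, t = t))
  beta <- backsolve(ch, forwardsolve(t(ch), state$xty))
  Xt <- state$X[seq_len(t), , drop = FALSE]
  res <- state$Y[seq_len(t), , drop = FALSE] - Xt %*% beta
  list(beta = beta, residuals = res, ok = TRUE, t = t)
}

# Resolve a matrix-or-design_matrix argument to a plain matrix.
.design_mat <- function(X) {
  if (inherits(X, "design_matrix")) X$X else as.matrix(X)
}

.contrast_vec <- function(c, p) {
  w <- if (inherits(c, "contrast")) c$weights else as.numeric(c)
  if (length(w) != p)
    stop("contrast length ", length(w), " != design columns ", p, call. = FALSE)
  w
}

#' Ordinary least-squares contrast estimate
#'
#' Computes \eqn{c \hat\beta} with \eqn{\hat\beta = (X'X)^{-1} X' y}, the
#' standard linear estimate of a contrast of regression coefficients. `y` may
#' be a matrix with one column per voxel, in which case a vector of estimates
#' is returned.
#'
#' @param X Design matrix (`design_matrix` object or plain matrix, `t x p`).
#' @param y Signal vector of length `t`, or `t x V` matrix.
#' @param c A [contrast()] or numeric `p`-vector.
#' @return Numeric scalar (vector input) or length-`V` vector.
#' @export
fit_contrast <- function(X, y, c) {
  Xm <- .design_mat(X)
  p <- ncol(Xm)
  y <- as.matrix(y)
  if (nrow(y) != nrow(Xm)) stop("length of y must match rows of X", call. = FALSE)
  if (nrow(Xm) < p) stop("need at least p = ", p, " scans to fit", call. = FALSE)
  w <- .contrast_vec(c, p)
  qx <- qr(Xm)
  if (qx$rank < p) {
    labs <- colnames(Xm)
    if (is.null(labs)) labs <- paste0("col", seq_len(p))
    dropped <- labs[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  out <- drop(crossprod(w, beta))
  if (length(out) == 1L) unname(out) else out
}

#' Design-based contrast variance factor
#'
#' Returns \eqn{c (X'X)^{-1} c'}, the design-dependent factor of the
#' contrast variance (the variance itself under unit white noise).
#'
#' @inheritParams fit_contrast
#' @return Positive scalar.
#' @export
contrast_design_variance <- function(X, c) {
  Xm <- .design_mat(X)
  w <- .contrast_vec(c, ncol(Xm))
  xtx <- crossprod(Xm)
  ch <- tryCatch(chol(xtx), error = function(e)
    stop("design matrix is rank deficient", call. = FALSE))
  v <- backsolve(ch, forwardsolve(t(ch), w))
  drop(crossprod(w, v))
}

#' Sandwich (robust) variance of a contrast estimate
#'
#' Heteroscedasticity-consistent variance of \eqn{c\hat\beta} that does not
#' assume homoscedastic or serially independent errors:
#' \deqn{c (X'X)^{-1} \left[\sum_i r_i^2 x_i x_i'\right] (X'X)^{-1} c'}
#' for `lag = 0` (HC0), with Bartlett-weighted cross-lag terms added for
#' `lag > 0` (the Newey-West form, which keeps the estimate non-negative).
#'
#' @param X Design matrix (`t x p`).
#' @param residuals Residual vector of length `t`, or `t x V` matrix from a
#'   completed fit.
#' @param c A [contrast()] or numeric `p`-vector.
#' @param lag Non-negative serial window; must be `< t`.
#' @return Non-negative scalar (or length-`V` vector).
#' @export
sandwich_variance <- function(X, residuals, c, lag = 0L) {
  Xm <- .design_mat(X)
  t <- nrow(Xm)
  res <- as.matrix(residuals)
  if (nrow(res) != t) stop("residuals must have one row per scan", call. = FALSE)
  if (lag < 0 || lag >= t)
    stop("'lag' must satisfy 0 <= lag < t", call. = FALSE)
  w <- .contrast_vec(c, ncol(Xm))
  xtx <- crossprod(Xm)
  a <- solve(xtx, w)              # (X'X)^{-1} c'
  u <- drop(Xm %*% a)             # per-scan leverage of the contrast
  g <- u * res                    # t x V
  v <- colSums(g^2)
  if (lag > 0) {
    for (l in seq_len(lag)) {
      wl <- 1 - l / (lag + 1)     # Bartlett weight
      v <- v + 2 * wl * colSums(g[seq_len(t - l), , drop = FALSE] *
                                  g[(1L + l):t, , drop = FALSE])
    }
    v <- pmax(v, 0)
  }
  if (length(v) == 1L) unname(v) else v
}

#' z-score of a contrast estimate
#'
#' @param estimate Contrast estimate(s).
#' @param variance Variance estimate(s); entries `<= 0` (degenerate voxels)
#'   yield `NA` rather than an error.
#' @return `estimate / sqrt(variance)`, `NA` where the variance is not positive.
#' @export
zscore <- function(estimate, variance) {
  bad <- !is.finite(variance) | variance <= 0
  out <- estimate / sqrt(pmax(variance, 0))
  out[bad] <- NA_real_
  out
}

#' Contrast estimates, robust variances and z-scores for a streaming GLM
#'
#' Convenience wrapper running [glm_fit()] once and evaluating each contrast's
#' estimate, sandwich variance and z-score across all voxels of the stream.
#'
#' @param state A [glm_stream_init()] state with `t >= p`.
#' @param contrasts List of [contrast()] objects (or numeric vectors).
#' @param lag Serial window for [sandwich_variance()].
#' @return Named list (one entry per contrast) of lists with `estimate`,
#'   `variance`, `z` (each length `n_voxels`); or `NULL` while estimates are
#'   undefined.
#' @export
glm_contrast_inference <- function(state, contrasts, lag = 0L) {
  fit <- glm_fit(state)
  if (!fit$ok) return(NULL)
  Xt <- state$X[seq_len(fit$t), , drop = FALSE]
  out <- lapply(contrasts, function(cc) {
    w <- .contrast_vec(cc, state$p)
    est <- drop(crossprod(w, fit$beta))
    v <- sandwich_variance(Xt, fit$residuals, w, lag = lag)
    v[state$degenerate] <- NA_real_
    list(estimate = est, variance = v, z = zscore(est, v))
  })
  names(out) <- vapply(contrasts, function(cc)
    if (inherits(cc, "contrast")) cc$label else "contrast", character(1))
  out
}
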