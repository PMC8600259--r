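#' Double-gamma hemodynamic response function parameters
#'
#' The canonical HRF is a difference of two gamma densities: a positive
#' response peaking around 5 s and a slower negative undershoot. Delays and
#' dispersions are in seconds; with dispersion 1 the gamma shape equals the
#' delay parameter, giving a mode at `peak_delay - peak_disp`.
#'
#' @param peak_delay Delay of the positive response (s); default 6.
#' @param undershoot_delay Delay of the undershoot (s); default 16.
#' @param peak_disp,undershoot_disp Dispersions (s); default 1.
#' @param ratio Undershoot amplitude relative to the peak; default 1/6.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1, ratio = 1 / 6) {
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio),
            class = "hrf_params")
}

#' Sample a double-gamma hemodynamic response kernel
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param length Kernel duration in seconds (> 0); should cover the
#'   undershoot (around 30 s) for block convolution.
#' @param params An [hrf_params()] object.
#' @return Numeric vector sampled at `0, dt, 2*dt, ...`, normalised so the
#'   peak value is 1. The kernel is 0 at time 0, rises to a single positive
#'   peak and (for `ratio > 0`) is followed by a negative undershoot.
#' @examples
#' k <- double_gamma_hrf(0.1, 32)
#' (which.max(k) - 1) * 0.1  # mode near 5 s for the canonical parameters
#' @export
double_gamma_hrf <- function(dt, length = 32, params = hrf_params()) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive sampling interval", call. = FALSE)
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length <= 0)
    stop("'length' must be a positive duration", call. = FALSE)
  tt <- seq(0, length, by = dt)
  h <- stats::dgamma(tt, shape = params$peak_delay / params$peak_disp,
                     scale = params$peak_disp) -
    params$ratio * stats::dgamma(tt, shape = params$undershoot_delay / params$undershoot_disp,
                                 scale = params$undershoot_disp)
  h / max(h)
}

#' GLM design specification
#'
#' Describes how the voxelwise design matrix is assembled from a protocol:
#' an intercept, one HRF-convolved regressor per condition, and `n_drift`
#' slow cosine drift regressors whose periods are derived from a reference
#' duration `T` as `2T/j` for column `j` (i.e. `2T, T, T/1.5, T/2, T/2.5`
#' for the first five). By default `T` is the full run duration.
#'
#' @param hrf An [hrf_params()] object.
#' @param n_drift Number of cosine drift regressors (default 5).
#' @param drift_ref_duration Reference duration `T` in seconds; `NULL` means
#'   the protocol's full duration `max_scans * tr`.
#' @param include_intercept Include a column of ones (default `TRUE`).
#' @param drift_phase `"midpoint"` (DCT-II convention, `cos(pi j (i-1/2)/N)`)
#'   or `"zero"` (`cos(pi j (i-1)/N)`, so every column is 1 at the first scan).
#' @param dt Convolution grid resolution in seconds (default 0.1).
#' @param hrf_length Kernel duration in seconds passed to [double_gamma_hrf()].
#' @param extra_regressors Optional matrix of user-supplied columns
#'   (`max_scans` rows), appended after the drift set.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(hrf = hrf_params(), n_drift = 5,
                        drift_ref_duration = NULL, include_intercept = TRUE,
                        drift_phase = c("midpoint", "zero"),
                        dt = 0.1, hrf_length = 32, extra_regressors = NULL) {
  if (n_drift < 0) stop("'n_drift' must be >= 0", call. = FALSE)
  structure(list(hrf = hrf, n_drift = as.integer(n_drift),
                 drift_ref_duration = drift_ref_duration,
                 include_intercept = isTRUE(include_intercept),
                 drift_phase = match.arg(drift_phase),
                 dt = dt, hrf_length = hrf_length,
                 extra_regressors = extra_regressors),
            class = "design_spec")
}

#' Cosine drift regressors
#'
#' Column `j` is a cosine of period `2T/j` evaluated on the scan-time grid,
#' the standard discrete-cosine low-frequency basis used to absorb scanner
#' drift, physiology and other slow fluctuations. The first five periods are
#' `2T, T, T/1.5, T/2, T/2.5`.
#'
#' @param T_ref Reference duration `T` in seconds (> 0).
#' @param tr Repetition time in seconds.
#' @param t Number of scans (rows) to return.
#' @param k Number of drift columns. Values above 5 extend the same `2T/j`
#'   period rule and require `extend = TRUE`.
#' @param phase `"midpoint"` or `"zero"`; see [design_spec()].
#' @param extend Allow `k > 5`.
#' @return A `t x k` matrix with values in `[-1, 1]`.
#' @export
cosine_drift_regressors <- function(T_ref, tr, t, k,
                                    phase = c("midpoint", "zero"),
                                    extend = FALSE) {
  phase <- match.arg(phase)
  if (!is.numeric(T_ref) || T_ref <= 0) stop("'T_ref' must be > 0", call. = FALSE)
  if (k > 5 && !extend)
    stop("k > 5 drift regressors requires extend = TRUE (period rule 2T/j)",
         call. = FALSE)
  if (k == 0L) return(matrix(numeric(0), nrow = t, ncol = 0))
  n_ref <- T_ref / tr                      # reference duration in scans
  i <- seq_len(t)
  frac <- if (phase == "midpoint") (i - 0.5) / n_ref else (i - 1) / n_ref
  out <- vapply(seq_len(k), function(j) cos(pi * j * frac), numeric(t))
  colnames(out) <- paste0("drift_", seq_len(k))
  out
}

#' Drift periods implied by a reference duration
#'
#' @param T_ref Reference duration in seconds.
#' @param k Number of drift regressors.
#' @return Numeric vector of periods `2*T_ref/j`, `j = 1..k`, in seconds.
#' @export
drift_periods <- function(T_ref, k = 5) 2 * T_ref / seq_len(k)

# HRF-convolved condition regressors for the full run, one column per
# condition, sampled at scan acquisition times (i-1)*tr and normalised to
# unit peak over the full run (so truncation never changes earlier rows).
condition_regressors <- function(protocol, spec) {
  dt <- spec$dt
  run_dur <- protocol$max_scans * protocol$tr
  tgrid <- seq(0, run_dur, by = dt)
  kern <- double_gamma_hrf(dt, spec$hrf_length, spec$hrf)
  scan_times <- (seq_len(protocol$max_scans) - 1) * protocol$tr
  idx <- round(scan_times / dt) + 1L
  out <- vapply(protocol$conditions, function(cn) {
    box <- numeric(length(tgrid))
    for (o in cn$onsets)
      box[tgrid >= o - 1e-9 & tgrid < o + cn$duration - 1e-9] <- 1
    resp <- stats::convolve(box, rev(kern), type = "open")[seq_along(tgrid)] * dt
    resp <- resp[idx]
    pk <- max(abs(resp))
    if (pk > 0) resp / pk else resp
  }, numeric(protocol$max_scans))
  colnames(out) <- names(protocol$conditions)
  out
}

#' Build the streaming GLM design matrix
#'
#' Assembles the first `t` rows of the design matrix implied by a protocol
#' and design spec: intercept, HRF-convolved condition regressors (unit peak
#' over the full run), and cosine drift regressors. Row `i` depends only on
#' protocol timing, never on data, so the `t`-row build is always the prefix
#' of the `max_scans`-row build and the matrix can be grown row-by-row as
#' volumes arrive.
#'
#' @param protocol A [stimulus_protocol()].
#' @param spec A [design_spec()].
#' @param t Number of scans; between 1 and `protocol$max_scans`.
#' @return An object of class `design_matrix`: list with the `t x p` matrix
#'   `X`, `column_labels`, `t`, `p` and the protocol's `tr`.
#' @examples
#' X <- build_design_matrix(make_paper_protocol(), design_spec())
#' X$p  # 8 columns: intercept + easy + hard + 5 drifts
#' @export
build_design_matrix <- function(protocol, spec = design_spec(),
                                t = protocol$max_scans) {
  stopifnot(inherits(protocol, "stimulus_protocol"), inherits(spec, "design_spec"))
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > protocol$max_scans ||
      t != round(t))
    stop("'t' must be an integer in 1..max_scans", call. = FALSE)
  t <- as.integer(t)

  cond <- condition_regressors(protocol, spec)[seq_len(t), , drop = FALSE]
  T_ref <- if (is.null(spec$drift_ref_duration))
    protocol$max_scans * protocol$tr else spec$drift_ref_duration
  drift <- cosine_drift_regressors(T_ref, protocol$tr, t, spec$n_drift,
                                   phase = spec$drift_phase)
  parts <- list()
  labels <- character(0)
  if (spec$include_intercept) {
    parts <- c(parts, list(intercept = rep(1, t)))
    labels <- "intercept"
  }
  parts <- c(parts, list(cond), list(drift))
  labels <- c(labels, colnames(cond), colnames(drift))
  if (!is.null(spec$extra_regressors)) {
    ex <- as.matrix(spec$extra_regressors)
    if (nrow(ex) < t)
      stop("'extra_regressors' must have at least t rows", call. = FALSE)
    ex <- ex[seq_len(t), , drop = FALSE]
    if (is.null(colnames(ex))) colnames(ex) <- paste0("extra_", seq_len(ncol(ex)))
    parts <- c(parts, list(ex))
    labels <- c(labels, colnames(ex))
  }
  X <- do.call(cbind, parts)
  colnames(X) <- labels
  if (any(!is.finite(X))) stop("design matrix has non-finite entries", call. = FALSE)
  structure(list(X = X, column_labels = labels, t = t, p = ncol(X),
                 tr = protocol$tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d scans x %d columns (TR %.3g s)\n  %s\n",
              x$t, x$p, x$tr, paste(x$column_labels, collapse = ", ")))
  invisible(x)
}

#' Contrast vector over design columns
#'
#' @param design A `design_matrix` (or an integer column count `p`).
#' @param weights Either a full numeric `p`-vector, or a named numeric vector
#'   whose names are design column labels (all other weights 0), or a single
#'   column label (weight 1 on that column).
#' @param label Optional text label.
#' @return Object of class `contrast`: numeric weight vector with a label.
#' @examples
#' X <- build_design_matrix(make_paper_protocol(), design_spec())
#' contrast(X, "easy")
#' @export
contrast <- function(design, weights, label = NULL) {
  if (inherits(design, "design_matrix")) {
    p <- design$p; labs <- design$column_labels
  } else {
    p <- as.integer(design); labs <- NULL
  }
  if (is.character(weights)) {
    stopifnot(!is.null(labs))
    w <- stats::setNames(rep(0, p), labs)
    if (!all(weights %in% labs))
      stop("unknown design column(s): ",
           paste(setdiff(weights, labs), collapse = ", "), call. = FALSE)
    w[weights] <- 1
    if (is.null(label)) label <- paste(weights, collapse = "+")
  } else if (!is.null(names(weights)) && !is.null(labs) &&
             all(names(weights) %in% labs)) {
    w <- stats::setNames(rep(0, p), labs)
    w[names(weights)] <- weights
    if (is.null(label)) label <- paste(names(weights), collapse = ",")
  } else {
    w <- as.numeric(weights)
    if (length(w) != p)
      stop("contrast length ", length(w), " != design columns ", p, call. = FALSE)
    if (is.null(label)) label <- "contrast"
  }
  if (all(w == 0)) stop("contrast must have a nonzero weight", call. = FALSE)
  structure(list(weights = unname(w), label = label), class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("Contrast '%s': [%s]\n", x$label,
              paste(format(x$weights), collapse = " ")))
  invisible(x)
}
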