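#' Simulation configuration
#'
#' Describes a synthetic block-design BOLD run with known ground truth.
#' Activation amplitudes are most conveniently given on the z scale at full
#' duration (`effect_z`): the raw contrast effect is then derived through the
#' design-based variance factor \eqn{c(X'X)^{-1}c'} and the marginal noise
#' standard deviation, so the same nominal effect size transfers across
#' protocols. Noise is AR(1) Gaussian; low-frequency drift is a random
#' combination of slow cosines deliberately not identical to the analysis
#' drift regressors.
#'
#' @param grid_shape Integer 3-vector of voxel dimensions.
#' @param active_fraction Fraction of voxels truly active per condition, in
#'   `[0, 1]`.
#' @param effect_z Activation amplitude as the target z-score at full run
#'   duration (ignored when `effect_beta` is given).
#' @param effect_beta Optional raw contrast effect in signal units.
#' @param noise_sd Standard deviation of the AR(1) Gaussian innovations.
#' @param ar1_phi Lag-1 autocorrelation of the noise, in `[0, 0.95]`.
#' @param drift_amplitude Scale of the simulated low-frequency drift
#'   (0 disables drift).
#' @param drift_components Number of random slow cosines per voxel.
#' @param drift_period_range Period range (s) the drift cosines are drawn from.
#' @param spatial_fwhm Optional FWHM (in voxels) of Gaussian smoothing applied
#'   to the noise field to emulate spatial smoothness (0 = none, the default).
#' @param seed RNG seed; identical config and seed give bit-identical runs.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(20, 20, 10), active_fraction = 0.25,
                              effect_z = 6, effect_beta = NULL,
                              noise_sd = 1, ar1_phi = 0.3,
                              drift_amplitude = 1, drift_components = 3,
                              drift_period_range = c(150, 1200),
                              spatial_fwhm = 0, seed = 1L) {
  if (active_fraction < 0 || active_fraction > 1)
    stop("'active_fraction' must lie in [0, 1]", call. = FALSE)
  if (ar1_phi < 0 || ar1_phi > 0.95)
    stop("'ar1_phi' must lie in [0, 0.95]", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  structure(list(grid_shape = as.integer(grid_shape),
                 active_fraction = active_fraction,
                 effect_z = effect_z, effect_beta = effect_beta,
                 noise_sd = noise_sd, ar1_phi = ar1_phi,
                 drift_amplitude = drift_amplitude,
                 drift_components = as.integer(drift_components),
                 drift_period_range = drift_period_range,
                 spatial_fwhm = spatial_fwhm, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Serially correlated Gaussian noise
#'
#' Stationary AR(1) series: `x[t] = phi * x[t-1] + e[t]` with Gaussian
#' innovations of standard deviation `sd` and a stationary initial state, so
#' the marginal standard deviation is `sd / sqrt(1 - phi^2)`.
#'
#' @param n_scans Series length.
#' @param n_voxels Number of independent series (columns).
#' @param phi Lag-1 autocorrelation.
#' @param sd Innovation standard deviation.
#' @return `n_scans x n_voxels` matrix.
#' @export
ar1_noise <- function(n_scans, n_voxels = 1L, phi = 0, sd = 1) {
  e <- matrix(stats::rnorm(n_scans * n_voxels, sd = sd), n_scans, n_voxels)
  if (phi != 0) {
    e[1L, ] <- stats::rnorm(n_voxels, sd = sd / sqrt(1 - phi^2))
    for (s in 2:n_scans) e[s, ] <- phi * e[s - 1L, ] + e[s, ]
  }
  e
}

#' Simulate a block-design BOLD run with known ground truth
#'
#' Each voxel's series is `X beta_true + drift + AR(1) noise`, where the
#' task part of `X` is the HRF-convolved block design of the protocol.
#' Active voxels (an independent random subset per condition) carry the
#' configured contrast effect; inactive voxels carry zero.
#'
#' @param config A [simulation_config()].
#' @param protocol A [stimulus_protocol()].
#' @param spec A [design_spec()] (used both to generate the task signal and,
#'   typically, later to analyse it).
#' @return Object of class `sim_run`: list with `series` (4D array, grid x
#'   scans), `truth` (per-condition logical activation maps `active`, true
#'   effect `theta` per condition, `beta` matrix voxels x conditions, noise
#'   parameters), and the generating `config`/`protocol`.
#' @export
simulate_run <- function(config, protocol, spec = design_spec()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(protocol, "stimulus_protocol"))
  set.seed(config$seed)
  grid <- config$grid_shape
  V <- prod(grid)
  n_scans <- protocol$max_scans
  conds <- names(protocol$conditions)

  dm <- build_design_matrix(protocol, spec, n_scans)
  # per-condition raw effect size
  theta <- vapply(conds, function(lab) {
    if (!is.null(config$effect_beta)) return(config$effect_beta)
    cvc <- contrast_design_variance(dm, contrast(dm, lab))
    sigma_marg2 <- if (config$ar1_phi < 1)
      config$noise_sd^2 / (1 - config$ar1_phi^2) else config$noise_sd^2
    config$effect_z * sqrt(sigma_marg2 * cvc)
  }, numeric(1))

  active <- lapply(conds, function(lab) {
    m <- rep(FALSE, V)
    n_act <- round(config$active_fraction * V)
    if (n_act > 0) m[sample.int(V, n_act)] <- TRUE
    array(m, dim = grid)
  })
  names(active) <- conds

  beta <- vapply(conds, function(lab) as.numeric(active[[lab]]) * theta[[lab]],
                 numeric(V))                       # V x n_cond
  cond_cols <- dm$X[, conds, drop = FALSE]         # n_scans x n_cond
  signal <- cond_cols %*% t(beta)                  # n_scans x V

  if (config$drift_amplitude > 0 && config$drift_components > 0) {
    st <- (seq_len(n_scans) - 1) * protocol$tr
    for (k in seq_len(config$drift_components)) {
      per <- stats::runif(V, config$drift_period_range[1], config$drift_period_range[2])
      ph <- stats::runif(V, 0, 2 * pi)
      amp <- config$drift_amplitude * stats::runif(V, 0.25, 1)
      signal <- signal +
        cos(outer(st, 2 * pi / per) + rep(ph, each = n_scans)) *
        rep(amp, each = n_scans)
    }
  }

  noise <- ar1_noise(n_scans, V, config$ar1_phi, config$noise_sd)
  if (config$spatial_fwhm > 0) {
    for (s in seq_len(n_scans)) {
      vol <- array(noise[s, ], dim = grid)
      noise[s, ] <- as.numeric(gaussian_smooth_3d(vol, config$spatial_fwhm,
                                                  voxel_mm = c(1, 1, 1)))
    }
  }
  Y <- signal + noise
  series <- array(t(Y), dim = c(grid, n_scans))
  structure(list(series = series,
                 truth = list(active = active, theta = theta, beta = beta,
                              noise = list(sd = config$noise_sd,
                                           phi = config$ar1_phi)),
                 config = config, protocol = protocol),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  g <- x$config$grid_shape
  cat(sprintf("Simulated run: %dx%dx%d grid, %d scans\n", g[1], g[2], g[3],
              dim(x$series)[4]))
  for (lab in names(x$truth$active))
    cat(sprintf("  %s: %d active voxel(s), effect %.4g\n", lab,
                sum(x$truth$active[[lab]]), x$truth$theta[[lab]]))
  invisible(x)
}

#' Replay a simulated series as NIfTI volumes on disk
#'
#' Writes one 3D NIfTI file per scan, named with a zero-padded scan index so
#' lexicographic order equals scan order, plus a JSON manifest recording the
#' write times. This emulates a scanner dumping freshly reconstructed volumes
#' into a watched folder.
#'
#' @param series 4D array (or a `sim_run`).
#' @param out_dir Writable output directory (created if needed).
#' @param cadence Seconds to wait between volumes; 0 writes as fast as
#'   possible.
#' @param prefix File-name prefix (default `"vol"`).
#' @return Character vector of volume paths, invisibly.
#' @export
stream_volumes <- function(series, out_dir, cadence = 0, prefix = "vol") {
  if (inherits(series, "sim_run")) series <- series$series
  stopifnot(length(dim(series)) == 4L)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  n <- dim(series)[4L]
  paths <- character(n)
  manifest <- vector("list", n)
  t0 <- Sys.time()
  for (s in seq_len(n)) {
    if (cadence > 0 && s > 1L) Sys.sleep(cadence)
    f <- file.path(out_dir, sprintf("%s_%04d.nii", prefix, s))
    RNifti::writeNifti(RNifti::asNifti(series[, , , s, drop = TRUE]), f)
    paths[s] <- f
    manifest[[s]] <- list(scan = s, file = basename(f),
                          elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
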