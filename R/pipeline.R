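#' Separable 3D Gaussian smoothing
#'
#' In-package spatial smoothing used in place of an external neuroimaging
#' toolbox. The kernel is separable, truncated at 4 standard deviations and
#' edge-renormalised, so constant images are preserved exactly.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm Full width at half maximum in millimetres (0 = identity).
#' @param voxel_mm Voxel size, scalar or length-3 (mm).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_mm = c(3, 3, 3)) {
  stopifnot(length(dim(vol)) == 3L)
  if (fwhm_mm <= 0) return(vol)
  voxel_mm <- rep_len(voxel_mm, 3L)
  dims <- dim(vol)
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm[ax]
    if (sigma <= 0) next
    n <- dims[ax]
    r <- min(n - 1L, max(1L, ceiling(4 * sigma)))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    # banded convolution matrix, rows renormalised at the edges
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      K[i, j] <- k[j - i + r + 1L]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(vol, perm), nrow = n)
    vol <- aperm(array(K %*% m, dims[perm]), order(perm))
  }
  vol
}

# Read a 3D volume from disk or pass an array through.
.read_volume <- function(x) {
  if (is.character(x)) {
    v <- RNifti::readNifti(x)
    arr <- as.array(v)
    if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
      arr <- arr[, , , 1L, drop = TRUE]
    arr
  } else {
    as.array(x)
  }
}

#' Ingest one volume: smooth, mask, flatten
#'
#' Applies optional Gaussian smoothing and the brain mask, returning one
#' value per in-mask voxel in the fixed (column-major) voxel ordering used
#' throughout a run.
#'
#' @param volume 3D array or NIfTI file path.
#' @param mask 3D logical array (or numeric, nonzero = in mask).
#' @param fwhm Smoothing FWHM in mm (0 = off).
#' @param voxel_mm Voxel size in mm.
#' @param smooth_before_mask Smooth the full volume before masking (default)
#'   or mask first (edge effects differ).
#' @return Numeric vector of length `sum(mask)`.
#' @export
ingest_volume <- function(volume, mask, fwhm = 0, voxel_mm = c(3, 3, 3),
                          smooth_before_mask = TRUE) {
  vol <- .read_volume(volume)
  mask <- as.array(mask) != 0
  if (!identical(dim(vol), dim(mask)))
    stop("volume grid ", paste(dim(vol), collapse = "x"),
         " does not match mask grid ", paste(dim(mask), collapse = "x"),
         call. = FALSE)
  if (fwhm > 0) {
    if (!smooth_before_mask) vol[!mask] <- 0
    vol <- gaussian_smooth_3d(vol, fwhm, voxel_mm)
  }
  as.numeric(vol[mask])
}

#' Real-time run configuration
#'
#' Bundles everything [run_realtime()] needs: the input volumes, mask,
#' protocol, design and SPRT settings, the global stop threshold and
#' preprocessing options.
#'
#' @param input A 4D array (grid x scans), a character vector of 3D NIfTI
#'   paths in scan order, or a directory containing them (sorted by name).
#' @param mask 3D logical array or NIfTI path; `NULL` means every voxel.
#' @param protocol A [stimulus_protocol()].
#' @param spec A [design_spec()].
#' @param sprt An [sprt_config()].
#' @param threshold Global percent-classified stop threshold in `(0, 1]`
#'   (default 0.8).
#' @param contrasts Named list of [contrast()] weights, one per condition to
#'   monitor; `NULL` builds the condition-vs-rest contrast for every protocol
#'   condition.
#' @param fwhm Smoothing FWHM in mm (default 0; typical subject analyses use
#'   8 mm).
#' @param voxel_mm Voxel size in mm.
#' @param lag Serial window of the sandwich variance (0 = HC0, the default).
#' @param out_dir Optional output directory for maps, stop sentinels, the
#'   per-scan trace and the run report.
#' @param eval_interval Evaluate the global rule every this many scans after
#'   the first stage (default 1 = every scan).
#' @param truncation_label Label leftover undecided voxels by the sign of
#'   their statistic at truncation (default `FALSE`).
#' @param smooth_before_mask See [ingest_volume()].
#' @param verbose Log one line per scan to stdout.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, mask = NULL, protocol, spec = design_spec(),
                       sprt = sprt_config(max_scans = protocol$max_scans),
                       threshold = 0.8, contrasts = NULL, fwhm = 0,
                       voxel_mm = c(3, 3, 3), lag = 0L, out_dir = NULL,
                       eval_interval = 1L, truncation_label = FALSE,
                       smooth_before_mask = TRUE, verbose = FALSE) {
  stopifnot(inherits(protocol, "stimulus_protocol"), inherits(spec, "design_spec"),
            inherits(sprt, "sprt_config"))
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  if (is.character(input)) {
    if (length(input) == 1L && dir.exists(input))
      input <- sort(list.files(input, pattern = "\\.nii(\\.gz)?$",
                               full.names = TRUE))
    missing <- input[!file.exists(input)]
    if (length(missing))
      stop("input volume(s) not found: ", paste(utils::head(missing, 3),
                                                collapse = ", "), call. = FALSE)
  }
  if (is.character(mask) && !file.exists(mask))
    stop("mask file not found: ", mask, call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  structure(list(input = input, mask = mask, protocol = protocol, spec = spec,
                 sprt = sprt, threshold = threshold, contrasts = contrasts,
                 fwhm = fwhm, voxel_mm = voxel_mm, lag = as.integer(lag),
                 out_dir = out_dir, eval_interval = as.integer(eval_interval),
                 truncation_label = isTRUE(truncation_label),
                 smooth_before_mask = isTRUE(smooth_before_mask),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the real-time early-stopping loop
#'
#' For every arriving scan the incremental GLM of each in-mask voxel is
#' updated. Once the first stage completes, each voxel's sandwich variance
#' calibrates its alternative hypothesis; thereafter the Wald statistic is
#' computed and voxels are classified against the stopping boundaries, the
#' global percent-classified rule is evaluated per condition, and stop
#' signals are emitted. Replaying identical inputs yields an identical
#' report.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: per-condition stop scans, the
#'   per-scan trace (classified fractions, status counts, wall time), final
#'   voxel states and maps-in-vector-form, and bookkeeping needed by
#'   [write_maps()].
#' @export
run_realtime <- function(config) {
  stopifnot(inherits(config, "run_config"))
  protocol <- config$protocol
  sprtc <- config$sprt
  n_max <- protocol$max_scans

  get_volume <- if (is.character(config$input)) {
    paths <- config$input
    function(s) if (s <= length(paths)) paths[s] else NULL
  } else {
    series <- config$input
    stopifnot(length(dim(series)) == 4L)
    function(s) if (s <= dim(series)[4L]) series[, , , s, drop = TRUE] else NULL
  }
  probe <- .read_volume(get_volume(1L))
  mask <- if (is.null(config$mask)) array(TRUE, dim(probe))
          else .read_volume(config$mask) != 0
  mask_idx <- which(mask)
  n_vox <- length(mask_idx)
  if (n_vox == 0L) stop("empty mask", call. = FALSE)

  dm <- build_design_matrix(protocol, config$spec, n_max)
  contrasts <- config$contrasts
  if (is.null(contrasts))
    contrasts <- lapply(names(protocol$conditions), function(lab)
      contrast(dm, lab))
  names(contrasts) <- vapply(contrasts, function(x) x$label, character(1))
  conds <- names(contrasts)

  stream <- glm_stream_init(dm$p, n_vox, n_max)
  states <- lapply(conds, function(x) sprt_state_init(n_vox))
  names(states) <- conds
  stopped <- stats::setNames(rep(FALSE, length(conds)), conds)
  stop_scan <- stats::setNames(rep(NA_integer_, length(conds)), conds)
  calibrated <- FALSE
  trace <- list()
  last_scan <- 0L
  inf <- NULL

  for (s in seq_len(n_max)) {
    tic <- Sys.time()
    vol <- get_volume(s)
    if (is.null(vol)) break
    y <- tryCatch(
      ingest_volume(vol, mask, fwhm = config$fwhm, voxel_mm = config$voxel_mm,
                    smooth_before_mask = config$smooth_before_mask),
      error = function(e) e)
    if (inherits(y, "error")) {
      if (grepl("does not match mask grid", conditionMessage(y)))
        stop(y)  # fatal configuration error
      warning("scan ", s, " skipped: ", conditionMessage(y), call. = FALSE)
      next
    }
    glm_update(stream, dm$X[s, ], y)
    last_scan <- s

    if (s < sprtc$first_stage_scans) next
    inf <- glm_contrast_inference(stream, contrasts, lag = config$lag)
    if (is.null(inf)) next

    if (!calibrated) {  # first usable inference at/after first-stage end
      for (lab in conds)
        states[[lab]] <- sprt_start_testing(states[[lab]],
                                            inf[[lab]]$variance, sprtc)
      calibrated <- TRUE
      next  # decisions start strictly after the first stage
    }

    for (lab in conds) {
      if (stopped[[lab]]) next
      lam <- wald_statistic(inf[[lab]]$estimate, inf[[lab]]$variance,
                            sprtc$theta0, states[[lab]]$theta1,
                            sided = sprtc$sided)
      states[[lab]] <- sprt_classify(states[[lab]], lam, s, sprtc,
                                     truncation_label = config$truncation_label)
      frac <- classified_fraction(states[[lab]])
      counts <- table(factor(states[[lab]]$status,
                             levels = c("active", "nonactive", "undecided",
                                        "degenerate")))
      evaluate <- (s - sprtc$first_stage_scans) %% config$eval_interval == 0L ||
        s == n_max
      if (evaluate) {
        dec <- global_stop_decision(frac, s, sprtc, config$threshold, lab)
        if (dec$stop) {
          stopped[[lab]] <- TRUE
          stop_scan[[lab]] <- s
          if (!is.null(config$out_dir)) write_stop_signal(dec, config$out_dir)
          if (config$verbose)
            cat(sprintf("scan %d: STOP %s (%.1f%% classified)\n", s, lab,
                        100 * frac))
        }
      }
      trace[[length(trace) + 1L]] <- data.frame(
        scan = s, condition = lab, fraction = frac,
        n_active = as.integer(counts[["active"]]),
        n_nonactive = as.integer(counts[["nonactive"]]),
        n_undecided = as.integer(counts[["undecided"]]),
        n_degenerate = as.integer(counts[["degenerate"]]),
        stopped = stopped[[lab]],
        elapsed_s = as.numeric(difftime(Sys.time(), tic, units = "secs")))
    }
    if (config$verbose && s %% 10L == 0L)
      cat(sprintf("scan %d: %s\n", s,
                  paste(sprintf("%s %.1f%%", conds,
                                100 * vapply(conds, function(l)
                                  classified_fraction(states[[l]]), numeric(1))),
                        collapse = ", ")))
    route <- condition_router(stopped, s, n_max)
    if (route$run_ended) break
  }

  first_stage_incomplete <- last_scan < sprtc$first_stage_scans || !calibrated
  final <- list()
  if (!first_stage_incomplete && !is.null(inf)) {
    for (lab in conds) {
      lam <- wald_statistic(inf[[lab]]$estimate, inf[[lab]]$variance,
                            sprtc$theta0, states[[lab]]$theta1,
                            sided = sprtc$sided)
      final[[lab]] <- list(z = inf[[lab]]$z, lambda = lam,
                           theta1 = states[[lab]]$theta1,
                           estimate = inf[[lab]]$estimate,
                           variance = inf[[lab]]$variance)
    }
  }

  report <- structure(list(
    stop_scan = stop_scan, stopped = stopped,
    last_scan = last_scan,
    first_stage_incomplete = first_stage_incomplete,
    trace = if (length(trace)) do.call(rbind, trace) else NULL,
    states = if (first_stage_incomplete) NULL else states,
    final = final,
    boundaries = sprt_boundaries(sprtc),
    threshold = config$threshold,
    mask_dim = dim(mask), mask_idx = mask_idx,
    n_voxels = n_vox, conditions = conds,
    sprt = sprtc), class = "run_report")

  if (!is.null(config$out_dir)) {
    if (!is.null(report$trace))
      utils::write.csv(report$trace,
                       file.path(config$out_dir, "trace.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(stop_scan = as.list(stop_scan), stopped = as.list(stopped),
           first_stage_incomplete = first_stage_incomplete,
           threshold = config$threshold, n_voxels = n_vox,
           last_scan = last_scan),
      file.path(config$out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    if (!first_stage_incomplete) write_maps(report, config$out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Real-time SPRT run report\n")
  if (x$first_stage_incomplete) {
    cat(sprintf("  FIRST STAGE INCOMPLETE: stream ended at scan %d (< %d)\n",
                x$last_scan, x$sprt$first_stage_scans))
    return(invisible(x))
  }
  for (lab in x$conditions) {
    sc <- x$stop_scan[[lab]]
    tr <- x$trace[x$trace$condition == lab, , drop = FALSE]
    fin <- tr[nrow(tr), ]
    cat(sprintf("  %s: stop %s | %.1f%% classified (%d active, %d nonactive, %d undecided, %d degenerate)\n",
                lab, if (is.na(sc)) "not reached" else paste("at scan", sc),
                100 * fin$fraction, fin$n_active, fin$n_nonactive,
                fin$n_undecided, fin$n_degenerate))
  }
  invisible(x)
}

# status -> label-map code
.status_code <- c(nonactive = 0, active = 1, undecided = 2, estimating = 2,
                  degenerate = 3)

#' Write classification and statistic maps as NIfTI
#'
#' For every monitored condition writes four volumes aligned to the input
#' grid: a label map (0 nonactive, 1 active, 2 undecided, 3 degenerate),
#' a z map, a Wald-statistic map and a theta1 map. Out-of-mask voxels are 0
#' in the label map and NA elsewhere.
#'
#' @param report A [run_realtime()] report with a completed first stage.
#' @param out_dir Output directory.
#' @param reference Optional NIfTI image (or path) supplying header/affine.
#' @return Named character vector of file paths, invisibly.
#' @export
write_maps <- function(report, out_dir, reference = NULL) {
  stopifnot(inherits(report, "run_report"))
  if (report$first_stage_incomplete)
    stop("first stage incomplete: no maps to write", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(reference)) reference <- RNifti::readNifti(reference)
  paths <- character(0)
  to_map <- function(values, fill) {
    arr <- array(fill, report$mask_dim)
    arr[report$mask_idx] <- values
    arr
  }
  wr <- function(arr, name) {
    f <- file.path(out_dir, paste0(name, ".nii"))
    img <- if (is.null(reference)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = reference)
    RNifti::writeNifti(img, f)
    stats::setNames(f, name)
  }
  for (lab in report$conditions) {
    st <- report$states[[lab]]
    fin <- report$final[[lab]]
    paths <- c(paths,
               wr(to_map(unname(.status_code[st$status]), 0), paste0(lab, "_label")),
               wr(to_map(fin$z, NA_real_), paste0(lab, "_z")),
               wr(to_map(fin$lambda, NA_real_), paste0(lab, "_lambda")),
               wr(to_map(fin$theta1, NA_real_), paste0(lab, "_theta1")))
  }
  invisible(paths)
}

#' Overlap between two activation label maps
#'
#' Compares the active voxels of a map (e.g. from an early-stopped run)
#' against a reference map (e.g. full duration): voxels in common, voxels
#' unique to each, and the percentage in common relative to the reference
#' map's active count.
#'
#' @param mapA,mapB 3D arrays or NIfTI paths; `mapB` is the reference.
#' @param active_value Label value coding "active" (default 1).
#' @return List with `common`, `unique_a`, `unique_b`, `n_active_a`,
#'   `n_active_b` and `pct_common` (percent of `mapB`'s actives also active
#'   in `mapA`).
#' @export
overlap_metrics <- function(mapA, mapB, active_value = 1) {
  a <- .read_volume(mapA); b <- .read_volume(mapB)
  if (!identical(dim(a), dim(b)))
    stop("label maps are on different grids", call. = FALSE)
  aa <- a == active_value; bb <- b == active_value
  common <- sum(aa & bb)
  n_b <- sum(bb)
  list(common = common,
       unique_a = sum(aa & !bb), unique_b = sum(bb & !aa),
       n_active_a = sum(aa), n_active_b = n_b,
       pct_common = if (n_b > 0) 100 * common / n_b else NA_real_)
}
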