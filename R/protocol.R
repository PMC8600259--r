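#' Block-design stimulus protocol
#'
#' A stimulus protocol is the experiment's clock: it records when each task
#' block of each condition is presented, on a scan (TR) grid with a hard
#' truncation horizon `max_scans`. Blocks are sustained task periods (e.g.
#' 36 s of arithmetic problems) separated by rest; the protocol stores task
#' onsets and durations in seconds from the start of the run.
#'
#' @param tr Repetition time in seconds (time between successive volumes).
#' @param conditions Named list, one entry per condition, each a list with
#'   `onsets` (numeric vector, seconds from run start, strictly increasing)
#'   and `duration` (scalar task-block duration in seconds).
#' @param max_scans Positive integer; the truncation horizon in scans.
#' @param lead_in Non-negative rest duration (seconds) before the first block.
#' @param rest Rest duration (seconds) following each task block. Used only
#'   for reporting block completion scans (the convention in which a block is
#'   "completed" once its trailing rest has elapsed); the hemodynamic
#'   regressors are built from the task period alone.
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol(tr = 3, max_scans = 20,
#'                        conditions = list(tap = list(onsets = 0, duration = 36)))
#' block_completion_scans(p)
#' @seealso [make_paper_protocol()] for the packaged 1-back protocol,
#'   [build_design_matrix()] for the derived GLM design.
#' @export
stimulus_protocol <- function(tr, conditions, max_scans, lead_in = 0, rest = 0) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive scalar duration in seconds", call. = FALSE)
  if (!is.numeric(max_scans) || length(max_scans) != 1L || max_scans < 1 ||
      max_scans != round(max_scans))
    stop("'max_scans' must be a positive integer", call. = FALSE)
  if (lead_in < 0) stop("'lead_in' must be non-negative", call. = FALSE)
  if (rest < 0) stop("'rest' must be non-negative", call. = FALSE)
  if (!is.list(conditions) || length(conditions) == 0L)
    stop("'conditions' must be a non-empty named list", call. = FALSE)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("every condition must be named", call. = FALSE)

  run_end <- max_scans * tr
  intervals <- list()
  for (lab in names(conditions)) {
    cn <- conditions[[lab]]
    if (is.null(cn$onsets) || is.null(cn$duration))
      stop("condition '", lab, "' needs 'onsets' and 'duration'", call. = FALSE)
    on <- as.numeric(cn$onsets); dur <- as.numeric(cn$duration)
    if (length(dur) != 1L || dur <= 0)
      stop("condition '", lab, "': 'duration' must be a positive scalar", call. = FALSE)
    if (length(on) && any(diff(on) <= 0))
      stop("condition '", lab, "': onsets must be strictly increasing", call. = FALSE)
    if (length(on) && any(on < lead_in - 1e-9))
      stop("condition '", lab, "': a block starts before the lead-in ends", call. = FALSE)
    if (length(on) && any(on + dur > run_end + 1e-9))
      stop("condition '", lab, "': a block ends after max_scans x tr = ",
           run_end, " s", call. = FALSE)
    if (length(on))
      intervals[[lab]] <- cbind(on, on + dur)
  }
  # blocks must not overlap in time, within or across conditions
  all_iv <- do.call(rbind, intervals)
  if (!is.null(all_iv) && nrow(all_iv) > 1L) {
    o <- order(all_iv[, 1L])
    s <- all_iv[o, , drop = FALSE]
    if (any(s[-1L, 1L] < s[-nrow(s), 2L] - 1e-9))
      stop("stimulus blocks overlap in time", call. = FALSE)
  }

  structure(
    list(tr = tr, max_scans = as.integer(max_scans), lead_in = lead_in,
         rest = rest,
         conditions = lapply(conditions, function(cn)
           list(onsets = as.numeric(cn$onsets), duration = as.numeric(cn$duration)))),
    class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Block-design stimulus protocol\n")
  cat(sprintf("  TR %.3g s, %d scans (%.0f s), lead-in %.3g s, rest %.3g s\n",
              x$tr, x$max_scans, x$max_scans * x$tr, x$lead_in, x$rest))
  for (lab in names(x$conditions)) {
    cn <- x$conditions[[lab]]
    cat(sprintf("  %s: %d block(s) of %.3g s at t = %s\n", lab,
                length(cn$onsets), cn$duration,
                paste(format(cn$onsets), collapse = ", ")))
  }
  invisible(x)
}

#' Scan index at which each stimulus block completes
#'
#' Returns, for each condition, the 1-based scan index during which each
#' block's cycle ends. A cycle is the task period plus the protocol's trailing
#' `rest`, so with `rest = 0` this is the scan containing the last task
#' second. This matches how completion scans are conventionally tabulated for
#' block designs in which every block is followed by a fixed rest period.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Named list of integer vectors, one per condition.
#' @export
block_completion_scans <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  lapply(protocol$conditions, function(cn) {
    end_s <- cn$onsets + cn$duration + protocol$rest
    as.integer(ceiling(end_s / protocol$tr - 1e-9))
  })
}

#' Read or write a stimulus protocol as YAML or JSON
#'
#' The on-disk representation uses keys `tr`, `max_scans`, `lead_in`, `rest`
#' and `conditions`, the latter a list of records `{label, onsets, duration}`.
#' The format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_protocol` returns a [stimulus_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  conds <- raw$conditions
  if (is.data.frame(conds))
    conds <- lapply(seq_len(nrow(conds)), function(i) as.list(conds[i, ]))
  cl <- list()
  for (cn in conds)
    cl[[cn$label]] <- list(onsets = unlist(cn$onsets), duration = cn$duration)
  stimulus_protocol(tr = raw$tr, conditions = cl, max_scans = raw$max_scans,
                    lead_in = if (is.null(raw$lead_in)) 0 else raw$lead_in,
                    rest = if (is.null(raw$rest)) 0 else raw$rest)
}

#' @rdname read_protocol
#' @param protocol A [stimulus_protocol()] to serialise.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  rec <- list(
    tr = protocol$tr, max_scans = protocol$max_scans,
    lead_in = protocol$lead_in, rest = protocol$rest,
    conditions = lapply(names(protocol$conditions), function(lab)
      list(label = lab,
           onsets = protocol$conditions[[lab]]$onsets,
           duration = protocol$conditions[[lab]]$duration)))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(rec, path)
  invisible(path)
}

#' The packaged 1-back arithmetic block protocol
#'
#' Two alternating difficulty levels ("easy", "hard"), six 36 s task blocks
#' per level, each followed by 21 s of rest, TR 3 s, 238 scans total and a
#' 6 s lead-in. Easy blocks complete (task + rest) at scans
#' 21, 59, 97, 135, 173, 211 and hard blocks at 40, 78, 116, 154, 192, 230,
#' so a first stage of 2 blocks per level ends at scan 78 and one of 4 blocks
#' per level at scan 154.
#'
#' @return A [stimulus_protocol()].
#' @export
make_paper_protocol <- function() {
  block <- 36; rest <- 21; cycle <- 2 * (block + rest)  # easy + hard = 114 s
  lead <- 6
  stimulus_protocol(
    tr = 3, max_scans = 238, lead_in = lead, rest = rest,
    conditions = list(
      easy = list(onsets = lead + (0:5) * cycle,          duration = block),
      hard = list(onsets = lead + block + rest + (0:5) * cycle, duration = block)))
}
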