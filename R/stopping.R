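#' Fraction of voxels classified
#'
#' The global stopping rule watches the fraction of in-mask voxels whose
#' SPRT has reached a decision (active or nonactive). Degenerate voxels are
#' excluded from both numerator and denominator.
#'
#' @param state An [sprt_state_init()] state, or a character status vector.
#' @param mask_size Number of in-mask voxels (defaults to the state length).
#' @return Fraction in `[0, 1]`.
#' @export
classified_fraction <- function(state, mask_size = NULL) {
  status <- if (inherits(state, "sprt_state")) state$status else as.character(state)
  if (is.null(mask_size)) mask_size <- length(status)
  if (mask_size <= 0 || length(status) == 0L)
    stop("empty mask: no voxels to classify", call. = FALSE)
  n_degen <- sum(status == "degenerate")
  eligible <- mask_size - n_degen
  if (eligible <= 0) return(0)
  sum(status %in% c("active", "nonactive")) / eligible
}

#' Global per-condition stop decision
#'
#' A condition stops once the classified fraction reaches the rule threshold,
#' but never during the first stage, however high the fraction.
#'
#' @param fraction Classified fraction in `[0, 1]`.
#' @param scan Current scan index.
#' @param config An [sprt_config()] (supplies the first-stage guard).
#' @param threshold Rule threshold in `(0, 1]` (e.g. 0.70, 0.80, 0.90).
#' @param condition_label Condition name for the record.
#' @return Object of class `stop_decision`: list with `condition_label`,
#'   `scan`, `fraction_classified`, `stop`, `rule_threshold`.
#' @export
global_stop_decision <- function(fraction, scan, config, threshold = 0.8,
                                 condition_label = "task") {
  stopifnot(inherits(config, "sprt_config"))
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  stop <- scan > config$first_stage_scans && fraction >= threshold
  structure(list(condition_label = condition_label, scan = as.integer(scan),
                 fraction_classified = fraction, stop = stop,
                 rule_threshold = threshold),
            class = "stop_decision")
}

#' @export
print.stop_decision <- function(x, ...) {
  cat(sprintf("[%s] scan %d: %.1f%% classified (rule %.0f%%) -> %s\n",
              x$condition_label, x$scan, 100 * x$fraction_classified,
              100 * x$rule_threshold, if (x$stop) "STOP" else "continue"))
  invisible(x)
}

#' Route per-condition stop decisions
#'
#' Each condition's stimulus stream is terminated independently; the run
#' ends when every condition has stopped or the truncation horizon is
#' reached.
#'
#' @param stopped Named logical vector: `TRUE` for conditions that have
#'   received a stop decision.
#' @param scan Current scan index.
#' @param max_scans Truncation horizon.
#' @return List with `running` (character vector of conditions still
#'   running), `run_ended` (logical) and `truncated` (`TRUE` when the run
#'   ended by hitting `max_scans` with conditions still running).
#' @export
condition_router <- function(stopped, scan, max_scans) {
  stopifnot(is.logical(stopped), !is.null(names(stopped)))
  running <- names(stopped)[!stopped]
  truncated <- length(running) > 0L && scan >= max_scans
  list(running = running,
       run_ended = length(running) == 0L || scan >= max_scans,
       truncated = truncated)
}

#' Write a stop-signal sentinel
#'
#' Emits the JSON sentinel a stimulus-presentation program polls for:
#' `{condition, scan, fraction}`. One file per condition, named
#' `stop_<condition>.json`.
#'
#' @param decision A [global_stop_decision()] with `stop = TRUE`.
#' @param out_dir Output directory.
#' @return The sentinel path, invisibly.
#' @export
write_stop_signal <- function(decision, out_dir) {
  stopifnot(inherits(decision, "stop_decision"))
  path <- file.path(out_dir, paste0("stop_", decision$condition_label, ".json"))
  jsonlite::write_json(list(condition = decision$condition_label,
                            scan = decision$scan,
                            fraction = decision$fraction_classified),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
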