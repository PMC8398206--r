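# CPU-time normalization for the two bottleneck program stages of a DFT
# run: the iterative SCF solver (link502) and the two-electron integral
# derivatives (link703). Raw logs report total CPU time over several
# program instances, possibly on several cores; scoring wants the average
# time for one instance on one core.

#' Normalize a CPU-time record to seconds per instance per core
#'
#' `total_cpu_time / (n_instances * n_cores)`. Whether logged CPU time
#' already aggregates over cores is ambiguous in practice; this package
#' divides by `n_cores`, and `n_cores` defaults to 1 so single-core logs
#' pass through unchanged. The measurement itself carries an uncertainty
#' of about +/- 2 s, recorded as an attribute.
#'
#' @param total_cpu_time total CPU seconds over all instances (>= 0).
#' @param n_instances number of program initializations (>= 1).
#' @param n_cores cores the time aggregates over (>= 1, default 1).
#' @return normalized seconds, with attribute `uncertainty_s = 2`.
#' @export
#' @examples
#' normalize_time(100, 4) # 25
#' normalize_time(120, 3, 2) # 20
normalize_time <- function(total_cpu_time, n_instances, n_cores = 1) {
  stop_if_not_finite(total_cpu_time, n_instances, n_cores, what = "timing")
  if (any(total_cpu_time < 0)) stop("total_cpu_time must be nonnegative", call. = FALSE)
  if (any(n_instances < 1) || any(n_cores < 1)) {
    stop("n_instances and n_cores must be >= 1", call. = FALSE)
  }
  structure(total_cpu_time / (n_instances * n_cores), uncertainty_s = 2)
}

#' Per-stage summary of normalized times
#'
#' Normalizes every record and reports, per stage, the tidy table of
#' combination times plus the stage maximum — the denominator of the
#' performance tier thresholds in scoring.
#'
#' @param records data.frame with columns `functional`, `basis`, `stage`,
#'   `total_cpu_time_s`, `n_instances`, `n_cores`.
#' @param stages stage labels expected in the table.
#' @return list of class `stage_summary`: `times` (data.frame with
#'   `normalized_s` added), `max_by_stage` (named numeric).
#' @export
stage_summary <- function(records, stages = c("link502", "link703")) {
  stopifnot(is.data.frame(records))
  needed <- c("functional", "basis", "stage", "total_cpu_time_s", "n_instances", "n_cores")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("timing table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(records$stage), stages)
  if (length(unknown)) {
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (st in stages) {
    if (!any(records$stage == st)) stop("no timing records for stage ", st, call. = FALSE)
  }
  records$normalized_s <- as.numeric(normalize_time(records$total_cpu_time_s,
                                                    records$n_instances,
                                                    records$n_cores))
  mx <- vapply(stages, function(st) max(records$normalized_s[records$stage == st]),
               numeric(1))
  records <- records[order(records$stage, records$functional, records$basis), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(times = records, max_by_stage = mx), class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat("Normalized stage times (s per instance per core):\n")
  for (st in names(x$max_by_stage)) {
    n <- sum(x$times$stage == st)
    cat(sprintf("  %s: %d records, max %.2f s\n", st, n, x$max_by_stage[[st]]))
  }
  invisible(x)
}
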