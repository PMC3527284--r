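#' Record the usage of a finished task
#'
#' CPU hours sum every attempt's processing time across all jobs (an
#' evicted-then-rerun job is charged for both attempts); queueing time is
#' excluded. Wall-clock hours run from submission to end and include any
#' time spent waiting for resources. The speed-up factor is their ratio:
#' the task's effective acceleration over running every job sequentially on
#' one core.
#'
#' @param bundle a terminal `job_bundle` (CPU times filled in by
#'   [run_bundle()]).
#' @param submitted,ended POSIXct submission and end times.
#' @return a one-row `usage_record` tibble: `task_id`, `task_type`,
#'   `submitted`, `ended`, `n_jobs`, `cpu_hours`, `wall_clock` (hours),
#'   `speedup`.
#' @export
record_usage <- function(bundle, submitted, ended) {
  if (ended <= submitted)
    stop(validation_error("task end time must be after submission time"))
  cpu <- bundle$jobs$cpu_time
  if (any(is.na(cpu))) {
    warning("missing CPU time for ",
            sum(is.na(cpu)), " job(s); recorded as 0")
    cpu[is.na(cpu)] <- 0
  }
  wall <- as.numeric(difftime(ended, submitted, units = "hours"))
  rec <- tibble::tibble(
    task_id = bundle$task$task_id, task_type = bundle$task$task_type,
    submitted = format(submitted, "%Y-%m-%d %H:%M:%S"),
    ended = format(ended, "%Y-%m-%d %H:%M:%S"),
    n_jobs = nrow(bundle$jobs),
    cpu_hours = sum(cpu) / 3600,
    wall_clock = wall)
  rec$speedup <- speedup(rec)
  structure(rec, class = c("usage_record", class(rec)))
}

#' Speed-up factor of a task
#'
#' Defined as CPU time divided by wall-clock time: how many times faster
#' the task completed than a sequential single-core run of all its jobs.
#'
#' @param record a `usage_record` (or any list with `cpu_hours` and
#'   `wall_clock` in the same unit).
#' @return the speed-up factor(s).
#' @examples
#' speedup(list(cpu_hours = 2280, wall_clock = 20)) # 114
#' @export
speedup <- function(record) {
  stopifnot(all(record$wall_clock > 0))
  record$cpu_hours / record$wall_clock
}

#' Append usage records to a flat store
#'
#' The store is an append-only TSV (one row per task); aggregates are
#' recomputable from it at any time with [usage_stats()].
#'
#' @param record a `usage_record` (one or more rows).
#' @param store path of the usage TSV.
#' @return `store`, invisibly.
#' @export
usage_append <- function(record, store) {
  new <- !file.exists(store)
  suppressWarnings(
    utils::write.table(record, store, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = new, append = !new))
  invisible(store)
}

#' Aggregate statistics over the usage store
#'
#' @param store path of the usage TSV written by [usage_append()].
#' @return a one-row tibble: task count, total jobs, total CPU hours, mean
#'   and maximum speed-up.
#' @export
usage_stats <- function(store) {
  recs <- tibble::as_tibble(utils::read.table(store, sep = "\t", header = TRUE))
  tibble::tibble(n_tasks = nrow(recs),
                 total_jobs = sum(recs$n_jobs),
                 total_cpu_hours = sum(recs$cpu_hours),
                 mean_speedup = mean(recs$speedup),
                 max_speedup = max(recs$speedup))
}

#' Plot speed-up against number of parallel jobs
#'
#' The classic usage scatter: one point per task, log-log axes, coloured by
#' task type.
#' @param store path of the usage TSV.
#' @return a ggplot.
#' @export
plot_speedup <- function(store) {
  recs <- tibble::as_tibble(utils::read.table(store, sep = "\t", header = TRUE))
  ggplot2::ggplot(recs, ggplot2::aes(x = .data$n_jobs, y = .data$speedup,
                                     colour = .data$task_type,
                                     size = log10(pmax(.data$cpu_hours, 1e-6)))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "parallel jobs", y = "speed-up factor",
                  size = "log10 CPU hours", colour = "task type")
}
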