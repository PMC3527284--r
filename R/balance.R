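#' Benchmark a single repeat of a task
#'
#' The load balancer's measurement phase: execute one repeat of the task
#' locally and return its elapsed wall-clock time. Wall-clock (not CPU)
#' time is used because the target runtime trades off against queueing and
#' transfer overheads, which are wall-clock phenomena. If the repeat is
#' still running after `benchmark_cap` seconds the run is abandoned and the
#' cap is returned flagged as timed out. The benchmark repeat is a pure
#' measurement: it is discarded, not counted towards the task's repeats.
#'
#' @param task a [task_spec()] of a repeats-type (`stochastic_repeat`,
#'   `optimization_repeat`, `parameter_estimation_repeat`), or any task
#'   carrying a `stub` workload function (see [workload_stub()]).
#' @param config a [load_balance_config()].
#' @return elapsed seconds (numeric scalar), with attribute `timed_out`
#'   (logical).
#' @export
benchmark_single_repeat <- function(task, config = task$balance %||% load_balance_config()) {
  run_one <- if (!is.null(task$stub)) {
    task$stub
  } else {
    stopifnot(task$task_type %in% c("stochastic_repeat", "optimization_repeat",
                                    "parameter_estimation_repeat"))
    one <- split_repeats(benchmark_variant(task), 1L)$jobs$document[[1]]
    function() run_job_document(one, output_path = tempfile(fileext = ".tsv"))
  }
  t0 <- Sys.time()
  res <- tryCatch(
    with_deadline(run_one, config$benchmark_cap),
    taskfarm_benchmark_timeout = function(e) e,
    error = function(e) stop("task-setup error: benchmark repeat failed: ",
                             conditionMessage(e))
  )
  timed_out <- inherits(res, "taskfarm_benchmark_timeout")
  elapsed <- if (timed_out) config$benchmark_cap
             else as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(elapsed, timed_out = timed_out)
}

# benchmarking must not consume the task's own seeds: measure a one-repeat
# variant whose repeat stream is offset far away from the real task's
benchmark_variant <- function(task) {
  task$repeat_count <- 1L
  task$base_seed <- task$base_seed + 1000003L
  task
}

# cooperative deadline: single-threaded execution cannot be interrupted
# mid-repeat, so the timeout is checked when the repeat returns; a repeat
# observed to exceed the cap signals a timeout condition instead of a timing
with_deadline <- function(fn, cap) {
  t0 <- Sys.time()
  out <- fn()
  if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > cap) {
    cond <- structure(
      class = c("taskfarm_benchmark_timeout", "condition"),
      list(message = "benchmark exceeded its wall-clock cap", call = NULL))
    stop(cond)
  }
  out
}

#' Repeats per job from a benchmark time
#'
#' The packing rule of the load balancer: with a measured single-repeat
#' time `s` and target per-job runtime `t`, each job receives
#' `floor(t / s)` repeats (never below 1), so that its predicted runtime
#' stays at or under the target. A single repeat at or above the target —
#' including a timed-out benchmark — yields one repeat per job, as does the
#' user override.
#'
#' @param single_time benchmark seconds (> 0), e.g. from
#'   [benchmark_single_repeat()]; a `timed_out` attribute forces 1.
#' @param config a [load_balance_config()].
#' @return integer >= 1.
#' @examples
#' repeats_per_job(300, load_balance_config(t_target = 900))  # 3
#' repeats_per_job(1200, load_balance_config(t_target = 900)) # 1
#' @export
repeats_per_job <- function(single_time, config = load_balance_config()) {
  stopifnot(single_time > 0)
  if (config$override_one_per_job) return(1L)
  if (isTRUE(attr(single_time, "timed_out"))) return(1L)
  if (single_time >= config$t_target) return(1L)
  max(1L, as.integer(floor(config$t_target / single_time)))
}

#' Split a repeats-type task using the load balancer
#'
#' Convenience wrapper: benchmark one repeat, derive the packing, split.
#'
#' @param task a repeats-type [task_spec()].
#' @param config a [load_balance_config()].
#' @return a `job_bundle`.
#' @export
balance_and_split <- function(task, config = task$balance %||% load_balance_config()) {
  r <- if (config$override_one_per_job) 1L
       else repeats_per_job(benchmark_single_repeat(task, config), config)
  split_repeats(task, r)
}
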