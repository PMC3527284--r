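#' Load-balancing configuration
#'
#' Controls how repeats are packed into parallel jobs: each job should run
#' for approximately `t_target` seconds. The default of 900 s (15 minutes)
#' is the trade-off between per-job submission overhead (dominant when jobs
#' are short) and under-use of the pool plus eviction risk (when jobs are
#' long); administrators deploying against a real pool are expected to tune
#' it.
#'
#' @param t_target target per-job runtime, seconds (> 0).
#' @param override_one_per_job if `TRUE`, skip benchmarking and assign one
#'   repeat per job regardless of timings.
#' @param benchmark_cap wall-clock budget for the single-repeat benchmark,
#'   seconds; defaults to `t_target`.
#' @return a `load_balance_config` list.
#' @export
load_balance_config <- function(t_target = 900, override_one_per_job = FALSE,
                                benchmark_cap = t_target) {
  stopifnot(t_target > 0, benchmark_cap > 0)
  structure(list(t_target = t_target,
                 override_one_per_job = isTRUE(override_one_per_job),
                 benchmark_cap = benchmark_cap),
            class = "load_balance_config")
}

TASK_TYPES <- c("sensitivity", "stochastic_repeat", "scan",
                "optimization_repeat", "parameter_estimation_repeat",
                "algorithm_sweep", "raw")

#' Describe a parallelizable task
#'
#' The user-facing description of one of the seven supported task types.
#' Which fields are required depends on `task_type`:
#'
#' * `sensitivity` — `target_spec` and `sensitivity_parameters` (a data
#'   frame `name`/`lower`/`upper`, typically the original value +/- x%);
#'   optionally `algorithm`/`settings` for the per-job optimizations.
#' * `stochastic_repeat` — `repeat_count`, plus `t_end`/`n_points` for the
#'   simulated time course.
#' * `scan` — `scan_grid`: either a tibble of concrete parameter-value
#'   tuples (one column per scanned parameter) or a generator spec from
#'   [scan_grid_range()] / [scan_grid_random()]; plus `scan_subtask`
#'   (`"time_course"`, `"steady_state"`, or `"optimization"`).
#' * `optimization_repeat` — `repeat_count`, `target_spec`, `direction`,
#'   `optimize_parameters` (bounds data frame as above).
#' * `parameter_estimation_repeat` — `repeat_count`, `estimation_data`
#'   (tibble `time` + observed species), `estimate_parameters` (bounds
#'   data frame).
#' * `algorithm_sweep` — `algorithms`: list of `list(algorithm=, settings=)`
#'   entries, plus `target_spec`, `direction`, `optimize_parameters`.
#' * `raw` — `repeat_count`, `raw_executable`, and `raw_args`, a template
#'   with `{job}` and `{out}` substitution tokens.
#'
#' @param task_type one of the seven types.
#' @param model an [rn_model()] (not used by `raw`).
#' @param ... type-specific fields, as above.
#' @param base_seed integer; job j receives seed `base_seed + j`, and global
#'   repeat g (across all jobs) is simulated with seed `base_seed + g`, so a
#'   whole task replays identically regardless of how it was split.
#' @param balance a [load_balance_config()].
#' @param task_id identifier used for directories, logs, and notifications.
#' @return a `task_spec` object.
#' @export
task_spec <- function(task_type, model = NULL, ..., base_seed = 0L,
                      balance = load_balance_config(),
                      task_id = paste0("task_", task_type)) {
  task_type <- match.arg(task_type, TASK_TYPES)
  spec <- structure(
    c(list(task_type = task_type, model = model, base_seed = as.integer(base_seed),
           balance = balance, task_id = task_id),
      list(...)),
    class = "task_spec")
  validate_task(spec)
  spec
}

#' Validate a task description
#'
#' Checks that the fields required by the task's type are present and
#' well-formed (this is also what the command-line `validate` command runs).
#'
#' @param task a `task_spec`.
#' @return `task`, invisibly; errors of class `taskfarm_validation` on the
#'   first violation.
#' @export
validate_task <- function(task) {
  stopifnot(inherits(task, "task_spec"))
  fail <- function(...) stop(validation_error(paste0(...)))
  tt <- task$task_type
  if (!is.null(task$model)) validate_rn_model(task$model)
  else if (tt != "raw") fail("task type '", tt, "' requires a model")
  needs_repeats <- tt %in% c("stochastic_repeat", "optimization_repeat",
                             "parameter_estimation_repeat", "raw")
  if (needs_repeats) {
    if (is.null(task$repeat_count) || task$repeat_count < 1)
      fail("repeat_count must be >= 1 for task type '", tt, "'")
  }
  check_bounds <- function(b, what) {
    if (is.null(b) || nrow(b) == 0) fail(what, " must be a non-empty bounds table")
    if (!all(c("name", "lower", "upper") %in% names(b)))
      fail(what, " needs columns name/lower/upper")
    if (!all(b$lower < b$upper)) fail(what, ": every lower bound must be < upper")
  }
  switch(tt,
    sensitivity = {
      if (is.null(task$target_spec)) fail("sensitivity task requires target_spec")
      check_bounds(task$sensitivity_parameters, "sensitivity_parameters")
      bad <- setdiff(task$sensitivity_parameters$name, names(task$model$parameters))
      if (length(bad)) fail("sensitivity parameters not in model: ",
                            paste(bad, collapse = ", "))
    },
    scan = {
      if (is.null(task$scan_grid)) fail("scan task requires scan_grid")
      if (is.null(task$scan_subtask) ||
          !task$scan_subtask %in% c("time_course", "steady_state", "optimization"))
        fail("scan_subtask must be time_course, steady_state or optimization")
    },
    optimization_repeat = ,
    algorithm_sweep = {
      if (is.null(task$target_spec)) fail(tt, " requires target_spec")
      check_bounds(task$optimize_parameters, "optimize_parameters")
      if (tt == "algorithm_sweep") {
        if (is.null(task$algorithms) || length(task$algorithms) == 0)
          fail("algorithm_sweep requires a non-empty algorithms list")
        keys <- vapply(task$algorithms, function(a)
          paste(a$algorithm, yaml::as.yaml(a$settings %||% list())), "")
        if (anyDuplicated(keys)) fail("duplicate algorithm+settings entries")
      }
    },
    parameter_estimation_repeat = {
      if (is.null(task$estimation_data)) fail(tt, " requires estimation_data")
      check_bounds(task$estimate_parameters, "estimate_parameters")
    },
    raw = {
      if (is.null(task$raw_args) || !grepl("{out}", task$raw_args, fixed = TRUE))
        fail("raw task requires a raw_args template containing the {out} token")
      if (is.null(task$raw_executable)) fail("raw task requires raw_executable")
    },
    stochastic_repeat = {
      if (is.null(task$t_end) || task$t_end <= 0) fail("stochastic_repeat requires t_end > 0")
    }
  )
  invisible(task)
}

validation_error <- function(msg) {
  structure(class = c("taskfarm_validation", "error", "condition"),
            list(message = msg, call = NULL))
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", x$task_id, " (", x$task_type, ")",
      if (!is.null(x$repeat_count)) paste0(", ", x$repeat_count, " repeats"),
      "\n", sep = "")
  invisible(x)
}

# ---- scan grids -------------------------------------------------------------

#' Scan-grid generators
#'
#' A scan grid is a tibble with one column per scanned parameter and one row
#' per subtask evaluation. `scan_grid_range()` builds the Cartesian product
#' of uniform ranges; `scan_grid_random()` describes independent uniform
#' random sampling, materialized once (seeded) before splitting so every
#' chunk sees the same realized grid.
#'
#' @param ... for `scan_grid_range()`: named `c(from, to, length)` triples.
#'   For `scan_grid_random()`: named `c(lower, upper)` pairs.
#' @param n number of random samples.
#' @return `scan_grid_range()` returns the materialized tibble;
#'   `scan_grid_random()` returns a generator spec consumed by
#'   [materialize_grid()].
#' @export
scan_grid_range <- function(...) {
  specs <- list(...)
  axes <- lapply(specs, function(s) seq(s[1], s[2], length.out = s[3]))
  tibble::as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))[names(specs)]
}

#' @rdname scan_grid_range
#' @export
scan_grid_random <- function(..., n) {
  structure(list(bounds = list(...), n = as.integer(n)), class = "scan_grid_random")
}

#' Materialize a scan grid
#'
#' Concrete tibbles pass through unchanged; random-sample generator specs
#' are realized with the given seed.
#'
#' @param grid a tibble or a [scan_grid_random()] spec.
#' @param seed integer seed for random grids.
#' @return a tibble of parameter-value tuples.
#' @export
materialize_grid <- function(grid, seed = 0L) {
  if (inherits(grid, "scan_grid_random")) {
    withr::with_seed(seed, {
      cols <- lapply(grid$bounds, function(b) stats::runif(grid$n, b[1], b[2]))
      tibble::as_tibble(cols)
    })
  } else {
    tibble::as_tibble(grid)
  }
}
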