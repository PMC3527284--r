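#' @rdname split_task
#' @export
new_job_bundle <- function(task, jobs) {
  stopifnot(inherits(task, "task_spec"))
  jobs$job_index <- seq_len(nrow(jobs)) - 1L
  jobs$seed <- task$base_seed + jobs$job_index
  jobs$state <- "created"
  jobs$exit_status <- NA_integer_
  jobs$cpu_time <- NA_real_
  jobs$attempts <- 0L
  jobs$output_file <- sprintf("job_%d.out.tsv", jobs$job_index)
  # job documents are self-contained: each carries its own seed and the
  # name of the output file it must produce
  jobs$document <- purrr::pmap(
    list(jobs$document, jobs$seed, jobs$output_file),
    function(doc, seed, out) c(doc, list(seed = seed, output = out)))
  structure(list(task = task, jobs = tibble::as_tibble(jobs)),
            class = "job_bundle")
}

#' @export
print.job_bundle <- function(x, ...) {
  cat("<job_bundle> ", x$task$task_id, ": ", nrow(x$jobs), " jobs (",
      x$task$task_type, ")\n", sep = "")
  print(dplyr::count(x$jobs, .data$state))
  invisible(x)
}

#' Summaries of a job bundle
#'
#' `tidy()` returns the per-job table (one row per job: index, seed, state,
#' exit status, CPU time, attempts); `glance()` a one-row overview.
#'
#' @param x a `job_bundle`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.job_bundle <- function(x, ...) {
  dplyr::select(x$jobs, -"document")
}

#' @rdname tidy.job_bundle
#' @exportS3Method generics::glance
glance.job_bundle <- function(x, ...) {
  tibble::tibble(task_id = x$task$task_id, task_type = x$task$task_type,
                 n_jobs = nrow(x$jobs),
                 n_completed = sum(x$jobs$state == "completed"),
                 n_failed = sum(x$jobs$state %in% c("failed", "held")),
                 cpu_time = sum(x$jobs$cpu_time, na.rm = TRUE))
}

#' Split a task into independent parallel jobs
#'
#' Converts a [task_spec()] into a `job_bundle`: an ordered table of jobs,
#' each with a self-contained job document (model + task fragment + seed +
#' output filename) that can be executed anywhere with no other context.
#' The split rule depends on the task type:
#'
#' * `sensitivity` — exactly 2 jobs per analysed parameter, ordered
#'   (parameter 1 maximization, parameter 1 minimization, parameter 2
#'   maximization, ...).
#' * `stochastic_repeat`, `optimization_repeat`,
#'   `parameter_estimation_repeat` — `ceiling(repeat_count /
#'   repeats_per_job)` jobs; every job carries `repeats_per_job` repeats
#'   except the last, which carries the remainder.
#' * `scan` — `chunk_count` contiguous, non-overlapping index subranges
#'   covering the grid exactly; chunk sizes differ by at most one, larger
#'   chunks first. A `chunk_count` exceeding the grid size is clamped with
#'   a warning.
#' * `algorithm_sweep` — one job per algorithm configuration, in list order.
#' * `raw` — `repeat_count` jobs of one repeat each, with the argument
#'   template's `{job}` and `{out}` tokens substituted.
#'
#' @param task a [task_spec()].
#' @param repeats_per_job repeats packed into each job (repeats-type tasks);
#'   normally produced by the load balancer ([repeats_per_job()]).
#' @param chunk_count number of scan chunks.
#' @return a `job_bundle` whose `jobs` tibble has `job_index` 0..N-1, one
#'   document per job, and per-job seeds `base_seed + job_index`.
#' @export
split_task <- function(task, repeats_per_job = 1L, chunk_count = 1L) {
  validate_task(task)
  switch(task$task_type,
    sensitivity = split_sensitivity(task),
    stochastic_repeat = ,
    optimization_repeat = ,
    parameter_estimation_repeat = split_repeats(task, repeats_per_job),
    scan = split_scan(task, chunk_count),
    algorithm_sweep = split_algorithm_sweep(task),
    raw = split_raw(task))
}

common_doc <- function(task, extra) {
  c(list(task_id = task$task_id, task_type = task$task_type,
         model = if (!is.null(task$model)) write_model_doc(task$model)),
    extra)
}

#' @rdname split_task
#' @export
split_sensitivity <- function(task) {
  stopifnot(task$task_type == "sensitivity")
  validate_task(task)
  pars <- task$sensitivity_parameters
  rows <- tidyr::expand_grid(param = pars$name, direction = c("maximize", "minimize"))
  docs <- purrr::pmap(rows, function(param, direction) {
    common_doc(task, list(
      kind = "sensitivity_optimization",
      param = param, direction = direction,
      target_spec = task$target_spec,
      bounds = as.data.frame(pars),
      algorithm = task$algorithm %||% "particle_swarm",
      settings = task$settings %||% list(),
      target_when = task$target_when %||% "final_time",
      t_end = task$t_end %||% 10))
  })
  bundle <- new_job_bundle(task, tibble::tibble(
    assigned_repeats = 1L, subrange_start = NA_integer_, subrange_end = NA_integer_,
    param = rows$param, direction = rows$direction, document = docs))
  bundle
}

#' @rdname split_task
#' @export
split_repeats <- function(task, repeats_per_job) {
  stopifnot(task$task_type %in% c("stochastic_repeat", "optimization_repeat",
                                  "parameter_estimation_repeat"))
  if (repeats_per_job < 1) stop(validation_error("repeats_per_job must be >= 1"))
  n <- task$repeat_count
  r <- as.integer(repeats_per_job)
  n_jobs <- ceiling(n / r)
  assigned <- rep(r, n_jobs)
  assigned[n_jobs] <- n - r * (n_jobs - 1)   # remainder goes in the last job
  offsets <- cumsum(c(0L, assigned[-n_jobs]))
  payload <- switch(task$task_type,
    stochastic_repeat = list(kind = "stochastic_repeat",
                             t_end = task$t_end,
                             n_points = task$n_points %||% 101L),
    optimization_repeat = list(kind = "optimization_repeat",
                               target_spec = task$target_spec,
                               direction = task$direction %||% "minimize",
                               bounds = as.data.frame(task$optimize_parameters),
                               algorithm = task$algorithm %||% "particle_swarm",
                               settings = task$settings %||% list(),
                               target_when = task$target_when %||% "final_time",
                               t_end = task$t_end %||% 10),
    parameter_estimation_repeat = list(kind = "parameter_estimation_repeat",
                                       data = as.data.frame(task$estimation_data),
                                       bounds = as.data.frame(task$estimate_parameters),
                                       algorithm = task$algorithm %||% "particle_swarm",
                                       settings = task$settings %||% list()))
  docs <- purrr::map2(assigned, offsets, function(a, off) {
    common_doc(task, c(payload, list(assigned_repeats = a, repeat_offset = off,
                                     base_seed = task$base_seed)))
  })
  new_job_bundle(task, tibble::tibble(
    assigned_repeats = as.integer(assigned),
    subrange_start = NA_integer_, subrange_end = NA_integer_,
    document = docs))
}

#' @rdname split_task
#' @export
split_scan <- function(task, chunk_count) {
  stopifnot(task$task_type == "scan")
  grid <- materialize_grid(task$scan_grid, seed = task$base_seed)
  n <- nrow(grid)
  if (chunk_count > n) {
    warning("chunk_count ", chunk_count, " exceeds grid size ", n,
            "; clamped to ", n)
    chunk_count <- n
  }
  sizes <- chunk_sizes(n, chunk_count)
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-length(ends)])
  docs <- purrr::map2(starts, ends, function(s, e) {
    common_doc(task, list(
      kind = "scan",
      subtask = task$scan_subtask,
      values = as.data.frame(grid[(s + 1):e, , drop = FALSE]),
      t_end = task$t_end %||% 10,
      n_points = task$n_points %||% 11L,
      target_spec = task$target_spec))
  })
  new_job_bundle(task, tibble::tibble(
    assigned_repeats = NA_integer_,
    subrange_start = as.integer(starts), subrange_end = as.integer(ends),
    document = docs))
}

# n points into k contiguous chunks, sizes differing by <= 1, larger first
chunk_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))[seq_len(k)]
}

#' @rdname split_task
#' @export
split_algorithm_sweep <- function(task) {
  stopifnot(task$task_type == "algorithm_sweep")
  validate_task(task)
  docs <- purrr::map(task$algorithms, function(a) {
    common_doc(task, list(
      kind = "algorithm_sweep",
      algorithm = a$algorithm, settings = a$settings %||% list(),
      target_spec = task$target_spec,
      direction = task$direction %||% "minimize",
      bounds = as.data.frame(task$optimize_parameters),
      target_when = task$target_when %||% "final_time",
      t_end = task$t_end %||% 10))
  })
  new_job_bundle(task, tibble::tibble(
    assigned_repeats = 1L,
    subrange_start = NA_integer_, subrange_end = NA_integer_,
    algorithm = vapply(task$algorithms, `[[`, "", "algorithm"),
    document = docs))
}

#' @rdname split_task
#' @export
split_raw <- function(task) {
  stopifnot(task$task_type == "raw")
  validate_task(task)
  idx <- seq_len(task$repeat_count) - 1L
  docs <- purrr::map(idx, function(j) {
    out <- sprintf("job_%d.out", j)
    args <- gsub("{job}", j, task$raw_args, fixed = TRUE)
    args <- gsub("{out}", out, args, fixed = TRUE)
    common_doc(task, list(kind = "raw", executable = task$raw_executable,
                          arguments = args))
  })
  bundle <- new_job_bundle(task, tibble::tibble(
    assigned_repeats = 1L,
    subrange_start = NA_integer_, subrange_end = NA_integer_,
    document = docs))
  bundle$jobs$output_file <- sprintf("job_%d.out", bundle$jobs$job_index)
  bundle
}

# ---- job document I/O -------------------------------------------------------

#' Write per-job documents into a task directory
#'
#' Each job's self-contained document is serialized as YAML to
#' `job_<index>.yml` inside `dir`; output files and logs for the job use
#' the same stem.
#'
#' @param bundle a `job_bundle`.
#' @param dir task directory (created if missing).
#' @return the updated bundle with a `doc_file` column, invisibly.
#' @export
write_job_documents <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf(file.path(dir, "job_%d.yml"), bundle$jobs$job_index)
  purrr::walk2(bundle$jobs$document, files, function(doc, f) {
    yaml::write_yaml(doc, f)
  })
  bundle$jobs$doc_file <- files
  bundle$dir <- dir
  invisible(bundle)
}

#' Read one job document back from disk
#' @param path a `job_<index>.yml` file.
#' @return the document list (data frames restored as data frames).
#' @export
read_job_document <- function(path) {
  doc <- yaml::read_yaml(path)
  for (fld in c("bounds", "values", "data"))
    if (!is.null(doc[[fld]])) doc[[fld]] <- as.data.frame(doc[[fld]])
  doc
}
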