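#' Run a task end to end
#'
#' The whole pipeline in one call: validate, split (load-balancing
#' repeats-type tasks against the configured target runtime), write job
#' documents and submit descriptions, run the bundle on the local pool (or
#' stop after writing submit files), check states, collate the results,
#' record usage, and deliver the completion or failure notification. All
#' artifacts are written into `<work_dir>/<task_id>/`.
#'
#' @param task a [task_spec()].
#' @param config a [read_global_config()] object (defaults apply when
#'   omitted).
#' @param chunk_count chunk count for scan tasks (default: `max_parallel`).
#' @return a `task_run` list: `bundle`, `state` (from [poll_states()]),
#'   `results` (from [collate_task()], `NULL` on failure), `usage`
#'   (a `usage_record`), `report` (a `failure_report` on failure), `dir`.
#' @examples
#' \donttest{
#' task <- task_spec("stochastic_repeat", fixture_model("birth_death"),
#'                   repeat_count = 4, t_end = 2, n_points = 5,
#'                   base_seed = 1, task_id = "demo")
#' run <- run_task(task)
#' run$state$task_state
#' }
#' @export
run_task <- function(task, config = read_global_config(), chunk_count = NULL) {
  validate_task(task)
  dir <- file.path(config$work_dir, task$task_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_log <- set_activity_log(config$log_path %||%
                                the_log$path %||%
                                file.path(dir, "activity.log"))
  on.exit(set_activity_log(old_log), add = TRUE)
  activity_log(sprintf("[%s] submit: %s task", task$task_id, task$task_type))
  submitted <- Sys.time()

  balance <- task$balance %||% load_balance_config(t_target = config$t_target)
  bundle <- switch(task$task_type,
    stochastic_repeat = ,
    optimization_repeat = ,
    parameter_estimation_repeat = balance_and_split(task, balance),
    scan = split_task(task, chunk_count = chunk_count %||%
                        config$backend$max_parallel),
    split_task(task))
  activity_log(sprintf("[%s] split into %d jobs", task$task_id, nrow(bundle$jobs)))
  bundle <- write_job_documents(bundle, dir)
  write_submit_descriptions(bundle, dir)
  if (config$backend$backend == "submit_files_only") {
    activity_log(sprintf("[%s] submit files written, not executed", task$task_id))
    return(structure(list(bundle = bundle, state = NULL, results = NULL,
                          usage = NULL, report = NULL, dir = dir),
                     class = "task_run"))
  }

  bundle <- run_bundle(bundle, config$backend, dir)
  state <- poll_states(bundle)
  bundle <- state$bundle
  usage <- record_usage(bundle, submitted, Sys.time())
  usage_append(usage, file.path(config$work_dir, "usage.tsv"))

  if (state$task_state == "error") {
    report <- classify_failure(bundle, dir)
    notify(task$task_id, "failed", config$notification_sink, report = report)
    archive <- package_failure_bundle(dir)
    activity_log(sprintf("[%s] failed (%s); diagnostics at %s",
                         task$task_id, report$phase, archive))
    return(structure(list(bundle = bundle, state = state, results = NULL,
                          usage = usage, report = report, dir = dir),
                     class = "task_run"))
  }
  results <- collate_task(bundle, dir)
  notify(task$task_id, "finished", config$notification_sink)
  activity_log(sprintf("[%s] finished; speed-up %.3g", task$task_id,
                       usage$speedup))
  structure(list(bundle = bundle, state = state, results = results,
                 usage = usage, report = NULL, dir = dir),
            class = "task_run")
}

#' @export
print.task_run <- function(x, ...) {
  st <- if (is.null(x$state)) "submit files written" else x$state$task_state
  cat("<task_run> ", x$bundle$task$task_id, ": ", st, ", ",
      nrow(x$bundle$jobs), " jobs\n", sep = "")
  if (!is.null(x$usage))
    cat("  cpu_hours = ", signif(x$usage$cpu_hours, 4), ", wall_clock = ",
        signif(x$usage$wall_clock, 4), " h, speed-up = ",
        signif(x$usage$speedup, 4), "\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
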