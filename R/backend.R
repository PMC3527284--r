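#' Backend configuration
#'
#' @param backend `"local_pool"` (run jobs in-process, emulating the pool's
#'   job lifecycle) or `"submit_files_only"` (only write submit description
#'   files for a real pool).
#' @param max_parallel slot count of the emulated pool: at most this many
#'   jobs are in the `running` state at any poll.
#' @param eviction_rate probability that a running attempt is evicted
#'   (test injection; default 0). May be a vector indexed by attempt
#'   number, e.g. `c(1, 0)` evicts every first attempt and no later one;
#'   the last element applies to all later attempts.
#' @param poll_interval seconds between queue polls of a real pool;
#'   bookkeeping only for the in-process backend.
#' @return a `backend_config` list.
#' @export
backend_config <- function(backend = c("local_pool", "submit_files_only"),
                           max_parallel = 1L, eviction_rate = 0,
                           poll_interval = 5) {
  backend <- match.arg(backend)
  stopifnot(max_parallel >= 1, all(eviction_rate >= 0), all(eviction_rate <= 1),
            eviction_rate[length(eviction_rate)] < 1) # reruns must terminate
  structure(list(backend = backend, max_parallel = as.integer(max_parallel),
                 eviction_rate = eviction_rate, poll_interval = poll_interval),
            class = "backend_config")
}

# ---- submit description files ----------------------------------------------

#' Write a submit description file for one job
#'
#' Emits the standard key = value dialect understood by high-throughput
#' schedulers: `executable`, `arguments`, `transfer_input_files` (comma
#' separated), `requirements`, `output`, `error`, `log`, then a final
#' `queue` line. The file parses back losslessly with
#' [read_submit_description()].
#'
#' @param job one row of a bundle's job table (list or one-row data frame).
#' @param paths named list: `executable`, `input_files` (character vector,
#'   must exist), `output`, `error`, `log`, optional `requirements` and
#'   `queue_count`, and `dir` (where to write).
#' @return the path of the written file, invisibly.
#' @export
write_submit_description <- function(job, paths) {
  stopifnot(!is.null(paths$executable), !is.null(paths$dir))
  if (!file.exists(paths$executable))
    stop("file not found: ", paths$executable)
  missing <- paths$input_files[!file.exists(paths$input_files)]
  if (length(missing)) stop("file not found: ", missing[1])
  qc <- paths$queue_count %||% 1L
  stopifnot(qc >= 1)
  idx <- if (is.data.frame(job)) job$job_index[1] else job$job_index
  args <- paths$arguments %||% basename(paths$input_files[1] %||% "")
  lines <- c(
    paste0("executable = ", paths$executable),
    paste0("arguments = ", args),
    paste0("transfer_input_files = ", paste(paths$input_files, collapse = ", ")),
    paste0("requirements = ", paths$requirements %||% "TRUE"),
    paste0("output = ", paths$output %||% sprintf("job_%d.stdout", idx)),
    paste0("error = ", paths$error %||% sprintf("job_%d.stderr", idx)),
    paste0("log = ", paths$log %||% sprintf("job_%d.log", idx)),
    paste0("queue", if (qc > 1) paste0(" ", qc) else "")
  )
  path <- file.path(paths$dir, sprintf("job_%d.sub", idx))
  writeLines(lines, path)
  invisible(path)
}

#' Read a submit description file
#'
#' @param path a `.sub` file written by [write_submit_description()].
#' @return a named list of the fields plus `queue_count`; a write of this
#'   list (via the `paths` argument of the writer) reproduces the file
#'   byte for byte.
#' @export
read_submit_description <- function(path) {
  lines <- readLines(path)
  qline <- grep("^queue", lines)
  if (length(qline) != 1 || qline != length(lines))
    stop("malformed submit description: expected a single final queue line")
  qc <- sub("^queue\\s*", "", lines[qline])
  kv <- strsplit(lines[-qline], " = ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = " = "), ""),
                          vapply(kv, `[[`, "", 1))
  list(executable = vals[["executable"]],
       arguments = vals[["arguments"]],
       input_files = trimws(strsplit(vals[["transfer_input_files"]], ",")[[1]]),
       requirements = vals[["requirements"]],
       output = vals[["output"]], error = vals[["error"]], log = vals[["log"]],
       queue_count = if (nzchar(qc)) as.integer(qc) else 1L)
}

#' Write submit description files for a whole bundle
#'
#' One `.sub` file per job, next to the job documents. The executable is
#' the bundled job-runner script (`system.file("scripts", "run_job.R")`),
#' whose single argument is the job document.
#'
#' @param bundle a `job_bundle` whose documents are on disk
#'   (see [write_job_documents()]).
#' @param dir the task directory.
#' @return character vector of written paths, invisibly.
#' @export
write_submit_descriptions <- function(bundle, dir = bundle$dir) {
  stopifnot(!is.null(dir))
  runner <- system.file("scripts", "run_job.R", package = "taskfarm")
  purrr::map_chr(seq_len(nrow(bundle$jobs)), function(i) {
    j <- bundle$jobs[i, ]
    write_submit_description(j, list(
      dir = dir, executable = runner,
      arguments = basename(j$doc_file %||% sprintf("job_%d.yml", j$job_index)),
      input_files = file.path(dir, sprintf("job_%d.yml", j$job_index)),
      output = sprintf("job_%d.stdout", j$job_index),
      error = sprintf("job_%d.stderr", j$job_index),
      log = sprintf("job_%d.log", j$job_index)))
  }) -> paths
  invisible(paths)
}

# ---- job execution ----------------------------------------------------------

# executes one job document; returns list(exit_status, output written)
run_job_document <- function(doc, output_path) {
  kind <- doc$kind
  model <- if (!is.null(doc$model)) read_model_doc(doc$model)
  switch(kind,
    stochastic_repeat = {
      acc <- NULL
      for (g in seq_len(doc$assigned_repeats) - 1L + doc$repeat_offset) {
        traj <- simulate_ssa(model, t_end = doc$t_end, n_points = doc$n_points,
                             seed = doc$base_seed + g)
        vals <- as.matrix(traj[, -1, drop = FALSE])
        if (is.null(acc)) {
          acc <- list(time = traj$time, n = 0L,
                      sum = vals * 0, sumsq = vals * 0)
        }
        acc$n <- acc$n + 1L
        acc$sum <- acc$sum + vals
        acc$sumsq <- acc$sumsq + vals^2
      }
      write_moments_tsv(acc, output_path)
    },
    sensitivity_optimization = {
      prob <- sensitivity_problem(model, doc)
      res <- run_optimization(prob, doc$algorithm, doc$settings, seed = doc$seed)
      df <- data.frame(param = doc$param, direction = doc$direction,
                       best_value = res$best_value)
      utils::write.table(df, output_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_progress_tsv(res, sub("\\.out\\.tsv$", ".trace.tsv", output_path))
    },
    optimization_repeat = {
      prob <- opt_problem(target_objective(model, doc), doc$bounds, doc$direction)
      run_repeat_optimizations(prob, doc, output_path)
    },
    parameter_estimation_repeat = {
      obj <- estimation_objective(model, tibble::as_tibble(doc$data),
                                  doc$bounds$name)
      prob <- opt_problem(obj, doc$bounds, "minimize")
      run_repeat_optimizations(prob, doc, output_path)
    },
    scan = run_scan_chunk(model, doc, output_path),
    algorithm_sweep = {
      prob <- opt_problem(target_objective(model, doc), doc$bounds, doc$direction)
      res <- run_optimization(prob, doc$algorithm, doc$settings, seed = doc$seed)
      df <- data.frame(algorithm = doc$algorithm, best_value = res$best_value,
                       as.list(res$best_parameters), check.names = FALSE)
      utils::write.table(df, output_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    raw = {
      # the argument template names outputs relative to the task directory
      status <- withr::with_dir(dirname(output_path),
        system(paste(doc$executable, doc$arguments),
               ignore.stdout = TRUE, ignore.stderr = TRUE))
      if (status != 0) stop("raw executable exited with status ", status)
    },
    stub = {
      if (isTRUE(doc$fail)) stop("stub job instructed to fail")
      if (!is.null(doc$duration) && doc$duration > 0) Sys.sleep(doc$duration)
      writeLines("ok", output_path)
    },
    stop("unknown job kind: ", kind)
  )
  invisible(output_path)
}

# objective evaluating the task's target expression on a model with the
# candidate parameters substituted
target_objective <- function(model, doc) {
  function(theta) {
    m <- set_parameters(model, theta)
    evaluate_target(m, doc$target_spec,
                    when = doc$target_when %||% "final_time",
                    t_end = doc$t_end %||% 10)
  }
}

# the per-parameter objective of optimization-based global sensitivity
# analysis: the scaled sensitivity coefficient of the target with respect to
# the job's parameter, free over the whole parameter box
sensitivity_problem <- function(model, doc) {
  p <- doc$param
  base <- target_objective(model, doc)
  objective <- function(theta) {
    h <- max(abs(theta[[p]]) * 1e-4, 1e-8)
    up <- theta; up[[p]] <- theta[[p]] + h
    dn <- theta; dn[[p]] <- theta[[p]] - h
    y <- base(theta)
    dy <- (base(up) - base(dn)) / (2 * h)
    if (abs(y) > 1e-12) dy * theta[[p]] / y else dy * theta[[p]]
  }
  opt_problem(objective, doc$bounds, doc$direction)
}

run_repeat_optimizations <- function(prob, doc, output_path) {
  rows <- purrr::map(seq_len(doc$assigned_repeats) - 1L + doc$repeat_offset,
    function(g) {
      res <- run_optimization(prob, doc$algorithm, doc$settings,
                              seed = doc$base_seed + g)
      data.frame(repeat_index = g, best_value = res$best_value,
                 as.list(res$best_parameters), check.names = FALSE)
    })
  utils::write.table(dplyr::bind_rows(rows), output_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

run_scan_chunk <- function(model, doc, output_path) {
  vals <- doc$values
  rows <- purrr::map(seq_len(nrow(vals)), function(i) {
    theta <- unlist(vals[i, , drop = FALSE])
    m <- set_parameters(model, theta)
    out <- switch(doc$subtask,
      time_course = {
        traj <- simulate_ode(m, t_end = doc$t_end, n_points = doc$n_points)
        as.list(traj[nrow(traj), -1, drop = FALSE])
      },
      steady_state = steady_state(m, t_end0 = doc$t_end),
      optimization = list(target = evaluate_target(m, doc$target_spec,
                                                   t_end = doc$t_end)))
    data.frame(as.list(theta), lapply(out, signif, 12), check.names = FALSE)
  })
  utils::write.table(dplyr::bind_rows(rows), output_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

write_moments_tsv <- function(acc, path) {
  sp <- colnames(acc$sum)
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(time = acc$time),
      stats::setNames(tibble::as_tibble(as.data.frame(acc$sum)), paste0("sum.", sp)),
      stats::setNames(tibble::as_tibble(as.data.frame(acc$sumsq)), paste0("sumsq.", sp))),
    cols = -"time", names_to = c(".value", "species"), names_sep = "\\.")
  long$n <- acc$n
  long <- long[, c("time", "species", "n", "sum", "sumsq")]
  utils::write.table(format(as.data.frame(long), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_moments_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
}

# ---- lifecycle emulation ----------------------------------------------------

#' Run a bundle on the local process-pool backend
#'
#' Emulates the job lifecycle of a high-throughput pool in-process: jobs
#' move `created -> idle -> running -> {completed, evicted, failed}`; an
#' evicted job is re-queued (`evicted -> idle`) and, since checkpointing is
#' unsupported, restarts from scratch on its next attempt; a job whose
#' document is malformed never starts and is marked `held`
#' (`idle -> held`). At most `max_parallel` jobs are in the running state
#' at any poll; per-job CPU time (summed over all attempts) and exit status
#' are recorded, and every lifecycle event is appended to the job's log
#' file and the task's activity log.
#'
#' @param bundle a `job_bundle`; its job documents are written to `dir`
#'   if not already on disk.
#' @param config a [backend_config()] with `backend = "local_pool"`.
#' @param dir task directory for documents, outputs, and logs.
#' @return the updated bundle: per-job `state`, `exit_status`, `cpu_time`,
#'   `attempts`, with the sequence of per-poll state snapshots in
#'   `attr(, "state_history")`.
#' @export
run_bundle <- function(bundle, config = backend_config(), dir = bundle$dir) {
  stopifnot(inherits(bundle, "job_bundle"))
  if (config$backend != "local_pool")
    stop("run_bundle requires the local_pool backend")
  if (is.null(dir)) dir <- file.path(tempdir(), bundle$task$task_id)
  if (is.null(bundle$dir) || !identical(bundle$dir, dir) ||
      is.null(bundle$jobs$doc_file))
    bundle <- write_job_documents(bundle, dir)
  jobs <- bundle$jobs
  n <- nrow(jobs)
  log_file <- function(i) file.path(dir, sprintf("job_%d.log", jobs$job_index[i]))
  jlog <- function(i, code, text) {
    line <- sprintf("%s %s %s", code, format(Sys.time(), "%Y-%m-%d %H:%M:%S"), text)
    cat(line, "\n", sep = "", file = log_file(i), append = TRUE)
    activity_log(sprintf("[%s] job %d: %s", bundle$task$task_id,
                         jobs$job_index[i], text))
  }

  state <- rep("created", n)
  for (i in seq_len(n)) { jlog(i, "000", "SUBMIT"); state[i] <- "idle" }
  queue <- seq_len(n)
  running <- integer(0)
  history <- list()
  snapshot <- function() history[[length(history) + 1L]] <<- state

  evict_p <- function(attempt) {
    r <- config$eviction_rate
    r[min(attempt, length(r))]
  }

  while (length(queue) || length(running)) {
    # fill free slots
    while (length(running) < config$max_parallel && length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      doc <- jobs$document[[i]]
      bad <- job_document_problem(doc)
      if (!is.null(bad)) {
        jlog(i, "012", paste("HELD", bad))
        state[i] <- "held"
        next
      }
      state[i] <- "running"
      running <- c(running, i)
    }
    snapshot()
    if (!length(running)) break
    # execute the longest-waiting running job to completion of one attempt
    i <- running[1]; running <- running[-1]
    jobs$attempts[i] <- jobs$attempts[i] + 1L
    jlog(i, "001", "EXECUTE")
    out_path <- file.path(dir, jobs$output_file[i])
    pt0 <- proc.time()
    res <- tryCatch({ run_job_document(jobs$document[[i]], out_path); 0L },
                    error = function(e) {
                      jlog(i, "009", paste("ERROR", conditionMessage(e)))
                      1L
                    })
    dt <- proc.time() - pt0
    cpu <- unname(dt[1] + dt[2])
    nominal <- jobs$document[[i]]$nominal_cpu
    if (!is.null(nominal)) cpu <- nominal   # sleep stubs declare their cost
    jobs$cpu_time[i] <- (if (is.na(jobs$cpu_time[i])) 0 else jobs$cpu_time[i]) + cpu
    if (stats::runif(1) < evict_p(jobs$attempts[i])) {
      jlog(i, "004", "EVICT")
      unlink(out_path)                      # no checkpointing: start over
      state[i] <- "evicted"
      snapshot()
      state[i] <- "idle"
      queue <- c(queue, i)
    } else {
      jlog(i, "005", sprintf("TERMINATE exit=%d", res))
      jobs$exit_status[i] <- res
      state[i] <- if (res == 0L) "completed" else "failed"
      snapshot()
    }
  }
  snapshot()
  jobs$state <- state
  bundle$jobs <- jobs
  bundle$dir <- dir
  attr(bundle, "state_history") <- history
  bundle
}

# NULL if the document can start, otherwise a reason string (pre-execution
# failure: the job is held and never executes)
job_document_problem <- function(doc) {
  if (is.null(doc$kind)) return("missing kind")
  if (!doc$kind %in% c("stochastic_repeat", "sensitivity_optimization",
                       "optimization_repeat", "parameter_estimation_repeat",
                       "scan", "algorithm_sweep", "raw", "stub"))
    return(paste("unknown kind", doc$kind))
  needs_model <- !doc$kind %in% c("raw", "stub")
  if (needs_model) {
    if (is.null(doc$model)) return("missing model")
    ok <- tryCatch({ read_model_doc(doc$model); TRUE }, error = function(e) FALSE)
    if (!ok) return("unparseable model document")
  }
  if (doc$kind == "raw" && !nzchar(Sys.which(doc$executable)) &&
      !file.exists(doc$executable))
    return(paste("executable not found:", doc$executable))
  NULL
}

#' Poll the state of a bundle
#'
#' Returns per-state job counts and the derived task state: `finished`
#' when every job completed with exit status 0, `error` when any job is
#' held, failed, or completed with a non-zero exit status (such jobs are
#' marked failed), otherwise `running`.
#'
#' @param bundle a `job_bundle`.
#' @return a list: `counts` (named integer vector), `task_state`,
#'   `held_jobs`, `failed_jobs` (job indices), and the updated `bundle`.
#' @export
poll_states <- function(bundle) {
  jobs <- bundle$jobs
  bad_exit <- jobs$state == "completed" & !is.na(jobs$exit_status) &
    jobs$exit_status != 0L
  jobs$state[bad_exit] <- "failed"
  bundle$jobs <- jobs
  counts <- table(factor(jobs$state,
    levels = c("created", "idle", "running", "held", "evicted",
               "completed", "failed")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  held <- jobs$job_index[jobs$state == "held"]
  failed <- jobs$job_index[jobs$state == "failed"]
  task_state <- if (length(held) || length(failed)) "error"
    else if (all(jobs$state == "completed")) "finished"
    else "running"
  list(counts = counts[counts > 0], task_state = task_state,
       held_jobs = held, failed_jobs = failed, bundle = bundle)
}
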