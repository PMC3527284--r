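#' Classify a failed task from its job logs
#'
#' Distinguishes failures that happened before the simulation engine ran
#' (a held job whose log shows a submit record but no execute record —
#' a malformed job specification) from failures after execution started
#' (an executed job that terminated with a non-zero exit status — a
#' problem with the way the task was set up). The probable-cause text is
#' drawn from an editable rule table keyed on (phase, log pattern); the
#' shipped table is at
#' `system.file("extdata", "failure_rules.tsv", package = "taskfarm")`.
#'
#' @param bundle a `job_bundle` in the error state (see [poll_states()]).
#' @param dir task directory holding the `job_<index>.log` files.
#' @param rules optional rule table (tibble `phase`/`pattern`/`cause`).
#' @return a `failure_report`: list with `task_id`, `phase`
#'   (`"pre_execution"`, `"post_execution"`, or `"unknown"`),
#'   `probable_cause`, `affected_jobs` (job indices), and `per_job`
#'   (tibble of per-job phase and cause).
#' @export
classify_failure <- function(bundle, dir = bundle$dir, rules = failure_rules()) {
  st <- poll_states(bundle)
  if (st$task_state != "error")
    stop("classify_failure requires a task in the error state (task is ",
         st$task_state, ")")
  affected <- sort(c(st$held_jobs, st$failed_jobs))
  per_job <- purrr::map_dfr(affected, function(idx) {
    log_path <- file.path(dir, sprintf("job_%d.log", idx))
    rec <- tryCatch(parse_job_log(log_path), error = function(e) e)
    if (inherits(rec, "error")) {
      return(tibble::tibble(job_index = idx, phase = "unknown",
                            cause = paste("log unreadable:", conditionMessage(rec))))
    }
    phase <- if (rec$held && !rec$executed) "pre_execution"
             else if (rec$executed) "post_execution"
             else "unknown"
    key <- if (phase == "pre_execution") rec$held_reason %||% ""
           else paste(rec$error_text %||% "", collapse = " ")
    tibble::tibble(job_index = idx, phase = phase,
                   cause = lookup_cause(rules, phase, key))
  })
  phase <- if (all(per_job$phase == "pre_execution")) "pre_execution"
           else if (any(per_job$phase == "post_execution")) "post_execution"
           else "unknown"
  structure(list(task_id = bundle$task$task_id, phase = phase,
                 probable_cause = per_job$cause[match(phase, per_job$phase)] %|na|%
                   per_job$cause[1],
                 affected_jobs = affected, per_job = per_job),
            class = "failure_report")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.failure_report <- function(x, ...) {
  cat("<failure_report> ", x$task_id, ": ", x$phase, " failure, jobs ",
      paste(x$affected_jobs, collapse = ", "), "\n  ", x$probable_cause,
      "\n", sep = "")
  invisible(x)
}

#' The shipped (phase, log pattern) -> probable cause table
#' @param path alternative rule file (TSV: phase, pattern, cause).
#' @return a tibble.
#' @export
failure_rules <- function(path = system.file("extdata", "failure_rules.tsv",
                                             package = "taskfarm")) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      quote = "", stringsAsFactors = FALSE))
}

lookup_cause <- function(rules, phase, key) {
  cand <- rules[rules$phase == phase, ]
  if (nrow(cand) == 0) return("Unclassified failure.")
  hit <- which(vapply(cand$pattern, function(p) grepl(p, key), TRUE))
  if (length(hit)) cand$cause[hit[1]] else "Unclassified failure."
}

# parse a job log into submit/execute/terminate/held facts
parse_job_log <- function(path) {
  if (!file.exists(path)) stop("no log file at ", path)
  lines <- readLines(path)
  held_lines <- grep("^012 .* HELD", lines, value = TRUE)
  term <- grep("^005 .* TERMINATE", lines, value = TRUE)
  exit <- if (length(term)) as.integer(sub(".*exit=([0-9]+).*", "\\1",
                                           term[length(term)])) else NA_integer_
  list(submitted = any(grepl("^000 ", lines)),
       executed = any(grepl("^001 ", lines)),
       evictions = sum(grepl("^004 ", lines)),
       held = length(held_lines) > 0,
       held_reason = if (length(held_lines))
         sub("^012 [0-9-]+ [0-9:]+ HELD ", "", held_lines[1]),
       exit_status = exit,
       error_text = sub("^009 [0-9-]+ [0-9:]+ ERROR ", "",
                        grep("^009 ", lines, value = TRUE)))
}

#' Package a task directory into a diagnostic archive
#'
#' Collects every file the task produced — job documents, submit
#' descriptions, logs, and any (partial) outputs — into a single gzipped
#' tar archive with a deterministic, sorted member listing, so a user can
#' inspect a failed task offline or hand-collate partial results.
#'
#' @param dir the task directory.
#' @param archive output path (default `<dir>.tar.gz`).
#' @return the archive path, invisibly.
#' @export
package_failure_bundle <- function(dir, archive = paste0(sub("/+$", "", dir), ".tar.gz")) {
  files <- sort(list.files(dir, recursive = TRUE))
  if (!length(files)) stop("no files to package in ", dir)
  withr::with_dir(dir, utils::tar(archive, files = files,
                                  compression = "gzip", tar = "internal"))
  invisible(archive)
}

# ---- notifications ----------------------------------------------------------

the_notifier <- new.env(parent = emptyenv())

#' Notify a sink that a task reached a terminal state
#'
#' Delivers exactly one notification per (task, terminal state) pair —
#' repeated calls for the same terminal event are suppressed. The sink is
#' pluggable: a function (called with the event list), a file path (one
#' YAML event appended per notification), or `NULL` (activity log only).
#' Sink failures are logged, never fatal to the task.
#'
#' @param task_id task identifier.
#' @param state terminal state: `"finished"` or `"failed"`.
#' @param sink a function, a file path, or `NULL`.
#' @param report optional [classify_failure()] report attached to failure
#'   events.
#' @return `TRUE` if a notification was delivered, `FALSE` if suppressed
#'   as a duplicate; invisibly.
#' @export
notify <- function(task_id, state = c("finished", "failed"), sink = NULL,
                   report = NULL) {
  state <- match.arg(state)
  key <- paste0(task_id, "\r", state)
  if (isTRUE(the_notifier[[key]])) return(invisible(FALSE))
  the_notifier[[key]] <- TRUE
  event <- list(task_id = task_id, state = state,
                time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                summary = if (!is.null(report))
                  paste0(report$phase, ": ", report$probable_cause))
  tryCatch({
    if (is.function(sink)) sink(event)
    else if (is.character(sink))
      cat(yaml::as.yaml(list(event)), file = sink, append = TRUE)
  }, error = function(e) {
    activity_log(paste("notification sink failed:", conditionMessage(e)))
  })
  activity_log(sprintf("[%s] notification: task %s", task_id, state))
  invisible(TRUE)
}

#' Forget delivered notifications (mainly for tests)
#' @return invisibly, `NULL`.
#' @export
reset_notifications <- function() {
  rm(list = ls(the_notifier), envir = the_notifier)
  invisible(NULL)
}
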