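#' Global configuration
#'
#' Site-wide settings, normally read from a YAML document: the
#' load-balancing target `t_target` (seconds; an administrator knob), the
#' backend settings, the working directory under which per-task directories
#' are created, the notification sink, the SD divisor used by ensemble
#' collation, and the activity-log path. Unknown keys are rejected.
#'
#' @param path YAML file; `NULL` yields the defaults.
#' @return a `global_config` list with elements `t_target`, `backend`
#'   (a [backend_config()]), `work_dir`, `notification_sink`,
#'   `sd_divisor`, `log_path`.
#' @export
read_global_config <- function(path = NULL) {
  defaults <- list(t_target = 900, max_parallel = 1L, backend = "local_pool",
                   eviction_rate = 0, poll_interval = 5,
                   work_dir = file.path(tempdir(), "taskfarm"),
                   notification_sink = NULL, sd_divisor = "sample",
                   log_path = NULL)
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(validation_error(paste("unknown configuration keys:",
                                paste(unknown, collapse = ", "))))
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$sd_divisor %in% c("sample", "population"))
    stop(validation_error("sd_divisor must be 'sample' or 'population'"))
  stopifnot(cfg$t_target > 0)
  structure(list(
    t_target = cfg$t_target,
    backend = backend_config(cfg$backend, max_parallel = cfg$max_parallel,
                             eviction_rate = cfg$eviction_rate,
                             poll_interval = cfg$poll_interval),
    work_dir = cfg$work_dir,
    notification_sink = cfg$notification_sink,
    sd_divisor = cfg$sd_divisor,
    log_path = cfg$log_path), class = "global_config")
}

the_log <- new.env(parent = emptyenv())

#' Route the activity log
#'
#' Every action — submissions, lifecycle events, errors, notifications —
#' is appended as a timestamped line to this file.
#'
#' @param path log file, or `NULL` to disable file logging.
#' @return the previous path, invisibly.
#' @export
set_activity_log <- function(path) {
  old <- the_log$path
  the_log$path <- path
  invisible(old)
}

activity_log <- function(text) {
  if (is.null(the_log$path)) return(invisible())
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), text, "\n",
      file = the_log$path, append = TRUE)
  invisible()
}
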