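#' Pool per-job partial moments into an ensemble summary
#'
#' Jobs of a stochastic-simulation-repeat task ship partial moments — for
#' every time point and species the repeat count n, the sum of amounts, and
#' the sum of squared amounts — rather than raw repeats, so transfer size
#' stays bounded for million-repeat ensembles while the merge remains
#' exact. This function pools those moments across jobs: the pooled mean is
#' sum of sums over total n, and the standard deviation is computed from
#' the pooled sums (sample SD, divisor n - 1, by default; the population
#' divisor n is available via `sd_divisor`). Any partition of the same
#' repeats yields identical output.
#'
#' @param chunk_summaries a list of per-job moment tables (tibbles with
#'   columns `time`, `species`, `n`, `sum`, `sumsq`), e.g. read from the
#'   job output files with [collate_ensemble()].
#' @param sd_divisor `"sample"` (n - 1) or `"population"` (n).
#' @return an `ensemble_summary`: tibble with columns `time`, `species`,
#'   `n`, `mean`, `sd` (`sd` is 0 where n = 1).
#' @export
summarize_ensemble <- function(chunk_summaries, sd_divisor = c("sample", "population")) {
  sd_divisor <- match.arg(sd_divisor)
  stopifnot(length(chunk_summaries) > 0)
  ref <- chunk_summaries[[1]][, c("time", "species")]
  for (i in seq_along(chunk_summaries)) {
    if (!isTRUE(all.equal(chunk_summaries[[i]][, c("time", "species")], ref,
                          check.attributes = FALSE)))
      stop("collation error: job ", i, " has a mismatched time grid or species order")
  }
  pooled <- dplyr::bind_rows(chunk_summaries) |>
    dplyr::group_by(.data$time, .data$species) |>
    dplyr::summarise(n = sum(.data$n), sum = sum(.data$sum),
                     sumsq = sum(.data$sumsq), .groups = "drop") |>
    dplyr::mutate(
      mean = .data$sum / .data$n,
      ss = pmax(.data$sumsq - .data$sum^2 / .data$n, 0),
      sd = dplyr::if_else(.data$n > 1,
        sqrt(.data$ss / (if (sd_divisor == "sample") .data$n - 1 else .data$n)),
        0)) |>
    dplyr::select("time", "species", "n", "mean", "sd") |>
    dplyr::arrange(match(.data$species, unique(ref$species)), .data$time)
  structure(pooled, class = c("ensemble_summary", class(pooled)))
}

#' Collate the ensemble summary of a completed stochastic-repeat bundle
#'
#' Reads every completed job's moment file from the task directory, pools
#' them with [summarize_ensemble()], and writes the summary TSV
#' (`Time`, then one mean and one SD column per species).
#'
#' @param bundle a completed `job_bundle` of type `stochastic_repeat`.
#' @param dir task directory.
#' @param sd_divisor see [summarize_ensemble()].
#' @return the `ensemble_summary`, invisibly writing
#'   `<dir>/ensemble_summary.tsv`.
#' @export
collate_ensemble <- function(bundle, dir = bundle$dir,
                             sd_divisor = c("sample", "population")) {
  done <- bundle$jobs$state == "completed"
  if (!all(done))
    stop("collation error: jobs not completed: ",
         paste(bundle$jobs$job_index[!done], collapse = ", "))
  chunks <- purrr::map(file.path(dir, bundle$jobs$output_file), read_moments_tsv)
  summ <- summarize_ensemble(chunks, sd_divisor = match.arg(sd_divisor))
  wide <- tidyr::pivot_wider(summ, id_cols = "time", names_from = "species",
                             values_from = c("mean", "sd"),
                             names_glue = "{species}.{.value}")
  names(wide)[1] <- "Time"
  utils::write.table(wide, file.path(dir, "ensemble_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summ)
}

#' Concatenate scan chunk outputs into the serial-run file
#'
#' Joins the per-chunk TSV outputs in job order: one header plus all data
#' rows. Because chunks are contiguous, non-overlapping subranges of the
#' grid, the result is identical — byte for byte, for deterministic
#' subtasks — to the file a serial run of the whole scan would have
#' produced.
#'
#' @param chunk_files paths ordered by job index.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
concatenate_scan_outputs <- function(chunk_files, path) {
  missing <- which(!file.exists(chunk_files))
  if (length(missing))
    stop("collation error: missing chunk outputs for jobs ",
         paste(missing - 1L, collapse = ", "))
  pieces <- lapply(chunk_files, readLines)
  header <- pieces[[1]][1]
  for (i in seq_along(pieces)) {
    if (pieces[[i]][1] != header)
      stop("collation error: job ", i - 1L, " has a mismatched header")
  }
  body <- unlist(lapply(pieces, function(x) x[-1]))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Select the best of repeated optimization results
#'
#' @param results a non-empty list of `opt_result` objects (or a tibble of
#'   per-repeat rows with a `best_value` column).
#' @param direction `"minimize"` or `"maximize"`.
#' @return the extremal element; ties are broken by the lowest position
#'   (i.e. lowest job/repeat index).
#' @export
select_best <- function(results, direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  if (is.data.frame(results)) {
    stopifnot(nrow(results) > 0)
    v <- results$best_value
    i <- if (direction == "minimize") which.min(v) else which.max(v)
    return(results[i, , drop = FALSE])
  }
  stopifnot(length(results) > 0)
  v <- vapply(results, `[[`, 1, "best_value")
  i <- if (direction == "minimize") which.min(v) else which.max(v)
  results[[i]]
}

#' Algorithms within tolerance of the best value
#'
#' @param results named list (or tibble with `algorithm` and `best_value`)
#'   of one result per algorithm.
#' @param direction `"minimize"` or `"maximize"`.
#' @param tolerance non-negative; 0 (the default) keeps exact ties only.
#' @return character vector of winning algorithm names.
#' @export
best_algorithms <- function(results, direction = c("minimize", "maximize"),
                            tolerance = 0) {
  direction <- match.arg(direction)
  if (is.data.frame(results)) {
    v <- stats::setNames(results$best_value, results$algorithm)
  } else {
    v <- vapply(results, `[[`, 1, "best_value")
  }
  stopifnot(length(v) > 0, !is.null(names(v)))
  best <- if (direction == "minimize") min(v) else max(v)
  names(v)[abs(v - best) <= tolerance]
}

#' Build a sensitivity report from a bundle's optimization results
#'
#' Pairs the per-parameter maximization and minimization results of a
#' global sensitivity analysis and tabulates, for each parameter, the
#' maximal and minimal sensitivity value found and the importance, defined
#' here as their range (max - min).
#'
#' @param results a tibble with columns `param`, `direction`
#'   (`"maximize"`/`"minimize"`), and `best_value` — one row per
#'   optimization job, 2 per parameter.
#' @return a `sensitivity_report` tibble: `param`, `max_value`,
#'   `min_value`, `importance`, sorted by decreasing importance.
#' @export
sensitivity_report <- function(results) {
  results <- tibble::as_tibble(results)
  if (nrow(results) %% 2 != 0)
    stop("sensitivity results must pair up (max, min) per parameter; got ",
         nrow(results), " rows")
  rep <- results |>
    tidyr::pivot_wider(id_cols = "param", names_from = "direction",
                       values_from = "best_value") |>
    dplyr::transmute(param = .data$param,
                     max_value = .data$maximize, min_value = .data$minimize,
                     importance = .data$maximize - .data$minimize) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  if (any(is.na(rep$max_value)) || any(is.na(rep$min_value)))
    stop("sensitivity results must contain both directions for every parameter")
  structure(rep, class = c("sensitivity_report", class(rep)))
}

#' Collate a completed bundle into its task's final artifacts
#'
#' Produces exactly what a serial run would have: an ensemble summary TSV
#' for stochastic repeats; the concatenated scan file; the best result plus
#' a model document with the winning parameters substituted for
#' optimization and estimation repeats and algorithm sweeps; the
#' sensitivity table for sensitivity tasks. Raw-mode outputs are left for
#' the user to collate.
#'
#' @param bundle a completed `job_bundle`.
#' @param dir task directory.
#' @return a list of collated results (content depends on the task type).
#' @export
collate_task <- function(bundle, dir = bundle$dir) {
  task <- bundle$task
  st <- poll_states(bundle)
  if (st$task_state == "error")
    stop("cannot collate a task in the error state; see classify_failure()")
  out_paths <- file.path(dir, bundle$jobs$output_file)
  switch(task$task_type,
    stochastic_repeat = list(ensemble = collate_ensemble(bundle, dir)),
    scan = {
      path <- file.path(dir, "scan_output.tsv")
      concatenate_scan_outputs(out_paths, path)
      list(scan_file = path)
    },
    sensitivity = {
      rows <- dplyr::bind_rows(lapply(out_paths, utils::read.table,
                                      sep = "\t", header = TRUE))
      rep <- sensitivity_report(rows)
      utils::write.table(rep, file.path(dir, "sensitivity_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(report = rep)
    },
    optimization_repeat = ,
    parameter_estimation_repeat = {
      rows <- dplyr::bind_rows(lapply(out_paths, utils::read.table,
                                      sep = "\t", header = TRUE,
                                      check.names = FALSE))
      best <- select_best(rows, task$direction %||% "minimize")
      par_cols <- setdiff(names(best), c("repeat_index", "best_value"))
      winner <- set_parameters(task$model,
                               stats::setNames(as.numeric(best[1, par_cols]),
                                               par_cols))
      write_model_doc(winner, file.path(dir, "best_model.txt"))
      list(best = tibble::as_tibble(best), best_model = winner)
    },
    algorithm_sweep = {
      rows <- dplyr::bind_rows(lapply(out_paths, utils::read.table,
                                      sep = "\t", header = TRUE,
                                      check.names = FALSE))
      dirn <- task$direction %||% "minimize"
      best <- select_best(rows, dirn)
      par_cols <- setdiff(names(best), c("algorithm", "best_value"))
      winner <- set_parameters(task$model,
                               stats::setNames(as.numeric(best[1, par_cols]),
                                               par_cols))
      write_model_doc(winner, file.path(dir, "best_model.txt"))
      list(best = tibble::as_tibble(best),
           best_algorithms = best_algorithms(rows, dirn,
                                             task$tolerance %||% 0),
           best_model = winner)
    },
    raw = list(outputs = out_paths)
  )
}

#' Plot an ensemble summary
#'
#' Mean particle number per species against time, with a +/- 1 SD ribbon.
#' @param object an `ensemble_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean,
                                       colour = .data$species,
                                       fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "particle number (mean ± SD)")
}

#' Plot a sensitivity report
#'
#' One bar per parameter spanning its minimal to maximal sensitivity value.
#' @param object a `sensitivity_report`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_report <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      param = stats::reorder(.data$param, .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$param)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$min_value,
                                         xmax = .data$max_value),
                            linewidth = 3, colour = "steelblue") +
    ggplot2::labs(x = "sensitivity of target", y = NULL,
                  title = "parameter importance (max–min sensitivity)")
}
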