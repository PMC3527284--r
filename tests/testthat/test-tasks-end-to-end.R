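test_that("a stochastic repeat task runs end to end and collates", {
  cfg <- local_config()
  run <- run_task(stochastic_task(6, id = "e2e_stoch"), cfg)
  expect_equal(run$state$task_state, "finished")
  expect_true(file.exists(file.path(run$dir, "ensemble_summary.tsv")))
  expect_equal(sum(tidy(run$bundle)$state == "completed"), 6)
  expect_equal(glance(run$bundle)$n_completed, 6)
  expect_s3_class(run$usage, "usage_record")
  expect_true(file.exists(file.path(cfg$work_dir, "usage.tsv")))
  # submit descriptions were written for every job and parse back
  subs <- list.files(run$dir, pattern = "\\.sub$", full.names = TRUE)
  expect_equal(length(subs), 6)
  expect_equal(read_submit_description(subs[1])$queue_count, 1L)
})

test_that("an optimization repeat selects the best repeat and exports the model", {
  cfg <- local_config()
  run <- run_task(quadratic_task(5, id = "e2e_opt"), cfg)
  expect_equal(run$state$task_state, "finished")
  expect_equal(nrow(run$results$best), 1)
  # maximizing A(1) = 100 exp(-k) drives k to its lower bound
  expect_equal(run$results$best_model$parameters[["k"]], 0.2, tolerance = 1e-2)
  best_doc <- read_model_doc(file.path(run$dir, "best_model.txt"))
  expect_equal(best_doc$parameters, run$results$best_model$parameters)
  # best-of over all repeats equals the extremal row across job outputs
  rows <- dplyr::bind_rows(lapply(
    file.path(run$dir, run$bundle$jobs$output_file),
    utils::read.table, sep = "\t", header = TRUE))
  expect_equal(run$results$best$best_value, max(rows$best_value))
})

test_that("an algorithm sweep runs each configuration and names winners", {
  cfg <- local_config()
  task <- task_spec("algorithm_sweep", fixture_model("decay"),
                    target_spec = "A", direction = "maximize",
                    optimize_parameters = data.frame(name = "k", lower = 0.2,
                                                     upper = 3),
                    algorithms = list(
                      list(algorithm = "particle_swarm",
                           settings = list(swarm_size = 10, iterations = 20)),
                      list(algorithm = "local_search", settings = list())),
                    t_end = 1, tolerance = 0.5,
                    base_seed = 2, task_id = "e2e_sweep")
  run <- run_task(task, cfg)
  expect_equal(run$state$task_state, "finished")
  expect_equal(nrow(run$bundle$jobs), 2)
  expect_true(all(run$results$best_algorithms %in%
                    c("particle_swarm", "local_search")))
  expect_gte(length(run$results$best_algorithms), 1)
})

test_that("raw mode runs the user executable once per repeat", {
  cfg <- local_config()
  exe <- file.path(cfg$work_dir, "touch_out.sh")
  dir.create(cfg$work_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("#!/bin/sh", 'echo "repeat $2" > "$4"'), exe)
  Sys.chmod(exe, "0755")
  task <- task_spec("raw", repeat_count = 3, raw_executable = exe,
                    raw_args = "--job {job} -o {out}",
                    base_seed = 0, task_id = "e2e_raw")
  run <- run_task(task, cfg)
  expect_equal(run$state$task_state, "finished")
  outs <- file.path(run$dir, sprintf("job_%d.out", 0:2))
  expect_true(all(file.exists(outs)))
  expect_equal(readLines(outs[3]), "repeat 2")
})

test_that("a failing task yields a report, an archive, and a notification", {
  reset_notifications()
  cfg <- local_config()
  events <- list()
  cfg$notification_sink <- function(e) events[[length(events) + 1]] <<- e
  # an unparseable model document is a pre-execution failure for every job
  task <- stochastic_task(2, id = "e2e_fail")
  bundle <- split_task(task, repeats_per_job = 1)
  bundle$jobs$document <- lapply(bundle$jobs$document, function(d) {
    d$model <- "not [ a model"
    d
  })
  dir <- file.path(cfg$work_dir, "e2e_fail")
  run <- run_bundle(bundle, cfg$backend, dir)
  st <- poll_states(run)
  expect_equal(st$task_state, "error")
  rep <- classify_failure(run)
  expect_equal(rep$phase, "pre_execution")
  expect_true(notify("e2e_fail", "failed", cfg$notification_sink, report = rep))
  expect_equal(events[[1]]$state, "failed")
  archive <- package_failure_bundle(dir)
  expect_true(file.exists(archive))
})

test_that("the run is replayable: same task, same artifacts", {
  cfg1 <- local_config(); cfg2 <- local_config()
  r1 <- run_task(stochastic_task(4, id = "replay"), cfg1)
  reset_notifications()
  r2 <- run_task(stochastic_task(4, id = "replay"), cfg2)
  expect_identical(readLines(file.path(r1$dir, "ensemble_summary.tsv")),
                   readLines(file.path(r2$dir, "ensemble_summary.tsv")))
})
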