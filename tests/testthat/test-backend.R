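test_that("submit description files follow the key = value dialect", {
  dir <- withr::local_tempdir()
  ins <- file.path(dir, c("a.yml", "b.txt", "c.txt"))
  file.create(ins)
  exe <- file.path(dir, "runner"); file.create(exe)
  path <- write_submit_description(list(job_index = 0L), list(
    dir = dir, executable = exe, input_files = ins,
    arguments = "a.yml", output = "job_0.stdout", error = "job_0.stderr",
    log = "job_0.log"))
  lines <- readLines(path)
  expect_equal(sum(lines == "queue"), 1)
  expect_equal(lines[length(lines)], "queue")
  tif <- grep("^transfer_input_files", lines, value = TRUE)
  expect_equal(length(strsplit(sub(".*= ", "", tif), ", ")[[1]]), 3)
  expect_error(
    write_submit_description(list(job_index = 1L), list(
      dir = dir, executable = exe, input_files = file.path(dir, "missing.yml"))),
    "file not found.*missing.yml")
})

test_that("write -> parse -> write reproduces the submit file byte for byte", {
  dir <- withr::local_tempdir()
  ins <- file.path(dir, "job_0.yml"); file.create(ins)
  exe <- file.path(dir, "runner"); file.create(exe)
  p1 <- write_submit_description(list(job_index = 0L), list(
    dir = dir, executable = exe, input_files = ins, arguments = "job_0.yml",
    requirements = 'OpSys == "LINUX"',
    output = "o", error = "e", log = "l"))
  parsed <- read_submit_description(p1)
  dir2 <- withr::local_tempdir()
  file.create(file.path(dir2, "job_0.yml"))
  parsed$input_files <- ins # same content, rewritten elsewhere
  p2 <- write_submit_description(list(job_index = 0L),
                                 c(list(dir = dir2, executable = parsed$executable),
                                   parsed[names(parsed) != "executable"]))
  expect_identical(readLines(p2), readLines(p1))
})

test_that("the local pool honours the slot limit and completes all jobs", {
  b <- stub_task(4)
  run <- run_bundle(b, backend_config(max_parallel = 2),
                    dir = withr::local_tempdir())
  hist <- attr(run, "state_history")
  expect_true(all(vapply(hist, function(s) sum(s == "running") <= 2, TRUE)))
  expect_true(all(run$jobs$state == "completed"))
  expect_true(all(run$jobs$exit_status == 0))
  expect_true(all(file.exists(file.path(run$dir, run$jobs$output_file))))
})

test_that("evicted jobs are re-queued, restarted, and complete on attempt 2", {
  b <- stub_task(3)
  run <- run_bundle(b, backend_config(max_parallel = 3, eviction_rate = c(1, 0)),
                    dir = withr::local_tempdir())
  expect_true(all(run$jobs$state == "completed"))
  expect_true(all(run$jobs$attempts == 2L))
  # requeue conservation: attempts = evictions + 1
  evs <- vapply(run$jobs$job_index, function(i) {
    sum(grepl("^004 ", readLines(file.path(run$dir, sprintf("job_%d.log", i)))))
  }, 1)
  expect_equal(run$jobs$attempts, evs + 1L)
})

test_that("only legal lifecycle transitions are ever observed", {
  legal <- list(created = c("created", "idle"),
                idle = c("idle", "running", "held"),
                running = c("running", "completed", "evicted", "failed"),
                evicted = c("evicted", "idle"),
                held = "held", completed = "completed", failed = "failed")
  b <- stub_task(6, fail_jobs = 2)
  run <- run_bundle(b, backend_config(max_parallel = 2, eviction_rate = c(0.5, 0)),
                    dir = withr::local_tempdir())
  hist <- attr(run, "state_history")
  for (k in seq_along(hist)[-1]) {
    prev <- hist[[k - 1]]; cur <- hist[[k]]
    for (i in seq_along(prev)) expect_true(cur[i] %in% legal[[prev[i]]])
  }
})

test_that("malformed job documents are held and never execute", {
  b <- stub_task(3)
  b$jobs$document[[2]]$kind <- NULL # malformed: no task fragment
  run <- run_bundle(b, backend_config(max_parallel = 2),
                    dir = withr::local_tempdir())
  expect_equal(run$jobs$state, c("completed", "held", "completed"))
  lg <- readLines(file.path(run$dir, "job_1.log"))
  expect_true(any(grepl("^012 .* HELD", lg)))
  expect_false(any(grepl("^001 ", lg)))
  st <- poll_states(run)
  expect_equal(st$task_state, "error")
  expect_equal(st$held_jobs, 1L)
})

test_that("poll_states summarises counts and flags non-zero exits as failed", {
  b <- stub_task(3, fail_jobs = 1)
  run <- run_bundle(b, backend_config(max_parallel = 1),
                    dir = withr::local_tempdir())
  st <- poll_states(run)
  expect_equal(st$task_state, "error")
  expect_equal(st$failed_jobs, 1L)
  expect_equal(unname(st$counts[c("completed", "failed")]), c(2L, 1L))

  ok <- run_bundle(stub_task(2), backend_config(), dir = withr::local_tempdir())
  st2 <- poll_states(ok)
  expect_equal(st2$task_state, "finished")
  expect_equal(unname(st2$counts["completed"]), 2L)
})

test_that("parallel execution writes the same bytes as a serial run", {
  t <- stochastic_task(6, t_end = 1, n_points = 4)
  serial <- run_bundle(split_task(t, repeats_per_job = 2),
                       backend_config(max_parallel = 1),
                       dir = withr::local_tempdir())
  wide <- run_bundle(split_task(t, repeats_per_job = 2),
                     backend_config(max_parallel = 3),
                     dir = withr::local_tempdir())
  for (f in serial$jobs$output_file) {
    expect_identical(readLines(file.path(wide$dir, f)),
                     readLines(file.path(serial$dir, f)))
  }
})
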