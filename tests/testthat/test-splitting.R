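sens_task <- function(p) {
  bd <- fixture_model("birth_death")
  pars <- data.frame(name = rep(names(bd$parameters), length.out = p),
                     lower = 1, upper = 2)
  pars$name <- paste0(pars$name, seq_len(p)) # distinct names
  m <- bd
  m$parameters <- c(m$parameters, stats::setNames(rep(1.5, p), pars$name))
  task_spec("sensitivity", m, target_spec = "A",
            sensitivity_parameters = pars, base_seed = 0, task_id = "sens")
}

test_that("sensitivity splitting makes two ordered jobs per parameter", {
  for (p in c(30, 10, 27, 1)) {
    b <- split_sensitivity(sens_task(p))
    expect_equal(nrow(b$jobs), 2 * p)
    expect_equal(b$jobs$direction[1:2], c("maximize", "minimize"))
    expect_equal(b$jobs$param[1:2], rep(b$jobs$param[1], 2))
    expect_equal(b$jobs$job_index, 0:(2 * p - 1))
  }
  bad <- sens_task(1)
  bad$sensitivity_parameters <- bad$sensitivity_parameters[0, ]
  expect_error(split_sensitivity(bad), "non-empty")
})

test_that("repeat splitting packs ceil(n/r) jobs with the remainder last", {
  b <- split_repeats(stochastic_task(10), 3)
  expect_equal(b$jobs$assigned_repeats, c(3, 3, 3, 1))
  b <- split_repeats(stochastic_task(1500), 3)
  expect_equal(nrow(b$jobs), 500)
  expect_true(all(b$jobs$assigned_repeats == 3))
  b <- split_repeats(stochastic_task(7), 1)
  expect_equal(b$jobs$assigned_repeats, rep(1, 7))
  expect_error(split_repeats(stochastic_task(5), 0), "repeats_per_job")
})

test_that("repeat assignments partition the requested repeats exactly", {
  for (case in list(c(10, 3), c(17, 5), c(100, 7), c(5, 9))) {
    b <- split_repeats(stochastic_task(case[1]), case[2])
    expect_equal(sum(b$jobs$assigned_repeats), case[1])
    offs <- vapply(b$jobs$document, function(d) d$repeat_offset, 1)
    reps <- vapply(b$jobs$document, function(d) d$assigned_repeats, 1)
    covered <- unlist(purrr::map2(offs, reps, function(o, r) o + seq_len(r) - 1))
    expect_equal(sort(covered), 0:(case[1] - 1))
  }
})

scan_task <- function(n) {
  task_spec("scan", fixture_model("decay"),
            scan_grid = scan_grid_range(k = c(0.1, 2, n)),
            scan_subtask = "time_course", t_end = 1, n_points = 3,
            base_seed = 2, task_id = "scan")
}

test_that("scan chunks balance sizes and reconstruct the grid in order", {
  b <- split_scan(scan_task(100), 4)
  expect_equal(b$jobs$subrange_end - b$jobs$subrange_start, rep(25, 4))
  b <- split_scan(scan_task(10), 3)
  expect_equal(b$jobs$subrange_end - b$jobs$subrange_start, c(4, 3, 3))

  grid <- materialize_grid(scan_task(10)$scan_grid)
  rebuilt <- dplyr::bind_rows(lapply(b$jobs$document, function(d) d$values))
  expect_equal(tibble::as_tibble(rebuilt), grid)
  expect_warning(b2 <- split_scan(scan_task(3), 5), "clamped")
  expect_equal(nrow(b2$jobs), 3)
})

test_that("random scan grids are materialized once, deterministically", {
  spec <- scan_grid_random(k = c(0.5, 1.5), n = 8)
  g1 <- materialize_grid(spec, seed = 9)
  g2 <- materialize_grid(spec, seed = 9)
  expect_identical(g1, g2)
  expect_true(all(g1$k >= 0.5 & g1$k <= 1.5))
  expect_equal(nrow(g1), 8)
})

test_that("algorithm sweeps get one job per configuration, in order", {
  base <- list(target_spec = "A",
               optimize_parameters = data.frame(name = "k", lower = 0.5, upper = 2),
               t_end = 1)
  mk <- function(algs) do.call(task_spec, c(
    list("algorithm_sweep", fixture_model("decay"), algorithms = algs,
         base_seed = 0, task_id = "sweep"), base))
  algs5 <- list(
    list(algorithm = "particle_swarm", settings = list(swarm_size = 4, iterations = 2)),
    list(algorithm = "particle_swarm", settings = list(swarm_size = 6, iterations = 2)),
    list(algorithm = "particle_swarm", settings = list(swarm_size = 8, iterations = 2)),
    list(algorithm = "local_search", settings = list(max_evaluations = 50)),
    list(algorithm = "local_search", settings = list(max_evaluations = 60)))
  b <- split_algorithm_sweep(mk(algs5))
  expect_equal(nrow(b$jobs), 5)
  expect_equal(b$jobs$algorithm,
               vapply(algs5, `[[`, "", "algorithm"))
  b2 <- split_algorithm_sweep(mk(algs5[1:2]))
  expect_equal(nrow(b2$jobs), 2)
  expect_error(mk(list()), "non-empty")
  expect_error(mk(algs5[c(1, 1)]), "duplicate")
})

test_that("raw mode substitutes the template and makes one job per repeat", {
  mk <- function(n, tmpl = "--seed {job} -o {out}")
    task_spec("raw", repeat_count = n, raw_executable = "true",
              raw_args = tmpl, base_seed = 0, task_id = "raw")
  b <- split_raw(mk(5))
  expect_equal(nrow(b$jobs), 5)
  expect_equal(b$jobs$document[[3]]$arguments, "--seed 2 -o job_2.out")
  expect_equal(nrow(split_raw(mk(1))$jobs), 1)
  expect_error(mk(3, "--seed {job}"), "\\{out\\}")
})

test_that("splitting is deterministic and seeds/documents are self-contained", {
  t <- stochastic_task(10)
  b1 <- split_task(t, repeats_per_job = 3)
  b2 <- split_task(t, repeats_per_job = 3)
  expect_identical(b1$jobs, b2$jobs)
  expect_equal(b1$jobs$seed, t$base_seed + b1$jobs$job_index)
  doc <- b1$jobs$document[[2]]
  expect_equal(doc$seed, b1$jobs$seed[2])
  expect_equal(doc$output, "job_1.out.tsv")
  expect_true(!is.null(doc$model))
})

test_that("job documents survive the YAML round trip", {
  b <- split_task(quadratic_task(4), repeats_per_job = 2)
  dir <- withr::local_tempdir()
  b <- write_job_documents(b, dir)
  doc <- read_job_document(file.path(dir, "job_1.yml"))
  orig <- b$jobs$document[[2]]
  expect_equal(doc$kind, orig$kind)
  expect_equal(doc$repeat_offset, orig$repeat_offset)
  expect_equal(tibble::as_tibble(doc$bounds), tibble::as_tibble(orig$bounds))
  expect_equal(read_model_doc(doc$model)$parameters,
               read_model_doc(orig$model)$parameters)
})
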