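moments_of <- function(mat, time = seq_len(nrow(mat)) - 1, species = "A") {
  # per-chunk partial moments from a (time x repeats) matrix of values
  tibble::tibble(time = time, species = species, n = ncol(mat),
                 sum = rowSums(mat), sumsq = rowSums(mat^2))
}

test_that("pooled moments reproduce textbook means and SDs", {
  five <- matrix(rep(c(1, 4, 9), 5), nrow = 3)
  s <- summarize_ensemble(list(moments_of(five)))
  expect_equal(s$mean, c(1, 4, 9))
  expect_equal(s$sd, c(0, 0, 0))

  two <- matrix(c(1, 3), nrow = 1)
  s2 <- summarize_ensemble(list(moments_of(two, time = 0)))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2))
  s2p <- summarize_ensemble(list(moments_of(two, time = 0)), "population")
  expect_equal(s2p$sd, 1)

  one <- matrix(5, nrow = 2)
  s3 <- summarize_ensemble(list(moments_of(one, time = 0:1)))
  expect_equal(s3$sd, c(0, 0)) # n = 1 reports SD 0
})

test_that("any partition of the repeats pools to identical moments", {
  set.seed(99)
  reps <- matrix(rpois(20 * 1000, 7), nrow = 20) # 20 time points, 1000 repeats
  direct <- summarize_ensemble(list(moments_of(reps)))
  split10 <- summarize_ensemble(lapply(split(1:1000, rep(1:10, each = 100)),
                                       function(j) moments_of(reps[, j])))
  split100 <- summarize_ensemble(lapply(split(1:1000, rep(1:100, each = 10)),
                                        function(j) moments_of(reps[, j])))
  # single-pass oracle, independent of the pooled-moment path
  expect_equal(direct$mean, rowMeans(reps), tolerance = 1e-12)
  expect_equal(direct$sd, apply(reps, 1, stats::sd), tolerance = 1e-12)
  expect_lt(max(abs(split10$mean - direct$mean) / pmax(direct$mean, 1)), 1e-9)
  expect_lt(max(abs(split10$sd - direct$sd) / pmax(direct$sd, 1)), 1e-9)
  expect_lt(max(abs(split100$sd - direct$sd) / pmax(direct$sd, 1)), 1e-9)
  expect_true(all(direct$sd >= 0))
  expect_error(summarize_ensemble(list(moments_of(reps),
                                       moments_of(reps[1:3, , drop = FALSE]))),
               "mismatched")
})

test_that("scan concatenation restores the serial file", {
  dir <- withr::local_tempdir()
  rows <- sprintf("%d\t%g", 1:10, sqrt(1:10))
  chunks <- split(rows, rep(1:3, c(4, 3, 3)))
  files <- file.path(dir, sprintf("job_%d.out.tsv", 0:2))
  for (i in 1:3) writeLines(c("k\tvalue", chunks[[i]]), files[i])
  out <- file.path(dir, "all.tsv")
  concatenate_scan_outputs(files, out)
  expect_identical(readLines(out), c("k\tvalue", rows))

  writeLines(c("WRONG\tvalue", chunks[[3]]), files[3])
  expect_error(concatenate_scan_outputs(files, out), "mismatched header")
  unlink(files[2])
  expect_error(concatenate_scan_outputs(files, out), "missing chunk")
})

test_that("best-of selection is extremal with lowest-index tie-breaking", {
  mk <- function(v) list(best_value = v, best_parameters = c(x = v))
  res <- lapply(c(3.2, 1.1, 2.0), mk)
  expect_equal(select_best(res, "minimize")$best_value, 1.1)
  expect_equal(select_best(res, "maximize")$best_value, 3.2)
  tie <- lapply(c(1.0, 2, 1.0), mk)
  picked <- select_best(tie, "minimize")
  expect_identical(picked, tie[[1]])
  expect_identical(select_best(list(mk(7))), list(best_value = 7,
                                                  best_parameters = c(x = 7)))
  expect_error(select_best(list()), "length")
  df <- data.frame(job = 0:2, best_value = c(1, 1, 0.5))
  expect_equal(select_best(df, "minimize")$job, 2)
})

test_that("winning algorithms fall within the tolerance of the best", {
  expect_equal(best_algorithms(data.frame(algorithm = c("A", "B"),
                                          best_value = c(1, 2))), "A")
  expect_setequal(best_algorithms(data.frame(algorithm = c("A", "B"),
                                             best_value = c(1, 1))), c("A", "B"))
  expect_setequal(best_algorithms(data.frame(algorithm = c("A", "B", "C"),
                                             best_value = c(1, 1.4, 2)),
                                  tolerance = 0.5), c("A", "B"))
})

test_that("the sensitivity report ranges max over min per parameter", {
  res <- tibble::tibble(param = rep(c("p", "q", "r"), each = 2),
                        direction = rep(c("maximize", "minimize"), 3),
                        best_value = c(4, -1, 0, 0, 2.5, 1))
  rep <- sensitivity_report(res)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$importance[rep$param == "p"], 5)
  expect_equal(rep$importance[rep$param == "q"], 0)
  expect_true(all(rep$max_value >= rep$min_value))
  expect_equal(rep$param[1], "p") # sorted by importance
  expect_error(sensitivity_report(res[1:3, ]), "pair up")
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("ensemble collation writes the Time/mean/SD table", {
  t <- stochastic_task(5, t_end = 1, n_points = 3, id = "coll")
  run <- run_bundle(split_task(t, repeats_per_job = 2), backend_config(),
                    dir = withr::local_tempdir())
  summ <- collate_ensemble(run)
  expect_s3_class(summ, "ensemble_summary")
  expect_equal(unique(summ$n), 5)
  expect_true(all(summ$sd >= 0))
  header <- readLines(file.path(run$dir, "ensemble_summary.tsv"), 1)
  expect_equal(header, "Time\tA.mean\tA.sd")
  expect_s3_class(autoplot(summ), "ggplot")
})
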