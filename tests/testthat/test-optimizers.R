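quad_problem <- function(direction = "minimize") {
  opt_problem(function(x) (x[["x"]] - 3)^2,
              data.frame(name = "x", lower = 0, upper = 10), direction)
}

test_that("both algorithms find the unique quadratic minimum", {
  for (alg in c("particle_swarm", "local_search")) {
    res <- run_optimization(quad_problem(), alg,
                            settings = if (alg == "particle_swarm")
                              list(swarm_size = 20, iterations = 200) else list(),
                            seed = 1)
    expect_lt(res$best_value, 1e-6)
    expect_equal(unname(res$best_parameters), 3, tolerance = 1e-3)
  }
})

test_that("maximization drives a convex objective to the boundary", {
  res <- run_optimization(quad_problem("maximize"), "particle_swarm",
                          settings = list(swarm_size = 20, iterations = 100),
                          seed = 5)
  expect_equal(unname(res$best_parameters), 10, tolerance = 1e-6)
  expect_equal(res$best_value, 49, tolerance = 1e-6)
})

test_that("every probed point respects the bounds", {
  seen <- list()
  prob <- opt_problem(function(x) { seen[[length(seen) + 1]] <<- x; sum(x^2) },
                      data.frame(name = c("a", "b"),
                                 lower = c(-1, 2), upper = c(1, 5)))
  for (alg in c("particle_swarm", "local_search")) {
    seen <- list()
    run_optimization(prob, alg, settings = list(swarm_size = 5, iterations = 20),
                     seed = 3)
    pts <- do.call(rbind, seen)
    expect_true(all(pts[, "a"] >= -1 & pts[, "a"] <= 1))
    expect_true(all(pts[, "b"] >= 2 & pts[, "b"] <= 5))
  }
})

test_that("progress traces are monotone and end at the reported best", {
  for (alg in c("particle_swarm", "local_search")) {
    for (dirn in c("minimize", "maximize")) {
      res <- run_optimization(quad_problem(dirn), alg,
                              settings = list(swarm_size = 6, iterations = 30),
                              seed = 2)
      tr <- res$progress_trace$best_value_so_far
      if (dirn == "minimize") expect_true(all(diff(tr) <= 0))
      else expect_true(all(diff(tr) >= 0))
      expect_equal(tr[length(tr)], res$best_value)
    }
  }
})

test_that("identical seeds give identical results; unknown algorithms error", {
  a <- run_optimization(quad_problem(), "particle_swarm",
                        settings = list(swarm_size = 10, iterations = 25), seed = 11)
  b <- run_optimization(quad_problem(), "particle_swarm",
                        settings = list(swarm_size = 10, iterations = 25), seed = 11)
  expect_identical(a, b)
  expect_error(run_optimization(quad_problem(), "genetic"), "unknown algorithm")
})

test_that("optimization fails cleanly when the objective is never finite", {
  bad <- opt_problem(function(x) NaN, data.frame(name = "x", lower = 0, upper = 1))
  expect_error(run_optimization(bad, "particle_swarm",
                                settings = list(swarm_size = 4, iterations = 3),
                                seed = 1),
               "optimization failure")
})

test_that("the best of 20 seeded swarms enters the Rosenbrock basin", {
  # the global minimum of (1-x)^2 + 100 (y-x^2)^2 on [-2,2]^2 is exactly
  # (1, 1) with value 0; verified here by a grid scan at resolution 0.01
  rosen <- function(p) (1 - p[["x"]])^2 + 100 * (p[["y"]] - p[["x"]]^2)^2
  g <- seq(-2, 2, by = 0.01)
  vx <- (1 - g)^2
  best_grid <- Inf
  for (y in g) best_grid <- min(best_grid, min(vx + 100 * (y - g^2)^2))
  expect_equal(best_grid, 0, tolerance = 1e-12)

  prob <- opt_problem(rosen, data.frame(name = c("x", "y"),
                                        lower = c(-2, -2), upper = c(2, 2)))
  vals <- vapply(1:20, function(s)
    run_optimization(prob, "particle_swarm",
                     settings = list(swarm_size = 40, iterations = 300),
                     seed = s)$best_value, 1)
  expect_lt(min(vals), 1e-3)
})

test_that("tidy, glance, and the progress export describe a result", {
  res <- run_optimization(quad_problem(), "local_search", seed = 1)
  td <- tidy(res)
  expect_equal(td$term, "x")
  gl <- glance(res)
  expect_equal(gl$algorithm, "local_search")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_progress_tsv(res, path)
  expect_equal(readLines(path)[1], "step\tbest_value_so_far")
  expect_s3_class(autoplot(res), "ggplot")
})
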