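#' Define a bounded-box optimization problem
#'
#' @param objective function mapping a named parameter vector to a scalar.
#' @param bounds data frame (or tibble) with columns `name`, `lower`,
#'   `upper`; `lower < upper` for every parameter.
#' @param direction `"minimize"` or `"maximize"`.
#' @return an object of class `opt_problem`.
#' @export
opt_problem <- function(objective, bounds, direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  bounds <- tibble::as_tibble(bounds)
  stopifnot(all(c("name", "lower", "upper") %in% names(bounds)),
            all(bounds$lower < bounds$upper))
  structure(list(objective = objective, bounds = bounds, direction = direction),
            class = "opt_problem")
}

#' Run a bounded-box optimization
#'
#' Two algorithms are shipped: a stochastic global-best particle swarm
#' (`"particle_swarm"`: constriction-standard coefficients, inertia 0.729,
#' cognitive and social weights 1.494, positions clamped to the bounds,
#' fully determined by `seed`) and a deterministic local search
#' (`"local_search"`: Nelder-Mead started from the centre of the box, every
#' probed point clamped to the bounds before evaluation). Maximization is
#' implemented by negating the objective internally; reported values are on
#' the original scale.
#'
#' @param problem an [opt_problem()].
#' @param algorithm `"particle_swarm"` or `"local_search"`.
#' @param settings named list. For particle swarm: `swarm_size` (>= 2,
#'   default 20) and `iterations` (>= 1, default 100). For local search:
#'   `max_evaluations` (default 500) and `reltol` (default 1e-10).
#' @param seed integer; ignored by the deterministic algorithm but still
#'   recorded.
#' @return an `opt_result`: list with `best_value`, `best_parameters`
#'   (named, within bounds), `algorithm`, `evaluations`, and
#'   `progress_trace` (tibble `step`, `best_value_so_far`, monotone in the
#'   optimization direction).
#' @examples
#' p <- opt_problem(function(x) (x[["x"]] - 3)^2,
#'                  data.frame(name = "x", lower = 0, upper = 10))
#' run_optimization(p, "local_search", seed = 1)$best_parameters
#' @export
run_optimization <- function(problem, algorithm = c("particle_swarm", "local_search"),
                             settings = list(), seed = 1L) {
  stopifnot(inherits(problem, "opt_problem"))
  if (!is.character(algorithm) || !algorithm[1] %in% c("particle_swarm", "local_search"))
    stop("unknown algorithm: ", algorithm[1])
  algorithm <- match.arg(algorithm)
  lower <- problem$bounds$lower
  upper <- problem$bounds$upper
  nms <- problem$bounds$name
  sign <- if (problem$direction == "maximize") -1 else 1
  n_eval <- 0L
  f <- function(x) {
    x <- pmin(pmax(x, lower), upper)   # every probe respects the box
    n_eval <<- n_eval + 1L
    v <- problem$objective(stats::setNames(x, nms))
    if (!length(v) || is.na(v) || !is.finite(v)) Inf else sign * v
  }

  res <- if (algorithm == "particle_swarm") {
    st <- utils::modifyList(list(swarm_size = 20L, iterations = 100L), settings)
    stopifnot(st$swarm_size >= 2, st$iterations >= 1)
    withr::with_seed(seed, pso_gbest(f, lower, upper,
                                     swarm_size = st$swarm_size,
                                     iterations = st$iterations))
  } else {
    st <- utils::modifyList(list(max_evaluations = 500L, reltol = 1e-10), settings)
    nelder_mead_box(f, lower, upper, max_evaluations = st$max_evaluations,
                    reltol = st$reltol)
  }
  if (!is.finite(res$value))
    stop("optimization failure: objective non-finite at every probed point")

  trace <- tibble::tibble(step = seq_along(res$trace),
                          best_value_so_far = sign * res$trace)
  structure(
    list(best_value = sign * res$value,
         best_parameters = stats::setNames(pmin(pmax(res$par, lower), upper), nms),
         algorithm = algorithm, direction = problem$direction,
         evaluations = n_eval, seed = seed,
         progress_trace = trace),
    class = "opt_result"
  )
}

# global-best PSO, constriction-standard coefficients
pso_gbest <- function(f, lower, upper, swarm_size, iterations,
                      w = 0.729, c1 = 1.494, c2 = 1.494) {
  d <- length(lower)
  span <- upper - lower
  pos <- matrix(stats::runif(swarm_size * d, lower, upper),
                nrow = swarm_size, byrow = TRUE)
  vel <- matrix(stats::runif(swarm_size * d, -span, span) / 10,
                nrow = swarm_size, byrow = TRUE)
  pbest <- pos
  pbest_val <- apply(pos, 1, f)
  g <- which.min(pbest_val)
  gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(swarm_size * d), nrow = swarm_size)
    r2 <- matrix(stats::runif(swarm_size * d), nrow = swarm_size)
    vel <- w * vel +
      c1 * r1 * (pbest - pos) +
      c2 * r2 * matrix(gbest, swarm_size, d, byrow = TRUE) - c2 * r2 * pos
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lower, swarm_size, d, byrow = TRUE)),
                matrix(upper, swarm_size, d, byrow = TRUE))
    val <- apply(pos, 1, f)
    better <- val < pbest_val
    pbest[better, ] <- pos[better, , drop = FALSE]
    pbest_val[better] <- val[better]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) { gbest <- pbest[g, ]; gbest_val <- pbest_val[g] }
    trace[it] <- gbest_val
  }
  list(par = gbest, value = gbest_val, trace = trace)
}

# deterministic Nelder-Mead from the box centre; probes clamped by f itself
nelder_mead_box <- function(f, lower, upper, max_evaluations, reltol) {
  start <- (lower + upper) / 2
  best_so_far <- Inf
  trace <- numeric(0)
  g <- function(x) {
    v <- f(x)
    best_so_far <<- min(best_so_far, v)
    trace <<- c(trace, best_so_far)
    v
  }
  res <- if (length(start) == 1) {
    # Nelder-Mead is unreliable in 1-D; golden-section is the deterministic choice
    o <- stats::optimize(g, lower = lower, upper = upper, tol = reltol)
    list(par = o$minimum, value = o$objective)
  } else {
    o <- stats::optim(start, g, method = "Nelder-Mead",
                      control = list(maxit = max_evaluations, reltol = reltol))
    list(par = o$par, value = o$value)
  }
  list(par = res$par, value = best_so_far, trace = trace)
}

#' @export
print.opt_result <- function(x, ...) {
  cat("<opt_result> ", x$algorithm, " (", x$direction, "): best value ",
      signif(x$best_value, 6), " after ", x$evaluations, " evaluations\n",
      sep = "")
  cat("  parameters: ",
      paste(names(x$best_parameters), signif(x$best_parameters, 6),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy an optimization result
#'
#' One row per parameter at the optimum.
#' @param x an `opt_result`.
#' @param ... unused.
#' @return a tibble with columns `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.opt_result <- function(x, ...) {
  tibble::tibble(term = names(x$best_parameters),
                 estimate = unname(x$best_parameters))
}

#' One-row summary of an optimization result
#' @param x an `opt_result`.
#' @param ... unused.
#' @return a one-row tibble: `algorithm`, `direction`, `best_value`,
#'   `evaluations`, `seed`.
#' @exportS3Method generics::glance
glance.opt_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, direction = x$direction,
                 best_value = x$best_value, evaluations = x$evaluations,
                 seed = x$seed)
}

#' Plot the progress trace of an optimization
#'
#' Best objective value against optimizer step.
#' @param object an `opt_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.opt_result <- function(object, ...) {
  ggplot2::ggplot(object$progress_trace,
                  ggplot2::aes(x = .data$step, y = .data$best_value_so_far)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "optimizer step", y = "best objective value",
                  title = paste0(object$algorithm, " (", object$direction, ")"))
}

#' Export a progress trace as two-column TSV
#' @param result an `opt_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_progress_tsv <- function(result, path) {
  utils::write.table(result$progress_trace, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
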