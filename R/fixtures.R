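#' Built-in toy reaction networks
#'
#' A small catalog of mass-action models used throughout the package's
#' examples and tests, so every orchestration path can be exercised without
#' any external model file:
#'
#' * `"decay"` — first-order decay A -> 0 (k = 1, A(0) = 100).
#' * `"birth_death"` — immigration-death 0 -> A (k = 10), A -> 0 (d = 1);
#'   the stationary law of A is Poisson with mean and variance k/d.
#' * `"isomerization"` — reversible A <-> B (kf = 0.3, kr = 0.1,
#'   A(0) = 50); total A + B is conserved.
#' * `"dimerization"` — 2A -> B (k = 0.005, A(0) = 100), second order.
#' * `"oscillator_3var"` — a three-species mass-action relaxation
#'   oscillator (Oregonator-type: Y -> X, X + Y -> 0, X -> 2X + Z,
#'   2X -> 0, Z -> Y), standing in for oscillatory signalling models.
#'
#' @param name one of the catalog names; see [fixture_names()].
#' @return an [rn_model()].
#' @examples
#' fixture_model("birth_death")
#' @export
fixture_model <- function(name) {
  switch(name,
    decay = rn_model(
      species = c(A = 100),
      reactions = list(list(name = "decay", reactants = c(A = 1),
                            products = c(), rate = "k")),
      parameters = c(k = 1), name = "decay"),
    birth_death = rn_model(
      species = c(A = 0),
      reactions = list(
        list(name = "birth", reactants = c(), products = c(A = 1), rate = "k"),
        list(name = "death", reactants = c(A = 1), products = c(), rate = "d")),
      parameters = c(k = 10, d = 1), name = "birth_death"),
    isomerization = rn_model(
      species = c(A = 50, B = 0),
      reactions = list(
        list(name = "fwd", reactants = c(A = 1), products = c(B = 1), rate = "kf"),
        list(name = "rev", reactants = c(B = 1), products = c(A = 1), rate = "kr")),
      parameters = c(kf = 0.3, kr = 0.1), name = "isomerization"),
    dimerization = rn_model(
      species = c(A = 100, B = 0),
      reactions = list(
        list(name = "dim", reactants = c(A = 2), products = c(B = 1), rate = "k")),
      parameters = c(k = 0.005), name = "dimerization"),
    oscillator_3var = rn_model(
      species = c(X = 500, Y = 1000, Z = 2000),
      reactions = list(
        list(name = "conv",  reactants = c(Y = 1), products = c(X = 1), rate = "k1"),
        list(name = "annih", reactants = c(X = 1, Y = 1), products = c(), rate = "k2"),
        list(name = "auto",  reactants = c(X = 1), products = c(X = 2, Z = 1), rate = "k3"),
        list(name = "decay", reactants = c(X = 2), products = c(), rate = "k4"),
        list(name = "feed",  reactants = c(Z = 1), products = c(Y = 1), rate = "k5")),
      parameters = c(k1 = 2, k2 = 0.1, k3 = 104, k4 = 0.016, k5 = 26),
      name = "oscillator_3var"),
    stop("unknown fixture model: ", name)
  )
}

#' Names of the built-in fixture models
#' @return character vector of catalog names.
#' @export
fixture_names <- function() {
  c("decay", "birth_death", "isomerization", "dimerization", "oscillator_3var")
}

#' Sleep-based workload stub
#'
#' A controlled fake repeat of known duration, used to exercise the load
#' balancer and the backend's lifecycle without real simulation cost. The
#' returned function sleeps for `duration` seconds when called; `nominal_cpu`
#' is the CPU cost the stub claims for accounting tests (sleeping consumes
#' essentially no processor time).
#'
#' @param duration seconds of wall-clock per repeat.
#' @param nominal_cpu claimed CPU seconds per repeat (default = `duration`).
#' @return a function of no arguments, with attributes `duration` and
#'   `nominal_cpu`.
#' @export
workload_stub <- function(duration, nominal_cpu = duration) {
  f <- function() { Sys.sleep(duration); invisible(duration) }
  attr(f, "duration") <- duration
  attr(f, "nominal_cpu") <- nominal_cpu
  f
}

#' Generate a synthetic parameter-estimation dataset
#'
#' Simulates a catalog model deterministically, adds i.i.d. Gaussian noise
#' of the stated standard deviation to every observed amount, and returns
#' the dataset together with the generating ("true") parameter values, so
#' parameter-recovery tests can compare estimates against a known truth.
#' Generation is fully determined by `seed`.
#'
#' @param model_name a [fixture_names()] entry.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   particle-number units.
#' @param n_points number of observation times (uniform over `[0, t_end]`).
#' @param seed integer seed.
#' @param t_end observation horizon (model time units).
#' @param path optional file; when given, the dataset is also written as TSV
#'   (columns `Time` then one per observed species).
#' @return a list with `data` (tibble: `time` + species columns),
#'   `true_parameters` (named numeric), `model` (the generating
#'   [rn_model()]), `noise_sd`, and `seed`.
#' @examples
#' d <- make_estimation_dataset("decay", noise_sd = 0.01, n_points = 20, seed = 1)
#' d$true_parameters
#' @export
make_estimation_dataset <- function(model_name, noise_sd, n_points, seed,
                                    t_end = 5, path = NULL) {
  model <- fixture_model(model_name)
  stopifnot(noise_sd >= 0, n_points >= 2)
  traj <- simulate_ode(model, t_end = t_end, n_points = n_points)
  noisy <- withr::with_seed(seed, {
    vals <- as.matrix(traj[, -1, drop = FALSE])
    vals + stats::rnorm(length(vals), sd = noise_sd)
  })
  data <- dplyr::bind_cols(traj[, 1], tibble::as_tibble(as.data.frame(noisy)))
  if (!is.null(path)) write_trajectory_tsv(data, path)
  list(data = data, true_parameters = model$parameters, model = model,
       noise_sd = noise_sd, seed = seed)
}

#' Sum-of-squares objective for fitting a model to a dataset
#'
#' Builds the parameter-estimation objective used by the
#' `parameter_estimation_repeat` task type: given candidate values for the
#' named free parameters, simulate the model over the dataset's time grid
#' and return the residual sum of squares against the observed amounts.
#'
#' @param model the [rn_model()] to fit.
#' @param data a dataset tibble (`time` + observed species columns).
#' @param free_parameters character vector of parameter names to estimate.
#' @return a function: named parameter vector -> residual sum of squares.
#' @export
estimation_objective <- function(model, data, free_parameters) {
  stopifnot(all(free_parameters %in% names(model$parameters)))
  times <- data$time
  obs_species <- intersect(names(data)[-1], model$species$name)
  obs <- as.matrix(data[, obs_species, drop = FALSE])
  function(theta) {
    m <- set_parameters(model, theta[free_parameters])
    traj <- try(simulate_ode(m, t_end = max(times), n_points = length(times)),
                silent = TRUE)
    if (inherits(traj, "try-error")) return(Inf)
    sum((as.matrix(traj[, obs_species, drop = FALSE]) - obs)^2)
  }
}
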