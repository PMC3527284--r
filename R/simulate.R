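#' Deterministic time course of a reaction network
#'
#' Assembles the mass-action rate equations d[S]/dt from the stoichiometry
#' (rate of reaction j = k_j * prod over reactants n^nu, in particle-number
#' units) and integrates them with an adaptive-step solver at relative
#' tolerance 1e-8.
#'
#' @param model an [rn_model()].
#' @param t_end positive end time (model time units).
#' @param n_points number of output points (>= 2) on a uniform grid over
#'   `[0, t_end]`.
#' @return a tibble trajectory: column `time` plus one column per species,
#'   in particle-number units.
#' @examples
#' decay <- fixture_model("decay")
#' traj <- simulate_ode(decay, t_end = 1, n_points = 11)
#' tail(traj, 1) # A ~ 100 * exp(-1)
#' @export
simulate_ode <- function(model, t_end, n_points = 101) {
  validate_rn_model(model)
  stopifnot(t_end > 0, n_points >= 2)
  mats <- reaction_matrices(model)
  y0 <- stats::setNames(model$species$initial_amount, model$species$name)
  k <- vapply(model$reactions, function(r) model$parameters[[r$rate]], 1)
  if (any(!is.finite(k))) stop("non-finite rate constant")
  deriv <- function(t, y, parms) {
    rates <- k * apply_mass_action(y, mats$reactant)
    list(as.vector(mats$net %*% rates))
  }
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (nrow(out) < n_points || any(!is.finite(out)))
    stop("integration failure: non-finite state first seen near t = ",
         signif(times[min(nrow(out) + 1, n_points)], 6))
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj)[1] <- "time"
  traj
}

# reactant/net stoichiometry matrices (species x reactions)
reaction_matrices <- function(model) {
  sp <- model$species$name
  nr <- length(model$reactions)
  reactant <- matrix(0, nrow = length(sp), ncol = nr, dimnames = list(sp, NULL))
  net <- reactant
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    if (length(r$reactants)) reactant[names(r$reactants), j] <- r$reactants
    if (length(r$reactants)) net[names(r$reactants), j] <- net[names(r$reactants), j] - r$reactants
    if (length(r$products))  net[names(r$products), j]  <- net[names(r$products), j] + r$products
  }
  list(reactant = reactant, net = net)
}

# deterministic mass action: prod over reactant species of n^nu, per reaction
apply_mass_action <- function(y, reactant) {
  apply(reactant, 2, function(nu) prod(y[nu > 0]^nu[nu > 0]))
}

#' Exact stochastic time course (Gillespie direct method)
#'
#' Simulates one realization of the reaction network's jump process with the
#' direct method. Propensities use mass-action combinatorics: a reaction
#' consuming nu copies of a species with n molecules contributes
#' choose(n, nu) (so a 2A self-reaction has propensity k * n(n-1)/2). The
#' state is recorded on the uniform output grid by piecewise-constant left
#' interpolation: the value at a grid point is the state after the last event
#' at or before that time. The same `(model, t_end, n_points, seed)` always
#' yields the same trajectory.
#'
#' @inheritParams simulate_ode
#' @param seed integer seed for this realization.
#' @return a tibble trajectory: `time` plus one integer-valued column per
#'   species.
#' @export
simulate_ssa <- function(model, t_end, n_points = 101, seed) {
  validate_rn_model(model)
  stopifnot(t_end > 0, n_points >= 2)
  x0 <- model$species$initial_amount
  if (any(x0 != round(x0)))
    stop("stochastic simulation requires integer initial amounts")
  mats <- reaction_matrices(model)
  k <- vapply(model$reactions, function(r) model$parameters[[r$rate]], 1)
  nr <- length(model$reactions)
  nsp <- nrow(model$species)
  times <- seq(0, t_end, length.out = n_points)

  # per-reaction reactant index/stoichiometry lists, for fast propensities
  r_idx <- vector("list", nr); r_nu <- vector("list", nr)
  for (j in seq_len(nr)) {
    nz <- which(mats$reactant[, j] > 0)
    r_idx[[j]] <- nz
    r_nu[[j]] <- mats$reactant[nz, j]
  }
  net <- mats$net

  run <- function() {
    x <- as.numeric(x0)
    t <- 0
    out <- matrix(NA_real_, nrow = n_points, ncol = nsp)
    nxt <- 1L
    a <- numeric(nr)
    repeat {
      for (j in seq_len(nr)) {
        idx <- r_idx[[j]]
        if (length(idx) == 0) { a[j] <- k[j]; next }
        n <- x[idx]; nu <- r_nu[[j]]
        a[j] <- k[j] * prod(choose(n, nu))
      }
      a0 <- sum(a)
      t_next <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
      while (nxt <= n_points && times[nxt] < t_next) {
        out[nxt, ] <- x
        nxt <- nxt + 1L
      }
      if (nxt > n_points) break
      t <- t_next
      j <- sample.int(nr, 1L, prob = a)
      x <- x + net[, j]
    }
    out
  }
  out <- withr::with_seed(seed, run())
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- model$species$name
  dplyr::bind_cols(tibble::tibble(time = times), traj)
}

#' Evaluate a target expression on a simulated model
#'
#' The target is a text expression over species names and parameter names,
#' evaluated either at the final time of a deterministic time course or at
#' steady state (found by long-time integration until the derivative norm
#' drops below `tol`). This is the objective used by the sensitivity and
#' optimization task types.
#'
#' @param model an [rn_model()].
#' @param target_spec text expression, e.g. `"A"` or `"A + B"`.
#' @param when `"final_time"` or `"steady_state"`.
#' @param t_end end time for `when = "final_time"` (also the initial horizon
#'   for steady-state search).
#' @param tol derivative max-norm below which the state counts as steady.
#' @param max_doublings steady-state search cap: the horizon is doubled at
#'   most this many times before giving up.
#' @return the scalar value of the expression.
#' @export
evaluate_target <- function(model, target_spec, when = c("final_time", "steady_state"),
                            t_end = 10, tol = 1e-9, max_doublings = 20) {
  when <- match.arg(when)
  expr <- parse_target(target_spec, model)
  if (when == "final_time") {
    traj <- simulate_ode(model, t_end = t_end, n_points = 2)
    state <- as.list(traj[nrow(traj), -1, drop = FALSE])
  } else {
    state <- steady_state(model, t_end0 = t_end, tol = tol,
                          max_doublings = max_doublings)
  }
  eval(expr, envir = c(state, as.list(model$parameters)))
}

parse_target <- function(target_spec, model) {
  expr <- str2lang(target_spec)
  ok <- c(model$species$name, names(model$parameters),
          "+", "-", "*", "/", "^", "(", "sqrt", "log", "exp", "abs")
  for (v in all.names(expr)) {
    if (!v %in% ok) stop("target expression references undefined name: ", v)
  }
  expr
}

steady_state <- function(model, t_end0 = 10, tol = 1e-9, max_doublings = 20) {
  mats <- reaction_matrices(model)
  k <- vapply(model$reactions, function(r) model$parameters[[r$rate]], 1)
  deriv_norm <- function(y) {
    rates <- k * apply_mass_action(y, mats$reactant)
    max(abs(as.vector(mats$net %*% rates)))
  }
  t_end <- t_end0
  m <- model
  for (i in seq_len(max_doublings + 1)) {
    traj <- simulate_ode(m, t_end = t_end, n_points = 2)
    y <- unlist(traj[nrow(traj), -1, drop = FALSE])
    if (deriv_norm(y) < tol) return(as.list(y))
    # restart from the endpoint with a doubled horizon
    m$species$initial_amount <- unname(y[m$species$name])
    t_end <- t_end * 2
  }
  stop("no steady state reached within iteration cap (derivative norm ",
       signif(deriv_norm(y), 3), " after ", max_doublings, " doublings)")
}

# ---- trajectory text I/O ----------------------------------------------------

#' Write a trajectory as tab-separated text
#'
#' First column `Time`, one column per species — the dialect all downstream
#' collation consumes.
#'
#' @param traj a trajectory tibble (column `time` first).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  out <- traj
  names(out)[1] <- "Time"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_tsv()]
#' @param path file to read.
#' @return a trajectory tibble with column `time` first.
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  names(df)[1] <- "time"
  tibble::as_tibble(df)
}
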