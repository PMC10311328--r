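#' Logarithmic recording grid
#'
#' The grids used for trajectory recording are \{0\} plus logarithmically
#' uniform points between \code{t_min} and \code{t_end} — dense at early
#' times where the dynamics away from a deterministic start are fastest.
#'
#' @param t_end Final time (s).
#' @param t_min First positive grid time (s); default 1e-3.
#' @param points Total number of grid points including 0 (default 1001).
#' @return An object of class \code{"time_grid"} with elements
#'   \code{points} (the times) and \code{count}.
#' @export
time_grid <- function(t_end, t_min = 1e-3, points = 1001L) {
  stopifnot(t_end > t_min, t_min > 0, points >= 2)
  pts <- c(0, exp(seq(log(t_min), log(t_end), length.out = points - 1L)))
  pts[length(pts)] <- t_end  # exact endpoint, no round-off
  structure(list(points = pts, count = length(pts)), class = "time_grid")
}

system_codes <- function(system) {
  kinds <- c(constant = 0L, linear = 1L, pure_quadratic = 2L,
             mass_action_2 = 3L)
  list(
    nu = vapply(system$reactions, `[[`, integer(1), "nu"),
    kind = unname(kinds[vapply(system$reactions, `[[`, character(1), "kind")]),
    rate = vapply(system$reactions, `[[`, numeric(1), "rate"),
    guard = vapply(system$reactions, function(r)
      if (is.null(r$guard_min)) 0L else r$guard_min, integer(1)))
}

#' Simulate one SSA trajectory
#'
#' Standard direct method: in state x, the waiting time to the next reaction
#' is exponential with rate equal to the total propensity
#' \eqn{\lambda = \sum_j a_j(x)} (mean \eqn{1/\lambda}), and reaction j fires
#' with probability \eqn{a_j(x)/\lambda}. Simulation stops when the next
#' waiting-time draw would cross \code{t_end} (that crossing draw is counted
#' in \code{draw_count}) or when \code{cap} reactions have been committed
#' (\code{capped = TRUE}). If the total propensity is zero the trajectory
#' rests at its state with \code{draw_count = 0}.
#'
#' @param system A \code{\link{reaction_system}}.
#' @param x0 Nonnegative integer initial state.
#' @param t_end Simulated time horizon (s).
#' @param cap Maximum number of committed reactions (default 10000).
#' @param seed Integer seed.
#' @return An object of class \code{"trajectory"}: \code{times} and
#'   \code{states} after each event, \code{x0}, \code{draw_count},
#'   \code{capped}, \code{seed}.
#' @export
simulate_trajectory <- function(system, x0, t_end, cap = 10000L, seed) {
  if (x0 < 0) stop("'x0' must be nonnegative")
  stopifnot(t_end > 0, cap >= 1)
  sc <- system_codes(system)
  set.seed(seed)
  res <- ssa_simulate_cpp(sc$nu, sc$kind, sc$rate, sc$guard,
                          as.integer(x0), t_end, as.integer(cap))
  structure(list(times = res$times, states = res$states,
                 x0 = as.integer(x0), t_end = t_end,
                 draw_count = res$draw_count, capped = res$capped,
                 seed = as.integer(seed)),
            class = "trajectory")
}

#' Evaluate a trajectory on a time grid
#'
#' Right-continuous piecewise-constant evaluation: the state at grid time t
#' is the state after the last event at or before t.
#'
#' @param traj A \code{trajectory}.
#' @param times Numeric times.
#' @return Integer states at \code{times}.
#' @export
trajectory_on_grid <- function(traj, times) {
  st <- c(traj$x0, traj$states)
  st[findInterval(times, c(0, traj$times))]
}

#' Simulate an ensemble of SSA trajectories
#'
#' Trajectory i uses seed \code{base_seed + i}, giving independent,
#' reproducible, order-independent streams. Capped trajectories are retained
#' with their last pre-cap state carried forward on the grid and flagged —
#' never silently dropped; downstream estimators exclude them with an
#' explicit count.
#'
#' @param system A \code{\link{reaction_system}}.
#' @param x0 Initial state.
#' @param t_end Time horizon (s).
#' @param n Number of trajectories.
#' @param grid A \code{\link{time_grid}} (default: 1001-point log grid on
#'   \code{[1e-3, t_end]}).
#' @param cap Reaction cap per trajectory.
#' @param base_seed Integer base seed.
#' @return An object of class \code{"ensemble"}: the grid, an
#'   \code{n x count} state matrix \code{states_on_grid}, per-trajectory
#'   \code{draw_counts}, \code{final_states}, \code{capped}, cap-hit times
#'   \code{cap_times} (NA when uncapped), and the configuration.
#' @export
run_ensemble <- function(system, x0, t_end, n, grid = time_grid(t_end),
                         cap = 10000L, base_seed = 1L) {
  stopifnot(n >= 1, inherits(grid, "time_grid"))
  G <- grid$count
  states <- matrix(NA_integer_, nrow = n, ncol = G)
  draw_counts <- integer(n)
  capped <- logical(n)
  cap_times <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- simulate_trajectory(system, x0, t_end, cap, seed = base_seed + i)
    states[i, ] <- trajectory_on_grid(tr, grid$points)
    draw_counts[i] <- tr$draw_count
    capped[i] <- tr$capped
    if (tr$capped) cap_times[i] <- tr$times[length(tr$times)]
  }
  structure(list(system_name = system$name, grid = grid,
                 states_on_grid = states, draw_counts = draw_counts,
                 final_states = states[, G], capped = capped,
                 cap_times = cap_times, x0 = as.integer(x0), t_end = t_end,
                 n = as.integer(n), cap = as.integer(cap),
                 base_seed = as.integer(base_seed)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "ensemble: system '%s', n = %d, t_end = %g s, cap = %d (%d capped)\n",
    x$system_name, x$n, x$t_end, x$cap, sum(x$capped)))
  invisible(x)
}

#' Escape times of capped trajectories
#'
#' For explosive systems the reaction cap acts as an escape proxy: a
#' trajectory that hits the cap has, for practical purposes, escaped to
#' large molecule numbers in finite time. Returns, per trajectory, the time
#' of the cap-hitting event, censored at \code{t_end} when the horizon
#' arrived before the cap.
#'
#' @param ensemble An \code{\link{run_ensemble}} result simulated with a cap.
#' @return Data frame with columns \code{time} and \code{censored}.
#' @export
escape_times <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  data.frame(
    time = ifelse(ensemble$capped, ensemble$cap_times, ensemble$t_end),
    censored = !ensemble$capped)
}

#' Persist an ensemble as plain-text tables
#'
#' Writes (a) \code{grid.csv}: rows = trajectories, columns = grid times
#' (header row of times); (b) \code{trajectories.csv}: per-trajectory seed,
#' draw_count, final_state, capped; (c) \code{meta.json}: system, n, cap,
#' base_seed, t_end, x0.
#'
#' @param ensemble An ensemble.
#' @param dir Output directory (created if missing).
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gridm <- ensemble$states_on_grid
  colnames(gridm) <- format(ensemble$grid$points, digits = 10, trim = TRUE)
  utils::write.csv(gridm, file.path(dir, "grid.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    seed = ensemble$base_seed + seq_len(ensemble$n),
    draw_count = ensemble$draw_counts,
    final_state = ensemble$final_states,
    capped = ensemble$capped),
    file.path(dir, "trajectories.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    system = ensemble$system_name, n = ensemble$n, cap = ensemble$cap,
    base_seed = ensemble$base_seed, t_end = ensemble$t_end,
    x0 = ensemble$x0),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
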