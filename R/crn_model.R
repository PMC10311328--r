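#' One-species reaction networks
#'
#' A reaction in a one-species network is a state change \code{nu} (+1 or -1
#' for every system studied here), a propensity form, a nonnegative rate
#' constant and an optional lower guard below which the propensity is zero.
#' Supported propensity forms:
#' \describe{
#'   \item{\code{constant}}{a(x) = c (zeroth order, e.g. immigration)}
#'   \item{\code{linear}}{a(x) = c x (first order, e.g. degradation)}
#'   \item{\code{pure_quadratic}}{a(x) = c x^2 (idealized second order)}
#'   \item{\code{mass_action_2}}{a(x) = c x (x - 1) (mass-action second
#'     order: the number of ordered educt pairs)}
#' }
#'
#' @param nu Integer state change when the reaction fires.
#' @param kind Propensity form, one of \code{"constant"}, \code{"linear"},
#'   \code{"pure_quadratic"}, \code{"mass_action_2"}.
#' @param rate Nonnegative rate constant (1/s).
#' @param guard_min Optional integer; the propensity is forced to 0 for
#'   states \code{x < guard_min}.
#' @return An object of class \code{"reaction"}.
#' @export
reaction <- function(nu, kind = c("constant", "linear", "pure_quadratic",
                                  "mass_action_2"),
                     rate, guard_min = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(nu), length(nu) == 1L, nu == round(nu))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("'rate' must be a single nonnegative finite number")
  if (!is.null(guard_min)) {
    stopifnot(is.numeric(guard_min), length(guard_min) == 1L,
              guard_min == round(guard_min))
    guard_min <- as.integer(guard_min)
  }
  structure(list(nu = as.integer(nu), kind = kind, rate = rate,
                 guard_min = guard_min),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  form <- switch(x$kind,
    constant = "c", linear = "c*x",
    pure_quadratic = "c*x^2", mass_action_2 = "c*x*(x-1)")
  guard <- if (is.null(x$guard_min)) "" else sprintf(" [x>=%d]", x$guard_min)
  cat(sprintf("reaction: nu=%+d  a(x)=%s%s  c=%g\n", x$nu, form, guard, x$rate))
  invisible(x)
}

#' @param name Label for the system.
#' @param reactions List of \code{reaction} objects.
#' @rdname reaction
#' @export
reaction_system <- function(name, reactions) {
  stopifnot(is.character(name), length(name) == 1L, length(reactions) >= 1L)
  if (!all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("'reactions' must be a list of reaction objects")
  structure(list(name = name, reactions = reactions, species_count = 1L),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system '%s' (%d reactions, 1 species)\n",
              x$name, length(x$reactions)))
  for (r in x$reactions) print(r)
  invisible(x)
}

#' Evaluate a propensity
#'
#' @param reaction A \code{reaction}.
#' @param x Nonnegative integer state (vectorized).
#' @return Nonnegative propensity value(s).
#' @export
propensity <- function(reaction, x) {
  if (any(x < 0)) stop("state 'x' must be nonnegative")
  a <- switch(reaction$kind,
    constant       = rep(reaction$rate, length(x)),
    linear         = reaction$rate * x,
    pure_quadratic = reaction$rate * x^2,
    mass_action_2  = reaction$rate * x * (x - 1))
  if (!is.null(reaction$guard_min)) a[x < reaction$guard_min] <- 0
  a
}

#' Total propensity of a system at a state
#'
#' @param system A \code{reaction_system}.
#' @param x Nonnegative integer state (vectorized).
#' @export
total_propensity <- function(system, x) {
  Reduce(`+`, lapply(system$reactions, propensity, x = x))
}

#' Construct the benchmark systems
#'
#' \describe{
#'   \item{\code{"P"}}{immigration-death benchmark: birth at constant rate 10,
#'     death at rate x. Converges to Poisson(10).}
#'   \item{\code{"W"}}{fat-tailed quadratic birth-death network:
#'     2A -> A and 2A -> 3A with mass-action x(x-1) propensities at unit rate,
#'     plus constant immigration at unit rate. Its stationary law approaches
#'     the discrete inverse-square distribution; no moments exist there.}
#'   \item{\code{"ideal"}}{the idealized quadratic system with pure x^2
#'     propensities: death guarded by [x >= 2], birth unguarded; with
#'     c1 = c2 = 1 the inverse-square pmf satisfies its stationary balance
#'     exactly.}
#'   \item{\code{"pure_growth"}}{a single birth reaction with quadratic
#'     propensity x^2 (the "ideal" system with c1 = 0): every trajectory
#'     explodes in finite time.}
#' }
#'
#' @param name One of \code{"P"}, \code{"W"}, \code{"ideal"},
#'   \code{"pure_growth"}.
#' @param c1,c2 Rate constants for the \code{"ideal"} system (death/birth).
#' @return A \code{reaction_system}.
#' @export
build_system <- function(name, c1 = 1, c2 = 1) {
  switch(name,
    P = reaction_system("P", list(
      reaction(+1, "constant", 10),
      reaction(-1, "linear", 1))),
    W = reaction_system("W", list(
      reaction(-1, "mass_action_2", 1),
      reaction(+1, "mass_action_2", 1),
      reaction(+1, "constant", 1))),
    ideal = reaction_system("ideal", list(
      reaction(-1, "pure_quadratic", c1, guard_min = 2L),
      reaction(+1, "pure_quadratic", c2))),
    pure_growth = reaction_system("pure_growth", list(
      reaction(+1, "pure_quadratic", 1))),
    stop("unknown system name: ", name))
}

#' Discrete probability mass tables
#'
#' A \code{pmf} pairs an integer support with probabilities. Probabilities
#' must be nonnegative and sum to at most 1 (a truncated table of an
#' infinite-support law is fine).
#'
#' @param k Integer support values.
#' @param p Probabilities.
#' @export
pmf_table <- function(k, p) {
  stopifnot(length(k) == length(p), all(k == round(k)), !anyDuplicated(k))
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (sum(p) > 1 + 1e-12) stop("probabilities sum to more than 1")
  structure(list(k = as.integer(k), p = as.numeric(p)), class = "pmf")
}

pmf_lookup <- function(pmf, k) {
  idx <- match(k, pmf$k)
  if (anyNA(idx))
    stop("pmf is not defined at state(s): ",
         paste(k[is.na(idx)], collapse = ", "))
  pmf$p[idx]
}

#' Stationary balance residual of the master equation
#'
#' Evaluates the steady-state condition of the chemical master equation at a
#' state \code{x}: the probability inflow minus outflow,
#' \deqn{\sum_j a_j(x - \nu_j)\,\bar P(x - \nu_j) - \sum_j a_j(x)\,\bar P(x),}
#' which is zero at every state exactly when \code{pmf} is stationary.
#'
#' @param system A \code{reaction_system}.
#' @param pmf A \code{pmf} covering \code{x} and all one-reaction neighbours
#'   of \code{x} (an error is raised if a required state is missing).
#' @param x Integer state(s) at which to evaluate the balance.
#' @return Residual value(s); zero iff the balance holds at \code{x}.
#' @export
steady_state_residual <- function(system, pmf, x) {
  vapply(x, function(xi) {
    inflow <- 0
    outflow <- 0
    for (r in system$reactions) {
      src <- xi - r$nu
      if (src >= 0) {
        a_src <- propensity(r, src)
        # a zero propensity needs no probability mass at the source state
        if (a_src > 0) inflow <- inflow + a_src * pmf_lookup(pmf, src)
      }
      a_x <- propensity(r, xi)
      if (a_x > 0) outflow <- outflow + a_x * pmf_lookup(pmf, xi)
    }
    inflow - outflow
  }, numeric(1))
}

#' Build a reaction system from a YAML configuration block
#'
#' The block has a \code{name} and a \code{reactions} list of
#' \code{{nu, kind, rate, guard_min}} entries, e.g.
#' \preformatted{
#' name: W
#' reactions:
#'   - {nu: -1, kind: mass_action_2, rate: 1}
#'   - {nu:  1, kind: mass_action_2, rate: 1}
#'   - {nu:  1, kind: constant,      rate: 1}
#' }
#'
#' @param config A parsed YAML list, or a path to a YAML file.
#' @return A \code{reaction_system}.
#' @export
system_from_yaml <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$name) || is.null(config$reactions))
    stop("config must have 'name' and 'reactions'")
  rxns <- lapply(config$reactions, function(r) {
    reaction(r$nu, r$kind, r$rate, guard_min = r$guard_min)
  })
  reaction_system(config$name, rxns)
}
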