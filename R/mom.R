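#' Derive truncation-closure moment equations
#'
#' For a one-species network with polynomial propensities of degree at most
#' two, the first two moment equations of the chemical master equation close
#' under truncation closure (all moments above the variance — skewness and
#' higher central moments — are set to zero). The resulting ODE system for
#' the approximate expectation \eqn{\tilde E} and variance \eqn{\tilde V} is
#' \deqn{d\tilde E/dt = \sum_j \nu_j \big(a_j(\tilde E) +
#'   \tfrac{1}{2} a_j''(\tilde E)\,\tilde V\big)}
#' \deqn{d\tilde V/dt = \sum_j 2\nu_j\, a_j'(\tilde E)\,\tilde V +
#'   \sum_j \nu_j^2 \big(a_j(\tilde E) +
#'   \tfrac{1}{2} a_j''(\tilde E)\,\tilde V\big).}
#' For degree-2 propensities the second-order Taylor expansion is exact, so
#' no truncation-order choice arises beyond the closure itself. Propensity
#' guards (the \code{guard_min} Boolean factor) are not representable in a
#' smooth moment expansion and are ignored here, exactly as the closed
#' moment equations of the guarded idealized system drop the guard.
#'
#' Coefficients are derived symbolically over the monomial basis
#' \{1, E, E^2, V, EV\} and kept exact.
#'
#' @param system A \code{\link{reaction_system}} with propensity degree <= 2.
#' @param neglect_variance If \code{TRUE}, additionally drop all
#'   \eqn{\tilde V} terms from the expectation equation and track only
#'   \eqn{\tilde E} (the one-equation closure used for the pure-growth
#'   escape-time analysis).
#' @return An object of class \code{"mom_system"} with named coefficient
#'   vectors \code{rhs_E} and \code{rhs_V} over \code{(1, E, E2, V, EV)}.
#' @export
derive_mom <- function(system, neglect_variance = FALSE) {
  zero <- c(`1` = 0, E = 0, E2 = 0, V = 0, EV = 0)
  rhs_E <- zero
  rhs_V <- zero
  for (r in system$reactions) {
    c_ <- r$rate
    # a(E), a'(E), a''(E) as coefficient vectors over {1, E, E2}
    a  <- switch(r$kind,
      constant       = c(`1` = c_, E = 0,   E2 = 0),
      linear         = c(`1` = 0,  E = c_,  E2 = 0),
      pure_quadratic = c(`1` = 0,  E = 0,   E2 = c_),
      mass_action_2  = c(`1` = -0, E = -c_, E2 = c_))
    d1 <- switch(r$kind,
      constant       = c(`1` = 0,        E = 0),
      linear         = c(`1` = c_,       E = 0),
      pure_quadratic = c(`1` = 0,        E = 2 * c_),
      mass_action_2  = c(`1` = -c_,      E = 2 * c_))
    d2 <- switch(r$kind,
      constant = 0, linear = 0, pure_quadratic = 2 * c_,
      mass_action_2 = 2 * c_)

    nu <- r$nu
    # closed propensity expectation: a(E) + a''(E) V / 2
    aV <- c(a, V = d2 / 2)   # over {1, E, E2, V}
    rhs_E[c("1", "E", "E2", "V")] <-
      rhs_E[c("1", "E", "E2", "V")] + nu * aV
    rhs_V[c("1", "E", "E2", "V")] <-
      rhs_V[c("1", "E", "E2", "V")] + nu^2 * aV
    # drift of the variance from the propensity slope: 2 nu a'(E) V
    rhs_V["V"]  <- rhs_V["V"]  + 2 * nu * d1[["1"]]
    rhs_V["EV"] <- rhs_V["EV"] + 2 * nu * d1[["E"]]
  }
  if (neglect_variance) rhs_E[c("V", "EV")] <- 0
  structure(list(rhs_E = rhs_E, rhs_V = rhs_V,
                 source = system$name,
                 neglect_variance = isTRUE(neglect_variance)),
            class = "mom_system")
}

eval_poly_EV <- function(coef, E, V) {
  coef[["1"]] + coef[["E"]] * E + coef[["E2"]] * E^2 +
    coef[["V"]] * V + coef[["EV"]] * E * V
}

#' @export
print.mom_system <- function(x, ...) {
  fmt <- function(cf) {
    terms <- c("1", "E", "E^2", "V", "E V")
    keep <- which(cf != 0)
    if (!length(keep)) return("0")
    paste(sprintf("%+g %s", cf[keep], terms[keep]), collapse = " ")
  }
  cat(sprintf("moment equations for '%s'%s\n", x$source,
              if (x$neglect_variance) " (variance neglected)" else ""))
  cat("  dE/dt =", fmt(x$rhs_E), "\n")
  if (!x$neglect_variance) cat("  dV/dt =", fmt(x$rhs_V), "\n")
  invisible(x)
}

#' Integrate closed moment equations with blow-up detection
#'
#' Adaptive integration (lsodar, relative tolerance 1e-9 by default) with
#' root-based event localization: integration halts at the first time
#' \eqn{\tilde E} or \eqn{\tilde V} crosses \code{blowup_threshold} and that
#' crossing time is recorded as \code{blowup_time}. Quadratic moment
#' equations can genuinely reach infinity in finite time (e.g.
#' \eqn{d\tilde E/dt = \tilde E^2} blows up at \eqn{t = 1/\tilde E(0)}), so
#' a threshold crossing is reported as a result, not an error; a non-finite
#' right-hand side before the threshold is likewise reported as blow-up.
#'
#' @param mom A \code{\link{derive_mom}} result.
#' @param E0,V0 Nonnegative initial expectation and variance.
#' @param grid A \code{\link{time_grid}} or numeric vector of output times
#'   starting at 0.
#' @param blowup_threshold Divergence threshold (default 1e8).
#' @param rtol,atol Integrator tolerances.
#' @return An object of class \code{"mom_solution"}: data frame columns
#'   \code{t}, \code{E}, \code{V} (NA when variance is neglected), plus
#'   element \code{blowup_time} (NULL if no blow-up). Rows are reported only
#'   up to the blow-up time.
#' @export
integrate_mom <- function(mom, E0, V0 = 0, grid, blowup_threshold = 1e8,
                          rtol = 1e-9, atol = 1e-9) {
  stopifnot(inherits(mom, "mom_system"), E0 >= 0, V0 >= 0)
  times <- if (inherits(grid, "time_grid")) grid$points else as.numeric(grid)
  stopifnot(length(times) >= 2, times[1] == 0)

  clamp <- function(v) {
    v[!is.finite(v)] <- 1e300  # drive the root function, never NaN-crash
    v
  }
  if (mom$neglect_variance) {
    rhs <- function(t, y, p)
      list(clamp(eval_poly_EV(mom$rhs_E, y[1], 0)))
    root <- function(t, y, p) y[1] - blowup_threshold
    y0 <- c(E = E0)
  } else {
    rhs <- function(t, y, p)
      list(clamp(c(eval_poly_EV(mom$rhs_E, y[1], y[2]),
                   eval_poly_EV(mom$rhs_V, y[1], y[2]))))
    root <- function(t, y, p) max(y[1], y[2]) - blowup_threshold
    y0 <- c(E = E0, V = V0)
  }
  out <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                         rtol = rtol, atol = atol, rootfunc = root)
  troot <- attr(out, "troot")
  blowup_time <- if (length(troot)) troot[1] else NULL
  df <- as.data.frame(out)
  names(df)[1] <- "t"
  if (mom$neglect_variance) df$V <- NA_real_
  if (!is.null(blowup_time)) df <- df[df$t <= blowup_time, , drop = FALSE]
  structure(list(t = df$t, E = df$E, V = df$V, blowup_time = blowup_time,
                 source = mom$source),
            class = "mom_solution")
}

#' @export
print.mom_solution <- function(x, ...) {
  cat(sprintf("moment solution for '%s': %d time points on [0, %g]\n",
              x$source, length(x$t), max(x$t)))
  if (!is.null(x$blowup_time))
    cat(sprintf("  blow-up detected at t = %.6g s\n", x$blowup_time))
  invisible(x)
}

#' Fixed point of the closed moment equations
#'
#' Solves \eqn{d\tilde E/dt = d\tilde V/dt = 0} when both right-hand sides
#' are linear in \eqn{(\tilde E, \tilde V)}. Returns \code{NULL} with a
#' message when no fixed point exists (e.g. a constant nonzero drift, as for
#' the fat-tailed system whose closed expectation grows without bound).
#'
#' @param mom A \code{mom_system} linear in (E, V).
#' @return Named vector \code{c(E =, V =)}, or NULL.
#' @export
mom_fixed_point <- function(mom) {
  if (any(mom$rhs_E[c("E2", "EV")] != 0) || any(mom$rhs_V[c("E2", "EV")] != 0))
    stop("fixed-point solver implemented for moment equations linear in (E, V)")
  A <- rbind(c(mom$rhs_E[["E"]], mom$rhs_E[["V"]]),
             c(mom$rhs_V[["E"]], mom$rhs_V[["V"]]))
  b <- -c(mom$rhs_E[["1"]], mom$rhs_V[["1"]])
  if (abs(det(A)) < 1e-14) {
    message("no isolated fixed point: drift matrix is singular")
    return(NULL)
  }
  sol <- solve(A, b)
  c(E = sol[1], V = sol[2])
}

#' Serialize moment systems and solutions
#'
#' @param mom A \code{mom_system}.
#' @param path Output path.
#' @export
mom_to_json <- function(mom, path) {
  jsonlite::write_json(list(source = mom$source,
                            neglect_variance = mom$neglect_variance,
                            basis = names(mom$rhs_E),
                            rhs_E = unname(mom$rhs_E),
                            rhs_V = unname(mom$rhs_V)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param sol A \code{mom_solution}.
#' @rdname mom_to_json
#' @export
mom_solution_to_csv <- function(sol, path) {
  utils::write.csv(data.frame(t = sol$t, E = sol$E, V = sol$V), path,
                   row.names = FALSE)
  invisible(path)
}
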