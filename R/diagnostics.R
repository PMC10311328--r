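#' Empirical pmf of an ensemble at a grid time
#'
#' Relative state frequencies over the uncapped trajectories at one
#' recording time; capped trajectories are excluded with an explicit count.
#'
#' @param ensemble A \code{\link{run_ensemble}} result.
#' @param t A time on the ensemble grid.
#' @return An object of class \code{"pmf_estimate"}: \code{time},
#'   \code{support}, \code{freq}, \code{n_effective}, \code{n_excluded}.
#' @export
empirical_pmf <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "ensemble"))
  col <- which(abs(ensemble$grid$points - t) < 1e-9 * max(1, abs(t)))
  if (length(col) != 1L) stop("'t' is not a grid time of this ensemble")
  keep <- !ensemble$capped
  if (!any(keep)) stop("all trajectories capped: no pmf estimate at t = ", t)
  x <- ensemble$states_on_grid[keep, col]
  tab <- table(x)
  structure(list(time = ensemble$grid$points[col],
                 support = as.integer(names(tab)),
                 freq = as.numeric(tab) / length(x),
                 n_effective = length(x),
                 n_excluded = sum(!keep)),
            class = "pmf_estimate")
}

#' Treat i.i.d. integer draws as a single-time pmf estimate
#'
#' @param x Integer draws.
#' @param time Nominal time label.
#' @rdname empirical_pmf
#' @export
pmf_estimate_from_draws <- function(x, time = NA_real_) {
  tab <- table(x)
  structure(list(time = time, support = as.integer(names(tab)),
                 freq = as.numeric(tab) / length(x),
                 n_effective = length(x), n_excluded = 0L),
            class = "pmf_estimate")
}

#' @export
print.pmf_estimate <- function(x, ...) {
  cat(sprintf(
    "pmf estimate at t = %g: support %d..%d over %d trajectories (%d excluded)\n",
    x$time, min(x$support), max(x$support), x$n_effective, x$n_excluded))
  invisible(x)
}

#' Log-log tail exponent of a pmf estimate
#'
#' A polynomial tail \eqn{P(k) \propto k^{\alpha}} is a straight line of
#' slope \eqn{\alpha} in the double-logarithmic plot; the inverse-square
#' stationary law has slope exactly -2. Ordinary least squares on
#' \eqn{(\log k, \log \hat P(k))} over the nonzero-frequency support in
#' \code{[k_lo, k_hi]} (zero bins are dropped — no pseudocounts). Moment
#' existence follows from the slope: a tail shallower than or at -2 leaves
#' the mean series divergent ("no mean"); between -3 and -2 the mean exists
#' but not the variance; steeper than -3, all of the first two moments may
#' exist. The classification applies these thresholds to the 95% band of
#' the fitted slope and returns \code{"inconclusive"} when the band
#' straddles a boundary, or when fewer than 4 support points are available.
#'
#' The default fit range runs from the 90th-percentile state to the largest
#' state observed at least 5 times.
#'
#' @param pmf A \code{\link{empirical_pmf}} result (or an exact pmf table
#'   via \code{\link{pmf_estimate_from_table}}).
#' @param k_lo,k_hi Fit range; defaults as described above.
#' @return An object of class \code{"tail_report"}: \code{exponent},
#'   \code{se}, \code{fit_range}, \code{n_points}, \code{classification}.
#' @export
tail_exponent <- function(pmf, k_lo = NULL, k_hi = NULL) {
  stopifnot(inherits(pmf, "pmf_estimate"))
  pos <- pmf$freq > 0
  supp <- pmf$support[pos]
  freq <- pmf$freq[pos]
  if (is.null(k_lo)) {
    cum <- cumsum(freq) / sum(freq)
    k_lo <- supp[which(cum >= 0.9)[1]]  # 90th-percentile state
  }
  if (is.null(k_hi)) {
    min_count <- 5 / pmf$n_effective
    cand <- supp[freq >= min_count]
    k_hi <- if (length(cand)) max(cand) else max(supp)
  }
  inr <- supp >= k_lo & supp <= k_hi
  if (sum(inr) < 4) {
    return(structure(list(exponent = NA_real_, se = NA_real_,
                          fit_range = c(k_lo, k_hi), n_points = sum(inr),
                          classification = "inconclusive"),
                     class = "tail_report"))
  }
  fit <- stats::lm(log(freq[inr]) ~ log(supp[inr]))
  sm <- suppressWarnings(summary(fit))$coefficients  # exact tables fit perfectly
  b <- sm[2, 1]
  se <- sm[2, 2]
  lo <- b - 1.96 * se
  hi <- b + 1.96 * se
  eps <- 1e-9  # boundary slopes (-2, -3) classify into their closed region
  cls <- if (lo >= -2 - eps) "no mean"
         else if (hi < -3 - eps) "all moments may exist"
         else if (lo >= -3 - eps && hi < -2 - eps) "no variance"
         else "inconclusive"
  structure(list(exponent = b, se = se, fit_range = c(k_lo, k_hi),
                 n_points = sum(inr), classification = cls),
            class = "tail_report")
}

#' @param table A \code{pmf} (exact table) to analyze as if it were
#'   an estimate.
#' @rdname tail_exponent
#' @export
pmf_estimate_from_table <- function(table, time = NA_real_) {
  stopifnot(inherits(table, "pmf"))
  structure(list(time = time, support = table$k, freq = table$p,
                 n_effective = .Machine$integer.max, n_excluded = 0L),
            class = "pmf_estimate")
}

#' @export
print.tail_report <- function(x, ...) {
  cat(sprintf(
    "tail fit on k in [%g, %g] (%d points): slope %.4f (se %.4f) -> %s\n",
    x$fit_range[1], x$fit_range[2], x$n_points, x$exponent, x$se,
    x$classification))
  invisible(x)
}

#' Step-count statistics of an ensemble
#'
#' The number of SSA draws needed to simulate a fixed horizon is a
#' hardware-independent run-time proxy, and its distribution inherits the
#' fat tail of the state distribution: quadratic propensities make expected
#' time increments vanish at large states, so escaped trajectories perform
#' enormous numbers of reactions. Reports the mean step count (uncapped
#' trajectories, exclusion counted), the fraction of trajectories needing
#' more than \code{R} draws (capped trajectories count as exceeding whenever
#' \code{cap > R}), the fraction with an odd draw count (uncapped; a
#' unit-step walk returning to its start needs an even number of committed
#' events, hence an odd draw count), and the fraction resting at
#' \code{x_star} at the horizon (capped trajectories count as not there).
#'
#' @param ensemble A \code{\link{run_ensemble}} result.
#' @param R Draw-count threshold (default 175).
#' @param x_star Reference state (default 1).
#' @return List: \code{mean_steps}, \code{n_excluded_mean},
#'   \code{frac_exceeding}, \code{odd_fraction}, \code{frac_final_at}.
#' @export
step_stats <- function(ensemble, R = 175L, x_star = 1L) {
  stopifnot(inherits(ensemble, "ensemble"))
  keep <- !ensemble$capped
  dc <- ensemble$draw_counts
  exceeding <- (dc > R) | (ensemble$capped & ensemble$cap > R)
  list(
    mean_steps = if (any(keep)) mean(dc[keep]) else NA_real_,
    n_excluded_mean = sum(!keep),
    frac_exceeding = mean(exceeding),
    odd_fraction = if (any(keep)) mean(dc[keep] %% 2 == 1) else NA_real_,
    frac_final_at = mean(keep & ensemble$final_states == x_star))
}

#' Export diagnostics
#'
#' @param pmf A \code{pmf_estimate}.
#' @param path Output file.
#' @export
pmf_estimate_to_csv <- function(pmf, path) {
  utils::write.csv(data.frame(k = pmf$support, freq = pmf$freq), path,
                   row.names = FALSE)
  invisible(path)
}

#' @param report A \code{tail_report} or \code{step_stats} list.
#' @rdname pmf_estimate_to_csv
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
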