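#' Prefix series of bias-free moment estimators
#'
#' For samples \eqn{x^{(1)}, \ldots, x^{(N)}} the bias-free estimators over
#' the first n samples are
#' \deqn{\hat E^n = \frac{1}{n}\sum_{i=1}^{n} x^{(i)}, \qquad
#'   \hat V^n = \frac{1}{n-1}\sum_{i=1}^{n} (x^{(i)} - \hat E^n)^2.}
#' The full prefix series (one value per n) is the standard convergence
#' diagnostic: under the central limit theorem it settles for distributions
#' with finite moments, while for fat-tailed samples single draws keep
#' disrupting it at any n. Computed in a single streaming (Welford) pass;
#' the n = 1 variance is undefined (denominator n - 1) and reported as NA,
#' never as 0.
#'
#' @param samples Numeric vector, N >= 1, in arrival order.
#' @return An object of class \code{"moment_series"}: data-frame-like fields
#'   \code{n}, \code{mean_prefix}, \code{var_prefix}, plus the raw
#'   \code{samples}.
#' @export
prefix_moments <- function(samples) {
  N <- length(samples)
  if (N < 1) stop("'samples' must be nonempty")
  if (anyNA(samples)) stop("'samples' must not contain NA")
  mean_prefix <- numeric(N)
  var_prefix <- rep(NA_real_, N)
  m <- 0
  M2 <- 0
  for (i in seq_len(N)) {
    d <- samples[i] - m
    m <- m + d / i
    M2 <- M2 + d * (samples[i] - m)
    mean_prefix[i] <- m
    if (i >= 2) var_prefix[i] <- M2 / (i - 1)
  }
  structure(list(n = seq_len(N), mean_prefix = mean_prefix,
                 var_prefix = var_prefix, samples = samples),
            class = "moment_series")
}

#' @export
print.moment_series <- function(x, ...) {
  N <- length(x$n)
  cat(sprintf("moment series over %d samples: final mean %.6g, variance %s\n",
              N, x$mean_prefix[N],
              if (N >= 2) format(x$var_prefix[N], digits = 6) else "undefined"))
  invisible(x)
}

#' Time-resolved moment estimation over an SSA ensemble
#'
#' Applies the bias-free estimators across trajectories at every grid time.
#' Capped trajectories are excluded (their state is frozen at the cap, which
#' would bias the tail of the distribution downward) and the exclusion count
#' is reported; if every trajectory is capped the estimate at that time is
#' undefined (NA) and flagged.
#'
#' @param ensemble A \code{\link{run_ensemble}} result.
#' @return Data frame with columns \code{t}, \code{mean}, \code{var},
#'   \code{n_included}, \code{n_excluded}.
#' @export
timecourse_moments <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  keep <- !ensemble$capped
  n_inc <- sum(keep)
  n_exc <- ensemble$n - n_inc
  tg <- ensemble$grid$points
  if (n_inc == 0) {
    warning("all trajectories capped: estimates undefined at every time")
    return(data.frame(t = tg, mean = NA_real_, var = NA_real_,
                      n_included = 0L, n_excluded = n_exc))
  }
  sub <- ensemble$states_on_grid[keep, , drop = FALSE]
  data.frame(t = tg,
             mean = colMeans(sub),
             var = if (n_inc >= 2) apply(sub, 2, stats::var) else NA_real_,
             n_included = n_inc, n_excluded = n_exc)
}

#' Dominance and disruption diagnostics for a moment series
#'
#' Two indicators of wild randomness in a prefix series. The \emph{gap} at
#' sample i is the log-scale jump the i-th sample causes in the variance
#' prefix, \eqn{|\log \hat V^i - \log \hat V^{i-1}|} (on the mean prefix
#' when a variance prefix is nonpositive or undefined, flagged via
#' \code{gap_series}); large gaps mark disruptive samples. The
#' \emph{dominance ratio} is the largest single-sample share of the final
#' variance sum, \eqn{\max_i (x^{(i)} - \hat E^N)^2 / \sum_j (x^{(j)} -
#' \hat E^N)^2 \in [0, 1]}: near 0 for well-behaved samples, near 1 when one
#' realization dominates the whole estimate. Both are reported as rankings;
#' no binary cutoff is imposed.
#'
#' @param series A \code{\link{prefix_moments}} result with N >= 2.
#' @return List with \code{index} (sample with the largest gap), \code{gap},
#'   \code{dominance_ratio}, and \code{gap_series} ("variance" or "mean").
#' @export
dominance_diagnostic <- function(series) {
  stopifnot(inherits(series, "moment_series"))
  N <- length(series$n)
  if (N < 2) stop("need at least 2 samples")
  v <- series$var_prefix
  use_var <- all(is.finite(v[-1]) & v[-1] > 0)
  if (use_var) {
    lg <- log(v[-1])             # defined from n = 2
    gaps <- abs(diff(lg))        # gap at sample i = 3..N
    idx_offset <- 2L
    gap_series <- "variance"
  } else {
    m <- series$mean_prefix
    if (any(m <= 0)) {
      # log undefined: fall back to absolute jumps of the mean prefix
      gaps <- abs(diff(m))
    } else {
      gaps <- abs(diff(log(m)))
    }
    idx_offset <- 1L
    gap_series <- "mean"
  }
  if (!length(gaps)) gaps <- 0
  i_max <- which.max(gaps)
  dev2 <- (series$samples - series$mean_prefix[N])^2
  tot <- sum(dev2)
  dominance <- if (tot > 0) max(dev2) / tot else 0
  list(index = as.integer(i_max + idx_offset), gap = gaps[i_max],
       dominance_ratio = dominance, gap_series = gap_series)
}

#' Write a moment series or time course as CSV
#'
#' @param x A \code{moment_series} or \code{timecourse_moments} data frame.
#' @param path Output file.
#' @export
moment_series_to_csv <- function(x, path) {
  if (inherits(x, "moment_series"))
    x <- data.frame(n = x$n, mean = x$mean_prefix, variance = x$var_prefix)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
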