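#' The discrete inverse-square probability law
#'
#' \code{inverse_square_pmf} evaluates \eqn{P(X = k) = 6/(\pi k)^2} on the
#' positive integers. Because \eqn{\sum 1/k^2 = \pi^2/6}, this is a proper,
#' normalized distribution — yet every moment series
#' \eqn{\sum_k P(k)\,k^m}, \eqn{m \ge 1}, diverges: the law has no mean and
#' no variance. It is the stationary solution of the idealized quadratic
#' birth-death network built by \code{\link{build_system}("ideal")}.
#'
#' @param k Positive integer(s).
#' @return Probability value(s).
#' @export
inverse_square_pmf <- function(k) {
  if (any(k < 1) || any(k != round(k)))
    stop("'k' must be a positive integer (support starts at 1)")
  6 / (pi * k)^2
}

#' Tabulate reference pmfs
#'
#' @param k_max Largest support value tabulated.
#' @return A \code{\link{pmf_table}} on 1..k_max (inverse-square) or
#'   0..k_max (Poisson).
#' @export
pmf_inverse_square <- function(k_max) {
  k <- seq_len(k_max)
  pmf_table(k, inverse_square_pmf(k))
}

#' @param lambda Poisson rate.
#' @rdname pmf_inverse_square
#' @export
pmf_poisson <- function(lambda, k_max) {
  k <- 0:k_max
  pmf_table(k, stats::dpois(k, lambda))
}

#' Partial sums of a moment series
#'
#' Computes \eqn{\sum_{k=1}^{K} p(k)\, k^m} for one or more cutoffs
#' \code{K}. For the inverse-square law the order-0 series converges to 1
#' (with analytic tail remainder between \eqn{6/(\pi^2 (K+1))} and
#' \eqn{6/(\pi^2 K)}), while every series of order \eqn{m \ge 1} diverges —
#' the order-1 partial sums grow like \eqn{(6/\pi^2)\ln K}. Divergent moment
#' series are precisely what "fat-tailed" means throughout this package.
#'
#' @param pmf_fun Function mapping a vector of positive integers to
#'   probabilities (e.g. \code{inverse_square_pmf}, or
#'   \code{function(k) dpois(k, 10)}).
#' @param m Moment order (0 = normalization check).
#' @param K Cutoff(s), each >= 1.
#' @return A data frame with columns \code{K} and \code{partial_sum}, with
#'   attribute \code{order = m}.
#' @export
partial_moment_sum <- function(pmf_fun, m, K) {
  stopifnot(is.function(pmf_fun), m >= 0, m == round(m), all(K >= 1))
  K <- sort(as.numeric(K))
  sums <- numeric(length(K))
  acc <- 0
  lo <- 1
  chunk <- 1e6
  for (i in seq_along(K)) {
    hi <- K[i]
    while (lo <= hi) {
      up <- min(hi, lo + chunk - 1)
      kk <- seq(lo, up)
      acc <- acc + sum(pmf_fun(kk) * kk^m)
      lo <- up + 1
    }
    sums[i] <- acc
  }
  structure(data.frame(K = K, partial_sum = sums), order = m)
}

#' Reference samples illustrating mild, slow and wild randomness
#'
#' Draws from the three reference distributions: a normal (mild randomness)
#' and a log-normal (slow randomness) that share the same mean \eqn{e} and
#' variance \eqn{e^4 - e^2}, and the discrete inverse-square law (wild
#' randomness) which has neither. The log-normal log-scale parameters
#' \eqn{\mu = 0}, \eqn{\sigma^2 = 2} are the unique solution of the moment
#' equations \eqn{e^{\mu + \sigma^2/2} = e} and
#' \eqn{(e^{\sigma^2}-1)e^{2\mu+\sigma^2} = e^4 - e^2}. The normal sample is
#' deliberately not truncated at zero.
#'
#' Inverse-square draws use exact inverse-CDF inversion: cumulative sums of
#' the pmf are tabulated up to \eqn{k = 10^6} and inverted by binary search;
#' the remaining tail mass (about \eqn{6 \times 10^{-7}}) is inverted through
#' the continuous Pareto approximation \eqn{P(X > k) \approx 6/(\pi^2 k)}.
#'
#' @param kind One of \code{"normal"}, \code{"lognormal"},
#'   \code{"inverse_square"}.
#' @param n Number of draws.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Numeric vector of length \code{n} (integers for
#'   \code{"inverse_square"}).
#' @export
sample_reference <- function(kind = c("normal", "lognormal", "inverse_square"),
                             n, seed) {
  kind <- match.arg(kind)
  if (n < 1) stop("'n' must be at least 1")
  set.seed(seed)
  switch(kind,
    normal = stats::rnorm(n, mean = exp(1), sd = sqrt(exp(4) - exp(2))),
    lognormal = stats::rlnorm(n, meanlog = 0, sdlog = sqrt(2)),
    inverse_square = sample_inverse_square(n))
}

# table cutoff for exact inverse-CDF inversion; beyond it the continuous
# Pareto tail P(X > k) ~ 6/(pi^2 k) is inverted instead
.inv_sq_table_max <- 1e6

.wm_cache <- new.env(parent = emptyenv())

inverse_square_cdf_table <- function() {
  if (is.null(.wm_cache$inv_sq_cdf)) {
    k <- seq_len(.inv_sq_table_max)
    .wm_cache$inv_sq_cdf <- cumsum(inverse_square_pmf(k))
  }
  .wm_cache$inv_sq_cdf
}

sample_inverse_square <- function(n) {
  cdf <- inverse_square_cdf_table()
  u <- stats::runif(n)
  k <- findInterval(u, cdf) + 1L
  tail <- u > cdf[.inv_sq_table_max]
  if (any(tail)) {
    # invert the continuous tail: 1 - u = 6/(pi^2 k)
    k[tail] <- pmax(.inv_sq_table_max + 1,
                    ceiling(6 / (pi^2 * (1 - u[tail]))))
  }
  as.numeric(k)
}

#' Write draws / pmf tables as CSV
#'
#' @param x Numeric draws, or a \code{pmf}.
#' @param path Output file.
#' @export
write_draws_csv <- function(x, path) {
  utils::write.csv(data.frame(value = x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
write_pmf_csv <- function(x, path) {
  stopifnot(inherits(x, "pmf"))
  utils::write.csv(data.frame(k = x$k, probability = x$p), path,
                   row.names = FALSE)
  invisible(path)
}
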