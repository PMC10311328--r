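test_that("prefix estimators agree with hand-evaluated finite sums", {
  ms <- prefix_moments(c(1, 2, 3))
  expect_equal(ms$mean_prefix, c(1, 1.5, 2))
  expect_equal(ms$var_prefix, c(NA_real_, 0.5, 1))
  const <- prefix_moments(rep(5, 4))
  expect_equal(const$var_prefix[-1], rep(0, 3))
  expect_true(is.na(const$var_prefix[1]))   # n = 1: undefined, not 0
  expect_error(prefix_moments(numeric(0)), "nonempty")
})

test_that("streaming pass equals the two-pass oracle on random inputs", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- switch(seed, rnorm(1e4), rlnorm(2000, 0, 2), rpois(500, 3))
    ms <- prefix_moments(x)
    oracle <- two_pass_prefix(x)
    expect_equal(ms$mean_prefix, oracle$mean, tolerance = 1e-10)
    expect_equal(ms$var_prefix, oracle$var, tolerance = 1e-10)
  }
})

test_that("ensemble time courses recover the closed-form mean and edge cases", {
  e <- fixture("P2000")
  tc <- timecourse_moments(e)
  # deterministic start: mean x0, variance 0
  expect_equal(tc$mean[1], 1)
  expect_equal(tc$var[1], 0)
  i5 <- e$grid$count
  target <- 10 - 9 * exp(-5)
  expect_lt(abs(tc$mean[i5] - target), 3 * sqrt(tc$var[i5] / tc$n_included[i5]))
  expect_equal(tc$n_excluded[1], sum(e$capped))

  frozen <- reaction_system("dead", list(reaction(1, "constant", 0)))
  ef <- run_ensemble(frozen, 3, 1, n = 10, grid = time_grid(1, points = 5),
                     base_seed = 1)
  tcf <- timecourse_moments(ef)
  expect_true(all(tcf$var == 0))
  expect_true(all(tcf$mean == 3))
})

test_that("a planted outlier is flagged with the maximal gap", {
  dd <- dominance_diagnostic(prefix_moments(c(1, 1, 1, 1000)))
  expect_equal(dd$index, 4L)
  expect_gt(dd$gap, 1)
  expect_gt(dd$dominance_ratio, 0.7)
  # constant samples: no gaps anywhere
  dc <- dominance_diagnostic(prefix_moments(rep(2, 6)))
  expect_equal(dc$gap, 0)
  expect_equal(dc$dominance_ratio, 0)
})

test_that("well-behaved samples have negligible dominance", {
  set.seed(31)
  dd <- dominance_diagnostic(prefix_moments(runif(1e4)))
  expect_lt(dd$dominance_ratio, 0.05)
  expect_equal(dd$gap_series, "variance")
})

test_that("mild randomness converges: Poisson sample means settle at 10", {
  inside <- vapply(1:100, function(seed) {
    set.seed(seed)
    abs(mean(rpois(1e4, 10)) - 10) < 5 * sqrt(10 / 1e4)
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("wild randomness dominates: inverse-square beats the Poisson control", {
  for (seed in c(2, 12, 22)) {
    wild <- sample_reference("inverse_square", 1e5, seed = seed)
    set.seed(seed + 1000)
    mild <- rpois(1e5, 10)
    d_wild <- dominance_diagnostic(prefix_moments(wild))$dominance_ratio
    d_mild <- dominance_diagnostic(prefix_moments(mild))$dominance_ratio
    expect_gt(d_wild, d_mild)
  }
})

test_that("series and time courses export as CSV", {
  dir <- withr::local_tempdir()
  moment_series_to_csv(prefix_moments(c(1, 2, 3)), file.path(dir, "ms.csv"))
  re <- read.csv(file.path(dir, "ms.csv"))
  expect_equal(re$mean, c(1, 1.5, 2))
})
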