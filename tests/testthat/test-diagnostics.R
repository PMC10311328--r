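test_that("empirical pmfs are normalized frequency tables over uncapped rows", {
  frozen <- reaction_system("dead", list(reaction(1, "constant", 0)))
  ef <- run_ensemble(frozen, 1, 1, n = 10, grid = time_grid(1, points = 5),
                     base_seed = 1)
  p <- empirical_pmf(ef, 1)
  expect_equal(p$support, 1L)
  expect_equal(p$freq, 1)
  expect_error(empirical_pmf(ef, 0.123), "not a grid time")

  e <- fixture("W2000")
  pw <- empirical_pmf(e, 5)
  expect_equal(sum(pw$freq), 1, tolerance = 1e-12)
  expect_equal(pw$n_effective + pw$n_excluded, e$n)
})

test_that("i.i.d. draws treated as a pmf estimate recover the exact law", {
  x <- sample_reference("inverse_square", 1e5, seed = 5)
  p <- pmf_estimate_from_draws(x)
  f1 <- p$freq[p$support == 1]
  p1 <- 6 / pi^2
  expect_lt(abs(f1 - p1), 3 * sqrt(p1 * (1 - p1) / 1e5))
})

test_that("tail slopes of known laws are recovered and classified", {
  exact <- tail_exponent(pmf_estimate_from_table(pmf_inverse_square(1000)),
                         k_lo = 10, k_hi = 1000)
  expect_lt(abs(exact$exponent - (-2)), 0.02)
  expect_equal(exact$classification, "no mean")

  k <- 1:1000
  cubic <- pmf_table(k, k^-3 / sum(k^-3))
  fit3 <- tail_exponent(pmf_estimate_from_table(cubic), k_lo = 10, k_hi = 1000)
  expect_lt(abs(fit3$exponent - (-3)), 0.05)
  expect_equal(fit3$classification, "no variance")

  pois <- tail_exponent(pmf_estimate_from_table(pmf_poisson(10, 40)),
                        k_lo = 20, k_hi = 40)
  expect_lt(pois$exponent, -3)   # super-polynomial decay
  expect_equal(pois$classification, "all moments may exist")
})

test_that("insufficient support yields an explicit inconclusive verdict", {
  p <- pmf_estimate_from_draws(c(1, 1, 1, 2, 2, 3))
  r <- tail_exponent(p, k_lo = 1, k_hi = 10)
  expect_equal(r$classification, "inconclusive")
  expect_true(is.na(r$exponent))
})

test_that("the fat-tailed ensemble's tail flattens over time", {
  e <- fixture("W5000")
  t_early <- grid_time_near(e, 0.05)
  early <- tail_exponent(empirical_pmf(e, t_early), k_lo = 1, k_hi = 20)
  late <- tail_exponent(empirical_pmf(e, 5), k_lo = 1, k_hi = 20)
  expect_gt(late$exponent, early$exponent)  # shallower slope at late times
})

test_that("step counts separate the mild and wild systems", {
  sP <- step_stats(fixture("P2000"))
  expect_lt(abs(sP$mean_steps - 90), 5)
  # essentially no immigration-death run needs < 40 or > 140 draws for 5 s
  dc <- fixture("P2000")$draw_counts
  expect_gte(mean(dc >= 40 & dc <= 140), 0.99)

  e <- fixture("W2000")
  sW <- step_stats(e, R = 175, x_star = 1)
  expect_gte(sW$frac_exceeding, 0.20)
  expect_gte(sW$frac_final_at, 0.40)
  # odd draw counts are the strict majority (one-sided binomial, alpha 0.01)
  n_unc <- sum(!e$capped)
  odd <- round(sW$odd_fraction * n_unc)
  expect_lt(binom.test(odd, n_unc, 0.5, alternative = "greater")$p.value, 0.01)
})

test_that("a resting ensemble has zero draws and no exceedances", {
  frozen <- reaction_system("dead", list(reaction(1, "constant", 0)))
  ef <- run_ensemble(frozen, 2, 1, n = 5, grid = time_grid(1, points = 5),
                     base_seed = 1)
  s <- step_stats(ef, R = 175, x_star = 2)
  expect_equal(s$mean_steps, 0)
  expect_equal(s$frac_exceeding, 0)
  expect_equal(s$frac_final_at, 1)
})

test_that("diagnostics export to CSV and JSON", {
  dir <- withr::local_tempdir()
  e <- fixture("W2000")
  p <- empirical_pmf(e, 5)
  pmf_estimate_to_csv(p, file.path(dir, "pmf.csv"))
  expect_equal(read.csv(file.path(dir, "pmf.csv"))$freq, p$freq)
  report_to_json(tail_exponent(p, 1, 20), file.path(dir, "tail.json"))
  back <- jsonlite::read_json(file.path(dir, "tail.json"))
  expect_true(is.numeric(back$exponent))
})
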