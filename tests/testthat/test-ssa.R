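test_that("the recording grid is {0} plus a log-uniform sweep", {
  g <- time_grid(5)
  expect_equal(g$count, 1001L)
  expect_equal(g$points[1], 0)
  expect_equal(g$points[2], 1e-3)
  expect_equal(g$points[g$count], 5)
  expect_true(all(diff(g$points) > 0))
  # log-uniform spacing between the positive points
  expect_equal(diff(log(g$points[-1])), rep(diff(log(g$points[2:3])), 999))
})

test_that("a zero-propensity system rests with no draws", {
  s <- reaction_system("dead", list(reaction(1, "constant", 0)))
  tr <- simulate_trajectory(s, x0 = 5, t_end = 3, seed = 1)
  expect_equal(length(tr$times), 0)
  expect_equal(tr$draw_count, 0)
  expect_false(tr$capped)
  expect_equal(trajectory_on_grid(tr, c(0, 1, 3)), c(5, 5, 5))
})

test_that("waiting times are exponential with rate = total propensity", {
  lambda <- 4
  s <- reaction_system("clock", list(reaction(1, "constant", lambda)))
  tr <- simulate_trajectory(s, 0, t_end = 1e9, cap = 1e5, seed = 123)
  waits <- diff(c(0, tr$times))
  expect_equal(length(waits), 1e5)
  expect_lt(abs(mean(waits) - 1 / lambda), 3 / (lambda * sqrt(1e5)))
  expect_equal(tr$draw_count, 1e5)  # capped: draws = committed events
  expect_true(tr$capped)
})

test_that("trajectories and ensembles are reproducible and structurally sound", {
  W <- build_system("W")
  e1 <- run_ensemble(W, 1, 1, n = 100, cap = 5000, base_seed = 4)
  e2 <- run_ensemble(W, 1, 1, n = 100, cap = 5000, base_seed = 4)
  expect_identical(e1$states_on_grid, e2$states_on_grid)
  expect_identical(e1$draw_counts, e2$draw_counts)
  expect_true(all(e1$states_on_grid[, 1] == 1))       # column 0 is x0
  tr <- simulate_trajectory(W, 1, 5, cap = 5000, seed = 5)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(abs(diff(c(tr$x0, tr$states))) == 1))  # nu = +/-1 steps
  if (!tr$capped) expect_equal(tr$draw_count, length(tr$times) + 1)
})

test_that("immigration-death ensemble mean follows the closed-form relaxation", {
  e <- fixture("P2000")
  x5 <- e$states_on_grid[, e$grid$count]
  target <- 10 - 9 * exp(-5)
  expect_lt(abs(mean(x5) - target), 3 * sd(x5) / sqrt(length(x5)))
})

test_that("the immigration-death ensemble equilibrates to Poisson(10)", {
  fs <- fixture("P5000")$final_states
  breaks <- c(-0.5, seq(3.5, 17.5), Inf)
  obs <- as.numeric(table(cut(fs, breaks)))
  pr <- diff(ppois(c(-1, 3:17, Inf), 10))
  pval <- suppressWarnings(chisq.test(obs, p = pr))$p.value
  expect_gt(pval, 0.01)
})

test_that("the fat-tailed system keeps x >= 1 and odd draw counts at x = 1", {
  e <- fixture("W2000")
  expect_true(all(e$states_on_grid >= 1))
  # a unit-step walk back at its start has even events, so odd draws
  dc <- e$draw_counts[!e$capped & e$final_states == 1]
  expect_true(all(dc %% 2 == 1))
})

test_that("escape times of the explosive system match the partial-sum oracle", {
  e <- fixture("growth500")
  et <- escape_times(e)
  expect_true(all(et$time >= 0 & et$time <= e$t_end))
  expect_true(all(e$capped))   # quadratic growth always hits the cap first
  # oracle: escape proxy time = sum of independent Exp(k^2) waits, k = 1..cap
  oracle_mean <- sum(1 / (1:10000)^2)
  oracle_sd <- sqrt(sum(1 / (1:10000)^4))
  expect_lt(abs(mean(et$time) - oracle_mean),
            3 * oracle_sd / sqrt(nrow(et)))
})

test_that("a birth-limited system never reaches the cap: all escapes censored", {
  e <- run_ensemble(build_system("P"), 1, 1, n = 50, cap = 10000,
                    base_seed = 9)
  et <- escape_times(e)
  expect_true(all(et$censored))
  expect_true(all(et$time == e$t_end))
})

test_that("ensembles round-trip through their plain-text persistence", {
  e <- run_ensemble(build_system("P"), 1, 1, n = 20,
                    grid = time_grid(1, points = 11), base_seed = 3)
  dir <- withr::local_tempdir()
  write_ensemble(e, dir)
  grid <- read.csv(file.path(dir, "grid.csv"))
  expect_equal(unname(as.matrix(grid)), unname(e$states_on_grid))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$system, "P")
  expect_equal(meta$n, 20L)
})
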