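coef_vec <- function(`1` = 0, E = 0, E2 = 0, V = 0, EV = 0)
  c(`1` = `1`, E = E, E2 = E2, V = V, EV = EV)

test_that("closed moment equations reproduce the printed systems exactly", {
  mP <- derive_mom(build_system("P"))
  expect_identical(mP$rhs_E, coef_vec(`1` = 10, E = -1))       # dE = 10 - E
  expect_identical(mP$rhs_V, coef_vec(`1` = 10, E = 1, V = -2))  # 10 - 2V + E

  mW <- derive_mom(build_system("W"))
  expect_identical(mW$rhs_E, coef_vec(`1` = 1))                # dE = 1
  expect_identical(mW$rhs_V, coef_vec(`1` = 1, E = -2, E2 = 2, V = 2))

  mG <- derive_mom(build_system("pure_growth"), neglect_variance = TRUE)
  expect_identical(mG$rhs_E, coef_vec(E2 = 1))                 # dE = E^2
})

test_that("fixed points: relaxation to (10, 10) for P, none for W", {
  expect_equal(mom_fixed_point(derive_mom(build_system("P"))),
               c(E = 10, V = 10))
  mW <- derive_mom(build_system("W"))
  # symbolically: dE/dt is the constant 1, so no state can be stationary
  expect_true(mW$rhs_E[["1"]] != 0 &&
                all(mW$rhs_E[c("E", "E2", "V", "EV")] == 0))
})

test_that("integration matches closed-form solutions of the linear systems", {
  g <- time_grid(5, points = 201)
  sP <- integrate_mom(derive_mom(build_system("P")), E0 = 1, V0 = 0, grid = g)
  expect_lt(max(abs(sP$E - (10 - 9 * exp(-sP$t)))), 1e-7)
  expect_lt(max(abs(sP$V - (10 - 9 * exp(-sP$t) - exp(-2 * sP$t)))), 1e-7)
  expect_true(all(sP$V >= 0))
  expect_null(sP$blowup_time)

  sW <- integrate_mom(derive_mom(build_system("W")), E0 = 1, V0 = 0, grid = g)
  expect_lt(max(abs(sW$E - (1 + sW$t))), 1e-7)
  # dV/dt = 1 + 2(E(E-1) + V) with E = 1 + t integrates to
  # V = 1.5 exp(2t) - t^2 - 2t - 1.5
  expect_lt(max(abs(sW$V - (1.5 * exp(2 * sW$t) - sW$t^2 - 2 * sW$t - 1.5))
                / pmax(1, abs(sW$V))), 1e-6)
  expect_true(all(sW$V >= 0))
})

test_that("the pure-growth expectation blows up at 1/E0", {
  mG <- derive_mom(build_system("pure_growth"), neglect_variance = TRUE)
  for (E0 in c(0.5, 1, 2, 4)) {
    sol <- integrate_mom(mG, E0 = E0, V0 = 0, grid = c(0, seq(0.01, 3, 0.01)))
    expect_false(is.null(sol$blowup_time))
    expect_lt(abs(sol$blowup_time * E0 - 1), 1e-2)
    expect_true(all(sol$t <= sol$blowup_time))
  }
})

test_that("moment systems and solutions serialize losslessly enough to reload", {
  dir <- withr::local_tempdir()
  mW <- derive_mom(build_system("W"))
  mom_to_json(mW, file.path(dir, "mom.json"))
  back <- jsonlite::read_json(file.path(dir, "mom.json"), simplifyVector = TRUE)
  expect_equal(back$rhs_E, unname(mW$rhs_E))
  expect_equal(back$rhs_V, unname(mW$rhs_V))
  sol <- integrate_mom(mW, 1, 0, grid = c(0, 0.5, 1))
  mom_solution_to_csv(sol, file.path(dir, "sol.csv"))
  re <- read.csv(file.path(dir, "sol.csv"))
  expect_equal(re$E, sol$E)
})
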