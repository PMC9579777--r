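test_that("best response matches the p = 2 closed form and grid search", {
  p2 <- ability_params(2)
  expect_equal(best_response(0.5, 0, p2), 0.4, tolerance = 1e-10)
  expect_equal(best_response(1, 0.5, p2), 0.25, tolerance = 1e-10)
  set.seed(11)
  a <- runif(20)
  e <- runif(20)
  expect_equal(best_response(a, e, p2), (1 - e) / (3 - a), tolerance = 1e-10)
  # independent brute-force audit at p = 1.25
  p125 <- ability_params(1.25)
  for (i in 1:5) {
    r <- best_response(a[i], e[i], p125)
    expect_equal(r, brute_force_best_response(a[i], e[i], p125),
                 tolerance = 1e-5)
  }
})

test_that("best response is zero against a saturating partner", {
  expect_identical(best_response(0.7, 1.2, ability_params(1.5)), 0)
  expect_identical(best_response(0, 1, ability_params(3)), 0)
})

test_that("Nash efforts match the p = 2 linear-FOC closed form on random pairs", {
  p2 <- ability_params(2)
  set.seed(42)
  a1 <- runif(100)
  a2 <- runif(100)
  for (i in seq_along(a1)) {
    sol <- nash_efforts(a1[i], a2[i], p2)
    cf <- closed_form_nash_p2(a1[i], a2[i])
    expect_equal(sol$efforts$e_focal, cf$e1, tolerance = 1e-8)
    expect_equal(sol$efforts$e_partner, cf$e2, tolerance = 1e-8)
  }
})

test_that("Nash solution for (1, 0) at p = 2 reproduces the worked example", {
  sol <- nash_efforts(1, 0, ability_params(2))
  expect_equal(sol$efforts$e_focal, 0.4, tolerance = 1e-9)
  expect_equal(sol$efforts$e_partner, 0.2, tolerance = 1e-9)
  expect_equal(sol$payoff_focal, 0.68, tolerance = 1e-9)
  expect_equal(sol$payoff_partner, 0.76, tolerance = 1e-9)
  expect_true(sol$converged)
  expect_lt(max(abs(sol$foc_residuals)), 1e-8)
})

test_that("symmetric pairs give equal efforts 1/(4 - a)", {
  p2 <- ability_params(2)
  for (a in c(0, 0.25, 0.5, 1)) {
    sol <- nash_efforts(a, a, p2)
    expect_equal(sol$efforts$e_focal, 1 / (4 - a), tolerance = 1e-9)
    expect_equal(sol$efforts$e_partner, sol$efforts$e_focal, tolerance = 1e-9)
  }
})

test_that("swapping the ability pair mirrors efforts and payoffs", {
  par <- ability_params(1.5)
  s12 <- nash_efforts(0.8, 0.3, par)
  s21 <- nash_efforts(0.3, 0.8, par)
  expect_equal(s12$efforts$e_focal, s21$efforts$e_partner, tolerance = 1e-9)
  expect_equal(s12$efforts$e_partner, s21$efforts$e_focal, tolerance = 1e-9)
  expect_equal(s12$payoff_focal, s21$payoff_partner, tolerance = 1e-9)
  expect_equal(s12$payoff_partner, s21$payoff_focal, tolerance = 1e-9)
})

test_that("Newton pair solver agrees with the alternating-bisection path", {
  set.seed(7)
  for (p in c(1.1, 1.25, 1.5, 2, 3.5)) {
    par <- ability_params(p)
    a1 <- runif(50)
    a2 <- runif(50)
    sN <- abilitygame:::solve_nash_pairs(a1, a2, par)
    sA <- abilitygame:::nash_alternating(a1, a2, par)
    expect_true(sN$converged)
    expect_true(sA$converged)
    expect_lt(max(abs(sN$e1 - sA$e1), abs(sN$e2 - sA$e2)), 1e-8)
  }
})

test_that("equilibrium totals stay strictly inside the unsaturated region", {
  set.seed(3)
  for (p in c(1.25, 1.5, 2)) {
    par <- ability_params(p)
    a1 <- runif(50)
    a2 <- runif(50)
    sol <- abilitygame:::solve_nash_pairs(a1, a2, par)
    expect_true(all(sol$e1 + sol$e2 < 1))
    expect_true(all(sol$e1 > 0 & sol$e2 > 0))
    w1 <- payoff(a1, sol$e1, sol$e2, par)
    w2 <- payoff(a2, sol$e2, sol$e1, par)
    expect_true(all(w1 >= 0 & w2 >= 0))
  }
})

test_that("mutant effort rises, partner effort falls, total rises with mutant ability", {
  grid <- seq(0, 1, length.out = 41)
  for (p in c(1.25, 1.5, 2)) {
    par <- ability_params(p)
    for (a_partner in c(0.2, 0.5, 0.9)) {
      sol <- abilitygame:::solve_nash_pairs(grid, rep(a_partner, 41), par)
      expect_true(all(diff(sol$e1) >= -1e-10))
      expect_true(all(diff(sol$e2) <= 1e-10))
      expect_true(all(diff(sol$e1 + sol$e2) >= -1e-10))
    }
  }
})

test_that("response slope matches the p = 2 formula and finite differences", {
  p2 <- ability_params(2)
  for (e in c(0.1, 0.3, 0.6)) {
    expect_equal(response_slope(0.5, e, p2), -0.4, tolerance = 1e-9)
    expect_equal(response_slope(1, e, p2), -0.5, tolerance = 1e-9)
  }
  h <- 1e-6
  for (p in c(1.25, 1.5, 2)) {
    par <- ability_params(p)
    for (a in c(0.2, 0.8)) {
      fd <- (best_response(a, 0.3 + h, par) -
               best_response(a, 0.3 - h, par)) / (2 * h)
      expect_equal(as.numeric(response_slope(a, 0.3, par)), fd,
                   tolerance = 1e-4)
    }
  }
})

test_that("response slope lies strictly in (-1, 0); corner flagged as 0", {
  set.seed(5)
  for (p in c(1.05, 1.25, 2, 4)) {
    par <- ability_params(p)
    s <- response_slope(runif(30), runif(30, 0, 0.9), par)
    expect_true(all(s > -1 & s < 0))
  }
  s0 <- response_slope(0.5, 1.5, ability_params(2))
  expect_identical(as.numeric(s0), 0)
  expect_true(attr(s0, "corner"))
})

test_that("responsiveness at the symmetric equilibrium is stronger for p = 1.25 than p = 2", {
  slope_at_sym_eq <- function(p) {
    par <- ability_params(p)
    sol <- nash_efforts(0.5, 0.5, par)
    abs(response_slope(0.5, sol$efforts$e_partner, par))
  }
  expect_gt(slope_at_sym_eq(1.25), slope_at_sym_eq(2.0))
})

test_that("solo optimum reproduces the worked example and the envelope theorem", {
  p2 <- ability_params(2)
  s <- solo_optimum(0.5, 0, p2)
  expect_equal(s$effort, 0.4, tolerance = 1e-9)
  expect_equal(s$payoff, 0.40, tolerance = 1e-9)
  sat <- solo_optimum(0.3, 1.5, ability_params(1.5))
  expect_identical(sat$effort, 0)
  expect_equal(sat$payoff, 1)
  # envelope theorem: d payoff / d a = e*^p
  par <- ability_params(1.5)
  h <- 1e-6
  for (a in c(0.3, 0.7)) {
    fd <- (solo_optimum(a + h, 0.2, par)$payoff -
             solo_optimum(a - h, 0.2, par)$payoff) / (2 * h)
    expect_equal(fd, solo_optimum(a, 0.2, par)$effort^1.5, tolerance = 1e-4)
  }
})

test_that("solo payoff increases with ability against a fixed environment", {
  a <- seq(0.05, 0.95, length.out = 19)
  for (p in c(1.25, 2)) {
    par <- ability_params(p)
    w <- vapply(a, function(ai) solo_optimum(ai, 0.3, par)$payoff, numeric(1))
    expect_true(all(diff(w) > 0))
  }
})

test_that("parameter validation rejects ill-conditioned cost exponents", {
  expect_error(ability_params(1), "must exceed 1")
  expect_error(ability_params(1 + 1e-9), "must exceed 1")
  expect_error(ability_params(0.9), "must exceed 1")
  expect_s3_class(ability_params(1 + 1e-5), "ability_params")
})
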