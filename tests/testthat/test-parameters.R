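# Beta fitting, probability conversion, utility mapping, complication costs.

test_that("method-of-moments beta fit recovers its moments exactly", {
  # symmetric closed form: mean 1/2, var 1/8 solves alpha = beta = 1/2
  b <- fit_beta_from_moments(0.5, sqrt(1 / 8))
  expect_equal(b$alpha, 0.5, tolerance = 1e-12)
  expect_equal(b$beta, 0.5, tolerance = 1e-12)

  # round-trip property over a grid of feasible (mean, sd)
  for (m in c(0.00923, 0.05, 0.3183, 0.5, 0.9)) {
    for (f in c(0.05, 0.3, 0.9)) {
      sd <- f * sqrt(m * (1 - m))
      fit <- fit_beta_from_moments(m, sd)
      expect_equal(beta_mean(fit), m, tolerance = 1e-9)
      expect_equal(beta_sd(fit), sd, tolerance = 1e-9)
    }
  }
})

test_that("infeasible or degenerate beta moments are rejected with the parameter named", {
  expect_error(fit_beta_from_moments(0.5, 0.6, label = "p_revision"),
               "p_revision", class = "crswnp_validation")
  expect_error(fit_beta_from_moments(0, 0.1), class = "crswnp_validation")
  expect_error(fit_beta_from_moments(1, 0.1), class = "crswnp_validation")
  expect_error(fit_beta_fixed_alpha(0), class = "crswnp_validation")
  expect_error(fit_beta_fixed_alpha(1), class = "crswnp_validation")
})

test_that("fixed-alpha beta fit reproduces the reported shape pairs", {
  # formula oracle: beta = alpha (1 - m) / m
  cases <- list(
    list(m = 0.3183, printed = 4.28),
    list(m = 0.086, printed = 21.2),
    list(m = 0.112, printed = 15.8),
    list(m = 0.052, printed = 36)
  )
  for (cs in cases) {
    fit <- fit_beta_fixed_alpha(cs$m, alpha = 2)
    expect_equal(fit$beta, 2 * (1 - cs$m) / cs$m, tolerance = 1e-12)
    expect_equal(fit$beta, cs$printed, tolerance = 0.02)  # printed pairs are rounded
    expect_equal(beta_mean(fit), cs$m, tolerance = 1e-12)
  }
  expect_equal(fit_beta_fixed_alpha(0.5, 2)$beta, 2)
})

test_that("annualized probabilities invert compounding", {
  expect_identical(annualize_probability(0, 5), 0)

  # oracle: solve 1 - (1 - a)^y = R numerically, independent of the closed form
  for (R in c(0.1802, 0.30, 0.9)) {
    for (y in c(1, 5, 20)) {
      a_oracle <- uniroot(function(a) 1 - (1 - a)^y - R, c(0, 1 - 1e-12),
                          tol = 1e-12)$root
      expect_equal(annualize_probability(R, y), a_oracle, tolerance = 1e-9)
    }
  }
  # the transcribed yearly revision rate corresponds to a ~18% 5-year risk
  expect_lt(abs(annualize_probability(0.18012, 5) - 0.03894), 1e-5)

  # identity property over years 1..50
  for (y in 1:50) {
    a <- annualize_probability(0.25, y)
    expect_equal(1 - (1 - a)^y, 0.25, tolerance = 1e-12)
  }
  expect_error(annualize_probability(1, 5), class = "crswnp_validation")
  expect_error(annualize_probability(0.2, 2.5), class = "crswnp_validation")
})

test_that("SNOT-22 utility mapping is linear, clipped and monotone", {
  m <- utility_mapping()  # default 0.81 - 0.0062 * score
  expect_identical(snot22_to_utility(0, m), m$intercept)
  expect_equal(snot22_to_utility(34.02, m), 0.81 - 0.0062 * 34.02,
               tolerance = 1e-12)
  # floor clipping
  steep <- utility_mapping(intercept = 0.5, slope = 0.05)
  expect_identical(snot22_to_utility(110, steep), 0)
  # monotone non-increasing, bounded
  u <- snot22_to_utility(seq(0, 110, by = 0.5), m)
  expect_true(all(diff(u) <= 0))
  expect_true(all(u >= 0 & u <= 1))
  expect_error(snot22_to_utility(-1, m), class = "crswnp_validation")
  expect_error(snot22_to_utility(111, m), class = "crswnp_validation")
})

test_that("expected complication cost is a weighted mean, permutation invariant", {
  costs <- c(anaphylaxis = 1446, arthritis = 3562, conjunctivitis = 179,
             egpa = 33292, hypersensitivity = 601, injection_reaction = 601)
  sh <- toy_shared(comp_costs = costs)
  expect_equal(expected_complication_cost(sh), mean(costs))  # = 6613.5
  expect_equal(mean(costs), 6613.5)

  one_hot <- function(nm) {
    w <- setNames(rep(0, 6), names(costs)); w[nm] <- 1; w
  }
  expect_equal(expected_complication_cost(
    toy_shared(comp_costs = costs, weights = one_hot("conjunctivitis"))), 179)
  expect_equal(expected_complication_cost(
    toy_shared(comp_costs = costs, weights = one_hot("egpa"))), 33292)

  # permutation invariance of named (weight, cost) pairs
  set.seed(4)
  w <- rexp(6); w <- setNames(w / sum(w), names(costs))
  ref <- expected_complication_cost(toy_shared(comp_costs = costs, weights = w))
  for (k in 1:5) {
    p <- sample(6)
    sh_p <- toy_shared(comp_costs = costs[p], weights = w[p])
    expect_equal(expected_complication_cost(sh_p), ref, tolerance = 1e-12)
  }

  expect_error(
    expected_complication_cost(list(complication_costs = costs,
                                    complication_weights = c(0.5, 0.5))),
    class = "crswnp_validation")
  expect_error(
    expected_complication_cost(list(complication_costs = costs,
                                    complication_weights = costs / sum(costs) + 0.01)),
    class = "crswnp_validation")
})

test_that("shipped complication-weight profiles are valid simplices", {
  for (p in c("equal", "rare_egpa", "calibrated")) {
    w <- complication_weight_profile(p)
    expect_length(w, 6)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  expect_equal(complication_weight_profile("rare_egpa")[["egpa"]], 0.01)
})

test_that("parameter estimates validate their distribution metadata", {
  expect_error(param_estimate(0.2, sd = 0.1, distribution = "fixed"),
               class = "crswnp_validation")
  expect_error(param_estimate(0.2, sd = 0.5, distribution = "beta"),
               class = "crswnp_validation")
  # SNOT-22 scale: sd feasibility is assessed on the rescaled score
  pe <- param_estimate(30.2, sd = 1.295, distribution = "beta", scale = 110)
  b <- crswnpCEA:::resolve_beta(pe)
  expect_equal(110 * beta_mean(b), 30.2, tolerance = 1e-9)
  expect_equal(110 * beta_sd(b), 1.295, tolerance = 1e-9)
})
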