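# PSA sampling, acceptability curves, ellipses, threshold search, dosing.

test_that("parameter sampling is reproducible and stream-stable", {
  tb <- load_parameter_table()
  d1 <- sample_parameters(tb, 50, seed = 123)
  d2 <- sample_parameters(tb, 50, seed = 123)
  expect_identical(d1, d2)
  # enlarging the number of draws leaves the first draws unchanged per row
  d3 <- sample_parameters(tb, 100, seed = 123)
  for (col in names(d1)) expect_identical(d3[[col]][1:50], d1[[col]])
  # fixed rows (costs, comparator rates) are not sampled
  expect_false(any(grepl("drug_cost|no_biologic", names(d1))))
  # all sampled probabilities valid, SNOT-22 on its scale
  expect_true(all(d1[["dupilumab.p_revision"]] >= 0 &
                    d1[["dupilumab.p_revision"]] <= 1))
  expect_true(all(d1[["omalizumab.snot22"]] >= 0 &
                    d1[["omalizumab.snot22"]] <= 110))
})

test_that("sampled adverse-event probabilities match their declared beta", {
  tb <- load_parameter_table()
  d <- sample_parameters(tb, 10000, seed = 5)
  x <- d[["dupilumab.p_adverse"]]
  # Beta(2, 4.28): mean and analytic SE of the empirical mean
  m <- 2 / (2 + 4.28)
  se <- sqrt(m * (1 - m) / (2 + 4.28 + 1)) / sqrt(10000)
  expect_lt(abs(mean(x) - m), 3 * se)
})

test_that("a degenerate (all fixed) PSA reproduces the deterministic base case", {
  spec <- replication_spec()
  spec$table <- degenerate_table(spec$table)
  ps <- run_psa(spec, n_draws = 1, seed = 9,
                arms = c("omalizumab", "dupilumab"))
  base_oma <- run_cohort(spec, "omalizumab")
  base_dup <- run_cohort(spec, "dupilumab")
  expect_identical(ps$cost[ps$strategy == "omalizumab"], base_oma$total_cost)
  expect_identical(ps$qaly[ps$strategy == "dupilumab"], base_dup$total_qaly)
})

test_that("PSA runs are seed-reproducible and correctly shaped", {
  spec <- replication_spec()
  ps1 <- run_psa(spec, n_draws = 40, seed = 11,
                 arms = c("omalizumab", "dupilumab"))
  ps2 <- run_psa(spec, n_draws = 40, seed = 11,
                 arms = c("omalizumab", "dupilumab"))
  expect_identical(ps1$cost, ps2$cost)
  expect_identical(ps1$qaly, ps2$qaly)
  expect_equal(nrow(ps1), 80)
  expect_true(all(ps1$cost >= 0))
  expect_true(all(ps1$qaly >= 0 & ps1$qaly <= spec$shared$horizon_years))

  no_table <- spec; no_table$table <- NULL
  expect_error(run_psa(no_table, 2, 1), class = "crswnp_validation")
})

test_that("acceptability fractions sum to one and split ties equally", {
  # two identical strategies: every draw is an exact tie
  cost <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  qaly <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  cc <- ceac(fake_psa(cost, qaly), wtp_grid = c(0, 1e4))
  expect_true(all(cc$acceptability == 0.5))

  # single draw gives an indicator curve
  cost1 <- cbind(a = 100, b = 0)
  qaly1 <- cbind(a = 1, b = 0.5)
  cc1 <- ceac(fake_psa(cost1, qaly1), wtp_grid = c(0, 150, 500))
  expect_setequal(unique(cc1$acceptability), c(0, 1))
  # at wtp 0 the cheaper strategy wins; far above the pairwise ICER (200) a wins
  expect_equal(cc1$acceptability[cc1$strategy == "b" & cc1$wtp == 0], 1)
  expect_equal(cc1$acceptability[cc1$strategy == "a" & cc1$wtp == 500], 1)

  # random cloud: sums are exactly 1 at every grid point
  set.seed(21)
  n <- 200
  cost <- cbind(a = runif(n, 0, 1e5), b = runif(n, 0, 1e5), c = runif(n, 0, 1e5))
  qaly <- cbind(a = runif(n, 0, 8), b = runif(n, 0, 8), c = runif(n, 0, 8))
  ps <- fake_psa(cost, qaly)
  grid <- seq(0, 2e5, length.out = 9)
  cc <- ceac(ps, grid)
  sums <- tapply(cc$acceptability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # at wtp = 0 the acceptability of each strategy is the fraction it is cheapest
  cheapest <- colnames(cost)[apply(cost, 1, which.min)]
  for (s in colnames(cost)) {
    expect_equal(cc$acceptability[cc$wtp == 0 & cc$strategy == s],
                 mean(cheapest == s), tolerance = 1e-9)
  }
  expect_error(ceac(ps, numeric(0)), class = "crswnp_validation")
  expect_error(ceac(ps, c(2, 1)), class = "crswnp_validation")
})

test_that("confidence ellipses are antisymmetric, degenerate-aware and calibrated", {
  set.seed(31)
  n <- 4000
  # known bivariate normal via Cholesky (independent construction)
  L <- chol(matrix(c(4, 3, 3, 9), 2))
  z <- matrix(rnorm(2 * n), n) %*% L
  dq <- 0.5 + z[, 1]; dc <- -2 + z[, 2]
  ps <- fake_psa(cost = cbind(t1 = dc, ref = 0 * dc),
                 qaly = cbind(t1 = dq, ref = 0 * dq))
  e <- confidence_ellipse(ps, "t1", "ref")
  expect_false(e$collapsed)
  expect_equal(unname(e$center), c(mean(dq), mean(dc)), tolerance = 1e-9)
  expect_equal(e$radius2, qchisq(0.95, 2), tolerance = 1e-12)
  # swapping the pair negates the center
  e2 <- confidence_ellipse(ps, "ref", "t1")
  expect_equal(unname(e2$center), -unname(e$center), tolerance = 1e-9)
  # empirical coverage close to the nominal 95%
  cover <- mean(in_ellipse(e, dq, dc))
  expect_lt(abs(cover - 0.95), 0.015)
  # boundary points lie on the contour
  pts <- ellipse_points(e, 64)
  d2 <- mapply(function(x, y) {
    v <- c(x, y) - e$center
    drop(t(v) %*% solve(e$cov) %*% v)
  }, pts$dqaly, pts$dcost)
  expect_true(all(abs(d2 - e$radius2) < 1e-6 * e$radius2))

  # identical draws collapse to a point
  same <- fake_psa(cost = cbind(t1 = rep(5, 10), ref = rep(0, 10)),
                   qaly = cbind(t1 = rep(1, 10), ref = rep(0, 10)))
  ec <- confidence_ellipse(same, "t1", "ref")
  expect_true(ec$collapsed)
  expect_error(confidence_ellipse(same[same$draw <= 2, ], "t1", "ref"),
               class = "crswnp_validation")
})

test_that("threshold prices equalise net monetary benefit within a dollar", {
  spec <- replication_spec()
  p <- threshold_price(spec, "dupilumab", "omalizumab", wtp = 50000)
  expect_lt(p, spec$arms$dupilumab$drug_cost_yearly)
  # substitution check: NMB gap at the returned price within the $1-bisection
  s2 <- spec
  s2$arms$dupilumab$drug_cost_yearly <- as.numeric(p)
  dup <- run_cohort(s2, "dupilumab"); oma <- run_cohort(s2, "omalizumab")
  gap <- (50000 * dup$total_qaly - dup$total_cost) -
    (50000 * oma$total_qaly - oma$total_cost)
  # $1 of yearly price maps to ~8 discounted dollars of NMB
  expect_lt(abs(gap), 10)

  # already cost-effective: current price returned with a notice
  cheap <- spec
  cheap$arms$dupilumab$drug_cost_yearly <- 1000
  expect_message(p2 <- threshold_price(cheap, "dupilumab", "omalizumab"),
                 "already cost-effective")
  expect_equal(as.numeric(p2), 1000)

  # no crossing anywhere in (0, current]: classed signal
  hopeless <- spec
  hopeless$arms$dupilumab$snot22$mean <- 100  # far worse outcomes at any price
  expect_error(threshold_price(hopeless, "dupilumab", "omalizumab"),
               class = "crswnp_no_threshold")
  expect_error(threshold_price(spec, "dupilumab", "nope"),
               class = "crswnp_lookup")
})

test_that("dosing scenarios rescale only the drug component", {
  spec <- replication_spec()
  H <- spec$shared$horizon_years
  base <- run_cohort(spec, "dupilumab")

  ident <- dosing_scenario(spec, "dupilumab", rep(1, H))
  tot <- attr(ident, "totals")
  expect_equal(tot$total_cost[tot$strategy == "dupilumab"], base$total_cost,
               tolerance = 1e-9)

  zero <- dosing_scenario(spec, "dupilumab", rep(0, H))
  tz <- attr(zero, "totals")
  # removing the drug leaves event costs only: difference equals the
  # discounted on-treatment drug accrual
  drug_accrual <- (1 - spec$arms$dupilumab$p_nonadherent) *
    spec$arms$dupilumab$drug_cost_yearly *
    sum((1 + spec$shared$discount_rate)^-(0:(H - 1)))
  expect_equal(base$total_cost - tz$total_cost[tz$strategy == "dupilumab"],
               drug_accrual, tolerance = 1e-6)
  # QALYs untouched by pricing
  expect_equal(tz$total_qaly[tz$strategy == "dupilumab"], base$total_qaly)

  expect_error(dosing_scenario(spec, "dupilumab", rep(-1, H)),
               class = "crswnp_validation")
  expect_error(dosing_scenario(spec, "dupilumab", rep(1, H - 1)),
               class = "crswnp_validation")
})
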