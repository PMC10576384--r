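# Synthetic model generator and individual-level microsimulation oracle.
#
# The generator produces structurally valid random configurations (no
# resemblance to any real drug) so every pipeline stage can be exercised
# without the shipped inputs; the microsimulation re-derives cohort
# expectations by brute force from per-patient Bernoulli event histories,
# sharing no accrual code with the cohort engine.

runif_corner <- function(n, lo, hi, corner = 0, p_corner = 0.05) {
  # uniform draw with a >= p_corner chance of the stated degenerate corner
  x <- stats::runif(n, lo, hi)
  ifelse(stats::runif(n) < p_corner, corner, x)
}

#' Generate a random, structurally valid model specification
#'
#' Draws 2-5 arms (the first is the no-treatment comparator), uniform event
#' probabilities, log-uniform costs in \[100, 50000\], SNOT-22 means in
#' \[5, 100\] with beta-feasible standard deviations, and a horizon of 1-20
#' years.  Degenerate corners (zero event probabilities, zero drug cost,
#' zero non-adherence) each occur with probability at least 5% so boundary
#' behaviour is routinely exercised.  Reproducible under `seed`.
#'
#' @param seed Integer seed.
#' @return A [model_spec()] that passes all parameter validation.
#' @export
generate_random_model <- function(seed) {
  set.seed(seed)
  n_arms <- sample(2:5, 1)
  horizon <- sample(1:20, 1)
  discount <- runif_corner(1, 0.005, 0.06)
  mapping <- utility_mapping(intercept = stats::runif(1, 0.6, 0.95),
                             slope = stats::runif(1, 0.001, 0.008))
  comp_costs <- stats::setNames(exp(stats::runif(6, log(100), log(50000))),
                                COMPLICATION_LABELS)
  w <- stats::rexp(6); w <- w / sum(w)
  shared <- shared_params(
    ess_cost = exp(stats::runif(1, log(100), log(50000))),
    complication_costs = comp_costs,
    complication_weights = stats::setNames(w, COMPLICATION_LABELS),
    ocs_course_cost = runif_corner(1, 5, 500),
    discount_rate = discount,
    horizon_years = horizon,
    wtp = stats::runif(1, 1e4, 3e5)
  )

  snot_est <- function() {
    m <- stats::runif(1, 5, 100)
    sd_max <- 110 * sqrt((m / 110) * (1 - m / 110))
    sd <- stats::runif(1, 0.05, 0.5) * sd_max
    param_estimate(m, sd = sd, distribution = "beta", scale = 110)
  }
  arms <- list()
  arms[["standard_care"]] <- strategy_params(
    "standard_care",
    p_revision_yearly = runif_corner(1, 0, 0.5),
    p_ocs_yearly = runif_corner(1, 0, 0.8),
    p_adverse_yearly = 0,
    p_nonadherent = 0,
    snot22 = snot_est(),
    drug_cost_yearly = 0
  )
  for (k in seq_len(n_arms - 1)) {
    nm <- paste0("treatment_", k)
    if (stats::runif(1) < 0.05) {
      # fully inert arm: the joint corner that isolates the discounted
      # annuity closed form
      arms[[nm]] <- strategy_params(nm, 0, 0, 0, 0, snot_est(), 0)
      next
    }
    arms[[nm]] <- strategy_params(
      nm,
      p_revision_yearly = runif_corner(1, 0, 0.5),
      p_ocs_yearly = runif_corner(1, 0, 0.8),
      p_adverse_yearly = runif_corner(1, 0, 0.8),
      p_nonadherent = runif_corner(1, 0, 0.4),
      snot22 = snot_est(),
      drug_cost_yearly = if (stats::runif(1) < 0.07) 0 else
        exp(stats::runif(1, log(100), log(50000)))
    )
  }
  model_spec(arms, shared, mapping, comparator = "standard_care")
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` independent patients through one strategy arm:
#' a single Bernoulli non-adherence draw at entry (absorbing), then yearly
#' Bernoulli revision / rescue-OCS / adverse events with their costs,
#' state-determined utilities and the same discounting convention as the
#' cohort engine - but via per-patient event histories rather than
#' expectation accrual, so it is an independent check of [run_cohort()].
#'
#' @param spec A [model_spec()].
#' @param arm Arm name.
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @return A `microsim_result`: means, Monte Carlo standard errors (`NA`
#'   with a flag when `n_patients == 1`) and `n_patients`.
#' @export
microsimulate <- function(spec, arm, n_patients, seed) {
  check_number(n_patients, "n_patients", lower = 1)
  a <- spec$arms[[arm]]
  if (is.null(a)) cea_stop("lookup", "unknown arm '%s'", arm)
  shared <- spec$shared
  comp <- spec$arms[[spec$comparator]]
  H <- shared$horizon_years
  mult <- spec$dosing_profiles[[arm]] %||% rep(1, H)
  comp_cost <- expected_complication_cost(shared)
  u_on <- snot22_to_utility(a$snot22$mean, spec$mapping)
  u_off <- snot22_to_utility(comp$snot22$mean, spec$mapping)

  set.seed(seed)
  n <- as.integer(n_patients)
  on <- stats::runif(n) >= a$p_nonadherent   # entry split, absorbing
  cost <- numeric(n)
  qaly <- numeric(n)
  for (t in 0:(H - 1)) {
    df <- (1 + shared$discount_rate)^(-t)
    rev_p <- ifelse(on, a$p_revision_yearly, comp$p_revision_yearly)
    ocs_p <- ifelse(on, a$p_ocs_yearly, comp$p_ocs_yearly)
    ae_p <- ifelse(on, a$p_adverse_yearly, 0)
    ycost <- (stats::runif(n) < rev_p) * shared$ess_cost +
      (stats::runif(n) < ocs_p) * shared$ocs_course_cost +
      (stats::runif(n) < ae_p) * comp_cost +
      on * a$drug_cost_yearly * mult[t + 1]
    cost <- cost + df * ycost
    qaly <- qaly + df * ifelse(on, u_on, u_off)
  }
  se <- if (n > 1) {
    c(cost = stats::sd(cost) / sqrt(n), qaly = stats::sd(qaly) / sqrt(n))
  } else {
    c(cost = NA_real_, qaly = NA_real_)
  }
  structure(list(arm = arm,
                 n_patients = n,
                 mean_cost = mean(cost),
                 mean_qaly = mean(qaly),
                 se_cost = se[["cost"]],
                 se_qaly = se[["qaly"]],
                 se_defined = n > 1),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> arm '%s', n=%d: cost $%.2f (SE %s), QALY %.4f (SE %s)\n",
              x$arm, x$n_patients, x$mean_cost,
              ifelse(x$se_defined, sprintf("%.2f", x$se_cost), "undefined"),
              x$mean_qaly,
              ifelse(x$se_defined, sprintf("%.5f", x$se_qaly), "undefined")))
  invisible(x)
}

#' Engine-versus-oracle agreement report
#'
#' Generates `n_specs` random models (generation and simulation use
#' separate seed streams), runs one randomly chosen arm of each through
#' both the cohort engine and the microsimulation oracle, and reports the
#' z-scores (difference / Monte Carlo SE) for cost and QALYs.
#'
#' @param n_specs Number of random specifications, default 50.
#' @param n_patients Patients per microsimulation, default 20000.
#' @param seed Integer seed.
#' @return Tibble with one row per spec: arm, engine and oracle values,
#'   SEs and z-scores.
#' @export
validate_engine <- function(n_specs = 50, n_patients = 20000, seed = 1) {
  set.seed(seed)
  gen_seeds <- sample.int(.Machine$integer.max - 1L, n_specs)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_specs)
  rows <- vector("list", n_specs)
  for (i in seq_len(n_specs)) {
    spec <- generate_random_model(gen_seeds[i])
    set.seed(sim_seeds[i])
    arm <- sample(names(spec$arms), 1)
    eng <- run_cohort(spec, arm, keep_trace = FALSE)
    mc <- microsimulate(spec, arm, n_patients, seed = sim_seeds[i])
    # an SE of exactly 0 (fully deterministic arm) must coincide to
    # floating-point accuracy
    zscore <- function(e, m, se) {
      if (se > 0) return((e - m) / se)
      if (abs(e - m) <= 1e-8 * max(1, abs(m))) 0 else Inf
    }
    zc <- zscore(eng$total_cost, mc$mean_cost, mc$se_cost)
    zq <- zscore(eng$total_qaly, mc$mean_qaly, mc$se_qaly)
    rows[[i]] <- tibble::tibble(
      spec_seed = gen_seeds[i], arm = arm,
      engine_cost = eng$total_cost, oracle_cost = mc$mean_cost,
      se_cost = mc$se_cost, z_cost = zc,
      engine_qaly = eng$total_qaly, oracle_qaly = mc$mean_qaly,
      se_qaly = mc$se_qaly, z_qaly = zq
    )
  }
  do.call(rbind, rows)
}
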