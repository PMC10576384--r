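# Annual-cycle Markov cohort engine.
#
# State structure: at model entry the non-adherent proportion moves to an
# absorbing off-treatment state that inherits the comparator's event rates,
# utility and zero drug cost; the remainder stays on treatment for the whole
# horizon.  Events (revision surgery, rescue OCS, adverse event) are
# cost-only and independent within a cycle; accrual is by expectation.
# The first cycle is undiscounted (factor (1+r)^-t, t = 0 .. H-1), with no
# half-cycle correction.

#' Per-cycle discount factor
#'
#' @param rate Nonnegative yearly discount rate.
#' @param cycle_index 0-based cycle index (cycle 0 is undiscounted).
#' @return `(1 + rate)^-cycle_index`.
#' @export
discount_factor <- function(rate, cycle_index) {
  check_number(rate, "rate", lower = 0)
  if (any(cycle_index < 0)) {
    cea_stop("validation", "`cycle_index` must be >= 0")
  }
  (1 + rate)^(-cycle_index)
}

#' Cohort state vector
#'
#' @param on_treatment,off_treatment Nonnegative proportions summing to 1.
#' @return A `state_vector` (cohort conservation enforced).
#' @export
state_vector <- function(on_treatment, off_treatment) {
  check_number(on_treatment, "on_treatment", lower = 0)
  check_number(off_treatment, "off_treatment", lower = 0)
  if (abs(on_treatment + off_treatment - 1) > 1e-9) {
    cea_stop("validation", "state proportions must sum to 1 (got %g)",
             on_treatment + off_treatment)
  }
  structure(list(on_treatment = on_treatment, off_treatment = off_treatment),
            class = "state_vector")
}

#' Expected cost accrued by one cohort cycle
#'
#' The on-treatment fraction accrues the (multiplier-scaled) drug cost plus
#' probability-weighted event costs: adverse event x expected complication
#' cost, rescue OCS course, and revision surgery.  The off-treatment
#' fraction accrues the comparator's revision and OCS event costs with zero
#' drug and zero biologic adverse-event cost.  Additive in the state split.
#'
#' @param arm A [strategy_params()].
#' @param shared A [shared_params()].
#' @param state A [state_vector()].
#' @param year_multiplier Nonnegative drug-cost multiplier for this cycle.
#' @param comparator The comparator [strategy_params()] whose event rates
#'   apply off treatment.
#' @return Expected cost (CAD) for the cycle.
#' @export
cycle_cost <- function(arm, shared, state, year_multiplier = 1,
                       comparator = arm) {
  check_number(year_multiplier, "year_multiplier", lower = 0)
  comp_cost <- expected_complication_cost(shared)
  on_cost <- arm$drug_cost_yearly * year_multiplier +
    arm$p_adverse_yearly * comp_cost +
    arm$p_ocs_yearly * shared$ocs_course_cost +
    arm$p_revision_yearly * shared$ess_cost
  off_cost <- comparator$p_revision_yearly * shared$ess_cost +
    comparator$p_ocs_yearly * shared$ocs_course_cost
  state$on_treatment * on_cost + state$off_treatment * off_cost
}

#' Expected QALYs accrued by one cohort cycle
#'
#' Convex combination of the on-treatment utility (arm SNOT-22 mapped to
#' utility) and the off-treatment utility (comparator SNOT-22).
#'
#' @param arm A [strategy_params()].
#' @param mapping A [utility_mapping()].
#' @param state A [state_vector()].
#' @param comparator_snot22 SNOT-22 score applying off treatment.
#' @return Expected QALYs for one year, bounded in \[0, 1\].
#' @export
cycle_qaly <- function(arm, mapping, state, comparator_snot22) {
  u_on <- snot22_to_utility(arm$snot22$mean, mapping)
  u_off <- snot22_to_utility(comparator_snot22, mapping)
  state$on_treatment * u_on + state$off_treatment * u_off
}

#' Run the cohort model for one strategy arm
#'
#' Applies the one-time non-adherence split at model entry, then accrues
#' expected costs and QALYs over the horizon with per-cycle discounting.
#'
#' @param spec A [model_spec()].
#' @param arm_name Name of the arm to run.
#' @param keep_trace If `FALSE`, skip building the per-cycle trace (used in
#'   tight Monte Carlo loops).
#' @return An object of class `cohort_trace`: per-cycle tibble `trace`
#'   (states, discount factor, undiscounted and discounted accruals) and
#'   totals `total_cost`, `total_qaly`, `undiscounted_cost`,
#'   `undiscounted_qaly`.
#' @export
run_cohort <- function(spec, arm_name, keep_trace = TRUE) {
  arm <- spec$arms[[arm_name]]
  if (is.null(arm)) {
    cea_stop("lookup", "unknown arm '%s' (have: %s)", arm_name,
             paste(names(spec$arms), collapse = ", "))
  }
  shared <- spec$shared
  comp <- spec$arms[[spec$comparator]]
  H <- shared$horizon_years
  mult <- spec$dosing_profiles[[arm_name]] %||% rep(1, H)

  on <- 1 - arm$p_nonadherent
  off <- arm$p_nonadherent

  comp_cost <- expected_complication_cost(shared)
  on_fixed <- arm$p_adverse_yearly * comp_cost +
    arm$p_ocs_yearly * shared$ocs_course_cost +
    arm$p_revision_yearly * shared$ess_cost
  off_cost <- comp$p_revision_yearly * shared$ess_cost +
    comp$p_ocs_yearly * shared$ocs_course_cost
  u_on <- snot22_to_utility(arm$snot22$mean, spec$mapping)
  u_off <- snot22_to_utility(comp$snot22$mean, spec$mapping)

  cost <- on * (arm$drug_cost_yearly * mult + on_fixed) + off * off_cost
  qaly <- rep(on * u_on + off * u_off, H)
  df <- (1 + shared$discount_rate)^(-(0:(H - 1)))

  out <- list(arm = arm_name,
              total_cost = sum(df * cost),
              total_qaly = sum(df * qaly),
              undiscounted_cost = sum(cost),
              undiscounted_qaly = sum(qaly))
  if (keep_trace) {
    out$trace <- tibble::tibble(
      cycle = 0:(H - 1),
      on_treatment = rep(on, H),
      off_treatment = rep(off, H),
      discount_factor = df,
      cost = cost,
      qaly = qaly,
      discounted_cost = df * cost,
      discounted_qaly = df * qaly
    )
  }
  structure(out, class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> arm '%s': discounted $%.2f / %.4f QALYs (undiscounted $%.2f / %.4f)\n",
              x$arm, x$total_cost, x$total_qaly,
              x$undiscounted_cost, x$undiscounted_qaly))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  as.data.frame(x$trace)
}

#' Run every arm and collect strategy outcomes
#'
#' @param spec A [model_spec()].
#' @param arms Arm names to run (default all).
#' @return Tibble with columns `strategy`, `total_cost`, `total_qaly` and
#'   (as attribute `"traces"`) the named list of [run_cohort()] results.
#' @export
run_all_arms <- function(spec, arms = names(spec$arms)) {
  traces <- lapply(arms, run_cohort, spec = spec)
  names(traces) <- arms
  out <- tibble::tibble(
    strategy = arms,
    total_cost = unname(vapply(traces, `[[`, 0, "total_cost")),
    total_qaly = unname(vapply(traces, `[[`, 0, "total_qaly"))
  )
  attr(out, "traces") <- traces
  out
}
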