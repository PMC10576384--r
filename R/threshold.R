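# Deterministic one-way sensitivity analyses: threshold drug price and
# alternative dosing-frequency scenarios.

#' Threshold yearly drug price by bisection
#'
#' Finds the yearly drug acquisition price at which the target strategy's
#' net monetary benefit equals the reference strategy's in the
#' deterministic base case, by monotone bisection to within `tol` dollars.
#' If the target is already cost-effective at its current price, the
#' current price is returned with a notice; if no crossing exists in
#' `(0, current price]`, a classed error (`crswnp_no_threshold`) is
#' raised.
#'
#' @param spec A [model_spec()].
#' @param target_arm,reference_arm Arm names.
#' @param wtp Willingness-to-pay (CAD/QALY); default the model's.
#' @param tol Bisection tolerance in CAD, default 1.
#' @return Threshold yearly price (CAD/year) with attributes
#'   `current_price`, `nmb_gap` (residual NMB difference at the returned
#'   price) and `iterations`.
#' @export
threshold_price <- function(spec, target_arm, reference_arm,
                            wtp = spec$shared$wtp, tol = 1) {
  for (a in c(target_arm, reference_arm)) {
    if (!a %in% names(spec$arms)) cea_stop("lookup", "unknown arm '%s'", a)
  }
  check_number(wtp, "wtp", lower = 0)
  current <- spec$arms[[target_arm]]$drug_cost_yearly
  ref <- run_cohort(spec, reference_arm, keep_trace = FALSE)
  nmb_ref <- wtp * ref$total_qaly - ref$total_cost

  gap_at <- function(price) {
    s <- spec
    s$arms[[target_arm]]$drug_cost_yearly <- price
    tr <- run_cohort(s, target_arm, keep_trace = FALSE)
    (wtp * tr$total_qaly - tr$total_cost) - nmb_ref
  }

  g_cur <- gap_at(current)
  if (g_cur >= 0) {
    message(sprintf("'%s' is already cost-effective vs '%s' at WTP %s; returning current price",
                    target_arm, reference_arm, format(wtp)))
    return(structure(current, current_price = current, nmb_gap = g_cur,
                     iterations = 0L))
  }
  if (gap_at(0) < 0) {
    cea_stop("no_threshold",
             "no price in (0, %s] makes '%s' cost-effective vs '%s' at WTP %s",
             format(current), target_arm, reference_arm, format(wtp))
  }

  lo <- 0; hi <- current; it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap_at(mid) >= 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  price <- (lo + hi) / 2
  structure(price, current_price = current, nmb_gap = gap_at(price),
            iterations = it)
}

#' Alternative dosing-frequency scenario
#'
#' Re-runs the deterministic base case with one arm's yearly drug cost
#' scaled by a per-year multiplier profile (dose-proportional pricing:
#' the multiplier is the fraction of the full-frequency injections given
#' that year).  Efficacy inputs are left unchanged, i.e. the reduced
#' frequency is assumed to maintain the same outcomes.
#'
#' @param spec A [model_spec()].
#' @param arm Arm whose drug cost is rescaled.
#' @param profile Numeric vector of nonnegative multipliers, one per model
#'   year.
#' @param baseline Baseline for ICER reporting (passed to
#'   [rank_strategies()]).
#' @return A [rank_strategies()] result over all arms under the scenario,
#'   with the per-arm [run_cohort()] traces in attribute `"traces"` and a
#'   tibble of discounted and undiscounted totals in attribute `"totals"`.
#' @export
dosing_scenario <- function(spec, arm, profile, baseline = NULL) {
  if (!arm %in% names(spec$arms)) cea_stop("lookup", "unknown arm '%s'", arm)
  H <- spec$shared$horizon_years
  if (length(profile) != H || any(!is.finite(profile)) || any(profile < 0)) {
    cea_stop("validation",
             "`profile` must be %d nonnegative multipliers (got %d)",
             H, length(profile))
  }
  spec$dosing_profiles[[arm]] <- profile
  outcomes <- run_all_arms(spec)
  traces <- attr(outcomes, "traces")
  res <- rank_strategies(outcomes, baseline = baseline)
  attr(res, "traces") <- traces
  attr(res, "totals") <- tibble::tibble(
    strategy = names(traces),
    total_cost = unname(vapply(traces, `[[`, 0, "total_cost")),
    total_qaly = unname(vapply(traces, `[[`, 0, "total_qaly")),
    undiscounted_cost = unname(vapply(traces, `[[`, 0, "undiscounted_cost")),
    undiscounted_qaly = unname(vapply(traces, `[[`, 0, "undiscounted_qaly"))
  )
  attr(res, "scenario") <- list(arm = arm, profile = profile)
  res
}
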