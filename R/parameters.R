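# Parameter containers and transformations: beta distribution fitting,
# probability conversions, the SNOT-22 -> utility mapping, and expected
# complication costs.

#' Beta distribution specification
#'
#' A pair of positive shape parameters describing a beta distribution used
#' to propagate uncertainty in probabilities and in rescaled SNOT-22
#' scores.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_spec` with elements `alpha` and `beta`.
#' @seealso [fit_beta_from_moments()], [fit_beta_fixed_alpha()]
#' @export
beta_spec <- function(alpha, beta) {
  check_number(alpha, "alpha", lower = .Machine$double.eps)
  check_number(beta, "beta", lower = .Machine$double.eps)
  structure(list(alpha = alpha, beta = beta), class = "beta_spec")
}

#' @export
print.beta_spec <- function(x, ...) {
  cat(sprintf("Beta(%.6g, %.6g)  mean %.6g, sd %.6g\n",
              x$alpha, x$beta, beta_mean(x), beta_sd(x)))
  invisible(x)
}

#' Analytic moments of a beta specification
#'
#' @param spec A [beta_spec()].
#' @return `beta_mean()` returns alpha/(alpha+beta); `beta_sd()` the
#'   analytic standard deviation.
#' @export
beta_mean <- function(spec) spec$alpha / (spec$alpha + spec$beta)

#' @rdname beta_mean
#' @export
beta_sd <- function(spec) {
  s <- spec$alpha + spec$beta
  sqrt(spec$alpha * spec$beta / (s^2 * (s + 1)))
}

#' Fit a beta distribution by the method of moments
#'
#' Inverts the beta mean/variance equations so that the returned
#' distribution has exactly the requested moments.  The variance of a beta
#' distribution cannot exceed `mean * (1 - mean)`; infeasible requests are
#' rejected with an error naming the offending parameter.
#'
#' @param mean Mean in (0, 1).
#' @param sd Positive standard deviation with `sd^2 < mean * (1 - mean)`.
#' @param label Optional parameter name used in error messages.
#' @return A [beta_spec()] whose analytic mean and sd equal the inputs.
#' @export
fit_beta_from_moments <- function(mean, sd, label = "parameter") {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) ||
      mean <= 0 || mean >= 1) {
    cea_stop("validation", "beta mean for `%s` must lie strictly in (0, 1), got %s",
             label, format(mean))
  }
  check_number(sd, paste0("sd of ", label), lower = 0)
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean)) {
    cea_stop("validation",
             "`%s`: variance %g is infeasible for a beta with mean %g (must be in (0, %g))",
             label, v, mean, mean * (1 - mean))
  }
  nu <- mean * (1 - mean) / v - 1
  beta_spec(mean * nu, (1 - mean) * nu)
}

#' Fit a beta distribution with a fixed first shape parameter
#'
#' Solves `alpha / (alpha + beta) = mean` for `beta` with `alpha` held
#' fixed, the convention used when only a mean and a nominal `Beta(2, x)`
#' pair are reported for a probability.
#'
#' @param mean Mean in (0, 1).
#' @param alpha Fixed positive first shape parameter (default 2).
#' @param label Optional parameter name used in error messages.
#' @return A [beta_spec()] with mean equal to `mean`.
#' @export
fit_beta_fixed_alpha <- function(mean, alpha = 2, label = "parameter") {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) ||
      mean <= 0 || mean >= 1) {
    cea_stop("validation", "beta mean for `%s` must lie strictly in (0, 1), got %s",
             label, format(mean))
  }
  check_number(alpha, "alpha", lower = .Machine$double.eps)
  beta_spec(alpha, alpha * (1 - mean) / mean)
}

#' Convert a cumulative multi-year risk to a constant yearly probability
#'
#' Assumes a constant yearly hazard, i.e. the complement compounds:
#' `1 - (1 - cumulative_rate)^(1/years)`.  Re-compounding the result over
#' `years` recovers the cumulative rate.
#'
#' @param cumulative_rate Cumulative risk over the whole period, in \[0, 1).
#' @param years Positive integer number of years in the period.
#' @return The equivalent yearly probability.
#' @export
annualize_probability <- function(cumulative_rate, years) {
  check_number(cumulative_rate, "cumulative_rate", lower = 0)
  if (cumulative_rate >= 1) {
    cea_stop("validation", "`cumulative_rate` must be < 1, got %g", cumulative_rate)
  }
  check_number(years, "years", lower = 1)
  if (years != as.integer(years)) {
    cea_stop("validation", "`years` must be a positive integer, got %g", years)
  }
  1 - (1 - cumulative_rate)^(1 / years)
}

#' Linear SNOT-22 to utility mapping
#'
#' Health utility is obtained from the 22-item Sinonasal Outcome Test
#' score (0-110, higher is worse) by a linear mapping
#' `utility = intercept - slope * score`, clipped to \[floor, ceiling\].
#' The default coefficients (0.81, 0.0062) are a generic published-style
#' anchor; the shipped replication configuration overrides them with
#' calibrated values (see the methods vignette).
#'
#' @param intercept Utility at a SNOT-22 score of 0.
#' @param slope Nonnegative utility decrement per SNOT-22 point.
#' @param floor,ceiling Clipping bounds, default 0 and 1.
#' @return An object of class `utility_mapping`.
#' @export
utility_mapping <- function(intercept = 0.81, slope = 0.0062,
                            floor = 0, ceiling = 1) {
  check_number(intercept, "intercept")
  check_number(slope, "slope", lower = 0)
  check_number(floor, "floor")
  check_number(ceiling, "ceiling", lower = floor)
  structure(list(intercept = intercept, slope = slope,
                 floor = floor, ceiling = ceiling),
            class = "utility_mapping")
}

#' Map SNOT-22 scores to health utilities
#'
#' @param score SNOT-22 score(s) in \[0, 110\].
#' @param mapping A [utility_mapping()].
#' @return Utilities in \[floor, ceiling\], monotone non-increasing in score.
#' @export
snot22_to_utility <- function(score, mapping = utility_mapping()) {
  if (!is.numeric(score) || any(is.na(score))) {
    cea_stop("validation", "`score` must be numeric without NAs")
  }
  if (any(score < 0 | score > 110)) {
    cea_stop("validation", "SNOT-22 scores must lie in [0, 110], got %g",
             score[which(score < 0 | score > 110)[1]])
  }
  clip01(mapping$intercept - mapping$slope * score, mapping$floor, mapping$ceiling)
}

# canonical complication labels, in fixture order
COMPLICATION_LABELS <- c("anaphylaxis", "arthritis", "conjunctivitis",
                         "egpa", "hypersensitivity", "injection_reaction")

#' Named complication-weight profiles
#'
#' Three shipped simplex weightings over the six costed biologic
#' complications (anaphylaxis, arthritis, conjunctivitis, EGPA,
#' hypersensitivity, injection reaction):
#' * `"equal"` - uniform weights (arithmetic mean of the six costs);
#' * `"rare_egpa"` - EGPA down-weighted to 0.01, remainder uniform;
#' * `"calibrated"` - maximum-entropy tilt toward the mild complications,
#'   used by the replication configuration (see the methods vignette).
#'
#' @param profile One of `"equal"`, `"rare_egpa"`, `"calibrated"`.
#' @return Named numeric vector summing to 1.
#' @export
complication_weight_profile <- function(profile = c("equal", "rare_egpa", "calibrated")) {
  profile <- match.arg(profile)
  w <- switch(profile,
    equal = rep(1 / 6, 6),
    rare_egpa = c(rep(0.99 / 5, 3), 0.01, rep(0.99 / 5, 2)),
    calibrated = c(0.1384, 0.0320, 0.3328, 0.0000, 0.2484, 0.2484)
  )
  stats::setNames(w, COMPLICATION_LABELS)
}

#' Expected cost of a biologic complication
#'
#' Weighted mean of the per-complication management costs under a simplex
#' of complication-type weights.  The probability and mix of complications
#' are taken to be identical across biologics, so a single expected cost
#' applies to every arm.
#'
#' @param shared A [shared_params()] object (or any list with
#'   `complication_costs` and `complication_weights`).
#' @return Expected complication cost in CAD.
#' @export
expected_complication_cost <- function(shared) {
  costs <- shared$complication_costs
  w <- shared$complication_weights
  if (length(w) != length(costs)) {
    cea_stop("validation",
             "complication weights (%d) and costs (%d) have different lengths",
             length(w), length(costs))
  }
  if (!is.null(names(w)) && !is.null(names(costs))) {
    if (!setequal(names(w), names(costs))) {
      cea_stop("validation", "complication weight names do not match cost names")
    }
    w <- w[names(costs)]
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    cea_stop("validation", "complication weights must be nonnegative and sum to 1")
  }
  sum(w * costs)
}

#' Parameter estimate with an uncertainty distribution
#'
#' @param mean Point estimate.
#' @param sd Optional nonnegative standard deviation (`NA` if unknown).
#' @param distribution `"fixed"` or `"beta"`.
#' @param alpha,beta Optional explicit beta shape parameters (used when a
#'   nominal pair such as Beta(2, 4.28) is reported instead of an sd).
#' @param scale Upper bound of the measurement scale (1 for probabilities,
#'   110 for SNOT-22); beta sampling operates on `mean/scale`.
#' @return An object of class `param_estimate`.
#' @export
param_estimate <- function(mean, sd = NA_real_,
                           distribution = c("fixed", "beta"),
                           alpha = NA_real_, beta = NA_real_, scale = 1) {
  distribution <- match.arg(distribution)
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0, allow_na = TRUE)
  check_number(scale, "scale", lower = .Machine$double.eps)
  sd <- if (length(sd) == 0 || is.null(sd)) NA_real_ else sd
  if (distribution == "fixed" && !is.na(sd) && sd != 0) {
    cea_stop("validation", "a fixed parameter cannot carry a nonzero sd (got %g)", sd)
  }
  if (distribution == "beta" && !is.na(sd) && sd > 0) {
    m <- mean / scale
    if (sd^2 / scale^2 >= m * (1 - m)) {
      cea_stop("validation",
               "sd %g is beta-infeasible for mean %g on scale %g", sd, mean, scale)
    }
  }
  structure(list(mean = mean, sd = sd, distribution = distribution,
                 alpha = alpha, beta = beta, scale = scale),
            class = "param_estimate")
}

# Resolve the beta_spec implied by a param_estimate, or NULL when the
# estimate is fixed / has no usable spread.  Draws are on the [0, scale]
# scale once multiplied back by `scale`.
resolve_beta <- function(pe, label = "parameter") {
  if (pe$distribution != "beta") return(NULL)
  if (!is.na(pe$alpha) && !is.na(pe$beta)) return(beta_spec(pe$alpha, pe$beta))
  if (!is.na(pe$sd) && pe$sd > 0) {
    return(fit_beta_from_moments(pe$mean / pe$scale, pe$sd / pe$scale, label = label))
  }
  NULL
}

#' Strategy-level model parameters
#'
#' Bundles every arm-specific input: yearly event probabilities (revision
#' endoscopic sinus surgery, rescue oral corticosteroids, biologic adverse
#' event), the one-time non-adherence proportion, the on-treatment SNOT-22
#' score and the yearly drug acquisition cost (0 for the no-biologic
#' comparator).
#'
#' @param name Strategy identifier.
#' @param p_revision_yearly,p_ocs_yearly,p_adverse_yearly Yearly event
#'   probabilities in \[0, 1\].
#' @param p_nonadherent One-time proportion of the cohort that abandons
#'   treatment at model entry.
#' @param snot22 SNOT-22 score while on this strategy, either a number or
#'   a [param_estimate()] on the 0-110 scale.
#' @param drug_cost_yearly Yearly drug cost in CAD (>= 0).
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(name, p_revision_yearly, p_ocs_yearly,
                            p_adverse_yearly, p_nonadherent, snot22,
                            drug_cost_yearly) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    cea_stop("validation", "strategy `name` must be a nonempty string")
  }
  check_probability(p_revision_yearly, paste0(name, ": p_revision_yearly"))
  check_probability(p_ocs_yearly, paste0(name, ": p_ocs_yearly"))
  check_probability(p_adverse_yearly, paste0(name, ": p_adverse_yearly"))
  check_probability(p_nonadherent, paste0(name, ": p_nonadherent"))
  if (inherits(snot22, "param_estimate")) {
    check_number(snot22$mean, paste0(name, ": snot22 mean"), 0, 110)
  } else {
    check_number(snot22, paste0(name, ": snot22"), 0, 110)
    snot22 <- param_estimate(snot22, distribution = "fixed", scale = 110)
  }
  check_number(drug_cost_yearly, paste0(name, ": drug_cost_yearly"), lower = 0)
  structure(list(name = name,
                 p_revision_yearly = p_revision_yearly,
                 p_ocs_yearly = p_ocs_yearly,
                 p_adverse_yearly = p_adverse_yearly,
                 p_nonadherent = p_nonadherent,
                 snot22 = snot22,
                 drug_cost_yearly = drug_cost_yearly),
            class = "strategy_params")
}

#' Shared model parameters
#'
#' Quantities common to all strategies: the cost of endoscopic sinus
#' surgery, the six complication costs and their mixing weights, the cost
#' of a rescue oral corticosteroid course, the yearly discount rate, the
#' model horizon and the willingness-to-pay threshold.
#'
#' @param ess_cost Cost of one endoscopic sinus surgery (CAD).
#' @param complication_costs Named numeric vector of per-complication
#'   management costs (CAD).
#' @param complication_weights Simplex weights over the complications;
#'   defaults to equal weights.
#' @param ocs_course_cost Cost of one rescue oral corticosteroid course
#'   (CAD), default 35.
#' @param discount_rate Yearly discount rate applied to costs and
#'   outcomes, default 0.03.
#' @param horizon_years Integer model horizon in years, default 10.
#' @param wtp Willingness-to-pay threshold in CAD per QALY, default 50000.
#' @return An object of class `shared_params`.
#' @export
shared_params <- function(ess_cost,
                          complication_costs,
                          complication_weights = NULL,
                          ocs_course_cost = 35,
                          discount_rate = 0.03,
                          horizon_years = 10,
                          wtp = 50000) {
  check_number(ess_cost, "ess_cost", lower = 0)
  if (!is.numeric(complication_costs) || length(complication_costs) < 1 ||
      any(complication_costs < 0)) {
    cea_stop("validation", "`complication_costs` must be nonnegative numbers")
  }
  if (is.null(complication_weights)) {
    complication_weights <- rep(1 / length(complication_costs),
                                length(complication_costs))
    names(complication_weights) <- names(complication_costs)
  }
  check_number(ocs_course_cost, "ocs_course_cost", lower = 0)
  check_number(discount_rate, "discount_rate", lower = 0)
  check_number(horizon_years, "horizon_years", lower = 1)
  if (horizon_years != as.integer(horizon_years)) {
    cea_stop("validation", "`horizon_years` must be an integer, got %g", horizon_years)
  }
  check_number(wtp, "wtp", lower = 0)
  out <- structure(list(ess_cost = ess_cost,
                        complication_costs = complication_costs,
                        complication_weights = complication_weights,
                        ocs_course_cost = ocs_course_cost,
                        discount_rate = discount_rate,
                        horizon_years = as.integer(horizon_years),
                        wtp = wtp),
                   class = "shared_params")
  expected_complication_cost(out)  # validates the simplex
  out
}
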