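# Fully resolved model specification.

#' Assemble a model specification
#'
#' Combines strategy arms, shared parameters, the utility mapping, the
#' designated no-treatment comparator (whose event rates and SNOT-22 are
#' inherited by patients who abandon a biologic) and optional per-year
#' drug-cost multipliers.
#'
#' @param arms Named list of [strategy_params()] (names must match each
#'   arm's `name`); must include the comparator.
#' @param shared A [shared_params()].
#' @param mapping A [utility_mapping()].
#' @param comparator Name of the comparator arm (default `"no_biologic"`).
#' @param dosing_profiles Optional named list of numeric vectors of length
#'   `horizon_years` of nonnegative drug-cost multipliers (default all 1).
#' @param table Optional [load_parameter_table()] result carrying the
#'   sampling distributions used by [run_psa()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(arms, shared, mapping = utility_mapping(),
                       comparator = "no_biologic",
                       dosing_profiles = NULL, table = NULL) {
  if (!length(arms) || !all(vapply(arms, inherits, TRUE, "strategy_params"))) {
    cea_stop("validation", "`arms` must be a nonempty list of strategy_params")
  }
  names(arms) <- vapply(arms, `[[`, "", "name")
  if (anyDuplicated(names(arms))) {
    cea_stop("validation", "duplicate strategy names in `arms`")
  }
  if (!comparator %in% names(arms)) {
    cea_stop("validation", "comparator '%s' is not among the arms", comparator)
  }
  H <- shared$horizon_years
  if (is.null(dosing_profiles)) dosing_profiles <- list()
  for (nm in names(dosing_profiles)) {
    prof <- dosing_profiles[[nm]]
    if (!nm %in% names(arms)) {
      cea_stop("validation", "dosing profile for unknown arm '%s'", nm)
    }
    if (length(prof) != H || any(!is.finite(prof)) || any(prof < 0)) {
      cea_stop("validation",
               "dosing profile for '%s' must be %d nonnegative multipliers", nm, H)
    }
  }
  structure(list(arms = arms, shared = shared, mapping = mapping,
                 comparator = comparator, dosing_profiles = dosing_profiles,
                 table = table),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", length(x$arms), " arms (",
      paste(names(x$arms), collapse = ", "), "), horizon ",
      x$shared$horizon_years, "y, discount ",
      format(100 * x$shared$discount_rate), "%/y, comparator '",
      x$comparator, "'\n", sep = "")
  invisible(x)
}

#' Path to the packaged replication run configuration
#'
#' @return Path to the installed `replication_config.json`.
#' @export
replication_config_file <- function() {
  system.file("extdata", "replication_config.json", package = "crswnpCEA",
              mustWork = TRUE)
}

#' Build the replication model
#'
#' Convenience wrapper: loads the packaged parameter table and run
#' configuration (calibrated utility mapping and complication mix, 10-year
#' horizon, 3% discounting, $50,000/QALY willingness-to-pay) into a ready
#' [model_spec()].
#'
#' @param config A run configuration (path or list), default the packaged
#'   replication configuration.
#' @return A `model_spec`.
#' @export
replication_model <- function(config = replication_config_file()) {
  build_model(load_run_config(config, quiet = TRUE))
}
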