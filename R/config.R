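# Run configuration: JSON key/value file driving every command entry point.

#' Load and validate a run configuration
#'
#' Reads a JSON run configuration (or takes a list), fills documented
#' defaults (each filled default is logged to stderr unless `quiet`), and
#' validates every field before any computation.  A relative
#' `parameter_file` is resolved against the package's `extdata` directory.
#'
#' @param config Path to a JSON file, or a named list.
#' @param quiet Suppress default-logging messages.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(config = replication_config_file(), quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      cea_stop("config", "configuration file does not exist: %s", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) cea_stop("config", "configuration must be a list or JSON path")

  defaults <- list(
    parameter_file = replication_parameter_file(),
    horizon_years = 10, discount_rate = 0.03, wtp = 50000,
    wtp_grid = list(from = 0, to = 400000, by = 1000),
    seed = 1, n_draws = 10000,
    utility_mapping = list(intercept = 0.81, slope = 0.0062),
    ocs_course_cost = 35,
    complication_weights = "equal",
    comparator = "no_biologic", baseline = "omalizumab",
    scenarios = list()
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
      if (!quiet) message(sprintf("config: '%s' not set, using default", k))
    }
  }

  if (!file.exists(config$parameter_file)) {
    candidate <- system.file("extdata", config$parameter_file,
                             package = "crswnpCEA")
    if (nzchar(candidate)) config$parameter_file <- candidate
  }
  if (!file.exists(config$parameter_file)) {
    cea_stop("config", "parameter file does not exist: %s", config$parameter_file)
  }
  check_number(config$horizon_years, "horizon_years", lower = 1)
  check_number(config$discount_rate, "discount_rate", lower = 0)
  check_number(config$wtp, "wtp", lower = 0)
  check_number(config$n_draws, "n_draws", lower = 1)
  check_number(config$seed, "seed")
  check_number(config$ocs_course_cost, "ocs_course_cost", lower = 0)
  um <- config$utility_mapping
  config$utility_mapping <- utility_mapping(
    intercept = um$intercept %||% 0.81,
    slope = um$slope %||% 0.0062,
    floor = um$floor %||% 0,
    ceiling = um$ceiling %||% 1
  )
  g <- config$wtp_grid
  config$wtp_grid <- if (is.list(g)) seq(g$from, g$to, by = g$by) else as.numeric(g)
  if (is.character(config$complication_weights)) {
    config$complication_weights <-
      complication_weight_profile(config$complication_weights)
  } else {
    config$complication_weights <- unlist(config$complication_weights)
  }
  structure(config, class = "run_config")
}

#' Build a model specification from a run configuration
#'
#' @param config A [load_run_config()] result (or anything it accepts).
#' @return A [model_spec()] carrying the parameter table for PSA.
#' @export
build_model <- function(config) {
  if (!inherits(config, "run_config")) config <- load_run_config(config, quiet = TRUE)
  table <- load_parameter_table(config$parameter_file)
  shared <- shared_params(
    ess_cost = table$shared$ess_cost,
    complication_costs = table$shared$complication_costs,
    complication_weights = config$complication_weights,
    ocs_course_cost = config$ocs_course_cost,
    discount_rate = config$discount_rate,
    horizon_years = config$horizon_years,
    wtp = config$wtp
  )
  arms <- lapply(names(table$strategies), function(s) table_strategy_params(table, s))
  names(arms) <- names(table$strategies)
  if (!config$comparator %in% names(arms)) {
    cea_stop("config", "comparator '%s' not present in parameter file",
             config$comparator)
  }
  model_spec(arms, shared, mapping = config$utility_mapping,
             comparator = config$comparator, table = table)
}

#' Serialize a model specification to JSON
#'
#' Writes a [model_spec()] (e.g. a generated synthetic fixture) in the
#' same JSON configuration format used for real runs, so fixtures
#' round-trip through [read_model_spec()].
#'
#' @param spec A [model_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  arms <- lapply(spec$arms, function(a) {
    list(name = a$name,
         p_revision_yearly = a$p_revision_yearly,
         p_ocs_yearly = a$p_ocs_yearly,
         p_adverse_yearly = a$p_adverse_yearly,
         p_nonadherent = a$p_nonadherent,
         snot22 = unclass(a$snot22),
         drug_cost_yearly = a$drug_cost_yearly)
  })
  payload <- list(arms = arms,
                  shared = unclass(spec$shared),
                  utility_mapping = unclass(spec$mapping),
                  comparator = spec$comparator,
                  dosing_profiles = spec$dosing_profiles)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model specification
#'
#' @param path JSON path written by [write_model_spec()].
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  arms <- lapply(p$arms, function(a) {
    sn <- a$snot22
    strategy_params(a$name, a$p_revision_yearly, a$p_ocs_yearly,
                    a$p_adverse_yearly, a$p_nonadherent,
                    snot22 = param_estimate(sn$mean, sd = sn$sd %||% NA_real_,
                                            distribution = sn$distribution,
                                            alpha = sn$alpha %||% NA_real_,
                                            beta = sn$beta %||% NA_real_,
                                            scale = sn$scale %||% 110),
                    drug_cost_yearly = a$drug_cost_yearly)
  })
  names(arms) <- vapply(arms, `[[`, "", "name")
  sh <- p$shared
  shared <- shared_params(sh$ess_cost, unlist(sh$complication_costs),
                          unlist(sh$complication_weights),
                          sh$ocs_course_cost, sh$discount_rate,
                          sh$horizon_years, sh$wtp)
  um <- p$utility_mapping
  dp <- p$dosing_profiles
  if (length(dp) == 0) dp <- NULL
  model_spec(arms, shared,
             mapping = utility_mapping(um$intercept, um$slope, um$floor, um$ceiling),
             comparator = p$comparator,
             dosing_profiles = dp)
}
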