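# Loading and validating the delimited parameter table.

STRATEGY_PARAM_NAMES <- c("p_revision", "p_ocs", "p_adverse",
                          "p_nonadherent", "snot22", "drug_cost_yearly")

#' Path to the packaged replication parameter table
#'
#' The shipped CSV transcribes the literature-derived Canadian inputs
#' (2021 CAD): yearly event probabilities, SNOT-22 means and standard
#' deviations, and costs, one row per (strategy, parameter).
#'
#' @return Path to the installed `table1_parameters.csv`.
#' @export
replication_parameter_file <- function() {
  system.file("extdata", "table1_parameters.csv", package = "crswnpCEA",
              mustWork = TRUE)
}

parse_distribution <- function(dist, mean, sd, scale, cell) {
  dist <- tolower(trimws(dist %||% ""))
  if (dist == "" || dist == "fixed") {
    return(param_estimate(mean, distribution = "fixed", scale = scale))
  }
  if (dist == "beta") {
    return(param_estimate(mean, sd = sd, distribution = "beta", scale = scale))
  }
  m <- regmatches(dist, regexec("^beta\\(([0-9.eE+-]+)[;,]([0-9.eE+-]+)\\)$", dist))[[1]]
  if (length(m) == 3) {
    return(param_estimate(mean, distribution = "beta",
                          alpha = as.numeric(m[2]), beta = as.numeric(m[3]),
                          scale = scale))
  }
  cea_stop("schema", "unrecognised distribution '%s' at %s", dist, cell)
}

#' Load and validate a parameter table
#'
#' Reads a delimited parameter file (columns `strategy`, `parameter`,
#' `mean`, `sd`, `distribution`, `units`, `source`) into fully validated
#' strategy-level and shared parameters.  Every strategy must provide all
#' six strategy parameters; any violated range or malformed distribution
#' is reported with the offending (strategy, parameter) cell.
#'
#' @param path Path to the CSV file; defaults to the packaged replication
#'   table.
#' @return An object of class `parameter_table`: a list with `strategies`
#'   (named list, each a named list of [param_estimate()]s), `shared`
#'   (`ess_cost` and named `complication_costs`), and `rows` (the raw
#'   tibble).
#' @export
load_parameter_table <- function(path = replication_parameter_file()) {
  if (!file.exists(path)) {
    cea_stop("schema", "parameter file does not exist: %s", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("strategy", "parameter", "mean", "sd", "distribution")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    cea_stop("schema", "parameter file is missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  raw$sd <- suppressWarnings(as.numeric(raw$sd))
  raw$mean <- suppressWarnings(as.numeric(raw$mean))
  if (anyNA(raw$mean)) {
    bad <- which(is.na(raw$mean))[1]
    cea_stop("schema", "non-numeric mean at (%s, %s)",
             raw$strategy[bad], raw$parameter[bad])
  }

  strategies <- list()
  for (s in unique(raw$strategy[raw$strategy != "shared"])) {
    rows <- raw[raw$strategy == s, ]
    missing_par <- setdiff(STRATEGY_PARAM_NAMES, rows$parameter)
    if (length(missing_par)) {
      cea_stop("schema", "strategy '%s' is missing parameter(s): %s",
               s, paste(missing_par, collapse = ", "))
    }
    est <- list()
    for (p in STRATEGY_PARAM_NAMES) {
      r <- rows[rows$parameter == p, ][1, ]
      scale <- if (p == "snot22") 110 else 1
      cell <- sprintf("(%s, %s)", s, p)
      pe <- tryCatch(
        parse_distribution(r$distribution, r$mean, r$sd, scale, cell),
        crswnp_validation = function(e) {
          cea_stop("schema", "invalid value at %s: %s", cell, conditionMessage(e))
        })
      est[[p]] <- pe
    }
    # range validation through the typed constructor
    tryCatch(
      strategy_params(s,
                      p_revision_yearly = est$p_revision$mean,
                      p_ocs_yearly = est$p_ocs$mean,
                      p_adverse_yearly = est$p_adverse$mean,
                      p_nonadherent = est$p_nonadherent$mean,
                      snot22 = est$snot22,
                      drug_cost_yearly = est$drug_cost_yearly$mean),
      crswnp_validation = function(e) {
        cea_stop("schema", "out-of-range value for strategy '%s': %s",
                 s, conditionMessage(e))
      })
    strategies[[s]] <- est
  }
  if (length(strategies) == 0) {
    cea_stop("schema", "parameter file contains no strategy rows")
  }

  shr <- raw[raw$strategy == "shared", ]
  if (!"ess_cost" %in% shr$parameter) {
    cea_stop("schema", "shared row 'ess_cost' is missing")
  }
  comp <- shr[startsWith(shr$parameter, "complication_"), ]
  comp_costs <- stats::setNames(comp$mean,
                                sub("^complication_", "", comp$parameter))
  if (any(comp_costs < 0)) {
    bad <- names(comp_costs)[comp_costs < 0][1]
    cea_stop("schema", "negative complication cost at (shared, complication_%s)", bad)
  }
  structure(list(
    strategies = strategies,
    shared = list(ess_cost = shr$mean[shr$parameter == "ess_cost"][1],
                  complication_costs = comp_costs),
    rows = tibble::as_tibble(raw)
  ), class = "parameter_table")
}

#' @export
print.parameter_table <- function(x, ...) {
  cat("<parameter_table> ", length(x$strategies), " strategies: ",
      paste(names(x$strategies), collapse = ", "), "\n", sep = "")
  cat("  shared: ess_cost $", format(x$shared$ess_cost), ", ",
      length(x$shared$complication_costs), " complication costs\n", sep = "")
  invisible(x)
}

# Deterministic point value of every strategy parameter, as strategy_params.
table_strategy_params <- function(table, name) {
  est <- table$strategies[[name]]
  if (is.null(est)) {
    cea_stop("lookup", "unknown strategy '%s' (have: %s)", name,
             paste(names(table$strategies), collapse = ", "))
  }
  strategy_params(name,
                  p_revision_yearly = est$p_revision$mean,
                  p_ocs_yearly = est$p_ocs$mean,
                  p_adverse_yearly = est$p_adverse$mean,
                  p_nonadherent = est$p_nonadherent$mean,
                  snot22 = est$snot22,
                  drug_cost_yearly = est$drug_cost_yearly$mean)
}

#' Force every distribution in a parameter table to its point estimate
#'
#' Used to show that a degenerate probabilistic analysis (all spreads
#' removed) collapses to the deterministic base case.
#'
#' @param table A [load_parameter_table()] result.
#' @return The same table with every `param_estimate` marked `fixed`.
#' @export
degenerate_table <- function(table) {
  for (s in names(table$strategies)) {
    for (p in names(table$strategies[[s]])) {
      pe <- table$strategies[[s]][[p]]
      table$strategies[[s]][[p]] <- param_estimate(pe$mean, distribution = "fixed",
                                                   scale = pe$scale)
    }
  }
  table
}
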