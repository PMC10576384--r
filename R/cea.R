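# Dominance classification, ICERs, net monetary benefit.

#' Strategy outcome
#'
#' @param name Strategy name.
#' @param total_cost,total_qaly Nonnegative totals.
#' @return A `strategy_outcome` list.
#' @export
strategy_outcome <- function(name, total_cost, total_qaly) {
  check_number(total_cost, "total_cost", lower = 0)
  check_number(total_qaly, "total_qaly", lower = 0)
  structure(list(name = name, total_cost = total_cost, total_qaly = total_qaly),
            class = "strategy_outcome")
}

outcome_fields <- function(x) {
  if (inherits(x, c("strategy_outcome", "cohort_trace"))) {
    list(cost = x$total_cost, qaly = x$total_qaly)
  } else if (is.list(x) && all(c("total_cost", "total_qaly") %in% names(x))) {
    list(cost = x$total_cost, qaly = x$total_qaly)
  } else {
    cea_stop("validation", "expected an object with total_cost and total_qaly")
  }
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_b - cost_a) / (qaly_b - qaly_a)`.  When the two strategies have
#' equal QALYs the ICER is undefined: `NA` is returned with a classed
#' warning rather than an error.
#'
#' @param a,b Objects with `total_cost` and `total_qaly` (e.g.
#'   [strategy_outcome()] or [run_cohort()] results); `a` is the reference.
#' @return CAD per QALY, or `NA` if undefined.
#' @export
icer <- function(a, b) {
  fa <- outcome_fields(a); fb <- outcome_fields(b)
  dq <- fb$qaly - fa$qaly
  if (dq == 0) {
    warning(structure(
      class = c("crswnp_undefined_icer", "warning", "condition"),
      list(message = "ICER undefined: equal QALYs", call = sys.call(-1))))
    return(NA_real_)
  }
  (fb$cost - fa$cost) / dq
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; linear in the willingness-to-pay, so the preferred
#' strategy in a pairwise comparison switches exactly at the pairwise ICER.
#'
#' @param outcome Object with `total_cost` and `total_qaly`.
#' @param wtp Nonnegative willingness-to-pay (CAD/QALY); may be a vector.
#' @return Net monetary benefit in CAD.
#' @export
nmb <- function(outcome, wtp) {
  if (any(wtp < 0)) cea_stop("validation", "`wtp` must be >= 0")
  f <- outcome_fields(outcome)
  wtp * f$qaly - f$cost
}

#' Rank strategies: dominance and ICERs
#'
#' Classifies each strategy as on the cost-effectiveness frontier, strictly
#' dominated (another strategy is no more costly and no less effective,
#' strictly better in at least one) or extended dominated (removed to keep
#' frontier ICERs strictly increasing).  Exact cost-and-QALY ties are kept
#' on the frontier and flagged.  ICERs are reported along the frontier and
#' against a configurable baseline.
#'
#' @param outcomes A data frame with columns `strategy`, `total_cost`,
#'   `total_qaly` (e.g. from [run_all_arms()]), or a list of
#'   [strategy_outcome()]s.
#' @param baseline Baseline strategy name for the `icer_vs_baseline`
#'   column, default `"omalizumab"` when present (else the cheapest
#'   frontier strategy).
#' @return A `cea_result` tibble sorted by increasing cost, with `status`
#'   (`on_frontier`, `strictly_dominated`, `extended_dominated`), `tie`
#'   flag, `icer_frontier` (vs the previous frontier strategy) and
#'   `icer_vs_baseline`.
#' @export
rank_strategies <- function(outcomes, baseline = NULL) {
  if (!is.data.frame(outcomes)) {
    outcomes <- do.call(rbind, lapply(outcomes, function(o) {
      f <- outcome_fields(o)
      data.frame(strategy = o$name, total_cost = f$cost, total_qaly = f$qaly)
    }))
  }
  if (nrow(outcomes) < 2) {
    cea_stop("validation", "need at least 2 strategies to rank")
  }
  if (anyDuplicated(outcomes$strategy)) {
    cea_stop("validation", "duplicate strategy names: %s",
             paste(unique(outcomes$strategy[duplicated(outcomes$strategy)]),
                   collapse = ", "))
  }
  if (is.null(baseline)) {
    baseline <- if ("omalizumab" %in% outcomes$strategy) "omalizumab" else NA
  }

  x <- outcomes[order(outcomes$total_cost, outcomes$total_qaly,
                      outcomes$strategy), ]
  n <- nrow(x)
  status <- rep("on_frontier", n)
  tie <- rep(FALSE, n)

  # strict dominance (exact ties spared and flagged)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (x$total_cost[j] == x$total_cost[i] &&
          x$total_qaly[j] == x$total_qaly[i]) {
        tie[i] <- TRUE
        next
      }
      if (x$total_cost[j] <= x$total_cost[i] &&
          x$total_qaly[j] >= x$total_qaly[i]) {
        status[i] <- "strictly_dominated"
        break
      }
    }
  }

  # extended dominance: frontier ICERs must be strictly increasing
  repeat {
    idx <- which(status == "on_frontier")
    if (length(idx) < 3) break
    removed <- FALSE
    for (k in 2:(length(idx) - 1)) {
      i0 <- idx[k - 1]; i1 <- idx[k]; i2 <- idx[k + 1]
      ic1 <- (x$total_cost[i1] - x$total_cost[i0]) /
        (x$total_qaly[i1] - x$total_qaly[i0])
      ic2 <- (x$total_cost[i2] - x$total_cost[i1]) /
        (x$total_qaly[i2] - x$total_qaly[i1])
      if (is.finite(ic1) && is.finite(ic2) && ic1 >= ic2) {
        status[i1] <- "extended_dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  idx <- which(status == "on_frontier")
  icer_frontier <- rep(NA_real_, n)
  if (length(idx) > 1) {
    for (k in 2:length(idx)) {
      i0 <- idx[k - 1]; i1 <- idx[k]
      dq <- x$total_qaly[i1] - x$total_qaly[i0]
      icer_frontier[i1] <- if (dq == 0) NA_real_ else
        (x$total_cost[i1] - x$total_cost[i0]) / dq
    }
  }

  icer_base <- rep(NA_real_, n)
  if (!is.na(baseline) && baseline %in% x$strategy) {
    b <- which(x$strategy == baseline)
    for (i in seq_len(n)) {
      if (i == b || status[i] != "on_frontier") next
      dq <- x$total_qaly[i] - x$total_qaly[b]
      icer_base[i] <- if (dq == 0) NA_real_ else
        (x$total_cost[i] - x$total_cost[b]) / dq
    }
  }

  out <- tibble::tibble(
    strategy = x$strategy,
    total_cost = x$total_cost,
    total_qaly = x$total_qaly,
    status = status,
    tie = tie,
    icer_frontier = icer_frontier,
    icer_vs_baseline = icer_base
  )
  attr(out, "baseline") <- baseline
  class(out) <- c("cea_result", class(out))
  out
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness ranking (baseline: ",
      attr(x, "baseline") %||% "none", ")\n", sep = "")
  disp <- data.frame(
    strategy = x$strategy,
    total_cost = sprintf("$%s", formatC(x$total_cost, format = "f",
                                        digits = 0, big.mark = ",")),
    total_qaly = sprintf("%.2f", x$total_qaly),
    status = x$status,
    icer_vs_baseline = ifelse(
      x$status != "on_frontier", "dominated",
      ifelse(is.na(x$icer_vs_baseline), "-",
             sprintf("$%s/QALY", formatC(x$icer_vs_baseline, format = "f",
                                         digits = 0, big.mark = ","))))
  )
  print(disp, row.names = FALSE)
  invisible(x)
}
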