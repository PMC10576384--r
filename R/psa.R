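# Probabilistic sensitivity analysis: parameter sampling, Monte Carlo
# propagation, acceptability curves and confidence ellipses.
#
# Sampling conventions: only parameters with a resolvable beta
# specification (a reported sd, or an explicit shape pair) are sampled;
# costs and the comparator's rates are fixed.  Each (strategy, parameter)
# row draws from its own seeded stream, so enlarging the number of draws
# leaves earlier draws unchanged.

psa_row_specs <- function(table) {
  specs <- list()
  for (s in names(table$strategies)) {
    for (p in names(table$strategies[[s]])) {
      pe <- table$strategies[[s]][[p]]
      bs <- resolve_beta(pe, label = sprintf("(%s, %s)", s, p))
      if (!is.null(bs)) {
        specs[[paste(s, p, sep = ".")]] <-
          list(strategy = s, parameter = p, beta = bs, scale = pe$scale)
      }
    }
  }
  specs
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Independent beta draws for every stochastic (strategy, parameter) row;
#' fixed rows pass through unchanged.  Probabilities are drawn on \[0, 1\],
#' SNOT-22 scores as `110 * Beta` fitted by moments on the rescaled
#' mean/sd.  Reproducible under a fixed seed; per-row sub-streams keep the
#' first `n` draws identical when `n_draws` is enlarged.
#'
#' @param table A [load_parameter_table()] result.
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A data frame of `n_draws` rows, one column per stochastic row
#'   named `strategy.parameter`, with attribute `"row_specs"`.
#' @export
sample_parameters <- function(table, n_draws, seed) {
  check_number(n_draws, "n_draws", lower = 1)
  specs <- psa_row_specs(table)
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, max(length(specs), 1L))
  draws <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    set.seed(row_seeds[k])
    draws[[names(specs)[k]]] <-
      sp$scale * stats::rbeta(n_draws, sp$beta$alpha, sp$beta$beta)
  }
  out <- if (length(draws)) as.data.frame(draws, check.names = FALSE) else
    data.frame(row.names = seq_len(n_draws))
  attr(out, "row_specs") <- specs
  attr(out, "seed") <- seed
  out
}

patch_arm <- function(arm, strategy_draws) {
  map <- c(p_revision = "p_revision_yearly", p_ocs = "p_ocs_yearly",
           p_adverse = "p_adverse_yearly", p_nonadherent = "p_nonadherent")
  for (p in names(strategy_draws)) {
    if (p == "snot22") {
      arm$snot22$mean <- strategy_draws[[p]]
    } else if (p %in% names(map)) {
      arm[[map[[p]]]] <- strategy_draws[[p]]
    } else if (p == "drug_cost_yearly") {
      arm$drug_cost_yearly <- strategy_draws[[p]]
    }
  }
  arm
}

#' Run a probabilistic sensitivity analysis
#'
#' For each Monte Carlo draw, replaces the stochastic parameters in every
#' arm and re-runs the cohort engine, collecting per-strategy discounted
#' cost/QALY pairs.
#'
#' @param spec A [model_spec()] carrying its parameter `table`.
#' @param n_draws Number of draws, default 10000.
#' @param seed Integer seed.
#' @param arms Arm names to evaluate (default all).
#' @return A `psa_result` tibble with columns `draw`, `strategy`, `cost`,
#'   `qaly`; the sampled parameters are attached as attribute `"draws"`.
#' @export
run_psa <- function(spec, n_draws = 10000, seed = 1, arms = names(spec$arms)) {
  if (is.null(spec$table)) {
    cea_stop("validation",
             "model_spec carries no parameter table; PSA needs sampling distributions")
  }
  draws <- sample_parameters(spec$table, n_draws, seed)
  specs <- attr(draws, "row_specs")
  by_strategy <- split(seq_along(specs),
                       vapply(specs, `[[`, "", "strategy"))

  n_arms <- length(arms)
  cost <- matrix(0, n_draws, n_arms, dimnames = list(NULL, arms))
  qaly <- matrix(0, n_draws, n_arms, dimnames = list(NULL, arms))
  for (i in seq_len(n_draws)) {
    spec_i <- spec
    for (s in names(by_strategy)) {
      if (!s %in% names(spec_i$arms)) next
      sd_i <- lapply(by_strategy[[s]], function(k) draws[i, k])
      names(sd_i) <- vapply(specs[by_strategy[[s]]], `[[`, "", "parameter")
      spec_i$arms[[s]] <- patch_arm(spec_i$arms[[s]], sd_i)
    }
    for (a in seq_len(n_arms)) {
      tr <- tryCatch(run_cohort(spec_i, arms[a], keep_trace = FALSE),
                     error = function(e) {
                       cea_stop("psa", "draw %d, arm '%s': %s", i, arms[a],
                                conditionMessage(e))
                     })
      cost[i, a] <- tr$total_cost
      qaly[i, a] <- tr$total_qaly
    }
  }
  out <- tibble::tibble(
    draw = rep(seq_len(n_draws), each = n_arms),
    strategy = rep(arms, n_draws),
    cost = as.vector(t(cost)),
    qaly = as.vector(t(qaly))
  )
  attr(out, "draws") <- draws
  attr(out, "seed") <- seed
  attr(out, "n_draws") <- n_draws
  class(out) <- c("psa_result", class(out))
  out
}

psa_matrices <- function(samples) {
  strategies <- unique(samples$strategy)
  n <- length(unique(samples$draw))
  list(
    strategies = strategies,
    cost = matrix(samples$cost, nrow = n, ncol = length(strategies),
                  byrow = TRUE, dimnames = list(NULL, strategies)),
    qaly = matrix(samples$qaly, nrow = n, ncol = length(strategies),
                  byrow = TRUE, dimnames = list(NULL, strategies))
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of draws in which each
#' strategy attains the maximal net monetary benefit (exact ties split
#' equally), so acceptabilities sum to 1 at every grid point.
#'
#' @param samples A [run_psa()] result.
#' @param wtp_grid Ascending nonnegative WTP grid (CAD/QALY).
#' @return A `ceac_curve` tibble with columns `wtp`, `strategy`,
#'   `acceptability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (length(wtp_grid) == 0) cea_stop("validation", "`wtp_grid` is empty")
  if (is.unsorted(wtp_grid)) cea_stop("validation", "`wtp_grid` must be ascending")
  m <- psa_matrices(samples)
  res <- matrix(0, length(wtp_grid), length(m$strategies),
                dimnames = list(NULL, m$strategies))
  for (g in seq_along(wtp_grid)) {
    nmb <- wtp_grid[g] * m$qaly - m$cost
    best <- matrixStats_rowMaxs(nmb)
    win <- nmb >= best - 1e-9 * pmax(1, abs(best))
    res[g, ] <- colMeans(win / rowSums(win))
  }
  out <- tibble::tibble(
    wtp = rep(wtp_grid, times = length(m$strategies)),
    strategy = rep(m$strategies, each = length(wtp_grid)),
    acceptability = as.vector(res)
  )
  class(out) <- c("ceac_curve", class(out))
  out
}

# row maxima without extra dependencies
matrixStats_rowMaxs <- function(x) do.call(pmax, as.data.frame(x))

#' Pairwise acceptability at one willingness-to-pay
#'
#' Fraction of draws in which `target` has strictly higher net monetary
#' benefit than `reference` (exact ties count one half).
#'
#' @param samples A [run_psa()] result.
#' @param target,reference Strategy names.
#' @param wtp Willingness-to-pay (CAD/QALY); may be a vector.
#' @return Fraction(s) in \[0, 1\].
#' @export
pairwise_acceptability <- function(samples, target, reference, wtp) {
  m <- psa_matrices(samples)
  for (s in c(target, reference)) {
    if (!s %in% m$strategies) cea_stop("lookup", "unknown strategy '%s'", s)
  }
  vapply(wtp, function(l) {
    d <- (l * m$qaly[, target] - m$cost[, target]) -
      (l * m$qaly[, reference] - m$cost[, reference])
    mean((d > 0) + 0.5 * (d == 0))
  }, 0)
}

#' Smallest willingness-to-pay at which a strategy wins a majority
#'
#' Sweeps the grid and returns the smallest WTP at which the pairwise
#' acceptability of `target` versus `reference` exceeds one half.
#'
#' @inheritParams pairwise_acceptability
#' @param wtp_grid Ascending WTP grid to sweep.
#' @return The crossover WTP, or `NA` if the curve never exceeds 0.5.
#' @export
ceac_crossover <- function(samples, target, reference, wtp_grid) {
  acc <- pairwise_acceptability(samples, target, reference, wtp_grid)
  hit <- which(acc > 0.5)
  if (!length(hit)) return(NA_real_)
  wtp_grid[hit[1]]
}

#' 95% confidence ellipse on the incremental cost-effectiveness plane
#'
#' Center and covariance of the joint (incremental QALY, incremental cost)
#' cloud of `target` minus `reference`, with the bivariate-normal contour
#' at the chi-square(2) quantile of the requested level.
#'
#' @param samples A [run_psa()] result (>= 3 draws).
#' @param target,reference Strategy names.
#' @param level Coverage level, default 0.95.
#' @return An `ellipse95` object: `center` (named `dqaly`, `dcost`),
#'   `cov` (2x2), `level`, `radius2` (chi-square quantile) and a
#'   `collapsed` flag for degenerate covariance.
#' @export
confidence_ellipse <- function(samples, target, reference, level = 0.95) {
  m <- psa_matrices(samples)
  n <- nrow(m$cost)
  if (n < 3) cea_stop("validation", "need >= 3 draws for an ellipse")
  dq <- m$qaly[, target] - m$qaly[, reference]
  dc <- m$cost[, target] - m$cost[, reference]
  ctr <- c(dqaly = mean(dq), dcost = mean(dc))
  S <- stats::cov(cbind(dqaly = dq, dcost = dc))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  collapsed <- any(ev <= .Machine$double.eps * max(abs(ev), 1))
  structure(list(center = ctr, cov = S, level = level,
                 radius2 = stats::qchisq(level, df = 2),
                 n = n, collapsed = collapsed),
            class = "ellipse95")
}

#' Boundary points of a confidence ellipse
#'
#' @param e An [confidence_ellipse()] result.
#' @param n_points Number of boundary points.
#' @return Tibble of `dqaly`, `dcost` boundary coordinates (a degenerate
#'   ellipse collapses onto its principal segment).
#' @export
ellipse_points <- function(e, n_points = 100) {
  theta <- seq(0, 2 * pi, length.out = n_points)
  eg <- eigen(e$cov, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  pts <- eg$vectors %*% rbind(sqrt(e$radius2 * lam[1]) * cos(theta),
                              sqrt(e$radius2 * lam[2]) * sin(theta))
  tibble::tibble(dqaly = e$center[1] + pts[1, ],
                 dcost = e$center[2] + pts[2, ])
}

#' Is a point inside a confidence ellipse?
#'
#' @param e An [confidence_ellipse()] result.
#' @param dqaly,dcost Point coordinates (vectorised).
#' @return Logical: squared Mahalanobis distance <= chi-square quantile.
#' @export
in_ellipse <- function(e, dqaly, dcost) {
  Sinv <- solve(e$cov)
  x <- dqaly - e$center[1]
  y <- dcost - e$center[2]
  (Sinv[1, 1] * x^2 + 2 * Sinv[1, 2] * x * y + Sinv[2, 2] * y^2) <= e$radius2
}

#' @export
print.ellipse95 <- function(x, ...) {
  cat(sprintf("<ellipse95> level %.2f, n %d, center (dQALY %.4f, dCost $%.2f)%s\n",
              x$level, x$n, x$center[1], x$center[2],
              if (x$collapsed) " [degenerate: collapses to a segment]" else ""))
  invisible(x)
}
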