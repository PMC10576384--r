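# Small builders used across the suite.  Everything is constructed in code;
# no stored fixtures beyond the packaged parameter table.

toy_shared <- function(horizon = 10, discount = 0.03, ocs = 35,
                       comp_costs = c(a = 1000, b = 2000),
                       weights = NULL, ess = 3987, wtp = 50000) {
  shared_params(ess_cost = ess, complication_costs = comp_costs,
                complication_weights = weights, ocs_course_cost = ocs,
                discount_rate = discount, horizon_years = horizon, wtp = wtp)
}

toy_arm <- function(name = "drug_a", prev = 0.02, pocs = 0.1, pae = 0.3,
                    pn = 0.05, snot = 30, drug = 20000) {
  strategy_params(name, prev, pocs, pae, pn, snot, drug)
}

toy_comparator <- function(snot = 50, prev = 0.04, pocs = 0.3) {
  strategy_params("standard_care", prev, pocs, 0, 0, snot, 0)
}

toy_spec <- function(arms = NULL, shared = toy_shared(),
                     mapping = utility_mapping()) {
  if (is.null(arms)) arms <- list(toy_comparator(), toy_arm())
  names(arms) <- vapply(arms, `[[`, "", "name")
  model_spec(arms, shared, mapping, comparator = "standard_care")
}

# psa_result-shaped tibble built by hand (draw-major, fixed strategy order)
fake_psa <- function(cost, qaly) {
  strategies <- colnames(cost)
  n <- nrow(cost)
  out <- tibble::tibble(
    draw = rep(seq_len(n), each = length(strategies)),
    strategy = rep(strategies, n),
    cost = as.vector(t(cost)),
    qaly = as.vector(t(qaly))
  )
  class(out) <- c("psa_result", class(out))
  out
}

replication_spec <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- replication_model()
    cache
  }
})
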