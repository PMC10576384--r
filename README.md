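# crswnpCEA

Cost-effectiveness modelling of biologic therapy for recalcitrant chronic
rhinosinusitis with nasal polyps (CRSwNP) in Canada.

Three biologics are approved in Canada for CRSwNP that remains symptomatic
after endoscopic sinus surgery (ESS) and medical therapy: dupilumab (q2w),
omalizumab (q4w) and mepolizumab (q4w). They are expensive, and the question
for a third-party payer is not only whether any biologic is worth its price
against revision ESS but which biologic is the most cost-efficient choice.
`crswnpCEA` implements a decision-tree + annual-cycle Markov cohort model
answering that question, for health-economics analysts and for anyone who
wants to stress the published conclusions under different prices, dosing
frequencies or utility assumptions.

## The model

Each strategy arm enters a decision tree where a proportion
*p*<sub>na</sub> of the cohort abandons the biologic immediately and moves
to an absorbing off-treatment state with the no-biologic comparator's event
rates and quality of life. The rest stay on treatment for the whole 10-year
horizon. Each one-year cycle *t* = 0, …, 9 accrues, discounted at rate
*r* = 3% by (1 + *r*)<sup>−*t*</sup>:

* **Costs** — drug acquisition, plus probability-weighted cost-only events:
  revision ESS (*p*<sub>rev</sub> × $3,987), rescue oral corticosteroids
  (*p*<sub>OCS</sub> × course cost) and biologic adverse events
  (*p*<sub>AE</sub> × expected complication cost, a simplex-weighted mean of
  six costed complications from anaphylaxis to EGPA).
* **QALYs** — disease-specific quality of life (SNOT-22, 0–110, higher =
  worse) mapped linearly to utility, *u* = α − β·SNOT-22, clipped to [0, 1].

Strategies are compared by dominance and by the incremental
cost-effectiveness ratio ICER = ΔC/ΔE against a $50,000/QALY
willingness-to-pay (WTP); net monetary benefit NMB = λ·E − C drives the
probabilistic analysis. Parameter uncertainty is propagated by Monte Carlo
with beta distributions (method-of-moments fits to reported mean/SD, or the
reported shape pairs), yielding cost-effectiveness acceptability curves and
the 95% confidence ellipse on the incremental plane. A bisection search
finds the yearly drug price at which a biologic's NMB equals the
comparator's, and per-year drug-cost multiplier profiles express
reduced-frequency dosing scenarios under dose-proportional pricing.

All inputs ship as a plain CSV (2021 CAD) plus a JSON run configuration;
a synthetic model generator and an independent patient-level
microsimulation oracle validate the cohort engine on random configurations.

## Worked example

```r
library(crswnpCEA)
spec <- replication_model()   # packaged inputs + calibrated configuration
out  <- run_all_arms(spec, arms = c("omalizumab", "dupilumab", "mepolizumab"))
rank_strategies(out, baseline = "omalizumab")
#> Cost-effectiveness ranking (baseline: omalizumab)
#>     strategy total_cost total_qaly             status icer_vs_baseline
#>   omalizumab   $169,361       5.34        on_frontier                -
#>    dupilumab   $207,075       5.51        on_frontier    $227,787/QALY
#>  mepolizumab   $216,061       5.13 strictly_dominated        dominated
```

Omalizumab is the cheapest biologic and accumulates 5.34 discounted QALYs
over 10 years; dupilumab buys 0.17 more QALYs at ≈$228k per QALY — far above
a $50k/QALY threshold — and mepolizumab is strictly dominated (costlier and
less effective than omalizumab). The price cut needed to change that:

```r
p <- threshold_price(spec, "dupilumab", "omalizumab", wtp = 50000)
sprintf("dupilumab threshold price: $%.0f/year (%.1f%%)",
        p, 100 * (p / attr(p, "current_price") - 1))
#> "dupilumab threshold price: $21850/year (-14.4%)"
```

Config-driven entry points write CSV/JSON reports with run manifests:
`cmd_base_case()`, `cmd_psa()`, `cmd_threshold()`, `cmd_scenario()` and
`cmd_validate()` (engine-vs-microsimulation agreement), each taking a
configuration path/list and an output directory.

## Acceptance script

`scripts/acceptance.R` recomputes the headline quantities of the analysis
from scratch against the installed package: the deterministic base-case
totals, the dupilumab-vs-omalizumab ICER, the mepolizumab dominance check,
both threshold prices, the seeded 10,000-draw PSA acceptability at
$150,000/QALY and its majority-crossover WTP, and the reduced-frequency
dupilumab dosing scenario. Run from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/model-methods.Rmd`) documents the model
structure and assumptions, the calibration of the utility mapping and
complication mix, the discounting and tie-break conventions, what the
synthetic generator does and does not emulate, and known limitations.
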