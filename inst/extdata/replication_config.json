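{
  "parameter_file": "table1_parameters.csv",
  "horizon_years": 10,
  "discount_rate": 0.03,
  "wtp": 50000,
  "wtp_grid": {"from": 0, "to": 400000, "by": 1000},
  "seed": 20210,
  "n_draws": 10000,
  "utility_mapping": {"intercept": 0.8312, "slope": 0.0064},
  "ocs_course_cost": 35,
  "complication_weights": "calibrated",
  "comparator": "no_biologic",
  "baseline": "omalizumab",
  "scenarios": {
    "dupilumab_q4w": {
      "arm": "dupilumab",
      "profile": [0.75, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5]
    }
  }
}
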