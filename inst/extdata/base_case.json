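{
  "schema_version": 1,
  "label": "base_case",
  "comment": "Base-case parameterization: EVT vs BMC for large-infarct ischemic stroke (ASPECTS 3-5), German healthcare-payer perspective, 2022 euros. 90-day mRS distributions from a European randomized trial; post-recurrence outcomes from Goyal et al.; RRs of death by mRS from Slot et al.; recurrence schedule from Lin et al.; EQ-5D-3L utilities from Ali et al.; long-term costs from German claims data. The printed BMC 90-day column sums to 1.02 (rounding) and is renormalized by the engine.",
  "dist90": {
    "evt": { "mrs01": 0.08, "mrs2": 0.09, "mrs3": 0.15, "mrs4": 0.19, "mrs5": 0.12, "dead": 0.37 },
    "bmc": { "mrs01": 0.02, "mrs2": 0.02, "mrs3": 0.12, "mrs4": 0.14, "mrs5": 0.20, "dead": 0.52 }
  },
  "dist_recurrent": { "mrs01": 0.13, "mrs2": 0.14, "mrs3": 0.15, "mrs4": 0.25, "mrs5": 0.14, "dead": 0.19 },
  "acute_costs": {
    "evt_survivor": 30490,
    "evt_dead": 15466,
    "bmc_survivor": 25352,
    "bmc_dead": 8814,
    "recurrent": 16670
  },
  "longterm_costs": { "mrs01": 6970, "mrs2": 7019, "mrs3": 18917, "mrs4": 19539, "mrs5": 19315 },
  "utilities": { "mrs01": 0.90, "mrs2": 0.83, "mrs3": 0.68, "mrs4": 0.38, "mrs5": 0.09, "dead": 0 },
  "mortality_rr": { "mrs01": 1, "mrs2": 1.12, "mrs3": 1.66, "mrs4": 1.92, "mrs5": 2.57 },
  "recurrence": [
    { "from_year": 1, "to_year": 1, "p": 0.11 },
    { "from_year": 2, "to_year": 2, "p": 0.08 },
    { "from_year": 3, "to_year": 3, "p": 0.02 },
    { "from_year": 4, "to_year": 5, "p": 0.01 },
    { "from_year": 6, "to_year": null, "p": 0.02 }
  ],
  "econ": {
    "starting_age": 72,
    "discount_rate_costs": 0.03,
    "discount_rate_effects": 0.03,
    "wtp_threshold": 46727,
    "max_age": 110,
    "cycle_length": 1
  },
  "psa": {
    "dist90.evt.mrs01": { "family": "beta", "alpha": 50.92, "beta": 573.08 },
    "dist90.evt.mrs2":  { "family": "beta", "alpha": 55.91, "beta": 568.09 },
    "dist90.evt.mrs3":  { "family": "beta", "alpha": 90.85, "beta": 533.15 },
    "dist90.evt.mrs4":  { "family": "beta", "alpha": 119.81, "beta": 504.19 },
    "dist90.evt.mrs5":  { "family": "beta", "alpha": 76.88, "beta": 547.12 },
    "dist90.evt.dead":  { "family": "beta", "alpha": 229.63, "beta": 394.37 },
    "dist90.bmc.mrs01": { "family": "beta", "alpha": 9.98, "beta": 629.02 },
    "dist90.bmc.mrs2":  { "family": "beta", "alpha": 9.98, "beta": 629.02 },
    "dist90.bmc.mrs3":  { "family": "beta", "alpha": 73.88, "beta": 565.12 },
    "dist90.bmc.mrs4":  { "family": "beta", "alpha": 86.86, "beta": 552.14 },
    "dist90.bmc.mrs5":  { "family": "beta", "alpha": 124.80, "beta": 514.20 },
    "dist90.bmc.dead":  { "family": "beta", "alpha": 333.48, "beta": 305.52 },
    "mortality_rr.mrs2": { "family": "lognormal", "log_mean": 0.11, "se": 0.16 },
    "mortality_rr.mrs3": { "family": "lognormal", "log_mean": 0.51, "se": 0.15 },
    "mortality_rr.mrs4": { "family": "lognormal", "log_mean": 0.65, "se": 0.16 },
    "mortality_rr.mrs5": { "family": "lognormal", "log_mean": 0.94, "se": 0.15 },
    "utilities.mrs01": { "family": "beta", "alpha": 3577.98, "beta": 397.55 },
    "utilities.mrs2":  { "family": "beta", "alpha": 2287.21, "beta": 468.46 },
    "utilities.mrs3":  { "family": "beta", "alpha": 1870.60, "beta": 880.28 },
    "utilities.mrs4":  { "family": "beta", "alpha": 1012.80, "beta": 1652.46 },
    "utilities.mrs5":  { "family": "beta", "alpha": 76.35, "beta": 771.98 },
    "longterm_costs.mrs01": { "family": "gamma", "alpha": 3976.22, "lambda": 0.57 },
    "longterm_costs.mrs2":  { "family": "gamma", "alpha": 613.20, "lambda": 0.09 },
    "longterm_costs.mrs3":  { "family": "gamma", "alpha": 1329.08, "lambda": 0.07 },
    "longterm_costs.mrs4":  { "family": "gamma", "alpha": 937.21, "lambda": 0.05 },
    "longterm_costs.mrs5":  { "family": "gamma", "alpha": 326.99, "lambda": 0.02 }
  },
  "dsa": {
    "econ.starting_age": [65, 80],
    "econ.discount_rate_costs": [0, 0.05],
    "econ.discount_rate_effects": [0, 0.05],
    "dist90.evt.mrs01": [0.06, 0.10],
    "dist90.evt.mrs2":  [0.07, 0.11],
    "dist90.evt.mrs3":  [0.12, 0.17],
    "dist90.evt.mrs4":  [0.16, 0.22],
    "dist90.evt.mrs5":  [0.10, 0.15],
    "dist90.evt.dead":  [0.33, 0.41],
    "dist90.bmc.mrs01": [0.01, 0.03],
    "dist90.bmc.mrs2":  [0.01, 0.03],
    "dist90.bmc.mrs3":  [0.09, 0.14],
    "dist90.bmc.mrs4":  [0.11, 0.16],
    "dist90.bmc.mrs5":  [0.16, 0.23],
    "dist90.bmc.dead":  [0.48, 0.56],
    "mortality_rr.mrs2": [0.82, 1.56],
    "mortality_rr.mrs3": [1.24, 2.23],
    "mortality_rr.mrs4": [1.41, 2.61],
    "mortality_rr.mrs5": [1.92, 3.43],
    "utilities.mrs01": [0.89, 0.91],
    "utilities.mrs2":  [0.82, 0.84],
    "utilities.mrs3":  [0.66, 0.70],
    "utilities.mrs4":  [0.36, 0.40],
    "utilities.mrs5":  [0.07, 0.11],
    "acute_costs.evt_survivor": [15245, 45735],
    "acute_costs.evt_dead":     [7733, 23199],
    "acute_costs.bmc_survivor": [12676, 38028],
    "acute_costs.bmc_dead":     [4407, 13221],
    "acute_costs.recurrent":    [8335, 25005],
    "longterm_costs.mrs01": [6753, 7187],
    "longterm_costs.mrs2":  [6464, 7575],
    "longterm_costs.mrs3":  [17900, 19934],
    "longterm_costs.mrs4":  [18288, 20790],
    "longterm_costs.mrs5":  [17221, 21409]
  }
}
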