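{
  "schema_version": 1,
  "label": "aspects4_synthetic",
  "comment": "SYNTHETIC placeholder: the real 90-day mRS distributions for this scenario come from external supplementary material and must be transcribed by the user; these values are constructed stand-ins chosen for clinical plausibility only. All other blocks equal the base case.",
  "dist90": {
    "evt": {
      "mrs01": 0.08,
      "mrs2": 0.09,
      "mrs3": 0.15,
      "mrs4": 0.2,
      "mrs5": 0.12,
      "dead": 0.36
    },
    "bmc": {
      "mrs01": 0.01,
      "mrs2": 0.02,
      "mrs3": 0.1,
      "mrs4": 0.13,
      "mrs5": 0.19,
      "dead": 0.55
    }
  },
  "dist_recurrent": {
    "mrs01": 0.13,
    "mrs2": 0.14,
    "mrs3": 0.15,
    "mrs4": 0.25,
    "mrs5": 0.14,
    "dead": 0.19
  },
  "acute_costs": {
    "evt_survivor": 30490,
    "evt_dead": 15466,
    "bmc_survivor": 25352,
    "bmc_dead": 8814,
    "recurrent": 16670
  },
  "longterm_costs": {
    "mrs01": 6970,
    "mrs2": 7019,
    "mrs3": 18917,
    "mrs4": 19539,
    "mrs5": 19315
  },
  "utilities": {
    "mrs01": 0.9,
    "mrs2": 0.83,
    "mrs3": 0.68,
    "mrs4": 0.38,
    "mrs5": 0.09,
    "dead": 0
  },
  "mortality_rr": {
    "mrs01": 1,
    "mrs2": 1.12,
    "mrs3": 1.66,
    "mrs4": 1.92,
    "mrs5": 2.57
  },
  "recurrence": [
    {
      "from_year": 1,
      "to_year": 1,
      "p": 0.11
    },
    {
      "from_year": 2,
      "to_year": 2,
      "p": 0.08
    },
    {
      "from_year": 3,
      "to_year": 3,
      "p": 0.02
    },
    {
      "from_year": 4,
      "to_year": 5,
      "p": 0.01
    },
    {
      "from_year": 6,
      "to_year": {},
      "p": 0.02
    }
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
    "mortality_rr.mrs2": {
      "family": "lognormal",
      "log_mean": 0.11,
      "se": 0.16
    },
    "mortality_rr.mrs3": {
      "family": "lognormal",
      "log_mean": 0.51,
      "se": 0.15
    },
    "mortality_rr.mrs4": {
      "family": "lognormal",
      "log_mean": 0.65,
      "se": 0.16
    },
    "mortality_rr.mrs5": {
      "family": "lognormal",
      "log_mean": 0.94,
      "se": 0.15
    },
    "utilities.mrs01": {
      "family": "beta",
      "alpha": 3577.98,
      "beta": 397.55
    },
    "utilities.mrs2": {
      "family": "beta",
      "alpha": 2287.21,
      "beta": 468.46
    },
    "utilities.mrs3": {
      "family": "beta",
      "alpha": 1870.6,
      "beta": 880.28
    },
    "utilities.mrs4": {
      "family": "beta",
      "alpha": 1012.8,
      "beta": 1652.46
    },
    "utilities.mrs5": {
      "family": "beta",
      "alpha": 76.35,
      "beta": 771.98
    },
    "longterm_costs.mrs01": {
      "family": "gamma",
      "alpha": 3976.22,
      "lambda": 0.57
    },
    "longterm_costs.mrs2": {
      "family": "gamma",
      "alpha": 613.2,
      "lambda": 0.09
    },
    "longterm_costs.mrs3": {
      "family": "gamma",
      "alpha": 1329.08,
      "lambda": 0.07
    },
    "longterm_costs.mrs4": {
      "family": "gamma",
      "alpha": 937.21,
      "lambda": 0.05
    },
    "longterm_costs.mrs5": {
      "family": "gamma",
      "alpha": 326.99,
      "lambda": 0.02
    }
  },
  "dsa": {
    "econ.starting_age": [
      65,
      80
    ],
    "econ.discount_rate_costs": [
      0,
      0.05
    ],
    "econ.discount_rate_effects": [
      0,
      0.05
    ],
    "mortality_rr.mrs2": [
      0.82,
      1.56
    ],
    "mortality_rr.mrs3": [
      1.24,
      2.23
    ],
    "mortality_rr.mrs4": [
      1.41,
      2.61
    ],
    "mortality_rr.mrs5": [
      1.92,
      3.43
    ],
    "utilities.mrs01": [
      0.89,
      0.91
    ],
    "utilities.mrs2": [
      0.82,
      0.84
    ],
    "utilities.mrs3": [
      0.66,
      0.7
    ],
    "utilities.mrs4": [
      0.36,
      0.4
    ],
    "utilities.mrs5": [
      0.07,
      0.11
    ],
    "acute_costs.evt_survivor": [
      15245,
      45735
    ],
    "acute_costs.evt_dead": [
      7733,
      23199
    ],
    "acute_costs.bmc_survivor": [
      12676,
      38028
    ],
    "acute_costs.bmc_dead": [
      4407,
      13221
    ],
    "acute_costs.recurrent": [
      8335,
      25005
    ],
    "longterm_costs.mrs01": [
      6753,
      7187
    ],
    "longterm_costs.mrs2": [
      6464,
      7575
    ],
    "longterm_costs.mrs3": [
      17900,
      19934
    ],
    "longterm_costs.mrs4": [
      18288,
      20790
    ],
    "longterm_costs.mrs5": [
      17221,
      21409
    ]
  }
}
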