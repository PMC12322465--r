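# strokecea

Cost-effectiveness modelling of endovascular thrombectomy (EVT) versus best
medical care (BMC) alone for acute ischemic stroke with established large
infarct (ASPECTS 3–5), from a German healthcare-payer perspective in 2022
euros.

## Who this is for

Health economists and stroke researchers who want a scripted, tested,
reproducible implementation of the standard cost–utility analysis for this
indication: a 90-day acute-phase decision tree feeding a lifetime
annual-cycle Markov cohort model over modified Rankin Scale (mRS) health
states, with stroke recurrence, life-table background mortality scaled by
mRS-specific relative risks of death, half-cycle correction, and 3% annual
discounting of costs and effects.

## The model in brief

Health states are `mrs01, mrs2, mrs3, mrs4, mrs5, dead` (severity-ordered,
`dead` absorbing). For strategy *s* with 90-day outcome distribution
*π_s*, lifetime discounted costs and QALYs are

    C_s = C_acute(π_s) + Σ_k (1 + r_c)^{-k} · c_k(π_s)
    E_s = E_acute(π_s) + Σ_k (1 + r_e)^{-k} · u_k(π_s)

where cycle *k* resolves recurrence first (post-recurrence outcome
constrained to no improvement), then background mortality
`min(1, qx(age) · RR_state)` for non-recurring patients, with mid-cycle
transitions credited half a cycle of cost and utility. Cost-effectiveness is
summarized by the incremental cost-effectiveness ratio

    ICER = (C_EVT − C_BMC) / (E_EVT − E_BMC)

against a willingness-to-pay threshold of 1.01 × 2022 per-capita GDP
(EUR 46 727/QALY). Parameter uncertainty is handled by a one-way
deterministic sensitivity analysis (tornado) and a seeded Monte Carlo
probabilistic sensitivity analysis (beta/gamma/lognormal sampling, 10 000
iterations) summarized as a cost-effectiveness acceptability curve (CEAC).
See the vignette `vignettes/model-methods.Rmd` for assumptions, numerical
choices and limitations.

## Worked example

```r
library(strokecea)

params <- load_params(system.file("extdata", "base_case.json",
                                  package = "strokecea"))
validate_params(params)
#> <strokecea_validation> 0 error(s), 1 warning(s)
#>   warning: dist90_bmc: probabilities sum to 1.0200 and will be renormalized

lt  <- default_life_table()     # synthetic Gompertz stand-in; a real
                                # life-table CSV can be read instead
evt <- run_cohort("EVT", params, lt)
bmc <- run_cohort("BMC", params, lt)
evt
#> <strokecea_cohort> EVT: discounted cost EUR 106 132, QALYs 2.73, life-years 6.24
bmc
#> <strokecea_cohort> BMC: discounted cost EUR 82 771, QALYs 1.41, life-years 4.37

icer(evt, bmc)
#> <strokecea_cea> EVT vs BMC
#>   dCost EUR 23 361, dQALY 1.32
#>   ICER EUR 17 667/QALY
#>   cost-effective at EUR 46727/QALY: TRUE
```

Reading: with the base-case inputs, EVT buys 1.32 extra discounted QALYs per
patient at an extra discounted lifetime cost of EUR 23 361, i.e. about
EUR 17 700 per QALY gained — well below the EUR 46 727 threshold, so EVT is
cost-effective. (Published reference values, computed with the official
German life table this repository cannot ship: EUR 24 257, 1.41 QALYs,
EUR 17 158/QALY; all quantities here agree within 10%.)

Sensitivity analyses and file-based runs:

```r
cmd_base_case(system.file("extdata", "base_case.json", package = "strokecea"),
              out_dir = "out/base")                    # results + traces + manifest
cmd_sensitivity(..., mode = "dsa", out_dir = "out/dsa")   # tornado.csv
cmd_sensitivity(..., mode = "psa", n_iter = 10000, seed = 1,
                out_dir = "out/psa")   # scatter, ceac.csv, psa_summary.json
```

or from a shell via the installed CLI script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/strokecea.R", package="strokecea"))') \
    run-psa --config inst/extdata/base_case.json --n 10000 --seed 1 --out out/psa
```

## Repository layout

- `R/` — parameters & validation, life tables, cohort engine, CEA
  statistics, DSA/PSA/CEAC, synthetic-data generators and microsimulation
  oracle, CLI.
- `inst/extdata/` — packaged configurations. `base_case.json` is the real
  parameterization; files suffixed `_synthetic` (ASPECTS subgroups,
  input-swap scenario) are clearly labelled stand-ins whose true
  distributions live in external supplementary material.
- `tests/testthat/` — unit, property and acceptance tests.
- `vignettes/model-methods.Rmd` — model, assumptions, numerical choices,
  limitations.
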