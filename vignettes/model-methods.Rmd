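---
title: "Model and methods: thrombectomy cost-effectiveness for large-infarct stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The decision problem

Endovascular thrombectomy (EVT) on top of best medical care (BMC) improves
90-day functional outcome — and, in recent European trial data, survival — in
acute ischemic stroke with an established large infarct (ASPECTS 3–5). The
procedure is expensive, and the survivors it adds are often severely disabled
patients with high long-term care costs. Whether the clinical benefit is
worth the money to a healthcare payer is therefore a genuine quantitative
question, and this package implements the standard instrument for answering
it: a decision-analytic cost–utility model producing an incremental
cost-effectiveness ratio (ICER) in euros per quality-adjusted life-year
(QALY), together with deterministic and probabilistic characterizations of
its uncertainty.

`strokecea` re-implements such a model for the German healthcare-payer
perspective with 2022-euro inputs, as a fully scripted, tested pipeline. All
inputs ship in a JSON configuration (`inst/extdata/base_case.json`): 90-day
modified Rankin Scale (mRS) outcome distributions per treatment arm taken
from a recent European randomized trial of EVT in large-core stroke,
post-recurrence outcome probabilities, mRS-specific relative risks of death,
an annual stroke-recurrence schedule, EQ-5D-3L utilities, acute-phase costs
derived from DRG reimbursement, and annual long-term costs estimated from
statutory health-insurance claims.

# Model structure

**Health states.** Six states ordered by severity: `mrs01` (mRS 0–1), `mrs2`,
`mrs3`, `mrs4`, `mrs5`, and absorbing `dead`. mRS 0 and 1 are collapsed, as
is common when utilities and costs do not separate them.

**Acute phase (decision tree).** The first 90 days after the index stroke are
represented by the arm-specific 90-day mRS distribution. Survivors (mRS 0–5)
receive the arm's survivor acute cost, decedents the lower decedent cost.
QALYs accrue for 90/365.25 years at the utility of the 90-day state; by
default decedents accrue zero acute QALYs (switchable via
`acute_dead_half_credit`, which credits half the acute period at the mean
surviving utility — the difference is below 0.25 QALYs and identical in
structure across arms). Acute quantities are undiscounted (year 0). There is
no recurrent stroke and no intracranial-hemorrhage state in the acute phase:
the underlying trial found no significant between-arm difference in either.

**Markov model (annual cycles, lifetime horizon).** Cycle *k* = 1, 2, …
corresponds to age `starting_age + k` (72 + *k* in the base case). Within a
cycle, for each alive state:

1. **Recurrence first.** A fraction `p_rec(k)` (keyed to years since the
   *index* stroke — 0.11, 0.08, 0.02, 0.01, 0.01, then 0.02 from year six
   onwards — and never reset by a recurrence) suffers a recurrent stroke,
   treated with BMC, and draws a new 90-day state from the post-recurrence
   distribution. By default improvement past the pre-recurrence state is
   disallowed: probability mass on less severe states is folded onto the
   current state (`recurrent_outcome()`; `allow_improvement = TRUE` gives
   the unconstrained distribution — the published description implies
   deterioration, but the source distribution does contain mRS 0–1 mass,
   so both behaviours are implemented and the conservative fold is the
   documented default).
2. **Background mortality** applies only to the non-recurring fraction:
   life-table `qx` at the cohort's age times the state's relative risk,
   capped at 1. Recurring patients are exempt that cycle — the 0.19 fatality
   inside the post-recurrence distribution substitutes, which avoids
   double-counting death risk.
3. **Accrual with half-cycle correction.** Stayers accrue one year of the
   state's long-term cost and utility; those dying or recurring mid-cycle
   accrue half a year of each; recurring patients additionally accrue the
   full recurrent-stroke acute cost (EUR 16 670). Survivors of a recurrence
   enter the next cycle in their new state (no new-state accrual within the
   recurrence cycle).

Cycle *k*'s cost is discounted by `(1 + r_c)^-k` and its QALYs by
`(1 + r_e)^-k` (both 3%/year in the base case, varied independently in
sensitivity analysis). The 0.25-year offset between the 90-day mark and the
cycle grid is deliberately ignored in both discounting and age arithmetic.
The simulation stops when age exceeds `max_age` (110) or alive mass falls
below 1e-9, whichever comes first.

The ICER is `(C_EVT - C_BMC) / (E_EVT - E_BMC)`, compared against a
willingness-to-pay threshold of 1.01 × 2022 per-capita GDP
(`threshold_from_gdp(46264, 1.01)` = EUR 46 727/QALY). Degenerate cases that
a two-strategy base case never reaches but probabilistic draws can —
dominance, zero incremental effect — are classified by the standard
conventions in `icer()`.

# Numerical and design choices

**Renormalizing printed distributions.** The published BMC 90-day column sums
to 1.02 because of print rounding. A cohort model needs exact conservation,
so distributions are renormalized — keeping the *dead* probability as printed
(it is the trial-exact death proportion, e.g. 0.52 = 65/125) and rescaling
the alive states proportionally to `1 - P(dead)`. This reproduces the
expected acute-phase cost `0.48·25 352 + 0.52·8 814 = 16 752.24` exactly.
Proportional rescaling of all six entries was the considered alternative; it
would shift the death probability to 0.5098 and change no conclusion, but
keeping the trial-exact mortality is the more faithful reading.

**Life table.** Mortality comes from any user-supplied `age,qx` CSV (the
official German period life table, sex-averaged, is the intended input).
Because that file cannot be redistributed here, the default is a synthetic
Gompertz table, `qx(age) = 1 - exp(-a·e^{b(age-72)})`, calibrated once to
`qx(72) = 0.02` and `qx(95) = 0.25` — anchor values typical of a contemporary
Western European total-population table. It is a stand-in, not a
reproduction: the Gompertz shape is somewhat heavier than the real table in
the late 70s/80s, which shortens life expectancy at 72 by roughly one to two
years and makes headline QALY totals come out a few percent low. Beyond the
tabulated maximum age the table is extended geometrically
(`qx · 1.1^(age - max_age)`, capped at 1). Age-specific costs and utilities
are held age-constant: the claims-data cost regression behind the long-term
costs included age terms, but its coefficients are unpublished.

**PSA sampling.** Each parameter with a distributional specification is drawn
independently: beta for probabilities and utilities, gamma for annual costs,
lognormal for relative risks. Two published-parameter quirks matter:

* The six beta draws of each 90-day distribution are renormalized by their
  sum (how the original analysis combined per-state betas into a simplex is
  not stated; a joint Dirichlet with the same alphas is available via
  `mrs_sampling = "dirichlet"`). The printed alphas are centred on unrounded
  trial proportions, so printed base values and beta means differ by up to
  0.005 — tests assert centring at that tolerance.
* The printed gamma *rate* parameters are rounded to two decimals, which for
  the smallest rate (mRS 5, lambda printed as 0.02) biases the implied mean
  by about 15%. `sample_psa()` therefore re-derives each rate as
  `alpha / base value` by default (same shape, hence the same coefficient of
  variation), so draws are centred on the printed base costs;
  `recenter_gamma = FALSE` restores the literal printed parameters.

Parameters with no printed distribution (acute costs, recurrence schedule,
post-recurrence distribution, age) are held fixed in the PSA. Each iteration
applies one parameter realization to *both* arms (common random parameters).
All Monte Carlo is driven by one explicit master seed and is bit-reproducible.

**One-way DSA.** Every parameter with a published range is varied one at a
time: the 90-day state probabilities at their 95% CI bounds (with the other
alive states rescaled proportionally so the distribution still sums to 1),
relative risks, utilities and long-term costs at their CIs, acute costs at
±50%, starting age over the 65–80 IQR, and the two discount rates over
0–5% (a conventional range; the published table lists none for them).

# The synthetic-data module and what green tests establish

`make_synthetic_params()` generates three worlds: `base_like` (the packaged
configuration with every CI-carrying parameter perturbed uniformly within its
interval), `null_effect` (EVT made identical to BMC, so incremental cost and
effect are exactly zero), and `known_truth` (one alive state, constant
hazard, zero costs, no recurrence — lifetime QALYs then have a closed
geometric-series form the engine must match to 1e-9).
`microsimulate_cohort()` is an independently coded patient-level simulation
of the identical event logic; the cohort engine must agree with its means
within Monte Carlo error (tested at n = 50 000 on several synthetic
configurations).

These fixtures emulate the *structure* of the decision problem — state
distributions, cost/utility scales, mortality shapes — not real patients:
they contain no covariate heterogeneity, no secular trends in care or
reimbursement, and the base-like perturbations are independent across
parameters. A green test suite therefore establishes that the engine computes
the stated model correctly and reproducibly; it does not validate the model's
clinical inputs, nor does the synthetic life table reproduce official German
mortality exactly.

Internal validation follows the hypothesized-direction approach: shrinking
the between-arm gap in 90-day death probability (interpolating the EVT
distribution towards BMC, or the shipped synthetic input-swap scenario
mimicking trial inputs with a survival benefit about a third the size) must
strictly shrink the absolute lifetime QALY difference, and does.

# Reference values and known limitations

Against the published reference results (EVT vs BMC lifetime costs
EUR 110 952 / 86 695, QALYs 2.84 / 1.42, ICER EUR 17 158/QALY), this
implementation with the synthetic default life table reproduces every
headline quantity within 10% (ICER +3.0%, incremental QALYs −6.2%; the gap
is dominated by the life-table stand-in and the stated accrual conventions).
The tornado is led by the EVT acute cost with all ICERs below EUR 25 000, as
published. Two reference checks do not pass as stated: the CEAC reaches 95%
acceptability exactly at EUR 22 000 on a EUR 1 000 grid (one grid step below
the published "above EUR 22 000"), and the ASPECTS 3/4/5 subgroup ICERs
cannot be reproduced because the subgroup 90-day distributions live in
external supplementary material — the shipped `aspects*_synthetic.json`
configurations are clearly labelled clinical-plausibility stand-ins, and the
corresponding test documents the gap rather than papering over it. Users with
access to the real subgroup distributions or an official life table can drop
them in via `--config` / `--life-table` without touching code.

Other limitations are those of any annual-cycle Markov cohort model: a fixed
cycle length coarser than early post-stroke dynamics, the memoryless
transition assumption (softened only by keying recurrence to time since the
index event), payer-perspective costs only, and no improvement on the mRS
after 90 days, which if anything understates the treatment effect.
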