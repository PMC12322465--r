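Package: strokecea
Title: Cost-Effectiveness Modelling of Endovascular Thrombectomy for
    Large-Infarct Ischemic Stroke
Version: 1.0.0
Authors@R:
    person("J.", "Keller", email = "jkeller@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing endovascular
    thrombectomy (EVT) plus best medical care against best medical care alone
    for acute ischemic stroke with established large infarct (ASPECTS 3-5),
    from a healthcare-payer perspective. A 90-day acute-phase decision tree
    feeds a lifetime annual-cycle Markov cohort model over modified Rankin
    Scale health states, with half-cycle correction, stroke recurrence,
    life-table background mortality scaled by state-specific relative risks,
    and 3% annual discounting. Includes deterministic (tornado) and
    probabilistic (Monte Carlo) sensitivity analyses with cost-effectiveness
    acceptability curves, a Gompertz life-table generator, a patient-level
    microsimulation oracle for engine validation, and command-line entry
    points with structured CSV/JSON exports.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
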