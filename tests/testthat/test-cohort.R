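test_that("acute phase expectations match hand computation", {
  p <- base_params()
  evt <- acute_phase("EVT", p)
  expect_equal(evt$acute_cost, 0.63 * 30490 + 0.37 * 15466)  # 24931.12
  expect_equal(evt$acute_qaly,
               (90 / 365.25) * sum(p$dist90_evt[mrs_states()[1:5]] *
                                     p$utilities[mrs_states()[1:5]]))
  bmc <- acute_phase("BMC", p)
  expect_equal(bmc$acute_cost, 0.48 * 25352 + 0.52 * 8814)   # 16752.24

  all_dead <- stats::setNames(c(0, 0, 0, 0, 0, 1), mrs_states())
  deg <- acute_phase("EVT", p, dist90 = all_dead)
  expect_equal(deg$acute_cost, p$acute$evt_dead)
  expect_equal(deg$acute_qaly, 0)
})

test_that("state mortality = life-table qx times relative risk, capped", {
  p <- base_params()
  expect_equal(state_mortality_prob(80, "mrs5", const_lt(0.04), p$rrs),
               0.04 * 2.57)  # 0.1028
  expect_equal(state_mortality_prob(80, "mrs01", const_lt(0.1), p$rrs), 0.1)
  expect_equal(state_mortality_prob(80, "mrs5", const_lt(0.5), p$rrs), 1)
  expect_error(state_mortality_prob(80, "dead", const_lt(0.1), p$rrs),
               "alive")
})

test_that("post-recurrence outcomes fold improvement mass onto the current state", {
  p <- base_params()
  d <- p$dist_recurrent
  expect_equal(recurrent_outcome("mrs01", d), d)  # nothing below mrs01
  r5 <- recurrent_outcome("mrs5", d)
  expect_equal(unname(r5[c("mrs5", "dead")]), c(0.81, 0.19))
  expect_equal(sum(r5[c("mrs01", "mrs2", "mrs3", "mrs4")]), 0)
  r3 <- recurrent_outcome("mrs3", d)
  expect_equal(unname(r3[c("mrs3", "mrs4", "mrs5", "dead")]),
               c(0.42, 0.25, 0.14, 0.19))
  expect_equal(recurrent_outcome("mrs5", d, allow_improvement = TRUE), d)
  expect_error(recurrent_outcome("dead", d), "alive")
})

test_that("discount factors", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(7, 0), 1)
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("run_cycle applies the half-cycle rule", {
  p <- base_params()
  states <- mrs_states()

  # absorbing state: nothing happens, nothing accrues
  dead_occ <- stats::setNames(c(0, 0, 0, 0, 0, 1), states)
  st <- run_cycle(dead_occ, 1, p, const_lt(0.3))
  expect_equal(st$occupancy, dead_occ)
  expect_equal(st$cost, 0)
  expect_equal(st$qaly, 0)

  # single state mrs2, no recurrence, death probability 0.2
  p2 <- p
  p2$recurrence$p <- 0
  p2$rrs[["mrs2"]] <- 1
  occ <- stats::setNames(c(0, 1, 0, 0, 0, 0), states)
  st <- run_cycle(occ, 1, p2, const_lt(0.2))
  expect_equal(unname(st$occupancy[c("mrs2", "dead")]), c(0.8, 0.2))
  expect_equal(st$qaly, (0.8 + 0.2 * 0.5) * 0.83)  # 0.747
  expect_equal(st$cost, 0.9 * 7019)

  # single state mrs01, no background mortality, year-1 recurrence 0.11
  occ1 <- stats::setNames(c(1, 0, 0, 0, 0, 0), states)
  st <- run_cycle(occ1, 1, p, const_lt(0))
  expect_equal(st$recurrence_mass, 0.11)
  expect_equal(st$cost, 0.89 * 6970 + 0.11 * (0.5 * 6970 + 16670))  # 8420.35
  # recurrence outcome from mrs01 is the unfolded distribution
  expect_equal(unname(st$occupancy[["dead"]]), 0.11 * 0.19)
  expect_equal(sum(st$occupancy), 1)

  expect_error(run_cycle(occ1 * 2, 1, p, const_lt(0)), "sum to 1")
})

test_that("run_cohort handles immediate extinction", {
  p <- base_params()
  p$dist90_evt <- stats::setNames(c(0, 0, 0, 0, 0, 1), mrs_states())
  res <- run_cohort("EVT", p, default_life_table())
  expect_equal(res$total_qaly, 0)
  expect_equal(res$total_cost, p$acute$evt_dead)
  expect_equal(res$life_years, 0)
})

test_that("occupancy is conserved and death is absorbing on synthetic configs", {
  lt <- default_life_table()
  for (seed in c(11, 22, 33)) {
    p <- make_synthetic_params(seed, "base_like")
    for (strat in c("EVT", "BMC")) {
      res <- run_cohort(strat, p, lt)
      occ <- as.matrix(res$trace[, mrs_states()])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
      expect_true(all(diff(res$trace$dead) >= -1e-15))
      expect_lte(res$total_cost, res$undiscounted_cost)
      expect_lte(res$total_qaly, res$undiscounted_qaly)
      expect_lte(res$total_qaly, res$life_years + 1e-12)
    }
  }
})

test_that("totals are monotone in utilities and long-term costs", {
  p <- base_params()
  lt <- default_life_table()
  base <- run_cohort("EVT", p, lt)
  for (key in c("utilities.mrs3", "utilities.mrs5")) {
    up <- run_cohort("EVT", param_set(p, key, param_get(p, key) + 0.05), lt)
    expect_gte(up$total_qaly, base$total_qaly)
  }
  for (key in c("longterm_costs.mrs01", "longterm_costs.mrs4")) {
    up <- run_cohort("EVT", param_set(p, key, param_get(p, key) + 1000), lt)
    expect_gte(up$total_cost, base$total_cost)
  }
})

test_that("engine matches the geometric closed form on the known-truth config", {
  q <- 0.2; u <- 1
  p <- make_synthetic_params(scenario = "known_truth",
                             theta = list(q = q, u = u, r = 0))
  lt <- gompertz_life_table(gompertz_spec(a = -log(1 - q), b = 0))
  res <- run_cohort("EVT", p, lt)
  K <- nrow(res$trace)
  expect_equal(K, 38)  # age cap at 110 binds before extinction
  # survivors at cycle start (1-q)^(k-1); stayers accrue u, mid-cycle deaths u/2
  analytic <- (90 / 365.25) * u + u * (1 - 0.5 * q) * (1 - (1 - q)^K) / q
  expect_equal(res$total_qaly, analytic, tolerance = 1e-9)
  expect_equal(res$total_cost, 0)
})

test_that("shrinking the 90-day death gap shrinks the QALY difference", {
  p <- base_params()
  lt <- default_life_table()
  evt0 <- acute_phase("EVT", p)$distribution_at_90d
  bmc0 <- acute_phase("BMC", p)$distribution_at_90d
  gaps <- c()
  dq <- c()
  for (t in c(0, 0.25, 0.5, 0.75)) {
    evt_t <- (1 - t) * evt0 + t * bmc0   # dead gap shrinks as t grows
    re <- run_cohort("EVT", p, lt, dist90 = evt_t)
    rb <- run_cohort("BMC", p, lt)
    gaps <- c(gaps, bmc0[["dead"]] - evt_t[["dead"]])
    dq <- c(dq, abs(re$total_qaly - rb$total_qaly))
  }
  expect_true(all(diff(gaps) < 0))
  expect_true(all(diff(dq) < 0))

  # packaged synthetic input-swap scenario behaves in the hypothesized
  # direction as well
  swap <- load_params(system.file("extdata", "rescue_japan_swap_synthetic.json",
                                  package = "strokecea"))
  d_swap <- abs(run_cohort("EVT", swap, lt)$total_qaly -
                  run_cohort("BMC", swap, lt)$total_qaly)
  d_base <- abs(run_cohort("EVT", p, lt)$total_qaly -
                  run_cohort("BMC", p, lt)$total_qaly)
  expect_lt(d_swap, d_base)
})
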