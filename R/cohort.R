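#' Discount factor for an annual cycle
#'
#' @param cycle_index Cycle number (0 = time of the index stroke).
#' @param rate Annual discount rate as a fraction (e.g. 0.03).
#' @return `(1 + rate)^(-cycle_index)`.
#' @export
discount_factor <- function(cycle_index, rate) {
  stopifnot(cycle_index >= 0)
  if (any(rate < 0)) stop("discount rate must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle_index)
}

# Strategy-specific 90-day inputs from a parameter set.
strategy_inputs <- function(strategy, params) {
  strategy <- match.arg(strategy, c("EVT", "BMC"))
  if (strategy == "EVT")
    list(dist90 = params$dist90_evt,
         cost_survivor = params$acute$evt_survivor,
         cost_dead = params$acute$evt_dead)
  else
    list(dist90 = params$dist90_bmc,
         cost_survivor = params$acute$bmc_survivor,
         cost_dead = params$acute$bmc_dead)
}

#' Expected cost and QALYs of the 90-day acute phase
#'
#' The decision tree assigns every 90-day survivor (mRS 0--5) the strategy's
#' survivor acute cost and every decedent the (lower) decedent acute cost.
#' QALYs accrue for 90/365.25 years at the utility of the 90-day state;
#' by default decedents accrue zero acute-phase QALYs (see
#' `dead_half_credit`). Acute quantities are undiscounted (they occur in
#' year 0).
#'
#' @param strategy `"EVT"` or `"BMC"`.
#' @param params A `strokecea_params` object.
#' @param dist90 Optional 90-day state distribution overriding the strategy's
#'   (renormalized internally).
#' @param cost_survivor,cost_dead Optional acute cost overrides (euros).
#' @param dead_half_credit If `TRUE`, 90-day decedents are credited half the
#'   acute period at the mean utility of the surviving cohort (their pre-death
#'   state is not observed); default `FALSE` (decedents accrue 0 QALYs).
#' @return List with `distribution_at_90d` (sums to 1), `acute_cost` (euros)
#'   and `acute_qaly`.
#' @export
#' @examples
#' p <- load_params(system.file("extdata", "base_case.json",
#'                              package = "strokecea"))
#' acute_phase("EVT", p)$acute_cost   # 0.63 * 30490 + 0.37 * 15466
acute_phase <- function(strategy, params, dist90 = NULL,
                        cost_survivor = NULL, cost_dead = NULL,
                        dead_half_credit = FALSE) {
  si <- strategy_inputs(strategy, params)
  if (is.null(dist90)) dist90 <- si$dist90
  if (is.null(cost_survivor)) cost_survivor <- si$cost_survivor
  if (is.null(cost_dead)) cost_dead <- si$cost_dead
  dist90 <- normalize_dist90(dist90)
  p_dead <- dist90[["dead"]]
  p_alive <- 1 - p_dead
  cost <- p_alive * cost_survivor + p_dead * cost_dead
  u <- params$utilities[ALIVE_STATES]
  qaly_alive <- sum(dist90[ALIVE_STATES] * u)
  qaly <- ACUTE_PHASE_YEARS * qaly_alive
  if (dead_half_credit && p_alive > 0)
    qaly <- qaly + 0.5 * ACUTE_PHASE_YEARS * p_dead * (qaly_alive / p_alive)
  list(distribution_at_90d = dist90, acute_cost = cost, acute_qaly = qaly)
}

#' Annual death probability in an mRS state
#'
#' Background life-table mortality multiplied by the state-specific relative
#' risk, capped at 1.
#'
#' @param age Age in years.
#' @param state One of the alive states `mrs01` .. `mrs5`.
#' @param lt A `strokecea_lifetable`.
#' @param rrs Named relative risks per alive state (`mrs01` = 1).
#' @return Probability of death within the year.
#' @export
state_mortality_prob <- function(age, state, lt, rrs) {
  if (!state %in% ALIVE_STATES)
    stop("state must be one of the alive states, got '", state, "'",
         call. = FALSE)
  min(1, annual_death_prob(lt, age) * rrs[[state]])
}

#' 90-day outcome distribution after a recurrent stroke
#'
#' By default improvement beyond the pre-recurrence state is not allowed: the
#' post-recurrence outcome is `max(current, drawn state)` in severity order,
#' i.e. the mass of the recurrent-outcome distribution on states less severe
#' than the current one is folded onto the current state. With
#' `allow_improvement = TRUE` the distribution is returned unchanged.
#'
#' @param current The pre-recurrence alive state.
#' @param dist_recurrent 90-day outcome distribution after recurrent stroke
#'   (treated with best medical care).
#' @param allow_improvement Allow outcomes less severe than `current`?
#' @return A state distribution (sums to whatever `dist_recurrent` sums to;
#'   renormalize upstream).
#' @export
#' @examples
#' p <- load_params(system.file("extdata", "base_case.json",
#'                              package = "strokecea"))
#' recurrent_outcome("mrs5", p$dist_recurrent)  # 0.81 mrs5, 0.19 dead
recurrent_outcome <- function(current, dist_recurrent,
                              allow_improvement = FALSE) {
  if (!current %in% ALIVE_STATES)
    stop("current state must be alive, got '", current, "'", call. = FALSE)
  d <- as_state_dist(dist_recurrent, "dist_recurrent")
  if (allow_improvement) return(d)
  i <- match(current, MRS_STATES)
  if (i > 1) {
    d[[current]] <- d[[current]] + sum(d[seq_len(i - 1)])
    d[seq_len(i - 1)] <- 0
  }
  d
}

# Annual recurrence probability for a given year since the index stroke.
recurrence_prob <- function(schedule, year) {
  hit <- schedule$from_year <= year & year <= schedule$to_year
  if (!any(hit)) return(0)
  schedule$p[which(hit)[1]]
}

# 5x6 matrix of post-recurrence outcome distributions, one row per current
# alive state (columns in MRS_STATES order, rows renormalized to sum 1).
fold_matrix <- function(dist_recurrent, allow_improvement = FALSE) {
  m <- t(vapply(ALIVE_STATES, function(s)
    renormalize_dist(recurrent_outcome(s, dist_recurrent, allow_improvement)),
    numeric(6)))
  dimnames(m) <- list(ALIVE_STATES, MRS_STATES)
  m
}

# One Markov cycle on plain numeric vectors. All quantities undiscounted.
# alive: mass per alive state; qd: annual death prob per alive state (already
# RR-scaled and capped); prec: recurrence probability this cycle; fold: 5x6
# post-recurrence matrix; ltc/util: per alive state; c_recur: acute cost of a
# recurrent stroke.
#
# Event order: recurrence first; recurring patients are exempt from background
# mortality that cycle (the recurrent distribution's own 90-day fatality
# substitutes). Half-cycle correction: mid-cycle transitions (death or
# recurrence) accrue half a year of the pre-transition state's cost and
# utility; the recurrent acute cost is applied in full.
cycle_step <- function(alive, dead, qd, prec, fold, ltc, util, c_recur) {
  rec <- alive * prec
  nonrec <- alive - rec
  die <- nonrec * qd
  stay <- nonrec - die
  from_rec <- drop(crossprod(fold, rec))          # length 6 over MRS_STATES
  new_alive <- stay + from_rec[ALIVE_STATES]
  new_dead <- dead + sum(die) + from_rec[["dead"]]
  half <- die + rec
  list(alive = new_alive,
       dead = new_dead,
       cost = sum(stay * ltc) + 0.5 * sum(half * ltc) + sum(rec) * c_recur,
       qaly = sum(stay * util) + 0.5 * sum(half * util),
       ly = sum(stay) + 0.5 * sum(half),
       recurrence_mass = sum(rec))
}

#' Run a single Markov cycle
#'
#' Advances a state-occupancy distribution through one annual cycle:
#' recurrence is resolved first among that cycle's alive cohort (with the
#' post-recurrence outcome constrained to no improvement by default), then
#' background mortality — life-table `qx` at the cohort's age times the mRS
#' relative risk, capped at 1 — applies to the non-recurring patients. Stayers
#' accrue a full year of the state's long-term cost and utility; patients
#' dying or recurring mid-cycle accrue half a year (half-cycle correction);
#' recurring patients additionally accrue the recurrent-stroke acute cost.
#' Outputs are undiscounted.
#'
#' @param occupancy State distribution at cycle start (must sum to 1).
#' @param cycle_index Cycle number (1, 2, ...); also the year since the index
#'   stroke used for the recurrence schedule. The cohort's age is
#'   `econ$starting_age + cycle_index`.
#' @param params A `strokecea_params` object.
#' @param lt A `strokecea_lifetable`.
#' @param allow_improvement Passed to [recurrent_outcome()].
#' @return List with `occupancy` (next cycle start, sums to 1), `cost`,
#'   `qaly`, `life_years` (all undiscounted) and `recurrence_mass`.
#' @export
run_cycle <- function(occupancy, cycle_index, params, lt,
                      allow_improvement = FALSE) {
  occupancy <- as_state_dist(occupancy, "occupancy")
  if (abs(sum(occupancy) - 1) > 1e-9)
    stop("occupancy must sum to 1, got ", sum(occupancy), call. = FALSE)
  age <- params$econ$starting_age + cycle_index
  qd <- pmin(1, annual_death_prob(lt, age) * params$rrs[ALIVE_STATES])
  st <- cycle_step(alive = occupancy[ALIVE_STATES],
                   dead = occupancy[["dead"]],
                   qd = qd,
                   prec = recurrence_prob(params$recurrence, cycle_index),
                   fold = fold_matrix(params$dist_recurrent,
                                      allow_improvement),
                   ltc = params$longterm[ALIVE_STATES],
                   util = params$utilities[ALIVE_STATES],
                   c_recur = params$acute$recurrent)
  occ <- c(st$alive, dead = st$dead)
  names(occ) <- MRS_STATES
  list(occupancy = occ, cost = st$cost, qaly = st$qaly, life_years = st$ly,
       recurrence_mass = st$recurrence_mass)
}

#' Run one strategy through the full model
#'
#' Runs the 90-day acute-phase decision tree, then annual Markov cycles
#' k = 1, 2, ... at ages `starting_age + k`, discounting each cycle's costs
#' at `(1 + discount_rate_costs)^-k` and QALYs at
#' `(1 + discount_rate_effects)^-k`, until age exceeds `econ$max_age`
#' (default 110) or the alive mass drops below `1e-9`. Acute-phase cost and
#' QALYs enter undiscounted (year 0).
#'
#' @inheritParams run_cycle
#' @param strategy `"EVT"` or `"BMC"`.
#' @param dist90 Optional 90-day distribution override (e.g. a subgroup or a
#'   PSA draw already stored in `params` makes this unnecessary).
#' @param keep_trace Keep the cycle-by-cycle trace (default `TRUE`; the PSA
#'   turns it off for speed).
#' @param acute_dead_half_credit Passed to [acute_phase()] as
#'   `dead_half_credit`.
#' @return A `strokecea_cohort` list: `strategy`, `total_cost`, `total_qaly`
#'   (discounted), `undiscounted_cost`, `undiscounted_qaly`, `life_years`
#'   (undiscounted), `acute` (the [acute_phase()] result) and `trace`, a data
#'   frame with one row per cycle (cycle, age, six occupancy columns,
#'   recurrence_mass, cost_discounted, qaly_discounted).
#' @export
#' @examples
#' p <- load_params(system.file("extdata", "base_case.json",
#'                              package = "strokecea"))
#' lt <- gompertz_life_table(gompertz_spec())
#' run_cohort("EVT", p, lt)$total_qaly
run_cohort <- function(strategy, params, lt, dist90 = NULL,
                       allow_improvement = FALSE, keep_trace = TRUE,
                       acute_dead_half_credit = FALSE) {
  strategy <- match.arg(strategy, c("EVT", "BMC"))
  ap <- acute_phase(strategy, params, dist90 = dist90,
                    dead_half_credit = acute_dead_half_credit)

  econ <- params$econ
  start_age <- econ$starting_age
  n_cycles <- max(0L, floor(econ$max_age - start_age))
  ages <- start_age + seq_len(n_cycles)
  qx <- if (n_cycles) annual_death_prob(lt, ages) else numeric()
  rr <- params$rrs[ALIVE_STATES]
  ltc <- params$longterm[ALIVE_STATES]
  util <- params$utilities[ALIVE_STATES]
  fold <- fold_matrix(params$dist_recurrent, allow_improvement)
  prec <- vapply(seq_len(n_cycles),
                 function(k) recurrence_prob(params$recurrence, k), numeric(1))
  dfc <- (1 + econ$discount_rate_costs)^(-seq_len(n_cycles))
  dfe <- (1 + econ$discount_rate_effects)^(-seq_len(n_cycles))
  c_recur <- params$acute$recurrent

  alive <- ap$distribution_at_90d[ALIVE_STATES]
  dead <- ap$distribution_at_90d[["dead"]]
  cost_d <- ap$acute_cost; cost_u <- ap$acute_cost
  qaly_d <- ap$acute_qaly; qaly_u <- ap$acute_qaly
  ly <- ACUTE_PHASE_YEARS * sum(alive)

  trace <- if (keep_trace)
    vector("list", n_cycles)
  else NULL

  k_used <- 0L
  for (k in seq_len(n_cycles)) {
    if (sum(alive) < 1e-9) break
    qd <- pmin(1, qx[k] * rr)
    st <- cycle_step(alive, dead, qd, prec[k], fold, ltc, util, c_recur)
    alive <- st$alive; dead <- st$dead
    cost_u <- cost_u + st$cost;       qaly_u <- qaly_u + st$qaly
    cost_d <- cost_d + st$cost * dfc[k]
    qaly_d <- qaly_d + st$qaly * dfe[k]
    ly <- ly + st$ly
    k_used <- k
    if (keep_trace)
      trace[[k]] <- c(cycle = k, age = ages[k], alive, dead = dead,
                      recurrence_mass = st$recurrence_mass,
                      cost_discounted = st$cost * dfc[k],
                      qaly_discounted = st$qaly * dfe[k])
  }

  if (keep_trace) {
    trace <- as.data.frame(do.call(rbind, trace[seq_len(k_used)]))
  }

  structure(list(strategy = strategy,
                 total_cost = cost_d, total_qaly = qaly_d,
                 undiscounted_cost = cost_u, undiscounted_qaly = qaly_u,
                 life_years = ly, acute = ap, trace = trace),
            class = "strokecea_cohort")
}

#' @export
print.strokecea_cohort <- function(x, ...) {
  cat("<strokecea_cohort> ", x$strategy, ": discounted cost EUR ",
      formatC(x$total_cost, format = "f", digits = 0, big.mark = " "),
      ", QALYs ", formatC(x$total_qaly, format = "f", digits = 2),
      ", life-years ", formatC(x$life_years, format = "f", digits = 2),
      "\n", sep = "")
  invisible(x)
}
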