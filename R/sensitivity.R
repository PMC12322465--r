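# Set one 90-day mRS-state probability and rescale the others proportionally
# so the distribution sums to 1. Varying an alive state keeps the dead
# probability fixed and rescales the other alive states; varying the dead
# probability rescales all alive states.
set_dist90_prob <- function(dist, state, value) {
  d <- normalize_dist90(dist)
  if (value < 0 || value > 1)
    stop("probability for ", state, " must be in [0,1], got ", value,
         call. = FALSE)
  if (state == "dead") {
    rest <- ALIVE_STATES
  } else {
    rest <- setdiff(ALIVE_STATES, state)
  }
  target_rest <- 1 - value - if (state == "dead") 0 else d[["dead"]]
  if (target_rest < 0)
    stop("probability ", value, " for ", state,
         " leaves no mass for the remaining states", call. = FALSE)
  s_rest <- sum(d[rest])
  d[rest] <- if (s_rest > 0) d[rest] * target_rest / s_rest
             else target_rest / length(rest)
  d[[state]] <- value
  d
}

# Apply one DSA value: 90-day mRS probabilities get proportional
# renormalization, everything else is a plain scalar replacement.
apply_param_value <- function(params, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (parts[1] == "dist90" && length(parts) == 3) {
    field <- paste0("dist90_", parts[2])
    params[[field]] <- set_dist90_prob(params[[field]], parts[3], value)
    params
  } else {
    param_set(params, key, value)
  }
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full model twice per parameter — once at the low and once at the
#' high end of its range, everything else at base — and records the resulting
#' ICERs. When a single 90-day mRS-state probability is varied, the remaining
#' alive-state probabilities are rescaled proportionally so the distribution
#' still sums to 1 (the dead probability is held fixed unless it is itself the
#' varied parameter). Entries are sorted by descending span for tornado
#' plotting.
#'
#' @param params A `strokecea_params` object.
#' @param lt A `strokecea_lifetable`.
#' @param ranges Named list of `c(low, high)` ranges keyed as in
#'   [param_get()]; defaults to the config's `dsa` block (Table-1 ranges plus
#'   0--5% for the discount rates).
#' @param threshold Willingness-to-pay threshold for the embedded [icer()]
#'   calls.
#' @return A `strokecea_tornado` data frame: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span = |icer_high - icer_low|`, sorted by
#'   descending span; the base-case ICER is in `attr(, "base_icer")`.
#' @export
one_way_dsa <- function(params, lt, ranges = params$dsa_ranges,
                        threshold = params$econ$wtp_threshold) {
  if (!length(ranges)) stop("no DSA ranges supplied", call. = FALSE)
  icer_at <- function(p) {
    res <- icer(run_cohort("EVT", p, lt, keep_trace = FALSE),
                run_cohort("BMC", p, lt, keep_trace = FALSE),
                threshold = threshold)
    res$icer
  }
  base_icer <- icer_at(params)
  rows <- lapply(names(ranges), function(key) {
    rng <- as.numeric(ranges[[key]])
    base <- param_get(params, key)   # errors on unknown keys
    if (length(rng) != 2)
      stop("DSA range for '", key, "' must be c(low, high)", call. = FALSE)
    lo <- icer_at(apply_param_value(params, key, rng[1]))
    hi <- icer_at(apply_param_value(params, key, rng[2]))
    data.frame(parameter = key, base = base, low = rng[1], high = rng[2],
               icer_low = lo, icer_high = hi, span = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer,
            class = c("strokecea_tornado", "data.frame"))
}

# Draw one value from a PSA distribution spec. `base` is the base-case value,
# used to re-derive the gamma rate (alpha / base) because the printed rates
# are rounded to 2 d.p., which would bias cost draws by up to 15%.
draw_spec <- function(spec, base, recenter_gamma = TRUE) {
  switch(spec$family,
    beta = stats::rbeta(1, spec$alpha, spec$beta),
    gamma = {
      rate <- if (recenter_gamma && base > 0) spec$alpha / base
              else spec$lambda
      stats::rgamma(1, shape = spec$alpha, rate = rate)
    },
    lognormal = exp(stats::rnorm(1, spec$log_mean, spec$se)),
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

#' Draw one probabilistic-sensitivity-analysis parameter realization
#'
#' Every parameter carrying a distributional specification (beta for
#' probabilities and utilities, gamma for annual costs, lognormal for relative
#' risks of death) is replaced by an independent draw; parameters without a
#' spec stay at their base value. The six beta draws of each 90-day mRS
#' distribution are renormalized by their sum so every sampled distribution
#' sums to 1 exactly (`mrs_sampling = "dirichlet"` draws the distribution
#' jointly from the Dirichlet with the same alphas instead). Uses the current
#' R random-number state; seed upstream (see [run_psa()]).
#'
#' @param params A `strokecea_params` object whose `psa_specs` are drawn from.
#' @param mrs_sampling `"independent"` (default: independent betas, then
#'   renormalize) or `"dirichlet"` for the 90-day distributions.
#' @param recenter_gamma Re-derive each gamma rate as `alpha / base value`
#'   (same shape, hence same coefficient of variation) so cost draws are
#'   centered on the base value despite the 2-d.p. rounding of the printed
#'   rates; default `TRUE`.
#' @return A `strokecea_params` realization with sampled values.
#' @export
sample_psa <- function(params, mrs_sampling = c("independent", "dirichlet"),
                       recenter_gamma = TRUE) {
  mrs_sampling <- match.arg(mrs_sampling)
  keys <- names(params$psa_specs)
  keys <- if (length(keys)) sort(keys, method = "radix") else character()
  dist_groups <- c("dist90.evt", "dist90.bmc")
  out <- params
  for (grp in dist_groups) {
    gkeys <- keys[startsWith(keys, paste0(grp, "."))]
    if (!length(gkeys)) next
    field <- paste0("dist90_", sub("dist90.", "", grp, fixed = TRUE))
    d <- out[[field]]
    for (key in gkeys) {
      spec <- params$psa_specs[[key]]
      state <- sub(paste0(grp, "."), "", key, fixed = TRUE)
      d[[state]] <- if (mrs_sampling == "dirichlet")
        stats::rgamma(1, shape = spec$alpha, rate = 1)
      else
        draw_spec(spec, base = param_get(params, key), recenter_gamma)
    }
    out[[field]] <- renormalize_dist(d)
  }
  scalar_keys <- keys[!startsWith(keys, "dist90.")]
  for (key in scalar_keys) {
    value <- draw_spec(params$psa_specs[[key]], base = param_get(params, key),
                       recenter_gamma = recenter_gamma)
    out <- param_set(out, key, value)
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: in each iteration one parameter realization is
#' drawn with [sample_psa()] and *both* strategies are run with that same
#' realization (common random parameters), recording incremental discounted
#' costs and QALYs. Fully reproducible from `master_seed`.
#'
#' @inheritParams one_way_dsa
#' @inheritParams sample_psa
#' @param n_iter Number of iterations (the reference analysis uses 10 000).
#' @param master_seed Integer seed driving all draws.
#' @return A `strokecea_psa` list: `draws` (data frame with per-iteration
#'   costs and QALYs per strategy, `delta_cost`, `delta_qaly`), `n_iter`,
#'   `master_seed`.
#' @export
run_psa <- function(params, lt, n_iter, master_seed = 1L,
                    mrs_sampling = c("independent", "dirichlet"),
                    recenter_gamma = TRUE) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  mrs_sampling <- match.arg(mrs_sampling)
  set.seed(as.integer(master_seed))
  cost_evt <- qaly_evt <- cost_bmc <- qaly_bmc <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    s <- sample_psa(params, mrs_sampling, recenter_gamma)
    re <- run_cohort("EVT", s, lt, keep_trace = FALSE)
    rb <- run_cohort("BMC", s, lt, keep_trace = FALSE)
    cost_evt[i] <- re$total_cost; qaly_evt[i] <- re$total_qaly
    cost_bmc[i] <- rb$total_cost; qaly_bmc[i] <- rb$total_qaly
  }
  draws <- data.frame(iter = seq_len(n_iter),
                      cost_evt = cost_evt, qaly_evt = qaly_evt,
                      cost_bmc = cost_bmc, qaly_bmc = qaly_bmc,
                      delta_cost = cost_evt - cost_bmc,
                      delta_qaly = qaly_evt - qaly_bmc)
  structure(list(draws = draws, n_iter = n_iter,
                 master_seed = as.integer(master_seed)),
            class = "strokecea_psa")
}

#' @export
print.strokecea_psa <- function(x, ...) {
  cat("<strokecea_psa> ", x$n_iter, " iterations (seed ", x$master_seed,
      ")\n", sep = "")
  cat("  mean dCost EUR ",
      formatC(mean(x$draws$delta_cost), format = "f", digits = 0,
              big.mark = " "),
      ", mean dQALY ",
      formatC(mean(x$draws$delta_qaly), format = "f", digits = 2), "\n",
      sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of cost-effectiveness is
#' the fraction of PSA iterations with positive incremental net monetary
#' benefit, `wtp * dQALY - dCost > 0`.
#'
#' @param psa A `strokecea_psa` result.
#' @param wtp_grid Willingness-to-pay grid in euros/QALY (default EUR 0 to
#'   100 000 in steps of 1 000).
#' @return A `strokecea_ceac` data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty", call. = FALSE)
  de <- psa$draws$delta_qaly
  dc <- psa$draws$delta_cost
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("strokecea_ceac", "data.frame"))
}

#' First willingness-to-pay reaching a target acceptability
#'
#' @param curve A `strokecea_ceac` data frame.
#' @param target Target probability in (0, 1), e.g. 0.95.
#' @return The smallest grid `wtp` whose probability is at least `target`, or
#'   `NA` if the curve never reaches it.
#' @export
wtp_at_probability <- function(curve, target) {
  stopifnot(nrow(curve) > 0, target > 0, target < 1)
  hit <- which(curve$probability >= target)
  if (!length(hit)) return(NA_real_)
  curve$wtp[hit[1]]
}
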