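#' Load a model parameterization from a JSON config file
#'
#' Reads a versioned JSON configuration holding the complete model
#' parameterization: 90-day mRS distributions per strategy, the post-recurrence
#' outcome distribution, acute-phase and annual long-term costs (2022 euros),
#' EQ-5D utilities, relative risks of death by mRS state, the annual recurrence
#' schedule, economic settings, and the distributional specifications / ranges
#' used by the probabilistic and deterministic sensitivity analyses.
#'
#' Packaged configurations live under `system.file("extdata", package =
#' "strokecea")`: `base_case.json` plus synthetic stand-ins for the ASPECTS
#' subgroups and the input-swap validation scenario (marked `_synthetic`).
#'
#' @param path Path to a JSON config file.
#' @param overrides Optional named list of `key = value` overrides applied
#'   after loading; keys use the dotted addressing of [param_get()], e.g.
#'   `list("econ.starting_age" = 65)`.
#' @return A `strokecea_params` object (see Details).
#' @details The returned object is a list with elements `dist90_evt`,
#'   `dist90_bmc`, `dist_recurrent` (named probability vectors over
#'   [mrs_states()]), `acute` (euros: `evt_survivor`, `evt_dead`,
#'   `bmc_survivor`, `bmc_dead`, `recurrent`), `longterm` (euros/year per alive
#'   state), `utilities` (per state, `dead` = 0), `rrs` (relative risk of death
#'   per alive state, `mrs01` = 1), `recurrence` (data frame `from_year`,
#'   `to_year`, `p`; the last row is open-ended with `to_year = Inf`), `econ`
#'   (starting age, discount rates for costs and effects, willingness-to-pay
#'   threshold, maximum age, cycle length), `psa_specs` and `dsa_ranges`.
#'   Distributions are stored as printed; renormalization to an exact sum of 1
#'   happens inside the engines.
#' @seealso [validate_params()], [write_params()], [param_get()]
#' @export
#' @examples
#' p <- load_params(system.file("extdata", "base_case.json",
#'                              package = "strokecea"))
#' p$dist90_evt[["dead"]]
load_params <- function(path, overrides = NULL) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("dist90", "dist_recurrent", "acute_costs", "longterm_costs",
                "utilities", "mortality_rr", "recurrence", "econ")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("config ", path, " is missing required block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  econ_defaults <- list(starting_age = 72, discount_rate_costs = 0.03,
                        discount_rate_effects = 0.03, wtp_threshold = 46727,
                        max_age = 110, cycle_length = 1)
  econ <- utils::modifyList(econ_defaults, as.list(raw$econ))

  rec <- as.data.frame(raw$recurrence)
  if (!all(c("from_year", "p") %in% names(rec)))
    stop("recurrence block needs columns from_year, p", call. = FALSE)
  if (is.null(rec$to_year)) rec$to_year <- rec$from_year
  # JSON null marks the open-ended last band; it may surface as NA or NULL
  rec$to_year <- vapply(rec$to_year, function(v)
    if (is.null(v) || length(v) == 0 || is.na(v)) Inf else as.numeric(v),
    numeric(1))
  rec$from_year <- as.numeric(unlist(rec$from_year))
  rec$p <- as.numeric(unlist(rec$p))
  rec <- rec[order(rec$from_year), c("from_year", "to_year", "p")]

  longterm <- unlist(raw$longterm_costs)[ALIVE_STATES]
  rrs <- unlist(raw$mortality_rr)[ALIVE_STATES]
  utilities <- unlist(raw$utilities)
  if (!"dead" %in% names(utilities)) utilities[["dead"]] <- 0
  utilities <- utilities[MRS_STATES]

  psa <- raw$psa
  if (is.data.frame(psa)) psa <- as.list(as.data.frame(t(psa)))
  psa_specs <- lapply(if (is.null(psa)) list() else psa, as.list)
  dsa <- lapply(if (is.null(raw$dsa)) list() else raw$dsa, as.numeric)

  ps <- structure(list(
    label = if (is.null(raw$label)) basename(path) else raw$label,
    schema_version = if (is.null(raw$schema_version)) 1L
                     else as.integer(raw$schema_version),
    dist90_evt = as_state_dist(unlist(raw$dist90$evt), "dist90.evt"),
    dist90_bmc = as_state_dist(unlist(raw$dist90$bmc), "dist90.bmc"),
    dist_recurrent = as_state_dist(unlist(raw$dist_recurrent),
                                   "dist_recurrent"),
    acute = as.list(unlist(raw$acute_costs)),
    longterm = longterm,
    utilities = utilities,
    rrs = rrs,
    recurrence = rec,
    econ = econ,
    psa_specs = psa_specs,
    dsa_ranges = dsa
  ), class = "strokecea_params")

  acute_req <- c("evt_survivor", "evt_dead", "bmc_survivor", "bmc_dead",
                 "recurrent")
  miss <- setdiff(acute_req, names(ps$acute))
  if (length(miss))
    stop("acute_costs block missing: ", paste(miss, collapse = ", "),
         call. = FALSE)

  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a fully named list", call. = FALSE)
    for (key in names(overrides))
      ps <- param_set(ps, key, overrides[[key]])
  }
  ps
}

#' Serialize a parameter set back to its JSON config format
#'
#' Round-trips with [load_params()]: loading, writing, and reloading yields an
#' identical parameter set.
#'
#' @param params A `strokecea_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "strokecea_params"))
  rec <- params$recurrence
  rec$to_year[is.infinite(rec$to_year)] <- NA
  out <- list(
    schema_version = params$schema_version,
    label = params$label,
    dist90 = list(evt = as.list(params$dist90_evt),
                  bmc = as.list(params$dist90_bmc)),
    dist_recurrent = as.list(params$dist_recurrent),
    acute_costs = params$acute,
    longterm_costs = as.list(params$longterm),
    utilities = as.list(params$utilities),
    mortality_rr = as.list(params$rrs),
    recurrence = rec,
    econ = params$econ,
    psa = params$psa_specs,
    dsa = params$dsa_ranges
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.strokecea_params <- function(x, ...) {
  cat("<strokecea_params> '", x$label, "' (schema v", x$schema_version, ")\n",
      sep = "")
  cat("  starting age ", x$econ$starting_age, ", discounting ",
      100 * x$econ$discount_rate_costs, "% costs / ",
      100 * x$econ$discount_rate_effects, "% effects, WTP threshold EUR ",
      x$econ$wtp_threshold, "/QALY\n", sep = "")
  cat("  90-day dead: EVT ", x$dist90_evt[["dead"]], ", BMC ",
      x$dist90_bmc[["dead"]], "\n", sep = "")
  cat("  ", length(x$psa_specs), " PSA distributions, ",
      length(x$dsa_ranges), " DSA ranges\n", sep = "")
  invisible(x)
}

# ---- dotted-key parameter addressing ---------------------------------------

# Resolve a dotted key like "dist90.evt.mrs4" to list(field, element).
resolve_key <- function(params, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  bad <- function() stop("unknown parameter key: '", key, "'", call. = FALSE)
  if (length(parts) == 3 && parts[1] == "dist90") {
    if (!parts[2] %in% c("evt", "bmc") || !parts[3] %in% MRS_STATES) bad()
    return(list(field = paste0("dist90_", parts[2]), element = parts[3]))
  }
  if (length(parts) == 2) {
    field <- switch(parts[1],
                    dist_recurrent = "dist_recurrent",
                    acute_costs = "acute",
                    longterm_costs = "longterm",
                    utilities = "utilities",
                    mortality_rr = "rrs",
                    econ = "econ",
                    bad())
    container <- params[[field]]
    if (!parts[2] %in% names(container)) bad()
    return(list(field = field, element = parts[2]))
  }
  bad()
}

#' Read or replace one scalar parameter by dotted key
#'
#' Scalar parameters are addressed with dotted keys mirroring the config
#' layout: `"dist90.evt.mrs4"`, `"acute_costs.evt_survivor"`,
#' `"longterm_costs.mrs3"`, `"utilities.mrs2"`, `"mortality_rr.mrs5"`,
#' `"econ.starting_age"`, `"dist_recurrent.mrs01"`. This addressing is what
#' config overrides, the one-way DSA and the PSA sampler use.
#'
#' @param params A `strokecea_params` object.
#' @param key Dotted parameter key.
#' @param value Replacement value (for `param_set`).
#' @return `param_get`: the numeric value. `param_set`: the modified
#'   parameter set.
#' @export
#' @examples
#' p <- load_params(system.file("extdata", "base_case.json",
#'                              package = "strokecea"))
#' param_get(p, "utilities.mrs2")
param_get <- function(params, key) {
  loc <- resolve_key(params, key)
  as.numeric(params[[loc$field]][[loc$element]])
}

#' @rdname param_get
#' @export
param_set <- function(params, key, value) {
  loc <- resolve_key(params, key)
  params[[loc$field]][[loc$element]] <- as.numeric(value)
  params
}

# ---- validation ------------------------------------------------------------

check_dist <- function(d, what, errors, warnings) {
  bad <- which(d < 0 | d > 1)
  for (i in bad)
    errors <- c(errors, sprintf("%s: state %s has probability %g outside [0,1]",
                                what, names(d)[i], d[[i]]))
  s <- sum(d)
  if (!length(bad)) {
    if (abs(s - 1) > 0.025) {
      errors <- c(errors, sprintf(
        "%s: probabilities sum to %.4f, outside tolerance [0.975, 1.025]",
        what, s))
    } else if (abs(s - 1) > 1e-12) {
      warnings <- c(warnings, sprintf(
        "%s: probabilities sum to %.4f and will be renormalized", what, s))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Validate a parameter set
#'
#' Checks every type invariant (probabilities in range and summing to 1 within
#' a 0.025 print-rounding tolerance, non-negative costs, utilities in `[0,1]`
#' with `dead` = 0, reference relative risk 1 for mRS 0--1, discount rates in
#' `[0, 0.2]`, PSA specs referring to existing scalar parameters with positive
#' shape parameters, DSA ranges bracketing their base values). Distributions
#' summing to something in `[0.975, 1.025]` but not exactly 1 — the printed
#' BMC 90-day column sums to 1.02 — produce a warning and are renormalized
#' downstream; they are not errors.
#'
#' @param params A `strokecea_params` object.
#' @return A `strokecea_validation` list with character vectors `errors` and
#'   `warnings`; the parameter set is usable iff `errors` is empty.
#' @export
validate_params <- function(params) {
  errors <- character()
  warnings <- character()

  for (nm in c("dist90_evt", "dist90_bmc", "dist_recurrent")) {
    r <- check_dist(params[[nm]], nm, errors, warnings)
    errors <- r$errors; warnings <- r$warnings
  }

  for (nm in names(params$acute))
    if (params$acute[[nm]] < 0)
      errors <- c(errors, sprintf("acute_costs.%s is negative (%g)", nm,
                                  params$acute[[nm]]))
  for (nm in names(params$longterm))
    if (params$longterm[[nm]] < 0)
      errors <- c(errors, sprintf("longterm_costs.%s is negative (%g)", nm,
                                  params$longterm[[nm]]))

  u <- params$utilities
  if (any(u < 0 | u > 1))
    errors <- c(errors, "utilities must lie in [0,1]")
  if (u[["dead"]] != 0)
    errors <- c(errors, "utility of the dead state must be 0")
  if (is.unsorted(rev(u[ALIVE_STATES])))
    warnings <- c(warnings,
                  "utilities are not non-increasing from mrs01 to mrs5")

  if (abs(params$rrs[["mrs01"]] - 1) > 1e-12)
    errors <- c(errors, "mortality_rr.mrs01 must be 1 (reference state)")
  if (any(params$rrs < 0))
    errors <- c(errors, "relative risks of death must be >= 0")

  if (any(params$recurrence$p < 0 | params$recurrence$p > 1))
    errors <- c(errors, "recurrence probabilities must lie in [0,1]")

  econ <- params$econ
  for (nm in c("discount_rate_costs", "discount_rate_effects"))
    if (econ[[nm]] < 0 || econ[[nm]] > 0.2)
      errors <- c(errors, sprintf("econ.%s = %g outside [0, 0.2]", nm,
                                  econ[[nm]]))
  if (econ$starting_age >= econ$max_age)
    errors <- c(errors, "econ.starting_age must be below econ.max_age")

  for (key in names(params$psa_specs)) {
    loc <- tryCatch(resolve_key(params, key), error = function(e) NULL)
    if (is.null(loc)) {
      errors <- c(errors, sprintf("PSA spec refers to unknown parameter '%s'",
                                  key))
      next
    }
    chk <- tryCatch({ distribution_mean(params$psa_specs[[key]]); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(chk))
      errors <- c(errors, sprintf("PSA spec '%s': %s", key, chk))
  }

  for (key in names(params$dsa_ranges)) {
    loc <- tryCatch(resolve_key(params, key), error = function(e) NULL)
    if (is.null(loc)) {
      errors <- c(errors, sprintf("DSA range refers to unknown parameter '%s'",
                                  key))
      next
    }
    rng <- params$dsa_ranges[[key]]
    base <- param_get(params, key)
    if (length(rng) != 2 || rng[1] > rng[2])
      errors <- c(errors, sprintf("DSA range for '%s' is not (low, high)", key))
    else if (base < rng[1] - 1e-9 || base > rng[2] + 1e-9)
      errors <- c(errors, sprintf(
        "DSA range for '%s' [%g, %g] does not bracket base value %g",
        key, rng[1], rng[2], base))
  }

  structure(list(errors = errors, warnings = warnings),
            class = "strokecea_validation")
}

#' @export
print.strokecea_validation <- function(x, ...) {
  cat("<strokecea_validation>", length(x$errors), "error(s),",
      length(x$warnings), "warning(s)\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Central value of a PSA distribution specification
#'
#' Returns the value each probabilistic-sensitivity-analysis distribution is
#' centered on: the mean for beta (`alpha / (alpha + beta)`) and gamma
#' (`alpha / lambda`) specifications, and the median `exp(log_mean)` for the
#' lognormal specifications used for relative risks.
#'
#' @param spec A list with `family` (`"beta"`, `"gamma"` or `"lognormal"`) and
#'   the family's parameters: `alpha`/`beta`, `alpha`/`lambda` (rate), or
#'   `log_mean`/`se`.
#' @return The central value, a scalar.
#' @export
#' @examples
#' distribution_mean(list(family = "beta", alpha = 50.92, beta = 573.08))
distribution_mean <- function(spec) {
  fam <- spec$family
  if (is.null(fam)) stop("distribution spec lacks a 'family'", call. = FALSE)
  switch(fam,
    beta = {
      if (spec$alpha <= 0 || spec$beta <= 0)
        stop("beta parameters must be positive", call. = FALSE)
      spec$alpha / (spec$alpha + spec$beta)
    },
    gamma = {
      if (spec$alpha <= 0 || spec$lambda <= 0)
        stop("gamma parameters must be positive", call. = FALSE)
      spec$alpha / spec$lambda
    },
    lognormal = {
      if (spec$se <= 0)
        stop("lognormal standard error must be positive", call. = FALSE)
      exp(spec$log_mean)
    },
    stop("unknown distribution family: ", fam, call. = FALSE)
  )
}
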