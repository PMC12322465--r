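#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes incremental costs and effects, the ICER (difference in mean costs
#' divided by difference in mean effects) where defined, the standard
#' dominance classification, and a cost-effectiveness flag at a
#' willingness-to-pay threshold.
#'
#' @param intervention,comparator `strokecea_cohort` results from the same
#'   parameter set and life table (typically EVT and BMC).
#' @param threshold Willingness-to-pay threshold in euros/QALY; defaults to
#'   46727 (1.01 times 2022 German per-capita GDP, see
#'   [threshold_from_gdp()]).
#' @return A `strokecea_cea` list: `delta_cost`, `delta_qaly`, `icer` (`NA`
#'   when `delta_qaly` is 0), `classification` (`"icer"`, `"dominant"`,
#'   `"dominated"` or `"equal"`) and `cost_effective` (dominant, or positive
#'   incremental effect with ICER below the threshold).
#' @export
#' @examples
#' p <- load_params(system.file("extdata", "base_case.json",
#'                              package = "strokecea"))
#' lt <- gompertz_life_table(gompertz_spec())
#' icer(run_cohort("EVT", p, lt), run_cohort("BMC", p, lt))
icer <- function(intervention, comparator, threshold = 46727) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  classification <-
    if (dc == 0 && de == 0) "equal"
    else if (dc <= 0 && de >= 0) "dominant"
    else if (dc >= 0 && de <= 0) "dominated"
    else "icer"
  ic <- if (de != 0) dc / de else NA_real_
  ce <- classification == "dominant" ||
    (de > 0 && !is.na(ic) && ic < threshold)
  structure(list(delta_cost = dc, delta_qaly = de, icer = ic,
                 classification = classification, cost_effective = ce,
                 threshold = threshold,
                 intervention = intervention$strategy,
                 comparator = comparator$strategy),
            class = "strokecea_cea")
}

#' @export
print.strokecea_cea <- function(x, ...) {
  cat("<strokecea_cea> ", x$intervention, " vs ", x$comparator, "\n", sep = "")
  cat("  dCost EUR ", formatC(x$delta_cost, format = "f", digits = 0,
                              big.mark = " "),
      ", dQALY ", formatC(x$delta_qaly, format = "f", digits = 2), "\n",
      sep = "")
  if (x$classification == "icer")
    cat("  ICER EUR ", formatC(x$icer, format = "f", digits = 0,
                               big.mark = " "), "/QALY\n", sep = "")
  else cat("  classification:", x$classification, "\n")
  cat("  cost-effective at EUR ", x$threshold, "/QALY: ", x$cost_effective,
      "\n", sep = "")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * total_qaly - total_cost`; sign-consistent with comparing the ICER
#' against the willingness-to-pay, and the statistic behind the CEAC.
#'
#' @param result A `strokecea_cohort` result (or any list with `total_qaly`
#'   and `total_cost`).
#' @param wtp Willingness to pay in euros per QALY (must be >= 0).
#' @return Net monetary benefit in euros.
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) stop("willingness to pay must be >= 0", call. = FALSE)
  wtp * result$total_qaly - result$total_cost
}

#' Willingness-to-pay threshold from per-capita GDP
#'
#' The threshold used in the base case is 1.01 times the 2022 German
#' per-capita gross domestic product of EUR 46 264, rounded to the nearest
#' euro (half away from zero): EUR 46 727 per QALY.
#'
#' @param gdp_per_capita Per-capita GDP in euros.
#' @param multiplier Threshold multiplier (default 1.01).
#' @return Threshold in euros/QALY, rounded half-up to the nearest euro.
#' @export
#' @examples
#' threshold_from_gdp(46264, 1.01)  # 46727
threshold_from_gdp <- function(gdp_per_capita, multiplier = 1.01) {
  stopifnot(gdp_per_capita > 0, multiplier > 0)
  floor(gdp_per_capita * multiplier + 0.5)
}
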