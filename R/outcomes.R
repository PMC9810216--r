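#' Life-years outcome calculus
#'
#' From the three paired arms of a scenario, computes the study outcomes,
#' all expressed as life-years (LY) per 1,000 persons measured from the
#' cohort reference age:
#' \itemize{
#' \item `LY` - life-years under the disrupted scenario;
#' \item `LYND` - life-years under the no-disruption counterfactual;
#' \item `LYNS` - life-years under no screening;
#' \item `LYL = LYND - LY` - life-years lost to the disruption;
#' \item `LYG_nd = LYND - LYNS` - life-years gained by undisrupted
#'   screening;
#' \item `pct_ly_lost = 100 LYL / LYG_nd` - the share of the screening
#'   benefit lost (`NA` when `LYG_nd <= 0`);
#' \item `ly_days_per_person = LYL / 1000 * 365.25` - the loss as
#'   life-days per person;
#' \item `se_LYL` - Monte Carlo standard error of LYL from the paired
#'   per-person differences (common random numbers make this far smaller
#'   than the unpaired error).
#' }
#'
#' @param arms a `scenario_arms` object from [run_scenario()], or a list
#'   with index-aligned `arm_result`s `disrupted`, `no_disruption`,
#'   `no_screening`.
#' @param scale persons per reporting unit (default 1,000).
#' @return a one-row data frame (an outcome record).
#' @export
compute_outcomes <- function(arms, scale = 1000) {
  a <- arms$disrupted; nd <- arms$no_disruption; ns <- arms$no_screening
  stopifnot(inherits(a, "arm_result"), inherits(nd, "arm_result"),
            inherits(ns, "arm_result"))
  if (a$n != nd$n || a$n != ns$n ||
      length(a$person_ly) != length(nd$person_ly) ||
      length(a$person_ly) != length(ns$person_ly))
    stop("misaligned arms: the three arms must have equal n, index-aligned")
  n <- a$n
  LY <- mean(a$person_ly) * scale
  LYND <- mean(nd$person_ly) * scale
  LYNS <- mean(ns$person_ly) * scale
  LYL <- LYND - LY
  LYG <- LYND - LYNS
  pct <- if (LYG > 0) 100 * LYL / LYG else NA_real_
  diffs <- nd$person_ly - a$person_ly
  se <- stats::sd(diffs) / sqrt(n) * scale
  diffs_g <- nd$person_ly - ns$person_ly
  se_g <- stats::sd(diffs_g) / sqrt(n) * scale
  data.frame(scenario_label = a$scenario_label,
             sensitivity_scenario = arms$sensitivity %||% NA_character_,
             param_set = arms$param_set %||% NA_character_,
             n = n,
             LY = LY, LYNS = LYNS, LYND = LYND,
             LYL = LYL, LYG_nd = LYG, pct_ly_lost = pct,
             ly_days_per_person = LYL / scale * 365.25,
             se_LYL = se, se_LYG = se_g,
             stringsAsFactors = FALSE)
}

format_range <- function(lo, hi, digits) {
  flo <- formatC(lo, format = "f", digits = digits)
  fhi <- formatC(hi, format = "f", digits = digits)
  if (identical(flo, fhi)) flo else paste(flo, "to", fhi)
}

#' Cross-model outcome ranges
#'
#' Summarises outcome records of the same scenario across natural-history
#' parameter sets (the cross-model range): per scenario and sensitivity
#' scenario, the min-max of LYL and of the percent benefit lost, rendered
#' `"lo to hi"` (collapsing to a single value when the ends agree at the
#' reported precision: LY to the nearest integer, percentages to one
#' decimal).
#'
#' @param records a data frame of outcome records ([compute_outcomes()]
#'   rows).
#' @return a data frame with one row per (scenario, sensitivity).
#' @export
range_across <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  key <- interaction(records$scenario_label, records$sensitivity_scenario,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    pct <- g$pct_ly_lost[!is.na(g$pct_ly_lost)]
    data.frame(
      scenario_label = g$scenario_label[1],
      sensitivity_scenario = g$sensitivity_scenario[1],
      n_sets = nrow(g),
      LYL_min = min(g$LYL), LYL_max = max(g$LYL),
      LYL_mid = (min(g$LYL) + max(g$LYL)) / 2,
      LYL_range = format_range(min(g$LYL), max(g$LYL), 0),
      pct_range = if (length(pct))
        format_range(min(pct), max(pct), 1) else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank scenarios by reduction in benefit
#'
#' Orders scenario summaries from highest to lowest mid-range life-years
#' lost (ties broken by label, lexicographically) and flags scenarios
#' whose loss is below two life-days per person - the visibility
#' threshold used when plotting ranked losses.
#'
#' @param records outcome records; grouped internally with
#'   [range_across()] when they contain several parameter sets.
#' @return the summary data frame ordered by descending `LYL_mid`, with a
#'   logical column `below_2_days`.
#' @export
rank_scenarios <- function(records) {
  sm <- range_across(records)
  sm$ly_days_per_person <- sm$LYL_mid / 1000 * 365.25
  sm$below_2_days <- sm$ly_days_per_person < 2
  sm[order(-sm$LYL_mid, sm$scenario_label), , drop = FALSE]
}
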