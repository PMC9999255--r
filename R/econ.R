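# Pairwise incremental cost-effectiveness / cost-utility comparison and
# WHO willingness-to-pay classification.

#' Classify an intervention against WHO GDP-per-capita thresholds
#'
#' For an intervention that *gains* QALYs, the cost per QALY gained is
#' compared with 1x and 3x GDP per capita: below 1x is highly
#' cost-effective, between 1x and 3x cost-effective, above 3x not
#' cost-effective.  For a *utility-reducing* but cost-saving intervention
#' the rule reverses: savings per QALY lost above 3x GDP are highly
#' cost-effective, between 1x and 3x cost-effective, and below 1x not
#' cost-effective (the savings do not compensate the loss).  Strict
#' dominance (cheaper and more effective / dearer and less effective) is
#' reported as such.
#'
#' @param delta_cost Incremental cost (intervention minus comparator), USD.
#' @param delta_qaly Incremental QALYs (same direction).
#' @param gdp GDP per capita, USD (threshold 1x; 3x is derived).
#' @param boundary_favorable Ratios exactly on a threshold take the more
#'   favourable class (default `TRUE`).
#' @return One of `"dominant"`, `"highly cost-effective"`,
#'   `"cost-effective"`, `"not cost-effective"`, `"dominated"`,
#'   `"equivalent"`.
#' @export
who_classify <- function(delta_cost, delta_qaly, gdp,
                         boundary_favorable = TRUE) {
  stopifnot(gdp > 0)
  lo <- gdp
  hi <- 3 * gdp
  lt <- function(a, b) if (boundary_favorable) a <= b else a < b
  gt <- function(a, b) if (boundary_favorable) a >= b else a > b
  if (delta_qaly > 0) {
    if (delta_cost <= 0) return("dominant")
    ratio <- delta_cost / delta_qaly
    if (lt(ratio, lo)) "highly cost-effective"
    else if (lt(ratio, hi)) "cost-effective"
    else "not cost-effective"
  } else if (delta_qaly < 0) {
    if (delta_cost >= 0) return("dominated")
    savings_per_qaly_lost <- (-delta_cost) / (-delta_qaly)
    if (gt(savings_per_qaly_lost, hi)) "highly cost-effective"
    else if (gt(savings_per_qaly_lost, lo)) "cost-effective"
    else "not cost-effective"
  } else {
    if (delta_cost < 0) "dominant"
    else if (delta_cost > 0) "dominated"
    else "equivalent"
  }
}

#' Net monetary benefit
#'
#' \eqn{NMB = \lambda \cdot QALY - Cost}; at willingness-to-pay
#' \eqn{\lambda} the strategy with the larger NMB is optimal.
#'
#' @param cost Total (discounted) cost, USD.
#' @param qaly Total (discounted) QALYs.
#' @param lambda Willingness-to-pay threshold, USD per QALY.
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(cost, qaly, lambda) {
  lambda * qaly - cost
}

#' Incremental cost-effectiveness and cost-utility comparison
#'
#' Compares an intervention arm against a baseline arm run on identical
#' model parameters.  Differences are intervention minus baseline; the ICER
#' is the incremental cost per year without blindness and the ICUR the
#' incremental cost per QALY, reported from the per-100,000-screened
#' incrementals (numerically identical to the per-person ratio).  Zero
#' effect denominators flag the corresponding ratio as undefined (`NA`) and
#' classification falls back to the cost comparison.
#'
#' @param a Intervention [run_cohort()] result (or any list with `cost`,
#'   `qaly`, `years_without_blindness`).
#' @param b Baseline result.
#' @param gdp GDP per capita for the WHO classification.
#' @param scale Population scale for incrementals (default 100,000).
#' @param boundary_favorable Passed to [who_classify()].
#' @return Object of class `econ_result` with per-person values, per-`scale`
#'   incrementals, `icer`, `icur`, the sign quadrant and `classification`.
#' @export
compare_strategies <- function(a, b, gdp, scale = 1e5,
                               boundary_favorable = TRUE) {
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  d_ywb <- a$years_without_blindness - b$years_without_blindness
  icer <- if (d_ywb != 0) (d_cost * scale) / (d_ywb * scale) else NA_real_
  icur <- if (d_qaly != 0) (d_cost * scale) / (d_qaly * scale) else NA_real_
  quadrant <- paste0(ifelse(d_cost >= 0, "C+", "C-"),
                     ifelse(d_qaly >= 0, "E+", "E-"))
  structure(list(
    per_person = data.frame(
      strategy = c(a$strategy %||% "a", b$strategy %||% "b"),
      cost = c(a$cost, b$cost),
      years_without_blindness = c(a$years_without_blindness,
                                  b$years_without_blindness),
      qaly = c(a$qaly, b$qaly)),
    delta_cost = d_cost, delta_qaly = d_qaly,
    delta_years_without_blindness = d_ywb,
    incr_cost_per_scale = d_cost * scale,
    incr_qaly_per_scale = d_qaly * scale,
    incr_ywb_per_scale = d_ywb * scale,
    scale = scale,
    icer = icer, icur = icur, quadrant = quadrant,
    classification = who_classify(d_cost, d_qaly, gdp, boundary_favorable),
    gdp = gdp
  ), class = "econ_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.econ_result <- function(x, ...) {
  cat("Incremental comparison (", x$per_person$strategy[1], " vs ",
      x$per_person$strategy[2], " baseline)\n", sep = "")
  pp <- x$per_person
  for (i in 1:2) {
    cat(sprintf("  %-8s cost $%.2f | years w/o blindness %.4f | QALY %.4f\n",
                pp$strategy[i], pp$cost[i], pp$years_without_blindness[i],
                pp$qaly[i]))
  }
  cat(sprintf("  incremental per %s: cost $%.2f | years %.2f | QALY %.2f\n",
              format(x$scale, big.mark = ","), x$incr_cost_per_scale,
              x$incr_ywb_per_scale, x$incr_qaly_per_scale))
  cat(sprintf("  ICER $%.2f per year without blindness | ICUR $%.2f per QALY\n",
              x$icer, x$icur))
  cat("  classification:", x$classification, "(quadrant", x$quadrant, ")\n")
  invisible(x)
}
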