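#' Convert a cumulative incidence proportion to a constant annual rate
#'
#' Epidemiological studies often report cumulative incidence over a multi-year
#' interval (e.g. a 5-year incidence of sight-threatening retinopathy), while a
#' discrete-time Markov model needs one-year transition probabilities.  Under a
#' constant-hazard assumption the instantaneous rate is
#' \eqn{r = -\log(1 - p) / t}.
#'
#' @param p Cumulative incidence proportion over the interval, in `[0, 1)`.
#' @param t Length of the interval in years, strictly positive.
#' @return The constant annual rate (per person-year), nonnegative.
#' @seealso [probability_from_rate()] for the inverse transform.
#' @examples
#' annual_rate_from_cumulative(0.18, 5)
#' @export
annual_rate_from_cumulative <- function(p, t) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be a cumulative incidence in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be a positive interval length in years", call. = FALSE)
  }
  -log(1 - p) / t
}

#' Convert a constant annual rate to a probability over an interval
#'
#' Inverse of [annual_rate_from_cumulative()]: a constant rate `r` acting for
#' `t` years yields event probability \eqn{1 - \exp(-rt)}.
#'
#' @param r Constant rate per year, nonnegative.
#' @param t Interval length in years, strictly positive.
#' @return Event probability in `[0, 1)`.
#' @examples
#' probability_from_rate(log(2), 1)  # 0.5
#' @export
probability_from_rate <- function(r, t = 1) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("`r` must be a nonnegative rate", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be a positive interval length in years", call. = FALSE)
  }
  1 - exp(-r * t)
}

#' Discount a value back from a given cycle
#'
#' Standard compound discounting: `value / (1 + rate)^cycle`.  Cycle 0 (the
#' model start) is undiscounted.
#'
#' @param value Amount (cost in USD, or utility).
#' @param rate Annual discount rate as a fraction (default 0.035).
#' @param cycle Cycle index, 0-based.
#' @return The discounted amount.
#' @export
discount <- function(value, rate, cycle) {
  if (any(rate < 0)) stop("`rate` must be nonnegative", call. = FALSE)
  if (any(cycle < 0)) stop("`cycle` must be nonnegative", call. = FALSE)
  value / (1 + rate)^cycle
}

#' Adjust an annual death probability by a state-specific odds ratio
#'
#' Background (general-population) mortality is adjusted for the excess
#' mortality of diabetes and its ocular complications on the odds scale:
#' the baseline probability is converted to odds, multiplied by the odds
#' ratio, and converted back, \eqn{q = OR\,o / (1 + OR\,o)} with
#' \eqn{o = p / (1 - p)}.
#'
#' @param base_prob Annual background death probability, in `[0, 1)`; the
#'   degenerate value 1 is returned unchanged with a warning.
#' @param or Odds ratio, strictly positive; `or = 1` returns `base_prob`.
#' @return Adjusted annual death probability in `[0, 1)`.
#' @examples
#' apply_mortality_or(0.5, 3)  # odds 1 -> 3, probability 0.75
#' @export
apply_mortality_or <- function(base_prob, or) {
  if (any(!is.finite(or)) || any(or <= 0)) {
    stop("`or` must be a positive odds ratio", call. = FALSE)
  }
  if (any(base_prob < 0) || any(base_prob > 1)) {
    stop("`base_prob` must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(base_prob == 1)) {
    warning("base_prob = 1 is degenerate; returning 1")
  }
  odds <- base_prob / (1 - base_prob)
  ifelse(base_prob == 1, 1, (or * odds) / (1 + or * odds))
}
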