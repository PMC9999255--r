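# One-way deterministic sensitivity analysis (tornado) and the
# referral-compliance threshold scan.

#' One-way sweep of a single parameter
#'
#' Re-runs the two-arm comparison with the named parameter set to its low
#' and then its high range end, all other parameters at base.  The base
#' configuration is untouched (the sweep is side-effect-free).
#'
#' @param cfg Base configuration.
#' @param name Parameter name (a row of [parameter_table()]) with
#'   `low < high`.
#' @return One-row data frame: ICUR and ICER at each end, classifications,
#'   spreads (absolute difference, `NA` when an end is undefined), and a
#'   `flagged` indicator set when an endpoint ratio is undefined or the two
#'   endpoint effect differences have opposite signs (dominance change).
#' @export
one_way_sweep <- function(cfg, name) {
  pt <- parameter_table(cfg)
  row <- pt[pt$name == name, ]
  if (nrow(row) != 1) stop("unknown parameter: ", name, call. = FALSE)
  if (!(row$low < row$high)) {
    # degenerate range: zero-width tornado bar
  }
  ends <- lapply(c(row$low, row$high), function(val) {
    run_base_case(set_parameter(cfg, name, val), ledger = FALSE,
                  check = "draw")$comparison
  })
  lo <- ends[[1]]; hi <- ends[[2]]
  spread_icur <- if (is.na(lo$icur) || is.na(hi$icur)) NA_real_ else
    abs(hi$icur - lo$icur)
  spread_icer <- if (is.na(lo$icer) || is.na(hi$icer)) NA_real_ else
    abs(hi$icer - lo$icer)
  flagged <- is.na(lo$icur) || is.na(hi$icur) ||
    sign(lo$delta_qaly) != sign(hi$delta_qaly) ||
    sign(lo$delta_cost) != sign(hi$delta_cost)
  data.frame(parameter = name, low = row$low, high = row$high,
             icur_at_low = lo$icur, icur_at_high = hi$icur,
             icer_at_low = lo$icer, icer_at_high = hi$icer,
             class_at_low = lo$classification,
             class_at_high = hi$classification,
             spread_icur = spread_icur, spread_icer = spread_icer,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Full tornado analysis
#'
#' Sweeps every parameter with a non-degenerate sensitivity range.  Entries
#' are sorted by descending ICUR spread; flagged entries (undefined or
#' sign-changing ratios, typically the compliance multiplier) sort last and
#' are usually reported separately rather than drawn as tornado bars.
#'
#' @param cfg Base configuration.
#' @return Data frame of [one_way_sweep()] rows.
#' @export
run_dsa <- function(cfg) {
  pt <- parameter_table(cfg)
  names_swept <- pt$name[pt$low < pt$high]
  out <- do.call(rbind, lapply(names_swept, function(nm) one_way_sweep(cfg, nm)))
  out[order(out$flagged, -pmin(out$spread_icur, Inf),
            method = "radix", na.last = TRUE), , drop = FALSE]
}

#' Referral-compliance threshold scan for the AI arm
#'
#' Applies a grid of compliance multipliers to the AI arm only (the swept
#' quantity is the change in referral compliance after adopting AI) and
#' records the WHO classification at each grid point, plus the smallest
#' multiplier at which each classification first appears.
#'
#' @param cfg Base configuration.
#' @param multipliers Grid of multipliers, by default 0.75 to 1.25.
#' @return List with `scan` (data frame multiplier / icur / classification)
#'   and `thresholds` (first multiplier reaching each class).
#' @export
compliance_threshold_scan <- function(cfg,
                                      multipliers = seq(0.75, 1.25, by = 0.025)) {
  scan <- do.call(rbind, lapply(multipliers, function(m) {
    cmp <- run_base_case(set_parameter(cfg, "compliance_multiplier_ai", m),
                         ledger = FALSE)$comparison
    data.frame(multiplier = m, delta_cost = cmp$delta_cost,
               delta_qaly = cmp$delta_qaly, icur = cmp$icur,
               classification = cmp$classification,
               stringsAsFactors = FALSE)
  }))
  first_at <- tapply(scan$multiplier, scan$classification, min)
  list(scan = scan,
       thresholds = data.frame(classification = names(first_at),
                               first_multiplier = as.numeric(first_at),
                               row.names = NULL))
}

#' Tornado plot of a DSA table
#'
#' @param dsa Data frame from [run_dsa()].
#' @param measure `"icur"` or `"icer"`.
#' @param top Number of (unflagged) parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, measure = c("icur", "icer"), top = 10) {
  measure <- match.arg(measure)
  lo <- dsa[[paste0(measure, "_at_low")]]
  hi <- dsa[[paste0(measure, "_at_high")]]
  d <- data.frame(parameter = dsa$parameter, low = lo, high = hi,
                  spread = abs(hi - lo), flagged = dsa$flagged)
  d <- d[!d$flagged & is.finite(d$spread), ]
  d <- utils::head(d[order(-d$spread), ], top)
  d$parameter <- stats::reorder(factor(d$parameter), d$spread)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low, xend = .data$high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = paste(toupper(measure), "(USD)"), y = NULL,
                  title = "One-way deterministic sensitivity analysis") +
    ggplot2::theme_minimal()
}
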