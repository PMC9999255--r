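# Care-pathway costing from a societal perspective.  Every flow is split
# into direct-medical / direct-nonmedical / indirect components; wage loss
# for participants and accompanying family members at screening and referral
# is zero by assumption (the cohort is past retirement age), but the
# component fields exist for generalisation.

flow_rows <- function(flow, comp, mass, cycle, rate) {
  und <- comp * mass
  data.frame(cycle = cycle, flow = flow, component = names(comp),
             undiscounted = unname(und),
             discounted = unname(discount(und, rate, cycle)),
             row.names = NULL)
}

#' Per-cycle cost flows for one cohort cycle
#'
#' Combines the six pathway flows for one annual cycle: per-attendee
#' screening, confirmatory referral examinations (true and false positives),
#' first-year treatment of newly detected disease (3 anti-VEGF injections
#' for macular oedema; photocoagulation or vitrectomy for severe
#' non-proliferative / proliferative retinopathy), follow-up treatment of
#' previously treated disease (1 injection plus an annual outpatient
#' review), the first-year blindness burden, and the indirect-only
#' continuing blindness burden.
#'
#' @param occupancy Cycle-start occupancy vector.
#' @param tallies Screening event tallies from [screening_update()].
#' @param new_blind Mass newly entering blindness at this cycle start.
#' @param costs Pathway cost list from [load_parameters()] (`model$costs`).
#' @param strategy Strategy configuration (for the screening cost).
#' @param cycle Cycle index, 0-based.
#' @param rate Annual discount rate.
#' @return List with `total_discounted`, `total_undiscounted` and a `ledger`
#'   data frame (cycle, flow, component, undiscounted, discounted).
#' @export
cycle_costs <- function(occupancy, tallies, new_blind, costs, strategy,
                        cycle, rate) {
  if (any(vapply(costs, function(x) any(x < 0), logical(1))) ||
      strategy$screening_cost < 0) {
    stop("negative cost component", call. = FALSE)
  }
  continuing_blind <- occupancy[["blind"]] - new_blind
  if (continuing_blind < -1e-12) {
    stop("blind inflow exceeds blind occupancy", call. = FALSE)
  }
  continuing_blind <- max(0, continuing_blind)
  prev_treated <- occupancy[["stdr_treated"]] + occupancy[["dme_treated"]]

  rows <- rbind(
    flow_rows("screening", c(total = strategy$screening_cost),
              tallies[["screened"]], cycle, rate),
    flow_rows("referral_exam", costs$referral, tallies[["referrals"]],
              cycle, rate),
    flow_rows("treatment_first_year", costs$treat_first_pdr,
              tallies[["tp_stdr"]], cycle, rate),
    flow_rows("treatment_first_year", costs$treat_first_dme,
              tallies[["tp_dme"]], cycle, rate),
    flow_rows("treatment_followup", costs$treat_followup, prev_treated,
              cycle, rate),
    flow_rows("blindness_first_year", costs$blind_first, new_blind,
              cycle, rate),
    flow_rows("blindness_followup", costs$blind_followup, continuing_blind,
              cycle, rate)
  )
  list(total_discounted = sum(rows$discounted),
       total_undiscounted = sum(rows$undiscounted),
       ledger = rows)
}

#' Decompose blind occupancy into first-year and continuing mass
#'
#' One-cycle tunnel bookkeeping: the mass newly blind at cycle `k` is the
#' inflow into blindness during the preceding transition, recovered from the
#' occupancy history and the per-cycle blind-to-blind retention probability
#' (1 minus the blind death probability).  All blind occupancy at cycle 0 is
#' treated as newly blind.
#'
#' @param blind_occupancy Numeric vector of blind-state occupancy by cycle
#'   (cycle 0 first).
#' @param stay_prob Per-cycle probability that a blind person remains alive
#'   (and blind); length `length(blind_occupancy) - 1`, recycled if scalar.
#' @return Data frame with columns `cycle`, `newly_blind`,
#'   `continuing_blind`; the two masses sum to the occupancy.
#' @export
blindness_tunnel <- function(blind_occupancy, stay_prob) {
  n <- length(blind_occupancy)
  stay <- rep_len(stay_prob, max(0, n - 1))
  newly <- numeric(n)
  newly[1] <- blind_occupancy[1]
  if (n > 1) {
    newly[-1] <- blind_occupancy[-1] - blind_occupancy[-n] * stay
  }
  newly <- pmax(0, newly)
  data.frame(cycle = seq_len(n) - 1L, newly_blind = newly,
             continuing_blind = blind_occupancy - newly)
}
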