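# Cohort state-transition engine.  Eight health states; disease severity can
# only increase (no regression, even under treatment), death is absorbing and
# is reached from every alive state via age-specific background mortality
# adjusted by a state-specific odds ratio.

#' Health states of the retinopathy model
#'
#' In order: free of retinopathy (diabetic, `no_dr`), non-sight-threatening
#' retinopathy (`non_stdr`), sight-threatening retinopathy and macular oedema
#' as parallel severe branches, each split into undetected and treated
#' sub-states, then blindness and death.
#'
#' @format Character vector of the eight state names.
#' @export
health_states <- c("no_dr", "non_stdr", "stdr_undetected", "stdr_treated",
                   "dme_undetected", "dme_treated", "blind", "dead")

alive_nonblind_states <- health_states[1:6]

#' Build the annual transition matrix for one age
#'
#' Disease progression probabilities are constant over age; treated severe
#' states progress at the untreated probability times the treatment
#' multiplier (treatment slows, never reverses, progression).  The death
#' column is the age-specific background probability adjusted on the odds
#' scale by the state's mortality odds ratio; the residual mass stays in the
#' current state.  Screening (detection) is a separate within-cycle step, so
#' the matrix has no undetected-to-treated entries and does not depend on the
#' screening strategy.
#'
#' @param model Validated model parameters from [load_parameters()].
#' @param age Age in years; must be covered by the mortality table.
#' @return An 8x8 row-stochastic matrix with dimnames [health_states].
#' @export
build_transition_matrix <- function(model, age) {
  q0 <- unname(model$qx[as.character(age)])
  if (is.na(q0)) stop("age ", age, " outside mortality-table support",
                      call. = FALSE)
  d <- c(no_dr = apply_mortality_or(q0, model$ors[["no_dr"]]),
         non_stdr = apply_mortality_or(q0, model$ors[["non_stdr"]]),
         stdr = apply_mortality_or(q0, model$ors[["stdr"]]),
         blind = apply_mortality_or(q0, model$ors[["blind"]]))
  p <- model$probs
  m <- model$treatment_multiplier

  S <- length(health_states)
  T <- matrix(0, S, S, dimnames = list(health_states, health_states))
  set_row <- function(from, to_probs, death) {
    s <- sum(to_probs) + death
    if (s > 1 + 1e-12) {
      stop("outgoing probability mass from state '", from,
           "' exceeds 1 (", signif(s, 6), ")", call. = FALSE)
    }
    T[from, names(to_probs)] <<- to_probs
    T[from, "dead"] <<- death
    T[from, from] <<- 1 - s
  }
  set_row("no_dr", c(non_stdr = p$no_dr_to_non_stdr), d[["no_dr"]])
  set_row("non_stdr", c(stdr_undetected = p$non_stdr_to_stdr,
                        dme_undetected = p$non_stdr_to_dme), d[["non_stdr"]])
  set_row("stdr_undetected", c(blind = p$stdr_to_blind), d[["stdr"]])
  set_row("stdr_treated", c(blind = p$stdr_to_blind * m), d[["stdr"]])
  set_row("dme_undetected", c(blind = p$dme_to_blind), d[["stdr"]])
  set_row("dme_treated", c(blind = p$dme_to_blind * m), d[["stdr"]])
  set_row("blind", c(), d[["blind"]])
  T["dead", "dead"] <- 1
  T
}

#' Apply one round of screening to a cohort occupancy vector
#'
#' Every alive, non-blind resident attends the annual community screening
#' (the programme re-screens people already diagnosed).  Undetected severe
#' disease is detected with probability sensitivity x compliance and moves to
#' the corresponding treated state; false-positive referrals arise from
#' retinopathy-free and non-sight-threatening states at rate
#' (1 - specificity) x compliance and incur referral costs without any state
#' change.
#'
#' @param occupancy Named occupancy vector over [health_states], summing to 1.
#' @param strategy A strategy configuration (sensitivity, specificity,
#'   compliance, screening cost).
#' @return List with the post-screening `occupancy` and `tallies` (screened
#'   mass, true positives by branch, false positives, completed referrals).
#' @export
screening_update <- function(occupancy, strategy) {
  v <- occupancy
  det <- strategy$sensitivity * strategy$compliance
  tp_stdr <- v[["stdr_undetected"]] * det
  tp_dme <- v[["dme_undetected"]] * det
  fp <- (v[["no_dr"]] + v[["non_stdr"]]) *
    (1 - strategy$specificity) * strategy$compliance
  v[["stdr_undetected"]] <- v[["stdr_undetected"]] - tp_stdr
  v[["stdr_treated"]] <- v[["stdr_treated"]] + tp_stdr
  v[["dme_undetected"]] <- v[["dme_undetected"]] - tp_dme
  v[["dme_treated"]] <- v[["dme_treated"]] + tp_dme
  list(occupancy = v,
       tallies = c(screened = sum(occupancy[alive_nonblind_states]),
                   tp_stdr = tp_stdr, tp_dme = tp_dme, fp = fp,
                   referrals = tp_stdr + tp_dme + fp))
}

#' Run the cohort model for one screening strategy
#'
#' Simulates the closed cohort over `n_cycles` annual cycles.  Within each
#' cycle the order of events is: screening (detection and referral), accrual
#' of costs and utilities from the cycle-start occupancy, then transition to
#' the next cycle's occupancy.  Costs and QALYs are discounted by cycle
#' index; years without blindness (occupancy of all alive non-blind states)
#' are accrued undiscounted unless `settings$discount_effects` is set.
#' First-year versus continuing blindness (and first-year versus follow-up
#' treatment) are distinguished by one-cycle tunnel bookkeeping on inflows.
#'
#' @param model Validated model parameters from [load_parameters()].
#' @param strategy A strategy configuration.
#' @param ledger If `TRUE` (default) a per-cycle cost ledger data frame is
#'   kept; disable for speed in Monte Carlo loops (the totals are identical).
#' @param mats Optional precomputed list of per-cycle transition matrices
#'   (they do not depend on the strategy, so Monte Carlo drivers share them
#'   between arms).
#' @return An object of class `cohort_trace`: occupancy matrix
#'   (`n_cycles + 1` rows), total discounted `cost`, `qaly`,
#'   `years_without_blindness`, per-cycle `tallies`, and optionally the cost
#'   `ledger`.
#' @export
run_cohort <- function(model, strategy, ledger = TRUE, mats = NULL) {
  n <- model$n_cycles
  r <- model$discount_rate
  st <- model$settings
  S <- length(health_states)

  if (is.null(mats)) {
    mats <- lapply(seq_len(n) - 1L,
                   function(k) build_transition_matrix(model,
                                                       model$start_age + k))
  }
  c_ref <- sum(model$costs$referral)
  c_pdr <- sum(model$costs$treat_first_pdr)
  c_dme <- sum(model$costs$treat_first_dme)
  c_fu <- sum(model$costs$treat_followup)
  c_b1 <- sum(model$costs$blind_first)
  c_bfu <- sum(model$costs$blind_followup)

  occ <- matrix(NA_real_, n + 1, S, dimnames = list(0:n, health_states))
  occ[1, ] <- model$init
  tallies <- matrix(0, n, 5,
                    dimnames = list(NULL, c("screened", "tp_stdr", "tp_dme",
                                            "fp", "referrals")))
  ledger_rows <- if (ledger) vector("list", n) else NULL

  cost <- 0
  qaly <- 0
  ywb <- 0
  new_blind <- model$init[["blind"]]  # initial blind mass counts as first-year

  v <- model$init
  for (k in seq_len(n)) {
    cyc <- k - 1L
    scr <- screening_update(v, strategy)
    w <- scr$occupancy
    tl <- scr$tallies
    tallies[k, ] <- tl

    if (ledger) {
      cc <- cycle_costs(v, tl, new_blind, model$costs, strategy, cyc, r)
      cost <- cost + cc$total_discounted
    } else {
      # arithmetic fast path; identical totals to the ledger path
      und <- strategy$screening_cost * tl[["screened"]] +
        c_ref * tl[["referrals"]] + c_pdr * tl[["tp_stdr"]] +
        c_dme * tl[["tp_dme"]] +
        c_fu * (v[["stdr_treated"]] + v[["dme_treated"]]) +
        c_b1 * new_blind + c_bfu * max(0, v[["blind"]] - new_blind)
      cost <- cost + und / (1 + r)^cyc
    }

    df <- if (st$half_cycle) {
      # half-cycle correction: state-membership accrual uses the midpoint of
      # cycle-start and cycle-end occupancy
      v_next <- as.vector(w %*% mats[[k]])
      (v + v_next) / 2
    } else v
    dfac <- 1 / (1 + r)^cyc
    qaly <- qaly + sum(df * model$utilities) * dfac
    alive_nb <- sum(df[alive_nonblind_states])
    ywb <- ywb + if (st$discount_effects) alive_nb * dfac else alive_nb

    if (ledger) ledger_rows[[k]] <- cc$ledger

    v_next <- as.vector(w %*% mats[[k]])
    names(v_next) <- health_states
    new_blind <- sum(w[setdiff(health_states, "blind")] *
                       mats[[k]][setdiff(health_states, "blind"), "blind"])
    occ[k + 1, ] <- v_next
    v <- v_next
  }

  structure(list(
    strategy = strategy$name,
    occupancy = occ,
    cost = cost,
    qaly = qaly,
    years_without_blindness = ywb,
    tallies = as.data.frame(cbind(cycle = 0:(n - 1), tallies)),
    ledger = if (ledger) do.call(rbind, ledger_rows) else NULL
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace (strategy:", x$strategy, ")\n")
  cat(sprintf("  discounted cost per person:  $%.2f\n", x$cost))
  cat(sprintf("  discounted QALYs per person: %.4f\n", x$qaly))
  cat(sprintf("  years without blindness:     %.4f\n",
              x$years_without_blindness))
  invisible(x)
}
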