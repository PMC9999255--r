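# Shared fixtures, built in code.

# A cohort with no disease, no mortality and no screening events: everyone
# stays in no_dr, so discounted QALYs reduce to the closed-form annuity.
cfg_event_free <- function(u = 0.8, discount_rate = 0.035,
                           screening_cost = 0) {
  cfg <- default_config()
  cfg$values[c("prev_non_stdr", "prev_stdr", "prev_dme",
               "p_no_dr_to_non_stdr", "p_non_stdr_to_stdr",
               "p_non_stdr_to_dme", "p_stdr_to_blind",
               "p_dme_to_blind")] <- 0
  cfg$values[c("u_no_dr", "u_non_stdr", "u_stdr", "u_blind")] <- u
  cfg$values$discount_rate <- discount_rate
  cfg$values$spec_ai <- 1
  cfg$values$cost_screening_ai <- screening_cost
  cfg$values$cost_screening_manual <- screening_cost
  cfg$mortality$qx[] <- 0
  cfg
}

# Discounted annuity factor over n cycles starting undiscounted at cycle 0.
annuity <- function(rate, n) sum(1 / (1 + rate)^(0:(n - 1)))

# Strategy stub for unit tests of screening_update.
make_strategy <- function(sensitivity, specificity, compliance,
                          screening_cost = 10, name = "test") {
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity, compliance = compliance,
                 screening_cost = screening_cost), class = "drs_strategy")
}

occupancy_vec <- function(...) {
  v <- stats::setNames(numeric(length(health_states)), health_states)
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}
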