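# Parameter registry: every model input is one row of the parameter table
# (name, base, low, high, dist, units, provenance) plus a flat named value
# list in the configuration.  Provenance separates values printed in the
# source programme description ("paper-text") from plausible stand-ins for
# unpublished appendix values ("supplement-placeholder"): any result that
# depends on the latter is a structural demonstration, not a reproduction.

# class drives the default sensitivity range and the PSA family:
#   probability/utility -> +/-10%, beta;  cost -> +/-50%, gamma;
#   or/multiplier -> log-normal;  fixed -> no range, no PSA draw.
param_meta <- function() {
  m <- rbind(
    c("u_no_dr",                 "utility",     "beta",      "utility",  "paper-text"),
    c("u_non_stdr",              "utility",     "beta",      "utility",  "paper-text"),
    c("u_stdr",                  "utility",     "beta",      "utility",  "paper-text"),
    c("u_blind",                 "utility",     "beta",      "utility",  "paper-text"),
    c("sens_ai",                 "probability", "beta",      "fraction", "paper-text"),
    c("spec_ai",                 "probability", "beta",      "fraction", "paper-text"),
    c("sens_manual",             "probability", "fixed",     "fraction", "paper-text"),
    c("spec_manual",             "probability", "fixed",     "fraction", "paper-text"),
    c("compliance_referral",     "probability", "beta",      "fraction", "paper-text"),
    c("compliance_multiplier_ai","multiplier",  "lognormal", "ratio",    "paper-text"),
    c("cost_screening_manual",   "cost",        "gamma",     "USD",      "paper-text"),
    c("cost_screening_ai",       "cost",        "gamma",     "USD",      "paper-text"),
    c("cost_blind_first_year",   "cost",        "gamma",     "USD",      "paper-text"),
    c("share_blind_direct_medical",    "share", "fixed",     "fraction", "paper-text"),
    c("share_blind_direct_nonmedical", "share", "fixed",     "fraction", "paper-text"),
    c("share_blind_indirect",          "share", "fixed",     "fraction", "paper-text"),
    c("discount_rate",           "rate",        "fixed",     "fraction/year", "paper-text"),
    c("gdp_per_capita",          "other",       "fixed",     "USD",      "paper-text"),
    c("exchange_rate_cny_per_usd", "other",     "fixed",     "CNY/USD",  "paper-text"),
    c("prev_non_stdr",           "probability", "beta",      "fraction", "supplement-placeholder"),
    c("prev_stdr",               "probability", "beta",      "fraction", "supplement-placeholder"),
    c("prev_dme",                "probability", "beta",      "fraction", "supplement-placeholder"),
    c("p_no_dr_to_non_stdr",     "probability", "beta",      "fraction/year", "supplement-placeholder"),
    c("p_non_stdr_to_stdr",      "probability", "beta",      "fraction/year", "supplement-placeholder"),
    c("p_non_stdr_to_dme",       "probability", "beta",      "fraction/year", "supplement-placeholder"),
    c("p_stdr_to_blind",         "probability", "beta",      "fraction/year", "supplement-placeholder"),
    c("p_dme_to_blind",          "probability", "beta",      "fraction/year", "supplement-placeholder"),
    c("treatment_multiplier",    "probability", "beta",      "ratio",    "supplement-placeholder"),
    c("or_mort_no_dr",           "or",          "lognormal", "odds ratio", "supplement-placeholder"),
    c("or_mort_non_stdr",        "or",          "lognormal", "odds ratio", "supplement-placeholder"),
    c("or_mort_stdr",            "or",          "lognormal", "odds ratio", "supplement-placeholder"),
    c("or_mort_blind",           "or",          "lognormal", "odds ratio", "supplement-placeholder"),
    c("cost_referral_direct_medical",      "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_referral_direct_nonmedical",   "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_referral_indirect",            "cost", "fixed", "USD", "supplement-placeholder"),
    c("cost_treat_first_dme_direct_medical",    "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_treat_first_dme_direct_nonmedical", "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_treat_first_dme_indirect",          "cost", "fixed", "USD", "supplement-placeholder"),
    c("cost_treat_first_pdr_direct_medical",    "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_treat_first_pdr_direct_nonmedical", "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_treat_first_pdr_indirect",          "cost", "fixed", "USD", "supplement-placeholder"),
    c("cost_treat_followup_direct_medical",     "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_treat_followup_direct_nonmedical",  "cost", "gamma", "USD", "supplement-placeholder"),
    c("cost_treat_followup_indirect",           "cost", "fixed", "USD", "supplement-placeholder"),
    c("cost_blind_followup_indirect",           "cost", "gamma", "USD", "supplement-placeholder")
  )
  data.frame(name = m[, 1], class = m[, 2], dist = m[, 3], units = m[, 4],
             provenance = m[, 5], stringsAsFactors = FALSE)
}

# default sensitivity half-widths, relative to base, by parameter class
range_rules <- c(probability = 0.10, utility = 0.10, cost = 0.50,
                 multiplier = 0.25, or = 0.10)

#' Background mortality table
#'
#' Annual all-cause death probabilities for the general population by single
#' year of age.  The shipped default is a synthetic Gompertz-type schedule
#' (probability growing exponentially with age) standing in for a published
#' national life table, which is not part of this package's sources.
#'
#' @param start_age First age covered (default 65).
#' @param n_ages Number of single-year ages.
#' @param q0 Annual death probability at `start_age`.
#' @param slope Log-linear increase per year of age.
#' @return A data frame with columns `age` and `qx`.
#' @export
default_mortality_table <- function(start_age = 65, n_ages = 36,
                                    q0 = 0.036, slope = 0.085) {
  age <- seq(start_age, length.out = n_ages)
  data.frame(age = age, qx = pmin(q0 * exp(slope * (age - start_age)), 0.95))
}

#' Default model configuration
#'
#' Builds the shipped configuration for the two-arm screening comparison.
#' Values printed in the programme description (utilities, test accuracy,
#' referral compliance, per-attendee screening costs, the first-year blindness
#' burden and its component split, the discount rate, the willingness-to-pay
#' thresholds and the CNY/USD exchange rate) carry provenance `"paper-text"`;
#' all epidemiological transition inputs and care-pathway cost components are
#' `"supplement-placeholder"` stand-ins of plausible magnitude.
#'
#' @return A configuration list with elements `values` (flat named list),
#'   `ranges` (explicit low/high overrides), `mortality` (age/qx data frame)
#'   and `settings`.
#' @export
default_config <- function() {
  values <- list(
    u_no_dr = 0.87, u_non_stdr = 0.79, u_stdr = 0.70, u_blind = 0.55,
    sens_ai = 0.8047, spec_ai = 0.9796,
    sens_manual = 1.0, spec_manual = 1.0,
    compliance_referral = 0.504,
    compliance_multiplier_ai = 1.0,
    cost_screening_manual = 10.10, cost_screening_ai = 9.60,
    cost_blind_first_year = 8920,
    share_blind_direct_medical = 0.532,
    share_blind_direct_nonmedical = 0.064,
    share_blind_indirect = 0.404,
    discount_rate = 0.035,
    gdp_per_capita = 22600,
    exchange_rate_cny_per_usd = 6.90,
    prev_non_stdr = 0.16, prev_stdr = 0.030, prev_dme = 0.020,
    p_no_dr_to_non_stdr = 0.060,
    p_non_stdr_to_stdr = 0.050,
    p_non_stdr_to_dme = 0.030,
    p_stdr_to_blind = 0.14,
    p_dme_to_blind = 0.090,
    treatment_multiplier = 0.43,
    or_mort_no_dr = 1.28, or_mort_non_stdr = 1.52,
    or_mort_stdr = 2.05, or_mort_blind = 2.70,
    cost_referral_direct_medical = 42, cost_referral_direct_nonmedical = 8,
    cost_referral_indirect = 0,
    cost_treat_first_dme_direct_medical = 3900,
    cost_treat_first_dme_direct_nonmedical = 25,
    cost_treat_first_dme_indirect = 0,
    cost_treat_first_pdr_direct_medical = 2000,
    cost_treat_first_pdr_direct_nonmedical = 25,
    cost_treat_first_pdr_indirect = 0,
    cost_treat_followup_direct_medical = 1900,
    cost_treat_followup_direct_nonmedical = 15,
    cost_treat_followup_indirect = 0,
    cost_blind_followup_indirect = 5600
  )
  cfg <- list(
    values = values,
    # manual grading is assumed perfectly accurate at base; its sensitivity
    # range reflects trained (non-expert) graders and is swept in DSA only
    ranges = list(sens_manual = c(0.90, 1.0), spec_manual = c(0.95, 1.0)),
    mortality = default_mortality_table(),
    settings = list(start_age = 65, n_cycles = 30,
                    half_cycle = FALSE, discount_effects = FALSE,
                    currency = "USD", scale_per = 1e5,
                    boundary_favorable = TRUE)
  )
  class(cfg) <- "drs_config"
  cfg
}

#' Parameter table with sensitivity ranges and PSA families
#'
#' One row per model parameter: base value, low/high deterministic
#' sensitivity range, probabilistic distribution family, units and
#' provenance.  Ranges follow the default conventions (probabilities and
#' utilities \eqn{\pm}10\%, costs \eqn{\pm}50\%, the AI compliance
#' multiplier \eqn{\pm}25\%) unless an explicit override is present in
#' `cfg$ranges`; parameters with `dist = "fixed"` and no override get a
#' degenerate `low = high = base` range.
#'
#' @param cfg A configuration, e.g. [default_config()].
#' @return A data frame with columns `name`, `base`, `low`, `high`, `dist`,
#'   `units`, `provenance`.
#' @export
parameter_table <- function(cfg) {
  meta <- param_meta()
  base <- vapply(meta$name, function(nm) {
    v <- cfg$values[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  low <- high <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    if (!is.null(cfg$ranges[[nm]])) {
      low[i] <- cfg$ranges[[nm]][1]
      high[i] <- cfg$ranges[[nm]][2]
    } else if (meta$dist[i] == "fixed" || is.na(base[i])) {
      low[i] <- high[i] <- base[i]
    } else {
      hw <- range_rules[[meta$class[i]]]
      low[i] <- base[i] * (1 - hw)
      high[i] <- base[i] * (1 + hw)
      if (meta$class[i] %in% c("probability", "utility")) {
        low[i] <- max(0, low[i])
        high[i] <- min(1, high[i])
      }
    }
  }
  data.frame(name = meta$name, base = base, low = low, high = high,
             dist = meta$dist, units = meta$units,
             provenance = meta$provenance, stringsAsFactors = FALSE)
}

#' Set one parameter value in a configuration
#'
#' @param cfg A configuration list.
#' @param name Parameter name, must exist in `cfg$values`.
#' @param value New numeric value.
#' @return The modified configuration.
#' @export
set_parameter <- function(cfg, name, value) {
  if (!name %in% names(cfg$values)) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  cfg$values[[name]] <- value
  cfg
}

cost_components <- function(direct_medical, direct_nonmedical, indirect) {
  c(direct_medical = direct_medical, direct_nonmedical = direct_nonmedical,
    indirect = indirect)
}

#' Split the first-year blindness burden into cost components
#'
#' @param total Total first-year economic burden of blindness, USD.
#' @param shares Named or positional vector of the direct-medical,
#'   direct-nonmedical and indirect shares; must sum to 1.
#' @return Named numeric vector of the three components, summing to `total`.
#' @export
blindness_cost_components <- function(total, shares = c(0.532, 0.064, 0.404)) {
  if (abs(sum(shares) - 1) > 1e-6) {
    stop("blindness cost shares must sum to 1", call. = FALSE)
  }
  cost_components(total * shares[1], total * shares[2], total * shares[3])
}

#' Validate a configuration and build the model inputs
#'
#' Checks every type invariant (probabilities and utilities in `[0, 1]`,
#' ordered state utilities, nonnegative costs, consistent ranges, blindness
#' shares summing to one, outgoing transition mass at most one, mortality
#' table coverage) and reports *all* violations at once.  Costs entered in
#' CNY (`settings$currency = "CNY"`) are converted to USD at load time using
#' the configured exchange rate.
#'
#' @param cfg A configuration list, see [default_config()].
#' @param check `"strict"` (default) additionally enforces the cross-field
#'   ordering of the state utilities; `"draw"` checks per-field bounds only,
#'   the mode used for sensitivity excursions and probabilistic draws, where
#'   independently perturbed utilities may legitimately cross.
#' @return A list with elements `model` (validated model parameters),
#'   `strategies` (list with `ai` and `manual` strategy configurations) and
#'   `config` (the possibly currency-converted configuration).
#' @export
load_parameters <- function(cfg, check = c("strict", "draw")) {
  check <- match.arg(check)
  meta <- param_meta()
  v <- cfg$values
  errs <- character(0)

  missing <- setdiff(meta$name, names(v))
  if (length(missing)) {
    errs <- c(errs, paste0("missing parameter: ", missing))
  }
  v <- v[intersect(meta$name, names(v))]
  bad_num <- names(v)[!vapply(v, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad_num)) {
    errs <- c(errs, paste0("non-numeric parameter: ", bad_num))
  }
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }

  # currency conversion happens before any bound checks on costs
  if (identical(cfg$settings$currency, "CNY")) {
    xr <- v$exchange_rate_cny_per_usd
    cost_names <- meta$name[meta$class == "cost"]
    for (nm in cost_names) v[[nm]] <- v[[nm]] / xr
    cfg$values[cost_names] <- v[cost_names]
    for (nm in intersect(names(cfg$ranges), cost_names)) {
      cfg$ranges[[nm]] <- cfg$ranges[[nm]] / xr
    }
    cfg$settings$currency <- "USD"
  }

  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)

  prob_like <- meta$name[meta$class %in% c("probability", "utility", "share")]
  for (nm in prob_like) {
    chk(v[[nm]] >= 0 && v[[nm]] <= 1,
        paste0(nm, " = ", v[[nm]], " must lie in [0, 1]"))
  }
  for (nm in meta$name[meta$class == "cost"]) {
    chk(v[[nm]] >= 0, paste0(nm, " = ", v[[nm]], " must be nonnegative"))
  }
  for (nm in meta$name[meta$class == "or"]) {
    chk(v[[nm]] > 0, paste0(nm, " = ", v[[nm]], " must be positive"))
  }
  chk(v$compliance_multiplier_ai > 0,
      "compliance_multiplier_ai must be positive")
  chk(v$discount_rate >= 0, "discount_rate must be nonnegative")
  chk(v$gdp_per_capita > 0, "gdp_per_capita must be positive")
  chk(v$exchange_rate_cny_per_usd > 0,
      "exchange_rate_cny_per_usd must be positive")
  if (check == "strict") {
    chk(v$u_no_dr >= v$u_non_stdr && v$u_non_stdr >= v$u_stdr &&
          v$u_stdr >= v$u_blind,
        "utilities must be ordered u_no_dr >= u_non_stdr >= u_stdr >= u_blind")
  }
  chk(abs(v$share_blind_direct_medical + v$share_blind_direct_nonmedical +
            v$share_blind_indirect - 1) <= 1e-6,
      "blindness cost shares must sum to 1")
  prev_sum <- v$prev_non_stdr + v$prev_stdr + v$prev_dme
  chk(prev_sum <= 1, "initial retinopathy prevalences must sum to at most 1")
  chk(v$p_non_stdr_to_stdr + v$p_non_stdr_to_dme <= 1,
      "outgoing transition probabilities from non-STDR exceed 1")

  if (check == "strict") {
    # range consistency concerns the base configuration; drawn values carry
    # their own implied ranges by construction
    pt <- parameter_table(cfg)
    bad_rng <- pt$name[!(pt$low <= pt$base & pt$base <= pt$high)]
    if (length(bad_rng)) {
      errs <- c(errs,
                paste0("range inversion (low <= base <= high violated): ",
                       bad_rng))
    }
  }

  st <- cfg$settings
  ages_needed <- seq(st$start_age, length.out = st$n_cycles)
  mort <- cfg$mortality
  chk(is.data.frame(mort) && all(c("age", "qx") %in% names(mort)),
      "mortality table must have columns age and qx")
  if (is.data.frame(mort) && all(c("age", "qx") %in% names(mort))) {
    chk(all(ages_needed %in% mort$age),
        "mortality table must cover every modelled age")
    chk(all(mort$qx >= 0 & mort$qx < 1),
        "mortality qx values must lie in [0, 1)")
  }

  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }

  init <- c(no_dr = 1 - prev_sum, non_stdr = v$prev_non_stdr,
            stdr_undetected = v$prev_stdr, stdr_treated = 0,
            dme_undetected = v$prev_dme, dme_treated = 0,
            blind = 0, dead = 0)
  stopifnot(abs(sum(init) - 1) < 1e-12)

  qx <- mort$qx[match(ages_needed, mort$age)]
  names(qx) <- ages_needed

  costs <- list(
    referral = cost_components(v$cost_referral_direct_medical,
                               v$cost_referral_direct_nonmedical,
                               v$cost_referral_indirect),
    treat_first_dme = cost_components(v$cost_treat_first_dme_direct_medical,
                                      v$cost_treat_first_dme_direct_nonmedical,
                                      v$cost_treat_first_dme_indirect),
    treat_first_pdr = cost_components(v$cost_treat_first_pdr_direct_medical,
                                      v$cost_treat_first_pdr_direct_nonmedical,
                                      v$cost_treat_first_pdr_indirect),
    treat_followup = cost_components(v$cost_treat_followup_direct_medical,
                                     v$cost_treat_followup_direct_nonmedical,
                                     v$cost_treat_followup_indirect),
    blind_first = blindness_cost_components(
      v$cost_blind_first_year,
      c(v$share_blind_direct_medical, v$share_blind_direct_nonmedical,
        v$share_blind_indirect)),
    blind_followup = cost_components(0, 0, v$cost_blind_followup_indirect)
  )

  model <- list(
    start_age = st$start_age, n_cycles = st$n_cycles,
    discount_rate = v$discount_rate,
    utilities = c(no_dr = v$u_no_dr, non_stdr = v$u_non_stdr,
                  stdr_undetected = v$u_stdr, stdr_treated = v$u_stdr,
                  dme_undetected = v$u_stdr, dme_treated = v$u_stdr,
                  blind = v$u_blind, dead = 0),
    init = init,
    probs = list(no_dr_to_non_stdr = v$p_no_dr_to_non_stdr,
                 non_stdr_to_stdr = v$p_non_stdr_to_stdr,
                 non_stdr_to_dme = v$p_non_stdr_to_dme,
                 stdr_to_blind = v$p_stdr_to_blind,
                 dme_to_blind = v$p_dme_to_blind),
    treatment_multiplier = v$treatment_multiplier,
    qx = qx,
    ors = c(no_dr = v$or_mort_no_dr, non_stdr = v$or_mort_non_stdr,
            stdr = v$or_mort_stdr, blind = v$or_mort_blind),
    costs = costs,
    gdp_per_capita = v$gdp_per_capita,
    exchange_rate = v$exchange_rate_cny_per_usd,
    settings = st
  )
  class(model) <- "drs_model"

  comp <- min(1, max(0, v$compliance_referral))
  strategies <- list(
    ai = structure(list(
      name = "ai",
      sensitivity = v$sens_ai, specificity = v$spec_ai,
      compliance = min(1, max(0, comp * v$compliance_multiplier_ai)),
      screening_cost = v$cost_screening_ai), class = "drs_strategy"),
    manual = structure(list(
      name = "manual",
      sensitivity = v$sens_manual, specificity = v$spec_manual,
      compliance = comp,
      screening_cost = v$cost_screening_manual), class = "drs_strategy")
  )

  list(model = model, strategies = strategies, config = cfg)
}

#' Read / write a configuration as JSON
#'
#' @param path File path.
#' @return `read_config()` returns a configuration list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$values <- as.list(cfg$values)
  cfg$settings <- as.list(cfg$settings)
  cfg$ranges <- lapply(cfg$ranges, as.numeric)
  cfg$mortality <- as.data.frame(cfg$mortality)
  class(cfg) <- "drs_config"
  cfg
}

#' @rdname read_config
#' @param cfg A configuration list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
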