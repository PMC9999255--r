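# Report generation: CSV exports mirroring the base-case summary table
# layout, DSA/PSA/CEAC tables, and a JSON run manifest.  All report
# functions are pure functions of (configuration, seed): re-running with
# identical inputs reproduces identical CSV contents.  Monetary values and
# ratios are printed to 2 decimals and probabilities to 4 in the rounded
# tables; a parallel full-precision export is always written.

write_manifest <- function(out_dir, command, seed, files) {
  manifest <- list(
    command = command,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("retscreen")),
    outputs = files)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

round_cols <- function(df, money = character(0), prob = character(0)) {
  for (nm in intersect(money, names(df))) df[[nm]] <- round(df[[nm]], 2)
  for (nm in intersect(prob, names(df))) df[[nm]] <- round(df[[nm]], 4)
  df
}

write_pair <- function(df, out_dir, stem, money = character(0),
                       prob = character(0)) {
  full <- file.path(out_dir, paste0(stem, "_full.csv"))
  pretty <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(df, full, row.names = FALSE)
  utils::write.csv(round_cols(df, money, prob), pretty, row.names = FALSE)
  c(pretty, full)
}

#' Base-case report
#'
#' Runs both arms and writes: a summary CSV in the base-case table layout
#' (per-person costs, years without blindness and QALYs per strategy, and
#' the per-100,000 incrementals, ICER and ICUR on the AI row), tidy cohort
#' trace CSVs (cycle, state, occupancy), per-cycle cost ledger CSVs, and a
#' run manifest.
#'
#' @param cfg A configuration.
#' @param out_dir Output directory (created if needed).
#' @return The comparison (`econ_result`), invisibly; files as side effect.
#' @export
report_base_case <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_base_case(cfg)
  cmp <- res$comparison
  summary_df <- data.frame(
    strategy = c("ai_assisted", "manual_grading"),
    cost_per_person = c(res$ai$cost, res$manual$cost),
    incr_cost_per_100k = c(cmp$incr_cost_per_scale, NA),
    years_without_blindness = c(res$ai$years_without_blindness,
                                res$manual$years_without_blindness),
    incr_years_per_100k = c(cmp$incr_ywb_per_scale, NA),
    qaly_per_person = c(res$ai$qaly, res$manual$qaly),
    incr_qaly_per_100k = c(cmp$incr_qaly_per_scale, NA),
    icer = c(cmp$icer, NA),
    icur = c(cmp$icur, NA),
    classification = c(cmp$classification, NA))
  files <- write_pair(summary_df, out_dir, "base_case_summary",
                      money = c("cost_per_person", "incr_cost_per_100k",
                                "icer", "icur"),
                      prob = c("qaly_per_person"))
  for (arm in c("ai", "manual")) {
    tr <- res[[arm]]
    occ <- as.data.frame(as.table(tr$occupancy))
    names(occ) <- c("cycle", "state", "occupancy")
    occ$cycle <- as.integer(as.character(occ$cycle))
    occ <- occ[order(occ$cycle), ]
    files <- c(files, write_pair(occ, out_dir, paste0("trace_", arm),
                                 prob = "occupancy"))
    files <- c(files, write_pair(tr$ledger, out_dir, paste0("ledger_", arm),
                                 money = c("undiscounted", "discounted")))
  }
  write_manifest(out_dir, "run-base", NA, basename(files))
  invisible(cmp)
}

#' Deterministic sensitivity analysis report
#'
#' Writes the tornado table and the AI-arm compliance-multiplier scan.
#'
#' @param cfg A configuration.
#' @param out_dir Output directory.
#' @return The tornado data frame, invisibly.
#' @export
report_dsa <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tornado <- run_dsa(cfg)
  files <- write_pair(tornado, out_dir, "dsa_tornado",
                      money = c("icur_at_low", "icur_at_high",
                                "icer_at_low", "icer_at_high",
                                "spread_icur", "spread_icer"))
  scan <- compliance_threshold_scan(cfg)
  files <- c(files, write_pair(scan$scan, out_dir, "dsa_compliance_scan",
                               money = c("delta_cost", "icur"),
                               prob = "delta_qaly"))
  files <- c(files,
             write_pair(scan$thresholds, out_dir, "dsa_compliance_thresholds"))
  write_manifest(out_dir, "run-dsa", NA, basename(files))
  invisible(tornado)
}

#' Probabilistic sensitivity analysis report
#'
#' Writes the per-draw incremental scatter and the acceptability curve
#' table (with the two WHO thresholds forced onto the grid).
#'
#' @param cfg A configuration.
#' @param seed Integer seed.
#' @param n_draws Number of Monte Carlo draws.
#' @param out_dir Output directory.
#' @return The `psa_result`, invisibly.
#' @export
report_psa <- function(cfg, seed, n_draws, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(cfg, n_draws = n_draws, seed = seed)
  files <- write_pair(psa$draws, out_dir, "psa_scatter",
                      money = c("cost_ai", "cost_manual", "delta_cost"),
                      prob = c("qaly_ai", "qaly_manual", "delta_qaly"))
  cc <- ceac(psa)
  files <- c(files, write_pair(cc, out_dir, "ceac",
                               money = "threshold",
                               prob = c("p_ai_optimal", "p_manual_optimal")))
  write_manifest(out_dir, "run-psa", seed, basename(files))
  invisible(psa)
}

#' Parameter table export
#'
#' Writes the full parameter registry (name, base, low, high, dist, units,
#' provenance) as CSV.
#'
#' @param cfg A configuration.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameter_table <- function(cfg, path) {
  utils::write.csv(parameter_table(cfg), path, row.names = FALSE)
  invisible(path)
}

#' Validate a configuration file
#'
#' @param path Path to a JSON configuration.
#' @return `TRUE` on success; stops with the full list of violations
#'   otherwise.
#' @export
validate_config_file <- function(path) {
  load_parameters(read_config(path))
  TRUE
}
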