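#' Run both screening arms and compare them
#'
#' Convenience wrapper: validates the configuration, runs the cohort engine
#' for the AI and manual grading arms on the same model parameters, and
#' returns the incremental comparison (AI minus manual; manual grading is
#' the baseline).
#'
#' @param cfg A configuration, e.g. [default_config()].
#' @param ledger Keep per-cycle cost ledgers (default `TRUE`).
#' @param check Validation mode passed to [load_parameters()].
#' @return List with elements `ai`, `manual` (class `cohort_trace`) and
#'   `comparison` (class `econ_result`).
#' @examples
#' res <- run_base_case(default_config())
#' res$comparison
#' @export
run_base_case <- function(cfg, ledger = TRUE, check = "strict") {
  lp <- load_parameters(cfg, check = check)
  ai <- run_cohort(lp$model, lp$strategies$ai, ledger = ledger)
  manual <- run_cohort(lp$model, lp$strategies$manual, ledger = ledger)
  list(ai = ai, manual = manual,
       comparison = compare_strategies(
         ai, manual, gdp = lp$model$gdp_per_capita,
         scale = cfg$settings$scale_per %||% 1e5,
         boundary_favorable = isTRUE(cfg$settings$boundary_favorable)))
}
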