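test_that("shipped default configuration carries the published headline values", {
  cfg <- default_config()
  lp <- load_parameters(cfg)
  expect_equal(lp$model$discount_rate, 0.035)
  expect_equal(unname(lp$model$utilities[c("no_dr", "non_stdr",
                                           "stdr_undetected", "blind")]),
               c(0.87, 0.79, 0.70, 0.55))
  expect_equal(lp$strategies$ai$sensitivity, 0.8047)
  expect_equal(lp$strategies$ai$specificity, 0.9796)
  expect_equal(lp$strategies$manual$sensitivity, 1.0)
  expect_equal(lp$strategies$ai$compliance, 0.504)
  expect_equal(lp$strategies$ai$screening_cost, 9.60)
  expect_equal(lp$strategies$manual$screening_cost, 10.10)
  expect_equal(lp$model$gdp_per_capita, 22600)
  expect_equal(lp$model$exchange_rate, 6.90)
  expect_equal(sum(lp$model$costs$blind_first), 8920)

  pt <- parameter_table(cfg)
  headline <- c("u_no_dr", "u_non_stdr", "u_stdr", "u_blind", "sens_ai",
                "spec_ai", "compliance_referral", "cost_screening_manual",
                "cost_screening_ai", "cost_blind_first_year",
                "discount_rate", "gdp_per_capita")
  expect_true(all(pt$provenance[pt$name %in% headline] == "paper-text"))
  expect_true(all(pt$provenance[grepl("^p_|^prev_|^or_mort", pt$name)] ==
                    "supplement-placeholder"))
})

test_that("sensitivity ranges follow the class conventions", {
  pt <- parameter_table(default_config())
  g <- function(nm, col) pt[pt$name == nm, col]
  expect_equal(g("u_no_dr", "low"), 0.87 * 0.9)
  expect_equal(g("u_no_dr", "high"), 0.87 * 1.1)
  expect_equal(g("cost_screening_ai", "low"), 9.60 * 0.5)
  expect_equal(g("cost_screening_ai", "high"), 9.60 * 1.5)
  expect_equal(g("compliance_multiplier_ai", "low"), 0.75)
  expect_equal(g("compliance_multiplier_ai", "high"), 1.25)
  # fixed parameters get degenerate ranges
  expect_equal(g("discount_rate", "low"), g("discount_rate", "high"))
  # manual accuracy: fixed at base for PSA but given a DSA range override
  expect_equal(g("sens_manual", "dist"), "fixed")
  expect_lt(g("sens_manual", "low"), 1)
})

test_that("validation rejects invariant violations and lists all failures", {
  cfg <- default_config()
  cfg$values$u_blind <- 1.2
  cfg$values$cost_screening_ai <- -5
  err <- tryCatch(load_parameters(cfg), error = conditionMessage)
  expect_match(err, "u_blind")
  expect_match(err, "cost_screening_ai")

  cfg <- default_config()
  cfg$values$u_stdr <- 0.80  # breaks ordering against u_non_stdr = 0.79
  expect_error(load_parameters(cfg), "ordered")

  cfg <- default_config()
  cfg$ranges$u_no_dr <- c(0.95, 0.99)  # base 0.87 outside [low, high]
  expect_error(load_parameters(cfg), "range inversion")

  cfg <- default_config()
  cfg$values$p_non_stdr_to_stdr <- 0.7
  cfg$values$p_non_stdr_to_dme <- 0.5
  expect_error(load_parameters(cfg), "exceed")

  cfg <- default_config()
  cfg$values$prev_non_stdr <- NULL
  expect_error(load_parameters(cfg), "missing parameter: prev_non_stdr")
})

test_that("initial distribution sums to one and respects prevalences", {
  lp <- load_parameters(default_config())
  expect_equal(sum(lp$model$init), 1, tolerance = 1e-12)
  expect_equal(unname(lp$model$init[["non_stdr"]]),
               default_config()$values$prev_non_stdr)
  expect_equal(unname(lp$model$init[["stdr_treated"]]), 0)
})

test_that("costs entered in CNY are converted to USD at load time", {
  cfg <- default_config()
  pt <- parameter_table(cfg)
  cost_names <- pt$name[grepl("^cost_", pt$name)]
  for (nm in cost_names) cfg$values[[nm]] <- cfg$values[[nm]] * 6.90
  cfg$settings$currency <- "CNY"
  lp <- load_parameters(cfg)
  expect_equal(lp$strategies$ai$screening_cost, 9.60, tolerance = 1e-12)
  expect_equal(sum(lp$model$costs$blind_first), 8920, tolerance = 1e-9)
})

test_that("configurations survive a JSON round trip", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  r1 <- run_base_case(cfg, ledger = FALSE)$comparison
  r2 <- run_base_case(cfg2, ledger = FALSE)$comparison
  expect_equal(r1$icur, r2$icur, tolerance = 1e-9)
  expect_equal(r1$delta_cost, r2$delta_cost, tolerance = 1e-9)
})

test_that("blindness cost components require shares summing to one", {
  expect_error(blindness_cost_components(100, c(0.5, 0.1, 0.1)),
               "sum to 1")
})
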