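test_that("degenerate parameters give an identity transition matrix", {
  cfg <- cfg_event_free()
  lp <- load_parameters(cfg)
  M <- build_transition_matrix(lp$model, 65)
  expect_equal(unname(M), diag(8))
})

test_that("a no-effect treatment multiplier leaves treated rows identical", {
  cfg <- default_config()
  cfg$values$treatment_multiplier <- 1
  lp <- load_parameters(cfg)
  M <- build_transition_matrix(lp$model, 70)
  expect_equal(M["stdr_treated", "blind"], M["stdr_undetected", "blind"])
  expect_equal(M["dme_treated", "blind"], M["dme_undetected", "blind"])
})

test_that("transition rows are stochastic across random scenarios and ages", {
  for (seed in 1:50) {
    lp <- load_parameters(generate_scenario(seed))
    for (age in c(65, 75, 85, 94)) {
      M <- build_transition_matrix(lp$model, age)
      expect_true(all(abs(rowSums(M) - 1) < 1e-12))
      expect_true(all(M >= 0 & M <= 1))
      # no transition toward a less severe state (severity increases with
      # the state index, so the lower triangle must be empty)
      expect_true(all(M[lower.tri(M)] == 0))
      expect_equal(unname(M["dead", ]), c(0, 0, 0, 0, 0, 0, 0, 1))
    }
  }
})

test_that("overfull outgoing mass is reported with the offending state", {
  cfg <- default_config()
  cfg$values$p_stdr_to_blind <- 0.95
  cfg$mortality$qx[] <- 0.3
  lp <- load_parameters(cfg)
  expect_error(build_transition_matrix(lp$model, 65), "stdr_undetected")
})

test_that("ages outside the mortality table are rejected", {
  lp <- load_parameters(default_config())
  expect_error(build_transition_matrix(lp$model, 200), "mortality-table")
})

test_that("screening moves detected mass and tallies false positives", {
  v <- occupancy_vec(no_dr = 0.7, non_stdr = 0.2, stdr_undetected = 0.10)
  ai <- make_strategy(0.8047, 0.9796, 0.504)
  out <- screening_update(v, ai)
  moved <- 0.10 * 0.8047 * 0.504  # 0.04055688
  expect_equal(unname(out$occupancy[["stdr_treated"]]), moved,
               tolerance = 1e-12)
  expect_equal(unname(out$tallies[["fp"]]), 0.9 * (1 - 0.9796) * 0.504)
  expect_equal(sum(out$occupancy), 1)

  perfect <- make_strategy(1, 1, 1)
  out2 <- screening_update(occupancy_vec(stdr_undetected = 0.6,
                                         dme_undetected = 0.4), perfect)
  expect_equal(unname(out2$occupancy[["stdr_undetected"]]), 0)
  expect_equal(unname(out2$occupancy[["dme_undetected"]]), 0)
  expect_equal(unname(out2$tallies[["fp"]]), 0)

  blind_sens <- make_strategy(0, 0.9, 1)
  out3 <- screening_update(v, blind_sens)
  expect_equal(out3$occupancy, v)
  expect_gt(out3$tallies[["fp"]], 0)
})

test_that("event-free cohort reproduces the closed-form annuity to 1e-10", {
  u <- 0.8
  cfg <- cfg_event_free(u = u)
  lp <- load_parameters(cfg)
  tr <- run_cohort(lp$model, lp$strategies$ai)
  expect_equal(tr$qaly, u * annuity(0.035, 30), tolerance = 1e-10)
  expect_equal(tr$years_without_blindness, 30, tolerance = 1e-10)
  expect_equal(tr$cost, 0)
})

test_that("undiscounted deathless cohort accrues 30 years without blindness", {
  cfg <- cfg_event_free(discount_rate = 0)
  cfg$values$p_no_dr_to_non_stdr <- 0.1  # disease but no blindness, no death
  lp <- load_parameters(cfg)
  tr <- run_cohort(lp$model, lp$strategies$manual)
  expect_equal(tr$years_without_blindness, 30, tolerance = 1e-12)
})

test_that("occupancy is conserved and death is monotone in the base run", {
  res <- run_base_case(default_config())
  for (tr in list(res$ai, res$manual)) {
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-14))
    expect_gt(tr$occupancy[31, "dead"], tr$occupancy[2, "dead"])
    expect_true(tr$cost >= 0 && tr$qaly >= 0 &&
                  tr$years_without_blindness >= 0)
  }
})

test_that("raising progression cannot increase QALYs; raising a cost cannot cut cost", {
  base <- run_base_case(default_config(), ledger = FALSE)
  worse <- default_config()
  worse$values$p_stdr_to_blind <- worse$values$p_stdr_to_blind * 1.5
  res_w <- run_base_case(worse, ledger = FALSE)
  expect_lte(res_w$ai$qaly, base$ai$qaly)
  expect_lte(res_w$manual$qaly, base$manual$qaly)

  dearer <- default_config()
  dearer$values$cost_treat_followup_direct_medical <- 3000
  res_d <- run_base_case(dearer, ledger = FALSE)
  expect_gte(res_d$ai$cost, base$ai$cost)
  expect_gte(res_d$manual$cost, base$manual$cost)
})

test_that("half-cycle correction changes accruals but conserves occupancy", {
  cfg <- default_config()
  cfg$settings$half_cycle <- TRUE
  lp <- load_parameters(cfg)
  tr_h <- run_cohort(lp$model, lp$strategies$ai)
  tr <- run_base_case(default_config())$ai
  expect_true(all(abs(rowSums(tr_h$occupancy) - 1) < 1e-10))
  expect_identical(tr_h$occupancy, tr$occupancy)
  expect_lt(tr_h$qaly, tr$qaly)  # mortality makes midpoint accrual smaller
})
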