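test_that("transition matrices are row-stochastic with an absorbing dead state", {
  scn <- paper_scenarios()$low_risk
  P <- build_transition_matrix(scn$bca, scn$variant)
  expect_equal(P["disease_free", "disease_free"], 1 - 0.0086 - 0.0023 - 0.0073)
  expect_equal(unname(rowSums(P)), rep(1, 4))
  expect_equal(unname(P["dead", ]), c(0, 0, 0, 1))
  # no return to disease-free from a recurrence state
  expect_equal(P["local_recurrence", "disease_free"], 0)
  # all risks zero: identity on alive states
  deg <- degenerate_scenario()
  P0 <- build_transition_matrix(deg$bca, deg$variant)
  expect_equal(unname(P0), diag(4))
  # infeasible probabilities rejected
  bad <- scn$bca
  bad$p_local_annual$base_value <- 0.7
  bad$p_mortality_annual$base_value <- 0.5
  expect_error(build_transition_matrix(bad, scn$variant), "sum to")
})

test_that("discounting follows (1 + r)^-k with cycle 0 undiscounted", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(sum(discount_factor(0:4, 0.03)), 4.717098, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("event-free cohorts reduce to the geometric closed form", {
  for (fl in list(variant_flags(),
                  variant_flags(event_timing = "next_cycle"))) {
    deg <- degenerate_scenario(procedure_cost = 2501, routine_cost = 36351,
                               variant = fl)
    res <- run_cohort(deg, "bca")
    dsum <- sum(discount_factor(0:4, 0.03))
    expect_equal(res$total_qaly, dsum, tolerance = 1e-12)
    expect_equal(res$total_cost, 2501 + 36351 * dsum, tolerance = 1e-12)
  }
  # zero discount rate: horizon x utility exactly
  deg0 <- degenerate_scenario(rate = 0)
  expect_equal(run_cohort(deg0, "bca")$total_qaly, 5)
})

test_that("certain immediate mortality yields zero QALYs under entry-cycle timing", {
  deg <- degenerate_scenario(variant = variant_flags(event_timing = "entry_cycle"))
  deg$bca$p_mortality_annual$base_value <- 1
  res <- run_cohort(deg, "bca")
  expect_equal(res$total_qaly, 0)
  expect_equal(res$trace$occupancy[res$trace$state == "dead"], rep(1, 5))
})

test_that("traces conserve the cohort and dead occupancy is nondecreasing", {
  for (seed in 1:300) {
    fl <- all_variants()[[1 + seed %% 32]]
    scn <- generate_synthetic_scenario(seed, variant = fl)
    for (strategy in c("bca", "bcs")) {
      res <- run_cohort(scn, strategy)
      occ <- matrix(res$trace$occupancy, ncol = 4, byrow = TRUE)
      expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
      expect_true(all(occ >= 0))
      expect_true(all(diff(occ[, 4]) >= -1e-15))
    }
  }
})

test_that("engine totals match the brute-force path enumeration oracle", {
  variants <- all_variants()
  for (seed in 1:24) {
    scn <- generate_synthetic_scenario(seed, variant = variants[[1 + seed %% 32]])
    for (strategy in c("bca", "bcs")) {
      res <- run_cohort(scn, strategy)
      orc <- oracle_cohort(scn, strategy)
      expect_equal(res$total_cost, orc[["cost"]], tolerance = 1e-10)
      expect_equal(res$total_qaly, orc[["qaly"]], tolerance = 1e-10)
    }
  }
  # and on the published scenarios
  for (scn in paper_scenarios()) {
    for (strategy in c("bca", "bcs")) {
      res <- run_cohort(scn, strategy)
      orc <- oracle_cohort(scn, strategy)
      expect_equal(res$total_cost, orc[["cost"]], tolerance = 1e-10)
      expect_equal(res$total_qaly, orc[["qaly"]], tolerance = 1e-10)
    }
  }
})

test_that("QALYs fall with mortality and costs rise unit-for-unit with procedure cost", {
  scn <- paper_scenarios()$low_risk
  qalys <- vapply(seq(0, 0.2, by = 0.02), function(m) {
    run_cohort(set_param(scn, "bca.p_mortality_annual", m), "bca")$total_qaly
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
  base <- run_cohort(scn, "bca")$total_cost
  bumped <- run_cohort(set_param(scn, "bca.procedure_cost", 2501 + 500),
                       "bca")$total_cost
  expect_equal(bumped - base, 500, tolerance = 1e-12)
  # nondecreasing in every cost parameter
  for (pp in c("shared.routine_annual_cost", "shared.local_recurrence_cost",
               "shared.advanced_disease_cost", "bca.complication_cost")) {
    lo <- run_cohort(set_param(scn, pp, get_param(scn, pp)$base_value), "bca")
    hi <- run_cohort(set_param(scn, pp, get_param(scn, pp)$base_value * 1.5),
                     "bca")
    expect_gte(hi$total_cost, lo$total_cost)
  }
})

test_that("trace exports round-trip through CSV", {
  res <- run_cohort(paper_scenarios()$low_risk, "bca")
  f <- withr::local_tempfile(fileext = ".csv")
  export_trace(res, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("cycle", "state", "occupancy",
                              "discounted_cost", "discounted_qaly"))
  expect_equal(back$occupancy, res$trace$occupancy)
})
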