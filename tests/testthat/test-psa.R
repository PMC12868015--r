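test_that("degenerate distributions make the PSA collapse onto the base case", {
  scn <- generate_synthetic_scenario(5)  # all-point parameters
  drawn <- withr::with_seed(1, draw_scenario(scn))
  expect_equal(drawn, scn)
  psa <- run_psa(scn, n = 8, seed = 3)
  base <- run_base_case(scn)
  expect_equal(unique(psa$draws$cost_bca), base$bca$total_cost)
  expect_equal(unique(psa$draws$qaly_bcs), base$bcs$total_qaly)
  expect_equal(unname(psa$summary$sd_cost), c(0, 0))
  if (base$preferred == "bca") {
    expect_equal(psa$proportion_bca_preferred, 1)
  }
})

test_that("identical seeds reproduce the PSA bit for bit", {
  scn <- paper_scenarios()$low_risk
  a <- run_psa(scn, n = 150, seed = 99)
  b <- run_psa(scn, n = 150, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  c <- run_psa(scn, n = 150, seed = 100)
  expect_false(identical(a$draws, c$draws))
})

test_that("scenario draws respect supports, sharing, and the risk simplex", {
  scn <- rescale_scenario(paper_scenarios()$low_risk)
  vals <- withr::with_seed(11, cryocea:::.psa_values(scn, 2000))
  for (pp in names(vals)) {
    p <- get_param(scn, pp)
    if (p$unit != "usd") {
      expect_true(all(vals[[pp]] >= 0 & vals[[pp]] <= 1))
    } else {
      expect_true(all(vals[[pp]] >= 0))
    }
  }
  # identical cost rows shared between arms: one draw
  expect_identical(vals[["bca.complication_cost"]],
                   vals[["bcs.complication_cost"]])
  # surgery local/distant recurrence split one total-recurrence draw
  expect_equal(vals[["bcs.p_local_annual"]] / vals[["bcs.p_distant_annual"]],
               rep(0.625 / 0.375, 2000))
  s <- vals[["bca.p_local_annual"]] + vals[["bca.p_distant_annual"]] +
    vals[["bca.p_mortality_annual"]]
  expect_true(all(s <= 1 + 1e-12))
  # point disutilities never move
  expect_equal(unique(vals[["bcs.treatment_disutility"]]), 0.10)
})

test_that("independent sampling is available behind the shared-draws flag", {
  scn <- rescale_scenario(paper_scenarios()$low_risk)
  vals <- withr::with_seed(11, cryocea:::.psa_values(scn, 500, shared_draws = FALSE))
  expect_false(identical(vals[["bca.complication_cost"]],
                         vals[["bcs.complication_cost"]]))
})

test_that("PSA means converge on the base case within Monte Carlo error", {
  scn <- paper_scenarios()$low_risk
  psa <- run_psa(scn, n = 4000, seed = 21)
  base <- run_base_case(scn)
  for (arm in c("bca", "bcs")) {
    i <- match(arm, psa$summary$strategy)
    se_cost <- psa$summary$sd_cost[i] / sqrt(psa$n)
    base_cost <- if (arm == "bca") base$bca$total_cost else base$bcs$total_cost
    # sampling distributions are mean-matched, so the PSA mean sits near
    # the base case (skewness of the small-alpha Betas allows a few SE)
    expect_lt(abs(psa$summary$mean_cost[i] - base_cost), 6 * se_cost)
  }
})

test_that("PSA dispersion reproduces the published cost and QALY SDs", {
  psa_low <- run_psa(paper_scenarios()$low_risk, n = 4000, seed = 31)
  psa_small <- run_psa(paper_scenarios()$small_1_20mm, n = 4000, seed = 32)
  published <- list(  # strategy-level SDs printed with the base case
    list(psa = psa_low, sd_cost = c(bca = 20307, bcs = 20361),
         sd_qaly = c(bca = 0.15, bcs = 0.15)),
    list(psa = psa_small, sd_cost = c(bca = 20307, bcs = 22264),
         sd_qaly = c(bca = 0.15, bcs = 0.15))
  )
  for (case in published) {
    s <- case$psa$summary
    for (arm in c("bca", "bcs")) {
      i <- match(arm, s$strategy)
      expect_lt(abs(s$sd_cost[i] - case$sd_cost[[arm]]) / case$sd_cost[[arm]],
                0.25)
      expect_lt(abs(s$sd_qaly[i] - case$sd_qaly[[arm]]) / case$sd_qaly[[arm]],
                0.25)
    }
  }
})

test_that("the acceptability curve is the preference fraction at each WTP", {
  scn <- paper_scenarios()$low_risk
  psa <- run_psa(scn, n = 400, seed = 8, wtp_grid = c(0, 5e4, 1e5))
  expect_equal(psa$ceac$p_bca[psa$ceac$wtp == 0],
               mean(psa$draws$delta_cost < 0))
  expect_equal(psa$ceac$p_bca[psa$ceac$wtp == 1e5],
               psa$proportion_bca_preferred)
  g <- glance(psa)
  expect_equal(g$proportion_bca_preferred, psa$proportion_bca_preferred)
  expect_equal(nrow(tidy(psa)), 400)
})
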