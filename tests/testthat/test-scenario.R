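test_that("shipped fixture files load to the published parameter values", {
  f <- system.file("extdata", "low_risk.yaml", package = "cryocea")
  scn <- read_scenario(f)
  expect_equal(scn$bca$procedure_cost$base_value, 2501)
  expect_equal(scn$bcs$procedure_cost$base_value, 18859)
  expect_equal(scn$shared$routine_annual_cost$base_value, 36351)
  expect_equal(scn$shared$u_distant$base_value, 0.685)
  expect_equal(scn$bcs$p_mortality_annual$base_value, 0.002)
  f2 <- system.file("extdata", "small_1_20mm.yaml", package = "cryocea")
  scn2 <- read_scenario(f2)
  expect_equal(scn2$bcs$p_mortality_annual$base_value, 0.0091)
  # identical cryoablation arm in both scenarios
  expect_equal(scn$bca, scn2$bca)
})

test_that("scenario round-trips through YAML and JSON unchanged", {
  scn <- paper_scenarios()$low_risk
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_scenario(scn, f)
    back <- read_scenario(f)
    expect_equal(back, scn, tolerance = 1e-12)
  }
})

test_that("validation names the offending path", {
  scn <- paper_scenarios()$low_risk
  expect_error(set_param(scn, "bcs.p_local_annual", 1.2), "bcs.p_local_annual")
  expect_error(set_param(scn, "bca.procedure_cost", -5), "bca.procedure_cost")
  expect_error(set_param(scn, "shared.u_distant", 1.4), "shared.u_distant")
  # joint risk constraint
  expect_error(set_param(scn, "bca.p_mortality_annual", 0.999), "sum to")
  expect_error(get_param(scn, "bca.no_such_field"), "unknown parameter path")
})

test_that("unknown configuration keys are rejected by name", {
  scn <- paper_scenarios()$low_risk
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, f)
  x <- yaml::read_yaml(f)
  x$bca$mystery_field <- 1
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f2)
  expect_error(read_scenario(f2), "mystery_field")
  x$bca$mystery_field <- NULL
  x$econ$inflation <- 0.02
  yaml::write_yaml(x, f2)
  expect_error(read_scenario(f2), "inflation")
})

test_that("missing fields are reported", {
  scn <- paper_scenarios()$low_risk
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, f)
  x <- yaml::read_yaml(f)
  x$shared$u_local <- NULL
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f2)
  expect_error(read_scenario(f2), "shared.u_local")
})

test_that("parameter tables expose every addressable parameter", {
  scn <- paper_scenarios()$low_risk
  pp <- param_paths(scn)
  expect_equal(nrow(pp), 2 * 9 + 7)
  expect_true(all(c("bca.procedure_cost", "shared.u_distant") %in% pp$path))
  tt <- tidy(scn)
  expect_true("implied_mean" %in% names(tt))
  # uncertain-only filter drops the point disutilities
  expect_false("bca.treatment_disutility" %in%
                 param_paths(scn, uncertain_only = TRUE)$path)
})

test_that("rescale_scenario reconciles only the discordant distributions", {
  scn <- rescale_scenario(paper_scenarios()$low_risk)
  # concordant after annualization: untouched
  expect_equal(get_param(scn, "bca.p_local_annual")$dist$a, 8)
  expect_equal(get_param(scn, "bca.p_mortality_annual")$dist$a, 7)
  # discordant: mean reset, effective sample size kept
  d <- get_param(scn, "bcs.p_local_annual")$dist
  expect_equal(d$a + d$b, 235 + 2707)
  expect_equal(dist_mean(d), 0.002)
  dm <- get_param(scn, "bcs.p_mortality_annual")$dist
  expect_equal(dist_mean(dm), 0.002)
  # the implied means now match the base case everywhere
  for (pp in param_paths(scn, uncertain_only = TRUE)$path) {
    p <- get_param(scn, pp)
    expect_lt(abs(dist_mean(p$dist) - p$base_value) /
                max(abs(p$base_value), 1e-12), 0.1)
  }
})

test_that("synthetic scenarios are valid and deterministic per seed", {
  s1 <- generate_synthetic_scenario(123)
  s2 <- generate_synthetic_scenario(123)
  expect_identical(s1, s2)
  s3 <- generate_synthetic_scenario(124)
  expect_false(identical(s1, s3))
  for (seed in 1:200) {
    expect_silent(validate_scenario(generate_synthetic_scenario(seed)))
  }
})
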