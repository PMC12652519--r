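test_that("parameter sampling is seeded, per-parameter stable, and degenerate-safe", {
  specs <- psa_specs()
  d1 <- sample_parameter_draws(specs, 50, seed = 3)
  d2 <- sample_parameter_draws(specs, 50, seed = 3)
  expect_identical(d1, d2)
  expect_false(identical(d1, sample_parameter_draws(specs, 50, seed = 4)))

  # dropping a parameter leaves the others' draws untouched (dedicated
  # sub-streams per parameter)
  d3 <- sample_parameter_draws(specs[names(specs) != "hr_all"], 50, seed = 3)
  expect_identical(d1[names(d3)], d3)

  # all-degenerate specs return the base parameter set exactly
  degen <- lapply(specs, function(s) {
    s$degenerate <- TRUE
    s
  })
  base <- tnbc_parameters()
  expect_equal(sample_parameters(base, degen, seed = 1), base)

  expect_error(sample_parameter_draws(list(hr = "not a spec"), 5, 1),
               "unfitted spec")
})

test_that("sampled hazard ratios centre on the published median", {
  specs <- psa_specs()
  x <- sample_parameter_draws(specs["hr_all"], 1e5, seed = 12)$hr_all
  se_med <- 1.2533 * sd(x) / sqrt(length(x))
  expect_lt(abs(median(x) - 0.66), 3 * se_med)
})

test_that("PSA is reproducible bit-for-bit and consistent with the base case", {
  psa <- run_psa(n_draws = 60, seed = 11, schedule = SCH)
  psa2 <- run_psa(n_draws = 60, seed = 11, schedule = SCH)
  expect_identical(psa$draws, psa2$draws)
  expect_identical(psa$summary, psa2$summary)
  expect_equal(psa$n_treated, 767, tolerance = 1e-9)
  expect_true(all(psa$summary$d_qaly_ci == sort(psa$summary$d_qaly_ci)))
  expect_gte(psa$summary$frac_cost_saving, 0)
  expect_lte(psa$summary$frac_cost_saving, 1)

  # single degenerate draw reproduces the deterministic base case
  degen <- lapply(psa_specs(), function(s) { s$degenerate <- TRUE; s })
  one <- run_psa(n_draws = 1, seed = 5, schedule = SCH, specs = degen)
  expect_equal(one$draws$d_qaly, BASE$comparison$d_qaly, tolerance = 1e-9)
  expect_equal(one$draws$d_cost, BASE$comparison$d_cost, tolerance = 1e-6)
  expect_equal(one$draws$d_yll, BASE$comparison$d_yll, tolerance = 1e-9)
})

test_that("draws with harmful sampled effects never gain life years", {
  psa <- run_psa(n_draws = 300, seed = 2, schedule = SCH)
  expect_true(all(psa$draws$d_yll[psa$draws$hr_all >= 1] <= 1e-9))
  expect_true(all(psa$draws$d_yll[psa$draws$hr_all < 1] >= -1e-9))
  # and deterministically: a harmful effect loses life years
  harmed <- run_base_case(SCH, tnbc_parameters(hr_treatment = 1.2))
  expect_lt(harmed$comparison$d_yll, 0)
})

test_that("PSA mean outcomes converge to the deterministic base case", {
  psa <- run_psa(n_draws = 2000, seed = 31, schedule = SCH)
  expect_lt(abs(psa$summary$d_qaly_mean - BASE$comparison$d_qaly) /
              BASE$comparison$d_qaly, 0.10)
  expect_lt(abs(psa$summary$d_yll_mean - BASE$comparison$d_yll) /
              BASE$comparison$d_yll, 0.10)
})

test_that("widening every parameter's uncertainty widens the PSA intervals", {
  specs <- psa_specs()
  tbl <- parameter_table()
  tbl <- tbl[tbl$name %in% names(specs), ]
  wide <- fit_parameter_table(within(tbl, {
    half <- (high95 - low95) / 2
    low95 <- mean - 2 * half
    high95 <- mean + 2 * half
  }))[names(specs)]
  # doubled ranges are infeasible for none of the base-case rows
  psa_n <- run_psa(n_draws = 300, seed = 8, schedule = SCH, specs = specs)
  psa_w <- run_psa(n_draws = 300, seed = 8, schedule = SCH, specs = wide)
  expect_gt(diff(psa_w$summary$d_qaly_ci), diff(psa_n$summary$d_qaly_ci))
  expect_gt(diff(psa_w$summary$d_cost_ci), diff(psa_n$summary$d_cost_ci))
})

test_that("CEAC is monotone towards certainty for a dominant intervention", {
  psa <- run_psa(n_draws = 200, seed = 6, schedule = SCH)
  cc <- ceac(psa, seq(0, 56000, by = 8000))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  expect_gte(cc$prob_cost_effective[nrow(cc)], cc$prob_cost_effective[1])
})

test_that("tornado spans behave and the treatment effect ranks highly", {
  tor <- tornado(SCH)
  expect_true(all(tor$span >= 0))
  expect_equal(tor$span, sort(tor$span, decreasing = TRUE))
  expect_equal(tor$span, abs(tor$icer_high - tor$icer_low), tolerance = 1e-9)

  # zero-width range produces zero span
  tbl <- parameter_table()
  row <- tbl[tbl$name == "c_death_other", ]
  row$low95 <- row$mean
  row$high95 <- row$mean
  tor0 <- tornado(SCH, tbl = row)
  expect_equal(tor0$span, 0, tolerance = 1e-9)
  expect_equal(tor0$icer_low, BASE$comparison$icer_qaly, tolerance = 1e-9)

  # treatment effect or terminal cost carries the widest span
  expect_true(any(tor$parameter[1:2] %in% c("hr_all", "c_terminal_tnbc")))
})
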