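test_that("base-case totals equal the sum of the per-band runs", {
  sub <- run_age_subgroup(SCH)
  expect_equal(nrow(sub), 6)
  expect_equal(sum(sub$d_yll), BASE$comparison$d_yll, tolerance = 1e-9)
  expect_equal(sum(sub$d_qaly), BASE$comparison$d_qaly, tolerance = 1e-9)
  expect_equal(sum(sub$d_cost), BASE$comparison$d_cost, tolerance = 1e-9)
  expect_equal(sum(sub$drug_cost), BASE$intervention$cost_drug_undisc,
               tolerance = 1e-9)
})

test_that("stage mixture totals equal fraction-weighted pure-stage runs", {
  st <- run_stage_subgroup(SCH)
  expect_equal(st$stage, c("localized", "regional", "distant"))
  expect_equal(sum(st$n_entry), 767, tolerance = 1e-9)

  # a pure-localized mixture equals a localized-parameter base run
  mix1 <- stage_mix()[1, ]
  mix1$fraction <- 1
  pure <- run_stage_subgroup(SCH, mix = mix1)
  direct <- run_base_case(SCH, tnbc_parameters(p_tnbc_death = 0.017,
                                               hr_treatment = 0.86))
  expect_equal(pure$d_qaly, direct$comparison$d_qaly, tolerance = 1e-9)
  expect_equal(pure$d_cost, direct$comparison$d_cost, tolerance = 1e-9)

  # per-stage rows scale linearly in the allocated fraction
  expect_equal(st$d_qaly[1], direct$comparison$d_qaly * 0.605,
               tolerance = 1e-9)
  expect_error(run_stage_subgroup(SCH, mix = transform(stage_mix(),
                                                       fraction = fraction * 2)),
               "sum to 1")
})

test_that("each scenario differs from base in exactly one parameter", {
  base_p <- tnbc_parameters()
  expected_field <- c("discount_rate", "discount_rate", "hr_treatment",
                      "c_drug_annual", "c_drug_annual", "c_mgmt_beyond_5y")
  for (id in 1:6) {
    ov <- scenario_overrides(id)
    expect_length(ov, 1)
    expect_identical(names(ov), expected_field[id])
    p <- do.call(modify_parameters, c(list(base_p), ov))
    changed <- names(base_p)[!vapply(names(base_p), function(f)
      identical(p[[f]], base_p[[f]]), logical(1))]
    expect_identical(changed, expected_field[id])
  }
})

test_that("scenario orderings match the published directionality", {
  sc <- lapply(1:6, run_scenario, schedule = SCH)

  # doubling the propranolol dose exactly doubles drug cost, nothing else
  expect_equal(sc[[5]]$intervention$cost_drug_undisc,
               2 * BASE$intervention$cost_drug_undisc, tolerance = 1e-9)
  expect_equal(sc[[5]]$comparison$d_yll, BASE$comparison$d_yll,
               tolerance = 1e-9)
  expect_equal(sc[[5]]$comparison$d_qaly, BASE$comparison$d_qaly,
               tolerance = 1e-9)

  # undiscounted gains exceed discounted gains, 3.5% sits between
  expect_gt(sc[[1]]$comparison$d_yll, BASE$comparison$d_yll)
  expect_gt(sc[[1]]$comparison$d_yll, sc[[2]]$comparison$d_yll)
  expect_gt(sc[[2]]$comparison$d_yll, BASE$comparison$d_yll)

  # a weaker effect (RR 0.74) gains less than the base effect (0.66)
  expect_lt(sc[[3]]$comparison$d_yll, BASE$comparison$d_yll)
  expect_gt(sc[[3]]$comparison$d_yll, 0)

  # carvedilol scenario keeps health outcomes, raises drug cost
  expect_equal(sc[[4]]$comparison$d_qaly, BASE$comparison$d_qaly,
               tolerance = 1e-9)
  expect_gt(sc[[4]]$comparison$d_cost, BASE$comparison$d_cost)

  # lifetime management costs penalise the longer-lived arm
  expect_gt(sc[[6]]$comparison$d_cost, BASE$comparison$d_cost)
  expect_equal(sc[[6]]$comparison$d_qaly, BASE$comparison$d_qaly,
               tolerance = 1e-9)
})

test_that("trial sample size reproduces the normal-approximation formula", {
  ss <- two_proportion_sample_size(0.12, 0.18, power = 0.80, alpha = 0.05)
  expect_equal(ss$n_per_group, 555)
  expect_equal(ss$n_total, 1110)
  expect_gt(ss$n_total, 1100)

  # symmetric in the two proportions
  expect_equal(two_proportion_sample_size(0.18, 0.12)$n_total, ss$n_total)

  # more power never means fewer patients
  n_power <- vapply(c(0.7, 0.8, 0.9, 0.95), function(pw)
    two_proportion_sample_size(0.12, 0.18, power = pw)$n_total, numeric(1))
  expect_true(all(diff(n_power) >= 0))
  expect_error(two_proportion_sample_size(0.15, 0.15), "infeasible")
  expect_error(two_proportion_sample_size(0, 0.5), "strictly inside")
})

test_that("run_study dispatches every analysis id", {
  expect_s3_class(run_study("base", schedule = SCH), "bbtnbc_basecase")
  expect_identical(attr(run_study("scenario_2", schedule = SCH), "scenario"), 2L)
  expect_equal(nrow(run_study("age_subgroup", schedule = SCH)), 6)
  expect_equal(nrow(run_study("stage_subgroup", schedule = SCH)), 3)
  expect_equal(run_study("samplesize")$n_total, 1110)
  psa <- run_study("psa", schedule = SCH, psa_n = 20, psa_seed = 2)
  expect_s3_class(psa, "bbtnbc_psa")
  expect_equal(psa$n_draws, 20)
  ev <- run_study("evpi", schedule = SCH, psa_n = 20, psa_seed = 2,
                  wtp_grid = c(0, 28000))
  expect_equal(nrow(ev), 2)
  expect_error(run_study("nope", schedule = SCH), "unknown analysis")
})
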