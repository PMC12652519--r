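test_that("risk/rate/probability conversions follow the life-table formulas", {
  expect_equal(annual_rate_from_five_year_risk(0), 0)
  expect_equal(annual_rate_from_five_year_risk(1 - exp(-5)), 1,
               tolerance = 1e-12)
  r <- annual_rate_from_five_year_risk(0.18)
  expect_equal(r, -log(0.82) / 5, tolerance = 1e-12)
  expect_equal(r, 0.0396902, tolerance = 1e-6)

  expect_equal(probability_from_rate(0), 0)
  # chained: five-year risk 0.18 maps to the annual probability ~0.039
  p <- probability_from_rate(r)
  expect_equal(p, 1 - exp(-r), tolerance = 1e-12)
  expect_equal(p, 0.03891285, tolerance = 1e-6)
  expect_equal(round(p, 3), 0.039)
  expect_equal(probability_from_rate(1e9), 1)

  expect_error(annual_rate_from_five_year_risk(1), "alpha")
  expect_error(probability_from_rate(-0.1), "non-negative")
})

test_that("hazard ratios act on the hazard scale", {
  p <- c(0, 0.039, 0.5, 0.99)
  expect_equal(apply_hazard_ratio(p, 1), p)
  expect_equal(apply_hazard_ratio(0.039, 0.66), 1 - 0.961^0.66,
               tolerance = 1e-12)
  expect_equal(apply_hazard_ratio(0.039, 0.66), 0.0259137, tolerance = 1e-6)
  expect_equal(apply_hazard_ratio(0.5, 0), 0)
  expect_equal(apply_hazard_ratio(0.5, 2), 0.75)
  expect_error(apply_hazard_ratio(1, 0.66), "probability")
  expect_error(apply_hazard_ratio(0.5, -1), "non-negative")
})

test_that("no-mortality cohort lives to the censoring age", {
  sch <- flat_schedule(q_all = 0)
  p <- neutral_params(p_tnbc_death = 0)
  tr <- run_cohort(500, 60, "standard", p, sch)
  expect_equal(sum(tr$ly), 500 * (85 - 60), tolerance = 1e-9)
  expect_equal(tail(tr$alive_end, 1), 500)
  # with unit utilities and no decrements QALY accrual equals life years
  expect_equal(sum(tr$qaly), sum(tr$ly), tolerance = 1e-12)
})

test_that("one cycle matches the hand-computed competing-risk split", {
  sch <- flat_schedule(q_all = 0.01)
  p <- tnbc_parameters(p_tnbc_death = 0.039)
  tr <- run_cohort(1000, 60, "standard", p, sch)
  expect_equal(tr$d_tnbc[1], 1000 * 0.039 * (1 - 0.01 / 2), tolerance = 1e-12)
  expect_equal(tr$d_tnbc[1], 38.805)
  expect_equal(tr$d_other[1], 1000 * 0.01 * (1 - 0.039 / 2),
               tolerance = 1e-12)
  expect_equal(tr$alive_end[1], 1000 * (1 - 0.039) * (1 - 0.01),
               tolerance = 1e-9)
  # cost accounting for the first cycle
  expect_equal(tr$cost_mgmt[1], 42409 * tr$ly[1], tolerance = 1e-9)
  expect_equal(tr$cost_terminal[1], 44327 * tr$d_tnbc[1], tolerance = 1e-9)
  expect_equal(tr$cost_drug[1], 0)
  tri <- run_cohort(1000, 60, "intervention", p, sch)
  expect_equal(tri$cost_drug[1], 113.95 * tri$ly[1], tolerance = 1e-9)
})

test_that("occupancy is conserved and death states absorb", {
  for (tr in list(run_cohort(767, 52, "standard", tnbc_parameters(), SCH),
                  run_cohort(111.8, 77, "intervention", tnbc_parameters(), SCH))) {
    total <- tr$alive_end + tr$cum_d_tnbc + tr$cum_d_other
    expect_equal(total, rep(tr$alive_start[1], nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr$cum_d_tnbc) >= 0))
    expect_true(all(diff(tr$cum_d_other) >= 0))
    expect_true(all(tr$ly <= tr$alive_start + 1e-12))
  }
})

test_that("null treatment effect changes drug cost only", {
  p <- tnbc_parameters(hr_treatment = 1)
  std <- run_cohort(767, 62, "standard", p, SCH)
  int <- run_cohort(767, 62, "intervention", p, SCH)
  same <- setdiff(names(std), "cost_drug")
  expect_equal(as.data.frame(int)[same], as.data.frame(std)[same],
               tolerance = 1e-12)
  expect_gt(sum(int$cost_drug), 0)
})

test_that("stronger treatment effects never reduce intervention life years", {
  lys <- vapply(c(0.4, 0.66, 0.8, 1, 1.3), function(hr) {
    p <- tnbc_parameters(hr_treatment = hr)
    sum(run_cohort(767, 62, "intervention", p, SCH)$ly)
  }, numeric(1))
  expect_true(all(diff(lys) <= 1e-9))
})

test_that("cohort trace agrees with an individual-level microsimulation", {
  p <- tnbc_parameters()
  n <- 1e5
  for (arm in c("standard", "intervention")) {
    sim <- microsim_arm(n, 62, arm, p, SCH, seed = 42)
    tr <- run_cohort(n, 62, arm, p, SCH)
    # mean life years within 3 SE of the microsimulation
    expect_lt(abs(sum(tr$ly) / n - sim$mean_ly), 3 * sim$se_ly)
    # final state occupancy within 3 binomial SEs
    for (st in c("frac_tnbc", "frac_other", "frac_alive")) {
      model_frac <- switch(st,
        frac_tnbc = tail(tr$cum_d_tnbc, 1) / n,
        frac_other = tail(tr$cum_d_other, 1) / n,
        frac_alive = tail(tr$alive_end, 1) / n)
      se <- sqrt(sim[[st]] * (1 - sim[[st]]) / n)
      expect_lt(abs(model_frac - sim[[st]]), 3 * se + 1e-12)
    }
  }
})

test_that("missing schedule ages raise a configuration error", {
  sch <- as.data.frame(SCH)
  sch <- sch[sch$age < 80, ]
  expect_error(run_cohort(100, 62, "standard", tnbc_parameters(), sch),
               "lacks required age")
  expect_error(run_cohort(100, 40, "standard", tnbc_parameters(), SCH),
               "entry_age")
})
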