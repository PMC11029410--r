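test_that("a null intervention leaves every cohort field unchanged", {
  x <- synth_inputs()
  co <- run_cohort(x, "male", 50, pif = 0)
  expect_identical(co$int, co$ref)
})

test_that("an immortal cohort keeps constant numbers alive", {
  x <- one_stratum_inputs(acm = 0, ihd_inc = 0.02, ihd_prev = 0.1,
                          ihd_mort = 0, ihd_yld_rate = 0, other_yld_rate = 0)
  co <- run_cohort(x, "female", 90, pif = 0)
  expect_equal(co$ref$alive, rep(1000, 11), tolerance = 1e-12)
  expect_equal(co$ref$person_years, rep(1000, 10), tolerance = 1e-12)
})

test_that("inconsistent inputs (IHD mortality above all-cause) are caught", {
  x <- one_stratum_inputs(acm = 0.005, ihd_inc = 0.02, ihd_prev = 0.2,
                          ihd_mort = 0.004)
  # force acm (mutating past validation) far below the input IHD mortality:
  # the intervention arm's modelled rate drops under full elimination, so the
  # replaced hazard acm - ihd_mort + rate goes negative and must error
  x$demography$acm <- 1e-5
  expect_error(run_cohort(x, "female", 90, pif = 1), "negative all-cause hazard")
})

test_that("toy-fixture life expectancy matches the hand-computed geometric lifetable", {
  toy <- generate_worked_toy()
  # the toy sits at the disease equilibrium p = i/f, so the modelled IHD rate
  # equals the input rate and the all-cause hazard stays at acm; survivorship
  # is then l(t) = exp(-acm * t) and trapezoidal person-years sum in closed
  # form
  for (sex in c("female", "male")) {
    m <- toy$demography$acm[toy$demography$sex == sex]
    co <- run_cohort(toy, sex, 90, pif = 0)
    l <- exp(-m * 0:10)
    le_hand <- sum((l[-11] + l[-1]) / 2)
    expect_equal(sum(co$ref$person_years) / 1000, le_hand, tolerance = 1e-6)
  }
})

test_that("health-adjusted person-years follow the disability-weighting formula", {
  expect_identical(halys_for_year(100, 0, 0, 0), 100)
  expect_equal(halys_for_year(100, 10, other_yld_rate = 0.05, dw_ihd = 0.1), 94,
               tolerance = 1e-12)
  expect_identical(halys_for_year(1, 1, 0.9999, 1), 0) # floored at zero
  expect_error(halys_for_year(100, 10, 0.05, 1.2), "dw_ihd")
  expect_error(halys_for_year(10, 20, 0.05, 0.1))
})

test_that("aggregation discounts with exponent zero in the first year", {
  g <- 123.45
  co <- fake_cohort(n = 5, int_halys = rep(g, 5))
  agg <- aggregate_population(list(co), horizons = 5, discount_rate = 0.03)
  expect_equal(pick(agg, "halys", "5y"), sum(g * 1.03^-(0:4)), tolerance = 1e-12)
  agg0 <- aggregate_population(list(co), horizons = 5, discount_rate = 0)
  expect_equal(pick(agg0, "halys", "5y"), 5 * g, tolerance = 1e-12)
  # event counts are never discounted
  co2 <- fake_cohort(n = 5, int_cases = rep(2, 5), ref_cases = rep(5, 5))
  agg2 <- aggregate_population(list(co2), horizons = 5, discount_rate = 0.1)
  expect_equal(pick(agg2, "ihd_events", "5y"), -15, tolerance = 1e-12)
  expect_equal(pick(agg2, "ihd_events_pct", "5y"), -60, tolerance = 1e-12)
})

test_that("sex-specific aggregates sum exactly to the combined totals", {
  x <- synth_inputs()
  res <- run_pipeline(x)
  shared <- c("ihd_events", "ihd_deaths", "halys", "ihd_healthcare_cost",
              "nonihd_healthcare_cost")
  for (h in unique(res$horizon)) {
    for (oc in shared) {
      expect_identical(
        pick(res, oc, h, "female") + pick(res, oc, h, "male"),
        pick(res, oc, h, "both")
      )
    }
    # the combined total is defined as combined ihd + combined nonihd, so its
    # sex additivity holds to floating-point round-off
    expect_equal(
      pick(res, "total_healthcare_cost", h, "female") +
        pick(res, "total_healthcare_cost", h, "male"),
      pick(res, "total_healthcare_cost", h, "both"),
      tolerance = 1e-12
    )
  }
})

test_that("undiscounted effects are nested across horizons", {
  x <- synth_inputs()
  res <- run_pipeline(x, scenario(discount_rate = 0))
  for (oc in c("ihd_events", "ihd_deaths", "halys")) {
    v <- vapply(c("5y", "10y", "lifetime"), function(h) abs(pick(res, oc, h)),
                numeric(1))
    expect_true(all(diff(v) >= 0))
  }
  # percent reductions stay within [0, 100)
  pcts <- abs(res$value[res$outcome %in% c("ihd_events_pct", "ihd_deaths_pct")])
  expect_true(all(pcts >= 0 & pcts < 100))
})

test_that("horizons beyond the simulated span are rejected", {
  co <- fake_cohort(n = 5)
  expect_error(aggregate_population(list(co), horizons = 200), "horizons")
  expect_error(aggregate_population(list(co), horizons = numeric(0)), "no horizons")
})
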