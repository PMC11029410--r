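test_that("a plan with only the primary scenario equals a direct pipeline run", {
  x <- synth_inputs()
  plan <- analysis_plan()["primary"]
  out <- run_plan(x, plan, n_iter = 0)
  direct <- run_pipeline(x, scenario())
  expect_equal(out$variants$primary, direct, tolerance = 0)
  expect_identical(out$errors, character(0))
})

test_that("variant results are unaffected by the presence of other variants", {
  x <- synth_inputs()
  plan <- analysis_plan()
  alone <- run_plan(x, plan["discount_0"], n_iter = 3, seed = 7)
  together <- run_plan(x, plan[c("primary", "discount_0")], n_iter = 3, seed = 7)
  expect_identical(alone$variants$discount_0$summary,
                   together$variants$discount_0$summary)
})

test_that("no discounting increases lifetime HALY gains", {
  x <- synth_inputs()
  plan <- analysis_plan()[c("primary", "discount_0", "discount_6")]
  out <- run_plan(x, plan, n_iter = 0)
  h <- function(v) pick(out$variants[[v]], "halys", "lifetime")
  expect_gt(h("discount_0"), h("primary"))
  expect_gt(h("primary"), h("discount_6"))
})

test_that("halving pre-intervention intake shrinks the PIF and the HALY gains", {
  x <- synth_inputs()
  out <- run_plan(x, analysis_plan()[c("primary", "intake_x0.5", "intake_x1.5")],
                  n_iter = 0)
  pif_lo <- compute_pif_table(apply_scenario(x, scenario(intake_scale = 0.5)),
                              scenario())
  pif_1 <- compute_pif_table(x, scenario())
  expect_true(all(pif_lo$pif < pif_1$pif))
  for (h in c("5y", "10y", "lifetime")) {
    expect_lt(pick(out$variants$intake_x0.5, "halys", h),
              pick(out$variants$primary, "halys", h))
    expect_gt(pick(out$variants$intake_x1.5, "halys", h),
              pick(out$variants$primary, "halys", h))
  }
})

test_that("cost toggles act only on their own cost stream", {
  x <- synth_inputs()
  out <- run_plan(x, analysis_plan()[c("primary", "no_industry_cost",
                                       "products_x2", "monitoring_x1.5")],
                  n_iter = 0)
  v <- out$variants
  for (h in c("5y", "10y", "lifetime")) {
    expect_identical(pick(v$no_industry_cost, "industry_cost", h), 0)
    expect_identical(pick(v$no_industry_cost, "gov_cost", h),
                     pick(v$primary, "gov_cost", h))
    expect_equal(pick(v$products_x2, "industry_cost", h),
                 2 * pick(v$primary, "industry_cost", h), tolerance = 1e-12)
    expect_gt(pick(v$monitoring_x1.5, "gov_cost", h),
              pick(v$primary, "gov_cost", h))
    # health outcomes untouched by cost toggles
    expect_identical(pick(v$products_x2, "halys", h), pick(v$primary, "halys", h))
  }
})

test_that("the smallest intake reduction is least likely to be cost-saving", {
  x <- synth_inputs()
  plan <- analysis_plan()[c("threshold_0.05", "threshold_0.20")]
  out <- run_plan(x, plan, n_iter = 40, seed = 13)
  p05 <- out$variants$threshold_0.05$probabilities
  p20 <- out$variants$threshold_0.20$probabilities
  expect_lte(p05$p_cost_saving[p05$horizon == "10y"],
             p20$p_cost_saving[p20$horizon == "10y"])
})

test_that("failing variants are reported while the rest continue", {
  x <- synth_inputs()
  plan <- analysis_plan()["primary"]
  plan$broken <- scenario("broken", horizons = c(5, 200)) # beyond the simulated span
  expect_warning(out <- run_plan(x, plan, n_iter = 0), "broken")
  expect_true("broken" %in% names(out$errors))
  expect_true("primary" %in% names(out$variants))
})
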