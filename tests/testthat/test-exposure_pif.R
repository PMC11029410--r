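test_that("relative risk is a power law in intake above the minimum-risk level", {
  expect_identical(rr_at_intake(0, 1.23), 1)
  expect_identical(rr_at_intake(2, 1.23), 1.23)
  expect_equal(rr_at_intake(1, 1.23), sqrt(1.23), tolerance = 1e-12)
  expect_equal(rr_at_intake(1, 1.23), 1.23^0.5, tolerance = 1e-15)
  # below TMREL the risk is flat at 1
  expect_identical(rr_at_intake(0.5, 1.23, tmrel = 1), 1)
  expect_true(all(diff(rr_at_intake(seq(0, 3, 0.1), 1.23)) >= 0))
})

test_that("point-mass PIF matches the closed form to 1e-10", {
  res <- compute_pif(intake_distribution(0.28, 0), intake_distribution(0, 0), 1.23)
  expect_equal(res$pif, 1 - 1.23^(-0.28 / 2), tolerance = 1e-10)
  expect_equal(res$pif, 0.0286, tolerance = 2e-3)

  set.seed(1)
  for (k in 1:25) {
    m_ref <- runif(1, 0.05, 2)
    m_cf <- runif(1, 0, m_ref)
    rr <- runif(1, 1, 2)
    res <- compute_pif(intake_distribution(m_ref, 0),
                       intake_distribution(m_cf, 0), rr)
    expect_equal(res$pif, 1 - rr^((m_cf - m_ref) / 2), tolerance = 1e-10)
  }
})

test_that("identical reference and counterfactual distributions give PIF = 0 exactly", {
  d <- intake_distribution(0.28, 0.1)
  expect_identical(compute_pif(d, d, 1.23)$pif, 0)
})

test_that("lognormal quadrature agrees with a large-sample Monte Carlo oracle", {
  cases <- list(c(mean = 0.28, sd = 0.1, rr = 1.23),
                c(mean = 0.5, sd = 0.25, rr = 1.4))
  set.seed(99)
  for (cs in cases) {
    ref <- intake_distribution(cs[["mean"]], cs[["sd"]])
    pif_q <- compute_pif(ref, intake_distribution(0, 0), cs[["rr"]])$pif
    s2 <- log(1 + (cs[["sd"]] / cs[["mean"]])^2)
    x <- rlnorm(1e6, log(cs[["mean"]]) - s2 / 2, sqrt(s2))
    rr_x <- cs[["rr"]]^(x / 2)
    # full elimination: PIF = 1 - 1/E[RR]; delta-method SE on the ratio
    m <- mean(rr_x)
    se <- sd(rr_x) / sqrt(length(x)) / m^2
    expect_lt(abs(pif_q - (1 - 1 / m)), 3 * se)
  }
})

test_that("lowering the counterfactual mean never decreases the PIF", {
  ref <- intake_distribution(0.3, 0.1)
  means <- seq(0.3, 0, by = -0.05)
  pifs <- vapply(
    means,
    function(m) compute_pif(ref, intake_distribution(m, ifelse(m > 0, 0.05, 0)),
                            1.23)$pif,
    numeric(1)
  )
  expect_true(all(diff(pifs) >= -1e-12))
  expect_true(all(pifs <= 1))
})

test_that("apply_pif scales incidence and rejects pif > 1", {
  expect_equal(apply_pif(0.002, 0.05), 0.0019, tolerance = 1e-15)
  expect_identical(apply_pif(0.002, 0), 0.002)
  p <- compute_pif(intake_distribution(0.28, 0), intake_distribution(0, 0), 1.23)$pif
  expect_equal(apply_pif(0.002, p), 0.002 * (1 - p), tolerance = 1e-15)
  expect_error(apply_pif(0.002, 1.1), "pif > 1")
})

test_that("the scenario counterfactual honours shifts and the null policy", {
  x <- synth_inputs()
  null_pifs <- compute_pif_table(x, scenario(post_intake = NULL))
  expect_identical(null_pifs$pif, rep(0, 30))

  full <- compute_pif_table(x, scenario())
  shift <- compute_pif_table(x, scenario(intake_shift = 0.1))
  big_shift <- compute_pif_table(x, scenario(intake_shift = 10))
  expect_true(all(full$pif > 0))
  expect_true(all(shift$pif > 0 & shift$pif < full$pif))
  # a shift beyond the whole intake floors the counterfactual at 0%E but
  # keeps no spread, matching full elimination
  expect_equal(big_shift$pif, full$pif, tolerance = 1e-12)
})
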