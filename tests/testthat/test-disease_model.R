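test_that("zero rates leave the disease state unchanged", {
  st <- disease_state(0.9, 0.08, 0.02)
  out <- step_disease(st, disease_rates(0, 0))
  expect_equal(out$s, st$s, tolerance = 1e-15)
  expect_equal(out$c, st$c, tolerance = 1e-15)
  expect_equal(out$d, st$d, tolerance = 1e-15)
})

test_that("the one-year step matches the closed form", {
  out <- step_disease(disease_state(1, 0), disease_rates(0.01, 0.1))
  expect_equal(out$s, exp(-0.01), tolerance = 1e-15)
  expect_equal(out$c, 0.01 * (exp(-0.01) - exp(-0.1)) / (0.1 - 0.01),
               tolerance = 1e-15)
})

test_that("closed-form step matches adaptive ODE integration on random rate grids", {
  skip_if_not_installed("deSolve")
  set.seed(17)
  grids <- rbind(
    expand.grid(i = c(0, 1e-6, 0.01, 0.2, 0.5), f = c(0, 1e-6, 0.05, 0.3)),
    data.frame(i = runif(30, 0, 0.5), f = runif(30, 0, 0.5)),
    data.frame(i = 0.1, f = 0.1),            # exact degeneracy
    data.frame(i = 0.1, f = 0.1 + 1e-13)     # near-degenerate
  )
  for (k in seq_len(nrow(grids))) {
    i <- grids$i[k]; f <- grids$f[k]
    s0 <- runif(1, 0.3, 1); c0 <- runif(1, 0, 1 - s0)
    sol <- ode_disease(s0, c0, i, f)
    out <- step_disease(disease_state(s0, c0), disease_rates(i, f))
    expect_lt(abs(out$s - sol[2, "s"]), 1e-8)
    expect_lt(abs(out$c - sol[2, "c"]), 1e-8)
    expect_lt(abs(out$d - sol[2, "d"]), 1e-8)
    # conservation of s + c + d along the step
    expect_lt(abs((out$s + out$c + out$d) - (s0 + c0)), 1e-12)
  }
})

test_that("the IHD mortality rate equals IHD deaths per person-year from the ODE", {
  skip_if_not_installed("deSolve")
  set.seed(4)
  for (k in 1:12) {
    i <- runif(1, 0, 0.3); f <- runif(1, 0, 0.4)
    s0 <- runif(1, 0.4, 1); c0 <- runif(1, 0, 1 - s0)
    rate <- ihd_mortality_rate(disease_state(s0, c0), disease_rates(i, f))
    sol <- ode_disease(s0, c0, i, f)
    oracle <- (sol[2, "d"] - sol[1, "d"]) / sol[2, "py"]
    expect_lt(abs(rate - oracle), 1e-8)
  }
  # incident cases can die within the same year: rate > 0 even from c = 0
  expect_gt(ihd_mortality_rate(disease_state(1, 0), disease_rates(0.1, 0.2)), 0)
  expect_equal(ihd_mortality_rate(disease_state(0.8, 0.2), disease_rates(0.1, 0)), 0)
  expect_error(ihd_mortality_rate(disease_state(0, 0), disease_rates(0.1, 0.1)),
               "no one alive")
})

test_that("monotone incidence ordering propagates to prevalence and mortality", {
  # lower incidence with equal case fatality gives lower prevalence and
  # IHD mortality at every age
  f <- 0.1
  st_lo <- st_hi <- disease_state(0.95, 0.05)
  for (a in 1:40) {
    r_lo <- ihd_mortality_rate(st_lo, disease_rates(0.01, f))
    r_hi <- ihd_mortality_rate(st_hi, disease_rates(0.02, f))
    st_lo <- step_disease(st_lo, disease_rates(0.01, f))
    st_hi <- step_disease(st_hi, disease_rates(0.02, f))
    expect_lte(st_lo$c / (st_lo$s + st_lo$c), st_hi$c / (st_hi$s + st_hi$c))
    expect_lte(r_lo, r_hi)
  }
})

test_that("case fatality derivation divides mortality by prevalence", {
  epi <- tibble::tibble(sex = c("female", "female"), age_group = c(50L, 55L),
                        ihd_prev = c(0.02, 0.05), ihd_mort = c(0.001, 0))
  cf <- derive_case_fatality(epi)
  expect_equal(cf$case_fatality, c(0.05, 0), tolerance = 1e-15)
  bad <- tibble::tibble(sex = "male", age_group = 60L, ihd_prev = 0, ihd_mort = 0.01)
  expect_error(derive_case_fatality(bad), "male, 60")
})
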