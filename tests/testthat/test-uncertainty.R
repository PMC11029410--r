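test_that("the triangular quantile function inverts the distribution", {
  qtriangular <- pmslt:::qtriangular
  expect_identical(qtriangular(0, 2, 3, 5), 2)
  expect_identical(qtriangular(1, 2, 3, 5), 5)
  # median of many draws near the analytic mean (a+b+c)/3
  set.seed(2)
  draws <- qtriangular(runif(2e5), 200, 400, 600)
  expect_equal(mean(draws), 400, tolerance = 0.01)
  # degenerate support returns the mode exactly
  expect_identical(qtriangular(0.73, 400, 400, 400), 400)
})

test_that("a single iteration collapses the summary onto itself", {
  x <- synth_inputs()
  mc <- run_monte_carlo(x, n_iter = 1, seed = 5)
  expect_identical(mc$summary$mean, mc$summary$`p2.5`)
  expect_identical(mc$summary$mean, mc$summary$`p97.5`)
})

test_that("identical seeds reproduce the Monte Carlo summary bit-for-bit", {
  x <- synth_inputs()
  a <- run_monte_carlo(x, n_iter = 8, seed = 21)
  b <- run_monte_carlo(x, n_iter = 8, seed = 21)
  c <- run_monte_carlo(x, n_iter = 8, seed = 22)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$summary$mean, c$summary$mean))
})

test_that("zero-spread inputs make every iteration equal the central run", {
  x <- degenerate_inputs()
  mc <- run_monte_carlo(x, n_iter = 3, seed = 9, cost_cv = 0)
  central <- run_pipeline(x)
  both <- central[central$sex == "both", ]
  for (h in unique(both$horizon)) {
    v <- both[both$horizon == h, ]
    want <- v$value[match(colnames(mc$draws[[h]]), v$outcome)]
    for (iter in 1:3) {
      expect_identical(unname(mc$draws[[h]][iter, ]), want)
    }
  }
})

test_that("the Monte Carlo mean agrees with the central run under near-linearity", {
  x <- synth_inputs()
  mc <- run_monte_carlo(x, n_iter = 150, seed = 31)
  central <- run_pipeline(x)
  h <- mc$draws[["10y"]][, "halys"]
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - pick(central, "halys", "10y")), 3 * se)
})

test_that("ICER classification follows the strict threshold", {
  z <- icer(-1e6, 1000)
  expect_true(z$cost_saving && z$cost_effective)
  expect_equal(z$icer, -1000, tolerance = 1e-12)

  at <- icer(374000, 1000)
  expect_false(at$cost_saving)
  expect_false(at$cost_effective) # exactly at the threshold: strict "<"
  expect_equal(at$icer, 374, tolerance = 1e-12)

  below <- icer(373999, 1000)
  expect_true(below$cost_effective)

  zero <- icer(0, 1000)
  expect_identical(zero$icer, 0)
  expect_true(zero$cost_effective)

  dom <- icer(5e6, -10)
  expect_true(dom$dominated)
  expect_true(is.na(dom$icer))
  expect_false(dom$cost_effective)
})

test_that("return on investment is the savings-to-government-cost ratio", {
  expect_equal(roi(90e6, 2e6), 45, tolerance = 1e-12)
  expect_identical(roi(0, 2e6), 0)
  expect_error(roi(1e6, 0), "gov_costs")
  # per-iteration ROI is the canonical summary; the ratio of means differs
  set.seed(3)
  savings <- runif(500, 10e6, 100e6)
  gov <- runif(500, 1e6, 3e6)
  per_iter <- mean(roi(savings, gov))
  of_means <- mean(savings) / mean(gov)
  expect_false(isTRUE(all.equal(per_iter, of_means)))
  expect_lt(abs(per_iter / of_means - 1), 0.25)
})

test_that("cost-saving and cost-effectiveness probabilities count iterations", {
  p <- mc_probabilities(c(-1, -2, -3), c(NA, -5, -1))
  expect_identical(unname(p), c(1, 1))
  p <- mc_probabilities(c(1, 2), c(100, 200))
  expect_identical(unname(p), c(0, 1))
  p <- mc_probabilities(c(-1, 1, 1, 1), c(-10, 400, 500, 600))
  expect_identical(unname(p), c(0.25, 0.25))
})

test_that("negative policy draws are truncated and counted", {
  x <- synth_inputs()
  set.seed(1)
  n_trunc <- 0L
  for (k in 1:50) {
    ds <- draw_set(x, cost_cv = 2) # absurd CV to force negatives
    expect_true(all(unlist(ds$policy) >= 0))
    n_trunc <- n_trunc + ds$truncated
  }
  expect_gt(n_trunc, 0)
})
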