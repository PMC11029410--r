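# Shared fixtures, built in code at test time.

synth_inputs <- function(seed = 42) {
  generate_inputs(synth_config(seed = seed))
}

# Inputs whose uncertain quantities all have zero spread: intake SD, log-RR SD
# and triangular cost widths collapse to points. Used with cost_cv = 0 to
# check that the Monte Carlo degenerates to the central run.
degenerate_inputs <- function(seed = 42) {
  x <- synth_inputs(seed)
  x$intake$sd_e_pct <- 0
  x$rr$ln_rr_sd <- 0
  x$costs_health$ihd_incident_min <- x$costs_health$ihd_incident_cost
  x$costs_health$ihd_incident_max <- x$costs_health$ihd_incident_cost
  x$costs_health$ihd_prevalent_min <- x$costs_health$ihd_prevalent_cost
  x$costs_health$ihd_prevalent_max <- x$costs_health$ihd_prevalent_cost
  x
}

# A hand-assembled single-stratum input set (validated without the
# 30-stratum completeness requirement), for focused lifetable tests.
one_stratum_inputs <- function(sex = "female", age_group = 90L,
                               pop = 1000, acm = 0.25,
                               ihd_inc = 0.02, ihd_prev = 0.2,
                               ihd_mort = 0.02, ihd_yld_rate = 0.02,
                               other_yld_rate = 0.1) {
  stratified_inputs(
    demography = tibble::tibble(sex = sex, age_group = age_group,
                                pop = pop, acm = acm),
    epi = tibble::tibble(sex = sex, age_group = age_group,
                         ihd_inc = ihd_inc, ihd_prev = ihd_prev,
                         ihd_mort = ihd_mort, ihd_yld_rate = ihd_yld_rate,
                         other_yld_rate = other_yld_rate),
    intake = tibble::tibble(sex = sex, age_group = age_group,
                            mean_e_pct = 0.3, sd_e_pct = 0.1),
    rr = tibble::tibble(age_group = age_group, rr_per_2e = 1.23,
                        ln_rr_sd = 0.054),
    costs_health = tibble::tibble(
      sex = sex, age_group = age_group,
      ihd_incident_cost = 400, ihd_incident_min = 200, ihd_incident_max = 600,
      ihd_prevalent_cost = 150, ihd_prevalent_min = 75, ihd_prevalent_max = 225,
      nonihd_percap = 100
    ),
    policy = policy_costs(gov_oneoff = 1000, gov_annual = 500,
                          industry_products = 10,
                          industry_cost_per_product = 100),
    complete = FALSE
  )
}

# Fake cohort trajectory with prescribed per-year vectors (zeros elsewhere),
# for exact aggregation arithmetic tests.
fake_cohort <- function(sex = "female", entry_age = 20L, n = 5L,
                        int_halys = numeric(n), int_cases = numeric(n),
                        ref_cases = numeric(n)) {
  zero <- numeric(n)
  arm <- function(halys, cases) {
    list(alive = numeric(n + 1L), person_years = zero, ihd_cases = cases,
         ihd_deaths = zero, ihd_prevalent_py = zero, halys = halys,
         ihd_cost = zero, nonihd_cost = zero)
  }
  structure(
    list(sex = sex, entry_age = entry_age,
         ref = arm(zero, ref_cases), int = arm(int_halys, int_cases)),
    class = "cohort_trajectory"
  )
}

# Extract one value from a tidy pipeline summary.
pick <- function(summary, outcome, horizon = "10y", sex = "both") {
  v <- summary$value[summary$outcome == outcome & summary$horizon == horizon &
                       summary$sex == sex]
  stopifnot(length(v) == 1)
  v
}

# Independent ODE oracle for the illness-death system via deSolve.
ode_disease <- function(s0, c0, i, f, times = c(0, 1)) {
  deSolve::ode(
    y = c(s = s0, c = c0, d = 0, py = 0),
    times = times,
    func = function(t, y, p) {
      list(c(-i * y[1], i * y[1] - f * y[2], f * y[2], y[1] + y[2]))
    },
    rtol = 1e-12, atol = 1e-14
  )
}
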