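# Multiple-cohort proportional multistate lifetable.
#
# Each (sex, 5-year band) cohort enters at its band's lower age and is
# simulated by single year of age until 100. Within each arm (reference /
# intervention) the disease submodel is advanced with arm-specific incidence;
# the lifetable all-cause hazard is
#   m_arm(a) = acm(a) - ihd_mort_input(a) + ihd_mortality_rate_arm(a)
# i.e. the input IHD mortality embedded in all-cause mortality is replaced by
# the modelled cause-specific rate. Survivorship uses an exponential
# within-year hazard, person-years the trapezoid rule, and health-adjusted
# person-years subtract prevalent-disability time from IHD (via a per-case
# disability weight) and from all other causes.

# Per-sex age-expanded input vectors (ages 20..99, index age - 19).
# Rates are piecewise constant within 5-year bands (step interpolation).
expand_sex <- function(inputs, sex, cost_draws = NULL) {
  pick <- function(tab) tab[tab$sex == sex, , drop = FALSE]
  d <- pick(inputs$demography)
  e <- pick(inputs$epi)
  ch <- pick(inputs$costs_health)
  cf <- derive_case_fatality(e)
  ages <- 20:(MODEL_CEILING - 1L)
  idx <- match(age_to_band(ages), d$age_group)
  dw <- ifelse(e$ihd_prev > 0, e$ihd_yld_rate / e$ihd_prev, 0)
  if (any(dw < 0 | dw > 1)) {
    k <- which(dw < 0 | dw > 1)[1]
    stop(sprintf("implied IHD disability weight outside [0, 1] for (%s, %d)",
                 sex, e$age_group[k]))
  }
  inc_cost <- ch$ihd_incident_cost
  prev_cost <- ch$ihd_prevalent_cost
  nonihd <- ch$nonihd_percap
  if (!is.null(cost_draws)) {
    inc_cost <- qtriangular(cost_draws$u_incident, ch$ihd_incident_min,
                            ch$ihd_incident_cost, ch$ihd_incident_max)
    prev_cost <- qtriangular(cost_draws$u_prevalent, ch$ihd_prevalent_min,
                             ch$ihd_prevalent_cost, ch$ihd_prevalent_max)
    if (cost_draws$cost_cv > 0) {
      nonihd <- pmax(qnorm(cost_draws$u_nonihd, ch$nonihd_percap,
                           cost_draws$cost_cv * ch$nonihd_percap), 0)
    }
  }
  list(
    sex = sex, ages = ages,
    acm = d$acm[idx], pop = stats::setNames(d$pop, d$age_group),
    inc = e$ihd_inc[idx], prev = e$ihd_prev[idx], mort = e$ihd_mort[idx],
    cf = cf$case_fatality[idx], dw = dw[idx],
    oyld = e$other_yld_rate[idx],
    inc_cost = inc_cost[idx], prev_cost = prev_cost[idx], nonihd = nonihd[idx]
  )
}

# Run one arm of one cohort. pif_age is a vector over ages 20..99 (0 for the
# reference arm). Returns per-year vectors (year 1 = entry age).
arm_run <- function(ev, entry_age, pif_age, pop0) {
  n <- MODEL_CEILING - entry_age
  i0 <- entry_age - 19L
  alive <- numeric(n + 1L)
  alive[1L] <- pop0
  py <- cases <- deaths <- prevpy <- halys <- ihd_cost <- nonihd_cost <- numeric(n)
  cst <- ev$prev[i0]
  sst <- 1 - cst
  for (t in seq_len(n)) {
    k <- i0 + t - 1L
    pif <- pif_age[k]
    if (pif > 1) stop("pif > 1 implies negative incidence")
    i <- ev$inc[k] * (1 - pif)
    f <- ev$cf[k]
    z <- disease_step_core(sst, cst, i, f)
    denom <- z$int_s + z$int_c
    rate <- if (denom > 0) f * z$int_c / denom else 0
    m <- ev$acm[k] - ev$mort[k] + rate
    if (m < 0) {
      stop(sprintf("negative all-cause hazard at age %d (%s): acm < input IHD mortality",
                   ev$ages[k], ev$sex))
    }
    a1 <- alive[t] * exp(-m)
    alive[t + 1L] <- a1
    p <- (alive[t] + a1) / 2
    py[t] <- p
    if (denom > 0) {
      cases[t] <- p * i * z$int_s / denom
      prevpy[t] <- p * z$int_c / denom
    }
    deaths[t] <- p * rate
    halys[t] <- max(p * (1 - ev$oyld[k]) - prevpy[t] * ev$dw[k], 0)
    ihd_cost[t] <- cases[t] * ev$inc_cost[k] + prevpy[t] * ev$prev_cost[k]
    nonihd_cost[t] <- p * ev$nonihd[k]
    sst <- z$s1
    cst <- z$c1
  }
  list(alive = alive, person_years = py, ihd_cases = cases,
       ihd_deaths = deaths, ihd_prevalent_py = prevpy, halys = halys,
       ihd_cost = ihd_cost, nonihd_cost = nonihd_cost)
}

#' Simulate one cohort under reference and intervention exposure
#'
#' Runs the illness-death submodel and lifetable for a single (sex, entry age)
#' cohort until age 100, in both arms. The intervention arm applies the
#' potential impact fraction to IHD incidence at every attained age; both arms
#' share all other inputs.
#'
#' @param inputs A validated `stratified_inputs` object.
#' @param sex `"female"` or `"male"`.
#' @param entry_age Cohort entry age: the lower bound of its 5-year band.
#' @param pif Either a single PIF applied at all ages, or a PIF table from
#'   [compute_pif_table()] (rows for `sex` are used, matched by age band).
#' @return An object of class `cohort_trajectory`: a list with `sex`,
#'   `entry_age`, and per-arm (`ref`, `int`) per-year vectors `alive`,
#'   `person_years`, `ihd_cases`, `ihd_deaths`, `ihd_prevalent_py`, `halys`,
#'   `ihd_cost`, `nonihd_cost`. Use `as_tibble()` for a tidy view.
#' @export
run_cohort <- function(inputs, sex, entry_age, pif = 0) {
  stopifnot(inherits(inputs, "stratified_inputs"),
            sex %in% SEXES, entry_age %in% AGE_LOWER)
  ev <- expand_sex(inputs, sex)
  pif_age <- pif_vector(pif, sex)
  pop0 <- ev$pop[[as.character(entry_age)]]
  structure(
    list(
      sex = sex, entry_age = entry_age,
      ref = arm_run(ev, entry_age, numeric(80L), pop0),
      int = arm_run(ev, entry_age, pif_age, pop0)
    ),
    class = "cohort_trajectory"
  )
}

# Expand a scalar PIF or a pif table into a by-age vector (ages 20..99).
pif_vector <- function(pif, sex) {
  if (is.numeric(pif) && length(pif) == 1L) {
    return(rep(pif, 80L))
  }
  stopifnot(is.data.frame(pif), all(c("sex", "age_group", "pif") %in% names(pif)))
  p <- pif[pif$sex == sex, , drop = FALSE]
  idx <- match(age_to_band(20:99), p$age_group)
  if (anyNA(idx)) stop("pif table does not cover all age bands")
  p$pif[idx]
}

#' @export
as_tibble.cohort_trajectory <- function(x, ...) {
  n <- length(x$ref$person_years)
  one <- function(arm, label) {
    tibble::tibble(
      sex = x$sex, entry_age = x$entry_age, arm = label,
      year = seq_len(n), age = x$entry_age + seq_len(n) - 1L,
      alive = arm$alive[-(n + 1L)],
      person_years = arm$person_years, ihd_cases = arm$ihd_cases,
      ihd_deaths = arm$ihd_deaths, ihd_prevalent_py = arm$ihd_prevalent_py,
      halys = arm$halys, ihd_cost = arm$ihd_cost, nonihd_cost = arm$nonihd_cost
    )
  }
  dplyr::bind_rows(one(x$ref, "reference"), one(x$int, "intervention"))
}

#' Health-adjusted person-years for one lifetable year
#'
#' `person_years * (1 - other_yld_rate) - ihd_prevalent_py * dw_ihd`, floored
#' at 0: person-time is down-weighted by the prevalent years-lived-with-
#' disability rate from all other causes, and time lived with IHD additionally
#' by the per-case IHD disability weight (`ihd_yld_rate / ihd_prev`).
#'
#' @param person_years Person-years lived in the year.
#' @param ihd_prevalent_py Person-years lived with IHD (`<= person_years`).
#' @param other_yld_rate YLD rate from all non-IHD causes, per person-year.
#' @param dw_ihd Per-case IHD disability weight, in `[0, 1]`.
#' @return Health-adjusted person-years.
#' @export
#' @examples
#' halys_for_year(100, 10, other_yld_rate = 0.05, dw_ihd = 0.1) # 94
halys_for_year <- function(person_years, ihd_prevalent_py, other_yld_rate,
                           dw_ihd) {
  stopifnot(all(person_years >= ihd_prevalent_py), all(ihd_prevalent_py >= 0))
  if (any(dw_ihd < 0 | dw_ihd > 1)) stop("dw_ihd must lie in [0, 1]")
  if (any(other_yld_rate < 0 | other_yld_rate > 1)) {
    stop("other_yld_rate must lie in [0, 1]")
  }
  pmax(person_years * (1 - other_yld_rate) - ihd_prevalent_py * dw_ihd, 0)
}

#' Discount factors
#'
#' @param n Number of years.
#' @param rate Annual discount rate.
#' @return `(1 + rate)^-(0:(n-1))`: the first simulation year is discounted
#'   with exponent 0.
#' @export
discount_factors <- function(n, rate) {
  stopifnot(rate >= 0)
  (1 + rate)^(-(seq_len(n) - 1L))
}

# Sum cohort per-year vectors into per-sex population streams over calendar
# years 1..80 (year 1 = first simulation year for every cohort).
pop_streams <- function(cohorts) {
  vars <- c("person_years", "ihd_cases", "ihd_deaths", "ihd_prevalent_py",
            "halys", "ihd_cost", "nonihd_cost")
  tmax <- 80L
  acc <- list()
  for (sex in SEXES) {
    acc[[sex]] <- list(
      ref = lapply(stats::setNames(vars, vars), function(v) numeric(tmax)),
      int = lapply(stats::setNames(vars, vars), function(v) numeric(tmax))
    )
  }
  for (co in cohorts) {
    n <- length(co$ref$person_years)
    for (arm in c("ref", "int")) {
      for (v in vars) {
        acc[[co$sex]][[arm]][[v]][seq_len(n)] <-
          acc[[co$sex]][[arm]][[v]][seq_len(n)] + co[[arm]][[v]]
      }
    }
  }
  acc
}

#' Aggregate cohort trajectories over reporting horizons
#'
#' Sums intervention-minus-reference differences in IHD events, IHD deaths and
#' HALYs (and healthcare cost components) across cohorts within each reporting
#' horizon, by sex and for both sexes combined (computed as female + male so
#' that sex-specific results sum exactly to totals). Event and death counts
#' are undiscounted; HALYs and costs are discounted at `discount_rate`, with
#' the first simulation year discounted with exponent 0.
#'
#' @param cohorts List of [run_cohort()] results (all 30 cohorts for a full
#'   population run).
#' @param horizons Numeric horizons in years; `Inf` denotes the population
#'   lifetime (all cohorts extinct or at age 100).
#' @param discount_rate Annual discount rate (default 0.03).
#' @return Tidy tibble with columns `horizon`, `sex`, `outcome`, `value`.
#'   Outcomes: `ihd_events`, `ihd_deaths` (undiscounted differences; negative
#'   means averted), `ihd_events_pct`, `ihd_deaths_pct` (percent of the
#'   reference-arm totals), `halys` (discounted HALYs gained),
#'   `ihd_healthcare_cost`, `nonihd_healthcare_cost`, `total_healthcare_cost`
#'   (discounted cost differences).
#' @export
aggregate_population <- function(cohorts, horizons = c(5, 10, Inf),
                                 discount_rate = 0.03) {
  if (length(horizons) == 0) stop("no horizons requested")
  tmax <- 80L
  if (any(is.finite(horizons) & (horizons < 1 | horizons > tmax))) {
    stop(sprintf("horizons must lie in [1, %d] years (or Inf for lifetime)", tmax))
  }
  acc <- pop_streams(cohorts)
  disc <- discount_factors(tmax, discount_rate)
  rows <- list()
  for (h in horizons) {
    hh <- min(h, tmax)
    w <- seq_len(hh)
    per_sex <- list()
    for (sex in SEXES) {
      a <- acc[[sex]]
      delta <- function(v, discounted = FALSE) {
        dv <- a$int[[v]][w] - a$ref[[v]][w]
        if (discounted) sum(dv * disc[w]) else sum(dv)
      }
      ihd_c <- delta("ihd_cost", TRUE)
      non_c <- delta("nonihd_cost", TRUE)
      per_sex[[sex]] <- c(
        ihd_events = delta("ihd_cases"),
        ihd_deaths = delta("ihd_deaths"),
        halys = delta("halys", TRUE),
        ihd_healthcare_cost = ihd_c,
        nonihd_healthcare_cost = non_c,
        total_healthcare_cost = ihd_c + non_c,
        ref_events = sum(a$ref$ihd_cases[w]),
        ref_deaths = sum(a$ref$ihd_deaths[w])
      )
    }
    both <- per_sex$female + per_sex$male
    # keep the decomposition total = ihd + nonihd exact at the combined level
    # (floating-point addition is not associative across the two identities)
    both[["total_healthcare_cost"]] <-
      both[["ihd_healthcare_cost"]] + both[["nonihd_healthcare_cost"]]
    per_sex$both <- both
    for (sex in c("female", "male", "both")) {
      v <- per_sex[[sex]]
      out <- c(
        v[c("ihd_events", "ihd_deaths", "halys", "ihd_healthcare_cost",
            "nonihd_healthcare_cost", "total_healthcare_cost")],
        ihd_events_pct = unname(100 * v["ihd_events"] / v["ref_events"]),
        ihd_deaths_pct = unname(100 * v["ihd_deaths"] / v["ref_deaths"])
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        horizon = horizon_label(h), sex = sex,
        outcome = names(out), value = unname(out)
      )
    }
  }
  dplyr::bind_rows(rows)
}
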