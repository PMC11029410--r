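# Synthetic GBD-style model inputs.
#
# Generates a complete, internally consistent 30-stratum input set so the full
# pipeline can run and be tested without any external data. Shapes follow the
# qualitative age pattern of GBD-type exports: Gompertz all-cause mortality,
# log-linear IHD incidence in age, a declining population pyramid, lognormal
# trans-fat intake distributions. Crucially, IHD prevalence is *derived* from
# incidence and case fatality by integrating the illness-death occupancy ODE
#   p'(a) = (1 - p) (i(a) - f p)
# across age, and IHD cause-specific mortality is f * prevalence, so the
# epidemiology is self-consistent under the package's own disease model
# (mirroring the mutual consistency of incidence, prevalence, case fatality
# and mortality that DisMod-style processing enforces in real inputs).

#' Configuration for the synthetic input generator
#'
#' Defaults emulate a populous lower-middle-income country with low trans-fat
#' intake: stratum mean intakes in 0.25-0.31 %E, relative risk 1.23 per 2%E,
#' and epidemiology/cost levels of plausible magnitude. They are structural
#' stand-ins, not estimates for any real population.
#'
#' @param seed RNG seed (the generator is deterministic given the seed).
#' @param intake_mean_range Interval (in %E) from which stratum mean intakes
#'   are drawn uniformly; must lie within `[0, 2]` %E.
#' @param intake_cv Coefficient of variation of intake within a stratum
#'   (SD = `intake_cv * mean`).
#' @param acm_gompertz All-cause mortality: `list(rate20, log_slope,
#'   male_ratio)` giving rate at age 20 and the Gompertz log-slope per year.
#' @param ihd_inc_shape IHD incidence: `list(onset_age, rate_at_onset,
#'   log_slope, male_ratio)`; zero below the onset age.
#' @param case_fatality_level Annual IHD case fatality rate (flat in age).
#' @param pop_pyramid `list(total, decline_rate)`: total adult population and
#'   the exponential decline of band size with age.
#' @param cost_levels `list(ihd_incident, ihd_prevalent, nonihd_base,
#'   nonihd_age_slope)` in USD; triangular bounds are mode -/+ 50%.
#' @param rr_per_2e Relative risk of incident IHD per 2%E (default 1.23).
#' @param ln_rr_sd SD of log RR for Monte Carlo draws (default 0.054,
#'   consistent with a 95% CI of roughly 1.11-1.37 around 1.23).
#' @param dw_ihd Per-case IHD disability weight (default 0.05).
#' @param policy A [policy_costs()] object for the generated config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         intake_mean_range = c(0.25, 0.31),
                         intake_cv = 0.3,
                         acm_gompertz = list(rate20 = 0.003, log_slope = 0.075,
                                             male_ratio = 1.15),
                         ihd_inc_shape = list(onset_age = 30,
                                              rate_at_onset = 6e-4,
                                              log_slope = 0.06,
                                              male_ratio = 1.4),
                         case_fatality_level = 0.08,
                         pop_pyramid = list(total = 9e7, decline_rate = 0.045),
                         cost_levels = list(ihd_incident = 400,
                                            ihd_prevalent = 150,
                                            nonihd_base = 55,
                                            nonihd_age_slope = 0.6),
                         rr_per_2e = 1.23,
                         ln_rr_sd = 0.054,
                         dw_ihd = 0.05,
                         policy = policy_costs(
                           gov_oneoff = 2.5e5, gov_annual = 2.2e5,
                           industry_products = 331,
                           industry_cost_per_product = 32000,
                           industry_annual_frac = 0.01
                         )) {
  stopifnot(length(intake_mean_range) == 2,
            intake_mean_range[1] >= 0, intake_mean_range[2] <= 2,
            intake_mean_range[1] <= intake_mean_range[2],
            intake_cv >= 0, case_fatality_level >= 0,
            rr_per_2e > 0, ln_rr_sd >= 0, dw_ihd >= 0, dw_ihd <= 1)
  structure(
    list(seed = seed, intake_mean_range = intake_mean_range,
         intake_cv = intake_cv, acm_gompertz = acm_gompertz,
         ihd_inc_shape = ihd_inc_shape,
         case_fatality_level = case_fatality_level,
         pop_pyramid = pop_pyramid, cost_levels = cost_levels,
         rr_per_2e = rr_per_2e, ln_rr_sd = ln_rr_sd, dw_ihd = dw_ihd,
         policy = policy),
    class = "synth_config"
  )
}

# Banded rate helpers (value at the band midpoint, constant within the band).
synth_acm <- function(cfg, sex, age_mid) {
  g <- cfg$acm_gompertz
  ratio <- if (sex == "male") g$male_ratio else 1
  ratio * g$rate20 * exp(g$log_slope * (age_mid - 20))
}

synth_inc <- function(cfg, sex, age_mid) {
  s <- cfg$ihd_inc_shape
  ratio <- if (sex == "male") s$male_ratio else 1
  ifelse(age_mid < s$onset_age, 0,
         ratio * s$rate_at_onset * exp(s$log_slope * (age_mid - s$onset_age)))
}

# Prevalence trajectory by single year of age from 20, under banded incidence,
# using the exact one-year illness-death solution. Case fatality within a band
# is the configured level, except that a band entered with zero prevalence
# uses 0 (the banded case fatality the model later derives as
# ihd_mort / ihd_prev is then exactly the rate that generated the data, so
# the disease submodel reproduces this trajectory without approximation).
synth_prevalence <- function(cfg, sex) {
  f_level <- cfg$case_fatality_level
  ages <- 20:99
  inc_band <- synth_inc(cfg, sex, age_to_band(ages) + 2.5)
  p <- numeric(length(ages) + 1L)
  p[1L] <- if (f_level > 0) min(synth_inc(cfg, sex, 22.5) / f_level, 0.5) else 0
  s <- 1 - p[1L]
  c <- p[1L]
  f_band <- stats::setNames(numeric(length(AGE_LOWER)), AGE_LOWER)
  f_cur <- 0
  for (k in seq_along(ages)) {
    if (as.character(ages[k]) %in% names(f_band)) { # band entry
      f_cur <- if (c / (s + c) > 0) f_level else 0
      f_band[[as.character(ages[k])]] <- f_cur
    }
    z <- disease_step_core(s, c, inc_band[k], f_cur)
    s <- z$s1
    c <- z$c1
    p[k + 1L] <- c / (s + c)
  }
  # prevalence at exact ages 20..100; band value = p at the band's lower age
  list(prev = stats::setNames(p[match(AGE_LOWER, c(ages, 100L))], AGE_LOWER),
       f = f_band)
}

#' Generate internally consistent synthetic model inputs
#'
#' @param cfg A [synth_config()].
#' @return A validated `stratified_inputs` object with 30 strata.
#'   Deterministic given `cfg$seed`. Errors if the configuration implies
#'   prevalence >= 1 or IHD mortality above all-cause mortality.
#' @export
#' @examples
#' inputs <- generate_inputs(synth_config(seed = 7))
#' inputs$epi
generate_inputs <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  strata <- all_strata()
  n <- nrow(strata)
  mid <- strata$age_group + 2.5

  intake_mean <- runif(n, cfg$intake_mean_range[1], cfg$intake_mean_range[2])
  intake <- tibble::tibble(
    sex = strata$sex, age_group = strata$age_group,
    mean_e_pct = intake_mean, sd_e_pct = cfg$intake_cv * intake_mean
  )

  acm <- mapply(function(s, a) synth_acm(cfg, s, a), strata$sex, mid)
  inc <- mapply(function(s, a) synth_inc(cfg, s, a), strata$sex, mid)
  traj_by_sex <- lapply(stats::setNames(SEXES, SEXES),
                        function(s) synth_prevalence(cfg, s))
  prev <- mapply(function(s, g) traj_by_sex[[s]]$prev[[as.character(g)]],
                 strata$sex, strata$age_group)
  fband <- mapply(function(s, g) traj_by_sex[[s]]$f[[as.character(g)]],
                  strata$sex, strata$age_group)
  if (any(prev >= 1)) stop("synthetic configuration implies prevalence >= 1")
  mort <- fband * prev
  if (any(mort > acm)) {
    stop("synthetic configuration implies ihd_mort > acm; lower case fatality or raise mortality")
  }
  epi <- tibble::tibble(
    sex = strata$sex, age_group = strata$age_group,
    ihd_inc = unname(inc), ihd_prev = unname(prev), ihd_mort = unname(mort),
    ihd_yld_rate = cfg$dw_ihd * unname(prev),
    other_yld_rate = pmin(0.04 + 0.0015 * (mid - 20), 0.25)
  )

  w <- exp(-cfg$pop_pyramid$decline_rate * (strata$age_group - 20))
  demography <- tibble::tibble(
    sex = strata$sex, age_group = strata$age_group,
    pop = cfg$pop_pyramid$total * w / sum(w),
    acm = unname(acm)
  )

  cl <- cfg$cost_levels
  nonihd <- cl$nonihd_base + cl$nonihd_age_slope * (mid - 20)
  costs_health <- tibble::tibble(
    sex = strata$sex, age_group = strata$age_group,
    ihd_incident_cost = cl$ihd_incident,
    ihd_incident_min = 0.5 * cl$ihd_incident,
    ihd_incident_max = 1.5 * cl$ihd_incident,
    ihd_prevalent_cost = cl$ihd_prevalent,
    ihd_prevalent_min = 0.5 * cl$ihd_prevalent,
    ihd_prevalent_max = 1.5 * cl$ihd_prevalent,
    nonihd_percap = nonihd
  )

  rr <- tibble::tibble(
    age_group = AGE_LOWER, rr_per_2e = cfg$rr_per_2e, ln_rr_sd = cfg$ln_rr_sd
  )

  stratified_inputs(
    demography = demography, epi = epi, intake = intake, rr = rr,
    costs_health = costs_health, policy = cfg$policy
  )
}

#' A tiny fixed worked example
#'
#' Two strata (both sexes, age band 90) with round-number rates chosen at the
#' disease-model equilibrium (prevalence = incidence / case fatality), so the
#' lifetable hazard is constant over the cohort's 10 remaining years and life
#' expectancy has a hand-computable closed form. Used in documentation and
#' exact tests.
#'
#' @return A `stratified_inputs` object with 2 strata (validated with
#'   `complete = FALSE`). Identical on every call.
#' @export
generate_worked_toy <- function() {
  strata <- tibble::tibble(sex = SEXES, age_group = c(90L, 90L))
  stratified_inputs(
    demography = tibble::tibble(
      sex = strata$sex, age_group = strata$age_group,
      pop = c(1000, 1000), acm = c(0.25, 0.30)
    ),
    epi = tibble::tibble(
      sex = strata$sex, age_group = strata$age_group,
      ihd_inc = 0.02, ihd_prev = 0.2, ihd_mort = 0.02,
      ihd_yld_rate = 0.02, other_yld_rate = 0.1
    ),
    intake = tibble::tibble(
      sex = strata$sex, age_group = strata$age_group,
      mean_e_pct = 0.3, sd_e_pct = 0.1
    ),
    rr = tibble::tibble(age_group = 90L, rr_per_2e = 1.23, ln_rr_sd = 0.054),
    costs_health = tibble::tibble(
      sex = strata$sex, age_group = strata$age_group,
      ihd_incident_cost = 400, ihd_incident_min = 200, ihd_incident_max = 600,
      ihd_prevalent_cost = 150, ihd_prevalent_min = 75, ihd_prevalent_max = 225,
      nonihd_percap = 100
    ),
    policy = policy_costs(
      gov_oneoff = 1000, gov_annual = 500,
      industry_products = 10, industry_cost_per_product = 100,
      industry_annual_frac = 0.01
    ),
    complete = FALSE
  )
}
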