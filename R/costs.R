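# Extended-healthcare-perspective cost streams.
#
# Healthcare: incident IHD events carry an acute-care cost, prevalent IHD
# person-years a follow-up cost, and every person-year alive the per-capita
# non-IHD expenditure of its stratum (so costs in added years of life are
# counted). Policy: government one-off + annual streams, industry initial
# reformulation + annual recurring fraction. Net cost = discounted policy
# costs + discounted change in total healthcare costs; negative = cost-saving.

#' Healthcare costs for one lifetable year
#'
#' @param incident_cases Incident IHD events in the year.
#' @param prevalent_py Person-years lived with IHD.
#' @param person_years Total person-years lived.
#' @param ihd_incident_cost Acute care cost per incident event, USD.
#' @param ihd_prevalent_cost Follow-up cost per prevalent case-year, USD.
#' @param nonihd_percap Non-IHD healthcare expenditure per person-year, USD.
#' @return List with `ihd` and `nonihd` USD amounts.
#' @export
#' @examples
#' healthcare_costs_year(10, 50, 1000, 200, 100, 70)
healthcare_costs_year <- function(incident_cases, prevalent_py, person_years,
                                  ihd_incident_cost, ihd_prevalent_cost,
                                  nonihd_percap) {
  stopifnot(all(c(incident_cases, prevalent_py, person_years) >= 0))
  list(
    ihd = incident_cases * ihd_incident_cost + prevalent_py * ihd_prevalent_cost,
    nonihd = person_years * nonihd_percap
  )
}

#' Policy implementation cost schedule
#'
#' Year 1 carries the government one-off cost plus the initial industry
#' reformulation outlay (`products * cost_per_product`); every year (including
#' year 1) carries the recurring government cost plus the recurring industry
#' fraction of the initial outlay.
#'
#' @param policy A [policy_costs()] object.
#' @param horizon_years Number of years to schedule (>= 1).
#' @param no_industry_cost Zero out the industry stream (sensitivity analysis
#'   assuming reformulation is part of the normal product life cycle).
#' @param monitoring_scale Multiplier on the recurring government stream
#'   (e.g. 1.5 for 50% greater monitoring costs).
#' @param industry_scale Multiplier on the industry stream (2 doubles the
#'   product count).
#' @param draws Optional Monte Carlo draws (list with `gov_oneoff`,
#'   `gov_annual`, `industry_initial`, `industry_annual`) replacing the
#'   central amounts.
#' @return Tibble with columns `year`, `gov`, `industry` (USD per year,
#'   undiscounted).
#' @export
policy_cost_schedule <- function(policy, horizon_years,
                                 no_industry_cost = FALSE,
                                 monitoring_scale = 1,
                                 industry_scale = 1,
                                 draws = NULL) {
  stopifnot(inherits(policy, "policy_costs"), horizon_years >= 1)
  h <- as.integer(horizon_years)
  initial <- policy$industry_products * policy$industry_cost_per_product
  gov_oneoff <- draws$gov_oneoff %||% policy$gov_oneoff
  gov_annual <- draws$gov_annual %||% policy$gov_annual
  ind_initial <- draws$industry_initial %||% initial
  ind_annual <- draws$industry_annual %||% (policy$industry_annual_frac * initial)
  gov <- rep(gov_annual * monitoring_scale, h)
  gov[1L] <- gov[1L] + gov_oneoff
  industry <- rep(ind_annual, h)
  industry[1L] <- industry[1L] + ind_initial
  industry <- industry * industry_scale
  if (no_industry_cost) industry[] <- 0
  tibble::tibble(year = seq_len(h), gov = gov, industry = industry)
}

#' Discounted net cost
#'
#' Discounted sum of annual policy costs plus the annual change
#' (intervention minus reference) in total healthcare costs. A negative net
#' cost indicates a cost-saving intervention.
#'
#' @param healthcare_delta Per-year change in total healthcare costs, USD.
#' @param policy_costs_by_year Per-year policy costs, USD (same length).
#' @param discount_rate Annual discount rate.
#' @return Discounted net cost, USD.
#' @export
net_cost <- function(healthcare_delta, policy_costs_by_year, discount_rate) {
  stopifnot(length(healthcare_delta) == length(policy_costs_by_year))
  disc <- discount_factors(length(healthcare_delta), discount_rate)
  sum((healthcare_delta + policy_costs_by_year) * disc)
}
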