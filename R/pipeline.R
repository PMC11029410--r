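# Full deterministic pipeline: exposure shift -> PIF -> disease model ->
# lifetable -> healthcare and policy costs -> summary.

#' Run the full cost-effectiveness pipeline once
#'
#' Executes one deterministic pass of the model: applies the scenario's input
#' scalings, computes per-stratum potential impact fractions, simulates all 30
#' cohorts in both arms, aggregates health outcomes and healthcare costs over
#' the reporting horizons, adds the policy cost schedule, and derives net
#' costs, the ICER and the return on government investment. When `draws` is
#' supplied (one Monte Carlo realisation from [draw_set()]) the drawn values
#' replace the central intake means, relative risks and unit costs.
#'
#' @param inputs A validated `stratified_inputs` object.
#' @param scn A [scenario()].
#' @param draws Optional [draw_set()] realisation.
#' @return Tidy summary tibble (`horizon`, `sex`, `outcome`, `value`):
#'   the [aggregate_population()] outcomes plus, for `sex = "both"`,
#'   `gov_cost`, `industry_cost`, `implementation_cost`, `net_cost` (all
#'   discounted USD), `icer` (USD per HALY gained) and `roi` (healthcare
#'   savings per USD of government spending).
#' @export
run_pipeline <- function(inputs, scn = scenario(), draws = NULL) {
  stopifnot(inherits(inputs, "stratified_inputs"), inherits(scn, "pmslt_scenario"))
  inputs <- apply_scenario(inputs, scn)
  pifs <- compute_pif_table(inputs, scn,
                            intake_means = draws$intake_means,
                            rr_draws = draws$rr)
  cohorts <- list()
  for (sex in SEXES) {
    ev <- expand_sex(inputs, sex, cost_draws = draws$costs)
    pif_age <- pif_vector(pifs, sex)
    for (entry in AGE_LOWER) {
      pop0 <- ev$pop[[as.character(entry)]]
      cohorts[[length(cohorts) + 1L]] <- structure(
        list(sex = sex, entry_age = entry,
             ref = arm_run(ev, entry, numeric(80L), pop0),
             int = arm_run(ev, entry, pif_age, pop0)),
        class = "cohort_trajectory"
      )
    }
  }
  summary <- aggregate_population(cohorts, scn$horizons, scn$discount_rate)
  sched <- policy_cost_schedule(
    inputs$policy, horizon_years = 80L,
    no_industry_cost = scn$no_industry_cost,
    monitoring_scale = scn$monitoring_scale,
    industry_scale = scn$industry_scale,
    draws = draws$policy
  )
  disc <- discount_factors(80L, scn$discount_rate)
  rows <- list(summary)
  for (h in scn$horizons) {
    hh <- min(h, 80L)
    w <- seq_len(hh)
    lab <- horizon_label(h)
    gov <- sum(sched$gov[w] * disc[w])
    industry <- sum(sched$industry[w] * disc[w])
    hc <- summary$value[summary$horizon == lab & summary$sex == "both" &
                          summary$outcome == "total_healthcare_cost"]
    hl <- summary$value[summary$horizon == lab & summary$sex == "both" &
                          summary$outcome == "halys"]
    net <- hc + gov + industry
    icer_val <- if (hl != 0) net / hl else NA_real_
    roi_val <- if (gov > 0) -hc / gov else NA_real_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      horizon = lab, sex = "both",
      outcome = c("gov_cost", "industry_cost", "implementation_cost",
                  "net_cost", "icer", "roi"),
      value = c(gov, industry, gov + industry, net, icer_val, roi_val)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scenario") <- scn$name
  out
}
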