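# Scenario definitions and the deterministic sensitivity / threshold plan.

#' Define an analysis scenario
#'
#' A scenario bundles the exposure counterfactual with the economic settings
#' and sensitivity toggles.
#'
#' @param name Scenario label.
#' @param post_intake Counterfactual [intake_distribution()]; the default
#'   (point mass at 0%E) represents complete elimination of industrial
#'   trans-fat. `NULL` means "no change" (a null policy with PIF = 0 in every
#'   stratum, useful for calibration checks).
#' @param tmrel Theoretical-minimum-risk intake, %E (default 0).
#' @param discount_rate Annual discount rate for HALYs and costs (default
#'   0.03).
#' @param horizons Reporting horizons in years; `Inf` = population lifetime.
#' @param intake_scale Multiplier on the pre-intervention intake mean and SD
#'   (0.5 and 1.5 in sensitivity analyses).
#' @param intake_shift Absolute reduction of the reference intake mean, %E,
#'   for the partial-compliance threshold analysis; when positive it replaces
#'   `post_intake` as the counterfactual (SD kept, mean floored at 0).
#' @param no_industry_cost Drop industry reformulation costs.
#' @param monitoring_scale Multiplier on the recurring government cost stream.
#' @param industry_scale Multiplier on the industry cost stream (2 = doubled
#'   product count).
#' @param ce_threshold Cost-effectiveness threshold, USD per HALY gained
#'   (default 374; an ICER strictly below it is classified cost-effective).
#' @return A list of class `pmslt_scenario`.
#' @export
scenario <- function(name = "primary",
                     post_intake = intake_distribution(0, 0),
                     tmrel = 0,
                     discount_rate = 0.03,
                     horizons = c(5, 10, Inf),
                     intake_scale = 1,
                     intake_shift = 0,
                     no_industry_cost = FALSE,
                     monitoring_scale = 1,
                     industry_scale = 1,
                     ce_threshold = 374) {
  stopifnot(discount_rate >= 0, intake_shift >= 0, intake_scale > 0,
            monitoring_scale >= 0, industry_scale >= 0, tmrel >= 0,
            length(horizons) >= 1)
  structure(
    list(name = name, post_intake = post_intake, tmrel = tmrel,
         discount_rate = discount_rate, horizons = horizons,
         intake_scale = intake_scale, intake_shift = intake_shift,
         no_industry_cost = no_industry_cost,
         monitoring_scale = monitoring_scale, industry_scale = industry_scale,
         ce_threshold = ce_threshold),
    class = "pmslt_scenario"
  )
}

#' Apply scenario input scalings
#'
#' Currently scales the pre-intervention intake mean and SD by
#' `intake_scale`; all other scenario settings act downstream (on the
#' counterfactual, discounting, or the policy cost schedule).
#'
#' @param inputs A `stratified_inputs` object.
#' @param scn A [scenario()].
#' @return The scaled `stratified_inputs`.
#' @export
apply_scenario <- function(inputs, scn) {
  if (scn$intake_scale != 1) {
    inputs$intake$mean_e_pct <- inputs$intake$mean_e_pct * scn$intake_scale
    inputs$intake$sd_e_pct <- inputs$intake$sd_e_pct * scn$intake_scale
  }
  inputs
}

#' The standard sensitivity and threshold analysis plan
#'
#' Named scenario variants: the primary analysis; 0% and 6% discount rates;
#' pre-intervention intake scaled by 0.5 and 1.5 (mean and SD); a residual
#' post-intervention intake of 0.1 +/- 0.01 %E; doubled product count; no
#' industry costs; 50% greater monitoring costs; and partial-compliance
#' threshold reductions of 0.05-0.20 %E.
#'
#' @param horizons Reporting horizons passed to every variant.
#' @return Named list of [scenario()] objects; `primary` is always first.
#' @export
analysis_plan <- function(horizons = c(5, 10, Inf)) {
  s <- function(name, ...) scenario(name = name, horizons = horizons, ...)
  plan <- list(
    primary = s("primary"),
    discount_0 = s("discount_0", discount_rate = 0),
    discount_6 = s("discount_6", discount_rate = 0.06),
    intake_x0.5 = s("intake_x0.5", intake_scale = 0.5),
    intake_x1.5 = s("intake_x1.5", intake_scale = 1.5),
    post_intake_0.1 = s("post_intake_0.1",
                        post_intake = intake_distribution(0.1, 0.01)),
    products_x2 = s("products_x2", industry_scale = 2),
    no_industry_cost = s("no_industry_cost", no_industry_cost = TRUE),
    monitoring_x1.5 = s("monitoring_x1.5", monitoring_scale = 1.5),
    threshold_0.05 = s("threshold_0.05", intake_shift = 0.05),
    threshold_0.10 = s("threshold_0.10", intake_shift = 0.10),
    threshold_0.15 = s("threshold_0.15", intake_shift = 0.15),
    threshold_0.20 = s("threshold_0.20", intake_shift = 0.20)
  )
  stopifnot(!anyDuplicated(names(plan)))
  plan
}

#' Run an analysis plan
#'
#' Runs each scenario variant through the full pipeline: the deterministic
#' central run when `n_iter = 0`, otherwise a Monte Carlo uncertainty analysis
#' with `n_iter` iterations. Each variant uses the same seed, so variants are
#' independent of each other's presence in the plan. A variant that fails
#' validation is reported and skipped; the others continue.
#'
#' @param inputs A validated `stratified_inputs` object.
#' @param plan Named list of [scenario()]s (default [analysis_plan()]).
#' @param n_iter Monte Carlo iterations per variant (0 = central run only).
#' @param seed RNG seed used for every variant.
#' @return List with `variants` (per-variant results: a summary tibble, or a
#'   `mc_summary` when `n_iter > 0`), `comparison` (net cost, HALYs, ICER and
#'   probabilities per variant and horizon) and `errors` (named character
#'   vector of failed variants).
#' @export
run_plan <- function(inputs, plan = analysis_plan(), n_iter = 0, seed = 1) {
  stopifnot(is.list(plan), length(plan) >= 1, !is.null(names(plan)))
  variants <- list()
  errors <- character()
  comp <- list()
  for (nm in names(plan)) {
    scn <- plan[[nm]]
    res <- tryCatch(
      if (n_iter > 0) {
        run_monte_carlo(inputs, scn, n_iter = n_iter, seed = seed)
      } else {
        run_pipeline(inputs, scn)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[nm] <- conditionMessage(res)
      warning(sprintf("variant '%s' failed: %s", nm, errors[nm]), call. = FALSE)
      next
    }
    variants[[nm]] <- res
    if (n_iter > 0) {
      sm <- res$summary
      cc <- sm[sm$outcome %in% c("net_cost", "halys", "icer"),
               c("horizon", "outcome", "mean")]
      names(cc)[names(cc) == "mean"] <- "value"
      cc <- tidyr::pivot_wider(cc, names_from = "outcome", values_from = "value")
      cc <- dplyr::left_join(cc, res$probabilities, by = "horizon")
    } else {
      cc <- res[res$outcome %in% c("net_cost", "halys", "icer") & res$sex == "both",
                c("horizon", "outcome", "value")]
      cc <- tidyr::pivot_wider(cc, names_from = "outcome", values_from = "value")
    }
    cc$variant <- nm
    comp[[nm]] <- cc
  }
  list(
    variants = variants,
    comparison = dplyr::bind_rows(comp),
    errors = errors
  )
}
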