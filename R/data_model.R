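# Input containers, validation and file IO.
#
# The input schema is a set of plain CSV tables, one row per (sex, age_group)
# stratum unless noted, plus a YAML run configuration:
#
#   demography.csv   sex, age_group, pop, acm
#   epi_ihd.csv      sex, age_group, ihd_inc, ihd_prev, ihd_mort,
#                    ihd_yld_rate, other_yld_rate
#   intake.csv       sex, age_group, mean_e_pct, sd_e_pct
#   rr.csv           age_group, rr_per_2e, ln_rr_sd          (15 rows, age only)
#   costs_health.csv sex, age_group, ihd_incident_cost, ihd_incident_min,
#                    ihd_incident_max, ihd_prevalent_cost, ihd_prevalent_min,
#                    ihd_prevalent_max, nonihd_percap
#   costs_policy.csv component, type {oneoff, annual}, amount_usd, sd_usd
#                    (government components only)
#   config.yml       industry reformulation parameters, currency, scenario
#                    defaults, Monte Carlo settings
#
# All rates are annual events per person(-year); intakes are % of total energy;
# monetary amounts are 2019 USD (the package does no inflation arithmetic, only
# USD -> NGN conversion for reporting).

#' Intake distribution (% of total energy)
#'
#' Trans-fat intake is described by its mean and standard deviation on the
#' natural %E scale. A positive-SD distribution is lognormal with
#' moment-matched parameters; `sd = 0` (or `mean = 0`) gives a degenerate
#' point mass.
#'
#' @param mean_e_pct Mean intake in %E (non-negative).
#' @param sd_e_pct Standard deviation in %E (non-negative).
#' @return A list of class `intake_distribution` with fields `mean_e_pct`,
#'   `sd_e_pct` and `family` (`"lognormal"` or `"degenerate"`).
#' @export
#' @examples
#' intake_distribution(0.28, 0.1)
#' intake_distribution(0, 0) # post-intervention elimination
intake_distribution <- function(mean_e_pct, sd_e_pct = 0) {
  stopifnot(length(mean_e_pct) == 1, length(sd_e_pct) == 1)
  if (mean_e_pct < 0) stop("intake mean_e_pct must be >= 0")
  if (sd_e_pct < 0) stop("intake sd_e_pct must be >= 0")
  family <- if (mean_e_pct > 0 && sd_e_pct > 0) "lognormal" else "degenerate"
  structure(
    list(mean_e_pct = mean_e_pct, sd_e_pct = sd_e_pct, family = family),
    class = "intake_distribution"
  )
}

#' Policy implementation cost parameters
#'
#' Government costs are a one-off legislation/setup amount plus a recurring
#' annual stream (monitoring, enforcement, campaigns). Industry costs are an
#' initial reformulation outlay (`products * cost_per_product`) plus an annual
#' recurring fraction of that outlay. Uncertain components are drawn from
#' normal distributions with SD equal to 20% of the central value in the
#' Monte Carlo analysis.
#'
#' @param gov_oneoff One-time government cost, USD, incurred in year 1.
#' @param gov_annual Recurring government cost, USD per year.
#' @param industry_products Number of food products requiring reformulation.
#' @param industry_cost_per_product Reformulation cost per product, USD.
#' @param industry_annual_frac Fraction of the initial reformulation cost
#'   recurring annually (default 0.01).
#' @param gov_oneoff_sd,gov_annual_sd Optional SDs for Monte Carlo draws;
#'   default 20% of the central value.
#' @return A list of class `policy_costs`.
#' @export
policy_costs <- function(gov_oneoff, gov_annual,
                         industry_products, industry_cost_per_product,
                         industry_annual_frac = 0.01,
                         gov_oneoff_sd = 0.2 * gov_oneoff,
                         gov_annual_sd = 0.2 * gov_annual) {
  vals <- c(gov_oneoff, gov_annual, industry_products,
            industry_cost_per_product, industry_annual_frac,
            gov_oneoff_sd, gov_annual_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("policy cost components must be finite and >= 0")
  }
  if (industry_annual_frac > 1) stop("industry_annual_frac must be in [0, 1]")
  structure(
    list(
      gov_oneoff = gov_oneoff, gov_annual = gov_annual,
      industry_products = industry_products,
      industry_cost_per_product = industry_cost_per_product,
      industry_annual_frac = industry_annual_frac,
      gov_oneoff_sd = gov_oneoff_sd, gov_annual_sd = gov_annual_sd
    ),
    class = "policy_costs"
  )
}

#' Assemble stratified model inputs
#'
#' Bundles the per-stratum input tables and scalar policy/currency parameters
#' into the validated container consumed by the pipeline. See the column
#' dictionary in `read_inputs()`.
#'
#' @param demography,epi,intake,costs_health Tibbles with one row per
#'   (sex, age_group) stratum.
#' @param rr Tibble with one row per age group (relative risks are age-specific
#'   and shared between sexes).
#' @param policy A [policy_costs()] object.
#' @param usd_to_ngn USD to Nigerian naira exchange rate (default 358).
#' @param validate Check all invariants (default `TRUE`).
#' @param complete Require the full 30-stratum set (default `TRUE`).
#' @return A list of class `stratified_inputs`.
#' @export
stratified_inputs <- function(demography, epi, intake, rr, costs_health,
                              policy, usd_to_ngn = 358,
                              validate = TRUE, complete = TRUE) {
  x <- structure(
    list(
      demography = dplyr::arrange(tibble::as_tibble(demography), sex, age_group),
      epi = dplyr::arrange(tibble::as_tibble(epi), sex, age_group),
      intake = dplyr::arrange(tibble::as_tibble(intake), sex, age_group),
      rr = dplyr::arrange(tibble::as_tibble(rr), age_group),
      costs_health = dplyr::arrange(tibble::as_tibble(costs_health), sex, age_group),
      policy = policy,
      usd_to_ngn = usd_to_ngn
    ),
    class = "stratified_inputs"
  )
  if (validate) validate_inputs(x, complete = complete)
  x
}

check_strata_complete <- function(tab, name, by_sex = TRUE) {
  want <- if (by_sex) all_strata() else tibble::tibble(age_group = AGE_LOWER)
  cols <- names(want)
  have <- unique(tab[cols])
  missing <- dplyr::anti_join(want, have, by = cols)
  if (nrow(missing) > 0) {
    m <- missing[1, ]
    lab <- if (by_sex) sprintf("(%s, %d)", m$sex, m$age_group) else
      sprintf("(age %d)", m$age_group)
    stop(sprintf("%s: missing stratum %s", name, lab), call. = FALSE)
  }
  dup <- nrow(tab) - nrow(have)
  if (dup > 0) stop(sprintf("%s: duplicated strata", name), call. = FALSE)
  invisible(TRUE)
}

fail_row <- function(table, row, msg) {
  lab <- if ("sex" %in% names(row)) {
    sprintf("(%s, %d)", row$sex, row$age_group)
  } else {
    sprintf("(age %d)", row$age_group)
  }
  stop(sprintf("%s: %s for stratum %s", table, msg, lab), call. = FALSE)
}

check_rows <- function(tab, name, cond, msg) {
  bad <- which(!cond)
  if (length(bad) > 0) fail_row(name, tab[bad[1], ], msg)
}

#' Validate stratified inputs
#'
#' Enforces every input invariant: non-negative rates, prevalence in `[0, 1)`,
#' IHD mortality not exceeding all-cause mortality, finite implied case
#' fatality (prevalence positive wherever IHD mortality is positive),
#' triangular cost bounds ordered, positive relative risks, and (optionally)
#' exact completeness of the 30-stratum set. Errors name the offending table
#' and stratum.
#'
#' @param x A `stratified_inputs` object.
#' @param complete Require all 30 strata present exactly once.
#' @return `x`, invisibly.
#' @export
validate_inputs <- function(x, complete = TRUE) {
  stopifnot(inherits(x, "stratified_inputs"))
  if (complete) {
    check_strata_complete(x$demography, "demography")
    check_strata_complete(x$epi, "epi_ihd")
    check_strata_complete(x$intake, "intake")
    check_strata_complete(x$rr, "rr", by_sex = FALSE)
    check_strata_complete(x$costs_health, "costs_health")
  }
  d <- x$demography
  check_rows(d, "demography", is.finite(d$pop) & d$pop >= 0, "negative population")
  check_rows(d, "demography", is.finite(d$acm) & d$acm >= 0, "negative mortality rate")

  e <- x$epi
  for (col in c("ihd_inc", "ihd_mort", "ihd_yld_rate", "other_yld_rate")) {
    check_rows(e, "epi_ihd", is.finite(e[[col]]) & e[[col]] >= 0,
               sprintf("negative %s", col))
  }
  check_rows(e, "epi_ihd", e$ihd_prev >= 0 & e$ihd_prev < 1,
             "ihd_prev outside [0, 1)")
  check_rows(e, "epi_ihd", e$ihd_prev > 0 | e$ihd_mort == 0,
             "ihd_mort > 0 with ihd_prev = 0 (case fatality undefined)")
  acm <- d$acm[match(paste(e$sex, e$age_group), paste(d$sex, d$age_group))]
  check_rows(e, "epi_ihd", e$ihd_mort <= acm + 1e-12, "ihd_mort > acm")

  it <- x$intake
  check_rows(it, "intake", it$mean_e_pct >= 0, "negative intake mean")
  check_rows(it, "intake", it$sd_e_pct >= 0, "negative intake SD")

  r <- x$rr
  check_rows(r, "rr", r$rr_per_2e > 0, "rr_per_2e must be > 0")
  check_rows(r, "rr", r$ln_rr_sd >= 0, "negative ln_rr_sd")

  ch <- x$costs_health
  for (col in c("ihd_incident_cost", "ihd_prevalent_cost", "nonihd_percap")) {
    check_rows(ch, "costs_health", is.finite(ch[[col]]) & ch[[col]] >= 0,
               sprintf("negative %s", col))
  }
  check_rows(ch, "costs_health",
             ch$ihd_incident_min <= ch$ihd_incident_cost &
               ch$ihd_incident_cost <= ch$ihd_incident_max,
             "triangular bounds violate min <= mode <= max (incident)")
  check_rows(ch, "costs_health",
             ch$ihd_prevalent_min <= ch$ihd_prevalent_cost &
               ch$ihd_prevalent_cost <= ch$ihd_prevalent_max,
             "triangular bounds violate min <= mode <= max (prevalent)")

  if (!inherits(x$policy, "policy_costs")) stop("policy must be a policy_costs object")
  if (!is.finite(x$usd_to_ngn) || x$usd_to_ngn <= 0) stop("usd_to_ngn must be > 0")
  invisible(x)
}

input_col_classes <- list(
  demography = c(sex = "character", age_group = "integer",
                 pop = "numeric", acm = "numeric"),
  epi_ihd = c(sex = "character", age_group = "integer", ihd_inc = "numeric",
              ihd_prev = "numeric", ihd_mort = "numeric",
              ihd_yld_rate = "numeric", other_yld_rate = "numeric"),
  intake = c(sex = "character", age_group = "integer",
             mean_e_pct = "numeric", sd_e_pct = "numeric"),
  rr = c(age_group = "integer", rr_per_2e = "numeric", ln_rr_sd = "numeric"),
  costs_health = c(sex = "character", age_group = "integer",
                   ihd_incident_cost = "numeric", ihd_incident_min = "numeric",
                   ihd_incident_max = "numeric", ihd_prevalent_cost = "numeric",
                   ihd_prevalent_min = "numeric", ihd_prevalent_max = "numeric",
                   nonihd_percap = "numeric"),
  costs_policy = c(component = "character", type = "character",
                   amount_usd = "numeric", sd_usd = "numeric")
)

# write_csv's default numeric formatting keeps 15-16 significant digits; 17
# are required for doubles to round-trip bit-exactly, so format them here.
write_csv_precise <- function(tab, path) {
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 17, format = "g"))
  readr::write_csv(tab, path)
}

# Base read.csv parses doubles with strtod (correctly rounded), which the
# bit-exact round-trip contract requires; vroom's fast parser can be off by
# an ulp in the last digit.
read_table_checked <- function(dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  cls <- input_col_classes[[name]]
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  want <- setdiff(names(cls), header)
  if (length(want) > 0) {
    stop(sprintf("%s.csv: missing column(s) %s", name,
                 paste(want, collapse = ", ")), call. = FALSE)
  }
  tab <- tryCatch(
    utils::read.csv(path, colClasses = cls, check.names = FALSE),
    error = function(e) {
      stop(sprintf("%s.csv: schema mismatch (%s)", name, conditionMessage(e)),
           call. = FALSE)
    },
    warning = function(w) {
      stop(sprintf("%s.csv: schema mismatch (%s)", name, conditionMessage(w)),
           call. = FALSE)
    }
  )
  tibble::as_tibble(tab[names(cls)])
}

#' Read and validate the model input tables
#'
#' Reads the CSV input set and YAML run configuration from a directory and
#' returns validated [stratified_inputs()]. All 30 strata must be present
#' exactly once; every type invariant is enforced, with errors naming the file
#' and stratum.
#'
#' @param dir Directory containing `demography.csv`, `epi_ihd.csv`,
#'   `intake.csv`, `rr.csv`, `costs_health.csv`, `costs_policy.csv`.
#' @param config Path to the YAML run configuration (default
#'   `file.path(dir, "config.yml")`). Supplies industry reformulation
#'   parameters and the USD/NGN rate.
#' @return A validated `stratified_inputs` object with the parsed configuration
#'   attached as attribute `"config"`.
#' @export
read_inputs <- function(dir, config = file.path(dir, "config.yml")) {
  cfg <- read_config(config)
  pol <- read_table_checked(dir, "costs_policy")
  bad <- !pol$type %in% c("oneoff", "annual")
  if (any(bad)) {
    stop(sprintf("costs_policy.csv: unknown type '%s' (component %s)",
                 pol$type[which(bad)[1]], pol$component[which(bad)[1]]), call. = FALSE)
  }
  if (any(pol$amount_usd < 0) || any(pol$sd_usd < 0)) {
    stop("costs_policy.csv: negative amount or sd", call. = FALSE)
  }
  gov_oneoff <- sum(pol$amount_usd[pol$type == "oneoff"])
  gov_annual <- sum(pol$amount_usd[pol$type == "annual"])
  # component SDs add in quadrature (independent normal components)
  gov_oneoff_sd <- sqrt(sum(pol$sd_usd[pol$type == "oneoff"]^2))
  gov_annual_sd <- sqrt(sum(pol$sd_usd[pol$type == "annual"]^2))
  ind <- cfg$industry
  policy <- policy_costs(
    gov_oneoff = gov_oneoff, gov_annual = gov_annual,
    industry_products = ind$products,
    industry_cost_per_product = ind$cost_per_product_usd,
    industry_annual_frac = ind$annual_frac,
    gov_oneoff_sd = gov_oneoff_sd, gov_annual_sd = gov_annual_sd
  )
  x <- stratified_inputs(
    demography = read_table_checked(dir, "demography"),
    epi = read_table_checked(dir, "epi_ihd"),
    intake = read_table_checked(dir, "intake"),
    rr = read_table_checked(dir, "rr"),
    costs_health = read_table_checked(dir, "costs_health"),
    policy = policy,
    usd_to_ngn = cfg$currency$usd_to_ngn
  )
  attr(x, "config") <- cfg
  x
}

#' Write the model input tables
#'
#' Inverse of [read_inputs()]: writes the six CSV tables plus `config.yml` to a
#' directory. Numeric values are written in shortest round-tripping decimal
#' form, so `read_inputs(write_inputs(x))` reproduces `x` exactly.
#'
#' @param x A `stratified_inputs` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(x, dir) {
  stopifnot(inherits(x, "stratified_inputs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_precise(x$demography, file.path(dir, "demography.csv"))
  write_csv_precise(x$epi, file.path(dir, "epi_ihd.csv"))
  write_csv_precise(x$intake, file.path(dir, "intake.csv"))
  write_csv_precise(x$rr, file.path(dir, "rr.csv"))
  write_csv_precise(x$costs_health, file.path(dir, "costs_health.csv"))
  p <- x$policy
  readr::write_csv(
    tibble::tibble(
      component = c("government_setup", "government_operations"),
      type = c("oneoff", "annual"),
      amount_usd = c(p$gov_oneoff, p$gov_annual),
      sd_usd = c(p$gov_oneoff_sd, p$gov_annual_sd)
    ),
    file.path(dir, "costs_policy.csv")
  )
  cfg <- list(
    industry = list(
      products = p$industry_products,
      cost_per_product_usd = p$industry_cost_per_product,
      annual_frac = p$industry_annual_frac
    ),
    currency = list(usd_to_ngn = x$usd_to_ngn)
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Read a run configuration file
#'
#' @param path YAML file with (at least) `industry:` (`products`,
#'   `cost_per_product_usd`, `annual_frac`) and `currency:` (`usd_to_ngn`)
#'   sections; optional `mc:` (`n_iter`) and `scenario:` sections.
#' @return A named list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    industry = list(products = 331, cost_per_product_usd = 32000, annual_frac = 0.01),
    currency = list(usd_to_ngn = 358),
    mc = list(n_iter = 2000),
    scenario = list(discount_rate = 0.03)
  )
  for (sec in names(defaults)) {
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], cfg[[sec]] %||% list())
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results summary and run manifest
#'
#' Emits the tidy results table (one row per outcome x horizon x sex) as
#' `results.csv` and a `manifest.json` run record (configuration hash, seed,
#' package version, timestamp).
#'
#' @param summary A results tibble with columns `horizon`, `sex`, `outcome`,
#'   `value` (as produced by [run_pipeline()]).
#' @param dir Output directory (created if needed).
#' @param seed Random seed used for the run (recorded in the manifest).
#' @param config Configuration object to hash into the manifest.
#' @return Invisibly, paths of the files written.
#' @export
write_results <- function(summary, dir, seed = NULL, config = NULL) {
  stopifnot(is.data.frame(summary))
  need <- c("horizon", "sex", "outcome", "value")
  if (!all(need %in% names(summary))) {
    stop("summary must have columns horizon, sex, outcome, value")
  }
  if (nrow(summary) == 0 || length(unique(summary$horizon)) == 0) {
    stop("summary has no horizons to write")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  results_path <- file.path(dir, "results.csv")
  write_csv_precise(summary, results_path)
  manifest <- list(
    package = "pmslt",
    version = as.character(utils::packageVersion("pmslt")),
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    config_hash = rlang::hash(config),
    n_rows = nrow(summary),
    horizons = unique(summary$horizon)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(results = results_path, manifest = manifest_path))
}

#' Convert USD amounts to Nigerian naira
#'
#' @param usd Numeric USD amounts.
#' @param rate Exchange rate, naira per USD (default 358, the 1 July 2019
#'   average).
#' @return `usd * rate`.
#' @export
#' @examples
#' usd_to_ngn(1e6)
usd_to_ngn <- function(usd, rate = 358) {
  stopifnot(is.numeric(rate), rate > 0)
  usd * rate
}
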