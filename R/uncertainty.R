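# Probabilistic (Monte Carlo) uncertainty analysis.
#
# Per iteration, one realisation of every uncertain input is drawn and the
# full deterministic pipeline is rerun:
#   - stratum intake means: lognormal, moment-matched to (mean, SD);
#   - relative risks: lognormal on RR (normal in log RR), independent per age
#     group, shared across sexes and arms;
#   - IHD unit costs: triangular (min, mode, max) with a common uniform
#     quantile across strata per cost type (fully correlated across strata,
#     marginally exact);
#   - non-IHD per-capita costs and policy cost components: normal with SD
#     equal to cost_cv (default 20%) of the central value, truncated at 0.
# Both arms share all draws (common random numbers).

# Inverse CDF of the triangular distribution, vectorised over all arguments.
# Degenerate support (min = mode = max) returns the mode exactly.
qtriangular <- function(p, min, mode, max) {
  stopifnot(all(min <= mode), all(mode <= max), all(p >= 0), all(p <= 1))
  n <- max(length(p), length(min), length(mode), length(max))
  p <- rep_len(p, n)
  min <- rep_len(min, n)
  mode <- rep_len(mode, n)
  max <- rep_len(max, n)
  out <- mode
  r <- max - min
  live <- r > 0
  fc <- numeric(n)
  fc[live] <- (mode[live] - min[live]) / r[live]
  lo <- live & p <= fc
  hi <- live & p > fc
  out[lo] <- min[lo] + sqrt(p[lo] * r[lo] * (mode[lo] - min[lo]))
  out[hi] <- max[hi] - sqrt((1 - p[hi]) * r[hi] * (max[hi] - mode[hi]))
  out
}

# Lognormal draw with natural-scale mean m and SD s (s = 0 -> m exactly).
rlnorm_matched <- function(n, m, s) {
  if (m <= 0 || s <= 0) return(rep(m, n))
  lp <- lognormal_params(m, s)
  rlnorm(n, lp$meanlog, lp$sdlog)
}

#' Draw one Monte Carlo realisation of all uncertain inputs
#'
#' @param inputs A `stratified_inputs` object (scenario-scaled if applicable).
#' @param cost_cv Coefficient of variation for normal cost draws (default 0.2:
#'   SD equal to 20% of the central estimate).
#' @return A `draw_set` list: `intake_means` (named by `"sex_age"`), `rr`
#'   (named by age group), `costs` (common quantiles `u_incident`,
#'   `u_prevalent`, `u_nonihd` plus `cost_cv`), `policy` (drawn USD amounts)
#'   and `truncated` (count of negative normal draws truncated to 0).
#' @export
draw_set <- function(inputs, cost_cv = 0.2) {
  it <- inputs$intake
  intake_means <- vapply(
    seq_len(nrow(it)),
    function(k) rlnorm_matched(1L, it$mean_e_pct[k], it$sd_e_pct[k]),
    numeric(1)
  )
  names(intake_means) <- paste(it$sex, it$age_group, sep = "_")
  rrtab <- inputs$rr
  rr <- exp(rnorm(nrow(rrtab), log(rrtab$rr_per_2e), rrtab$ln_rr_sd))
  # keep degenerate draws bit-identical to the central value
  rr[rrtab$ln_rr_sd == 0] <- rrtab$rr_per_2e[rrtab$ln_rr_sd == 0]
  names(rr) <- rrtab$age_group
  costs <- list(u_incident = runif(1), u_prevalent = runif(1),
                u_nonihd = runif(1), cost_cv = cost_cv)
  p <- inputs$policy
  initial <- p$industry_products * p$industry_cost_per_product
  raw <- c(
    gov_oneoff = rnorm(1, p$gov_oneoff, if (cost_cv > 0) p$gov_oneoff_sd else 0),
    gov_annual = rnorm(1, p$gov_annual, if (cost_cv > 0) p$gov_annual_sd else 0),
    industry_initial = rnorm(1, initial, cost_cv * initial),
    industry_annual = rnorm(1, p$industry_annual_frac * initial,
                            cost_cv * p$industry_annual_frac * initial)
  )
  truncated <- sum(raw < 0)
  raw <- pmax(raw, 0)
  structure(
    list(intake_means = intake_means, rr = rr, costs = costs,
         policy = as.list(raw), truncated = truncated),
    class = "draw_set"
  )
}

#' Incremental cost-effectiveness ratio with classification
#'
#' @param net_cost Discounted net cost, USD.
#' @param halys_gained Discounted HALYs gained.
#' @param threshold Cost-effectiveness threshold, USD per HALY (default 374).
#'   Classification uses strict `<`.
#' @return List with `icer` (USD/HALY; `NA` when dominated), `cost_saving`
#'   (`net_cost < 0`), `cost_effective` (cost-saving or ICER strictly below
#'   the threshold) and `dominated` (`halys_gained <= 0` with
#'   `net_cost >= 0`).
#' @export
#' @examples
#' icer(-1e6, 1000) # cost-saving
#' icer(374000, 1000) # at the threshold: not cost-effective under strict "<"
icer <- function(net_cost, halys_gained, threshold = 374) {
  dominated <- halys_gained <= 0 && net_cost >= 0
  value <- if (dominated) NA_real_ else net_cost / halys_gained
  cost_saving <- net_cost < 0
  list(
    icer = value,
    cost_saving = cost_saving,
    cost_effective = cost_saving || (!dominated && value < threshold),
    dominated = dominated
  )
}

#' Return on government investment
#'
#' @param healthcare_savings Healthcare cost-savings, USD (positive =
#'   savings).
#' @param gov_costs Government implementation costs, USD (> 0).
#' @return Savings per USD of government spending.
#' @export
#' @examples
#' roi(90e6, 2e6) # 45
roi <- function(healthcare_savings, gov_costs) {
  if (any(gov_costs <= 0)) stop("gov_costs must be > 0")
  healthcare_savings / gov_costs
}

#' Probabilities of cost-saving and cost-effectiveness
#'
#' @param net_costs Per-iteration net costs, USD.
#' @param icers Per-iteration ICERs (`NA` allowed for dominated iterations).
#' @param threshold Cost-effectiveness threshold (strict `<`).
#' @return Named vector `p_cost_saving` (fraction with net cost < 0) and
#'   `p_cost_effective` (fraction cost-saving or with ICER < threshold).
#' @export
mc_probabilities <- function(net_costs, icers, threshold = 374) {
  stopifnot(length(net_costs) >= 1, length(icers) == length(net_costs))
  saving <- net_costs < 0
  effective <- saving | (!is.na(icers) & icers < threshold)
  c(p_cost_saving = mean(saving), p_cost_effective = mean(effective))
}

mc_outcomes <- c("ihd_events", "ihd_deaths", "halys", "ihd_healthcare_cost",
                 "nonihd_healthcare_cost", "total_healthcare_cost",
                 "gov_cost", "industry_cost", "implementation_cost",
                 "net_cost", "icer", "roi")

#' Monte Carlo uncertainty analysis
#'
#' Runs `n_iter` full-pipeline iterations, each with a fresh [draw_set()], and
#' summarises the distribution of the intervention effects: means and
#' 2.5th/97.5th percentiles per outcome and horizon (both sexes combined),
#' plus the probability of the policy being cost-saving and cost-effective and
#' the return on government investment. Reproducible bit-for-bit given `seed`.
#'
#' @param inputs A validated `stratified_inputs` object.
#' @param scn A [scenario()].
#' @param n_iter Number of iterations (default 2000).
#' @param seed RNG seed.
#' @param cost_cv Coefficient of variation of the normal cost draws
#'   (default 0.2).
#' @return An object of class `mc_summary`: `summary` (tibble: `horizon`,
#'   `outcome`, `mean`, `p2.5`, `p97.5`), `probabilities` (per horizon),
#'   `draws` (iteration x outcome matrix per horizon), `central` (the
#'   central-input run), `n_iter`, `seed`, `truncated_draws`.
#' @export
run_monte_carlo <- function(inputs, scn = scenario(), n_iter = 2000, seed = 1,
                            cost_cv = 0.2) {
  stopifnot(n_iter >= 1)
  inputs <- apply_scenario(inputs, scn)
  scn_unit <- scn
  scn_unit$intake_scale <- 1 # inputs already scaled; avoid double-scaling
  labs <- horizon_label(scn$horizons)
  central <- run_pipeline(inputs, scn_unit)
  draws_by_h <- lapply(labs, function(l) {
    matrix(NA_real_, nrow = n_iter, ncol = length(mc_outcomes),
           dimnames = list(NULL, mc_outcomes))
  })
  names(draws_by_h) <- labs
  truncated <- 0L
  set.seed(seed)
  for (iter in seq_len(n_iter)) {
    ds <- draw_set(inputs, cost_cv = cost_cv)
    truncated <- truncated + ds$truncated
    res <- tryCatch(
      run_pipeline(inputs, scn_unit, draws = ds),
      error = function(e) {
        stop(sprintf("Monte Carlo iteration %d failed: %s", iter,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    both <- res[res$sex == "both", ]
    for (l in labs) {
      v <- both[both$horizon == l, ]
      draws_by_h[[l]][iter, ] <- v$value[match(mc_outcomes, v$outcome)]
    }
  }
  sum_rows <- list()
  prob_rows <- list()
  for (l in labs) {
    m <- draws_by_h[[l]]
    sum_rows[[l]] <- tibble::tibble(
      horizon = l, outcome = mc_outcomes,
      mean = colMeans(m, na.rm = TRUE),
      `p2.5` = apply(m, 2, quantile, probs = 0.025, na.rm = TRUE),
      `p97.5` = apply(m, 2, quantile, probs = 0.975, na.rm = TRUE)
    )
    pr <- mc_probabilities(m[, "net_cost"], m[, "icer"], scn$ce_threshold)
    prob_rows[[l]] <- tibble::tibble(
      horizon = l,
      p_cost_saving = pr[["p_cost_saving"]],
      p_cost_effective = pr[["p_cost_effective"]]
    )
  }
  structure(
    list(
      summary = dplyr::bind_rows(sum_rows),
      probabilities = dplyr::bind_rows(prob_rows),
      draws = draws_by_h,
      central = central,
      n_iter = n_iter, seed = seed, truncated_draws = truncated
    ),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary: %d iterations (seed %s)\n", x$n_iter,
              format(x$seed)))
  print(x$summary, n = Inf)
  print(x$probabilities)
  invisible(x)
}
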