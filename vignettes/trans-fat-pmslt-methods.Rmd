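---
title: "Methods: a proportional multistate lifetable model of trans-fat elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a proportional multistate lifetable model of trans-fat elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
```

# The model

`pmslt` estimates the health and economic consequences of removing industrial
trans-fatty acids (iTFA) from a national food supply. The comparison is
between a *reference* population with stable trans-fat intake and an
*intervention* population identical in every other respect, simulated with a
multiple-cohort proportional multistate lifetable (Markov) model:

1. **Exposure.** Trans-fat intake in each of 30 sex and 5-year-age strata is
   described by a lognormal distribution with mean and SD on the natural
   scale (% of total energy, %E). The policy counterfactual is, by default, a
   point mass at 0%E (complete elimination).
2. **Potential impact fraction (PIF).** Relative risk of incident ischaemic
   heart disease (IHD) is log-linear in intake above the
   theoretical-minimum-risk level (TMREL, 0%E): $RR(x) = \rho^{\max(x -
   \text{tmrel},\,0)/2}$ with $\rho = 1.23$ per 2%E by default. The
   continuous distribution-shift PIF per stratum is
   $$\mathrm{PIF} = 1 - \frac{E_{\text{cf}}[RR(X)]}{E_{\text{ref}}[RR(X)]},$$
   and intervention incidence is $i_\text{int} = i_\text{ref}(1 -
   \mathrm{PIF})$.
3. **Disease model.** An illness-death process (well → IHD → IHD death,
   remission fixed at 0, conditional on surviving other causes) with annual
   incidence $i$ and case fatality $f$ is advanced by exact one-year
   solutions of $\dot s = -is$, $\dot c = is - fc$, $\dot d = fc$. Case
   fatality is derived from the inputs as $f = m_\text{IHD}/p$ (cause-specific
   mortality over prevalence), a documented stand-in for DisMod-style
   reconciliation.
4. **Lifetable.** Each (sex, band) cohort enters at its band's lower age and
   is simulated by single year of age until extinction or age 100. The
   all-cause hazard replaces the input IHD mortality with the modelled,
   arm-specific rate: $m_\text{arm}(a) = \text{acm}(a) - m_\text{IHD}(a) +
   r_\text{arm}(a)$, where $r_\text{arm} = f\bar c/(\bar s + \bar c)$ uses
   exact within-year average occupancies. Survivorship is $l(a+1) =
   l(a)e^{-m}$ and person-years are trapezoidal.
5. **HALYs.** Health-adjusted life years weight person-time by prevalent
   disability: $\text{HALY} = PY(1 - \text{yld}_\text{other}) -
   PY_\text{IHD}\,dw_\text{IHD}$, floored at 0, with the per-case IHD
   disability weight derived as $dw = \text{yld}_\text{IHD}/p$.
6. **Costs (extended healthcare perspective).** Incident IHD events carry an
   acute-care cost, prevalent IHD person-years a follow-up cost, and every
   person-year the per-capita non-IHD expenditure of its stratum — so
   healthcare costs in added years of life are counted. Policy costs comprise
   a government one-off plus annual stream and an industry reformulation
   outlay (products × cost per product, in year 1) plus an annual fraction
   (1%) of that outlay. Net cost = discounted policy costs + discounted
   change in total healthcare costs; negative means cost-saving.
7. **Summary measures.** ICER = net cost / HALYs gained (cost-effective when
   strictly below the willingness-to-pay threshold, default US\$374/HALY;
   negative net cost = cost-saving); ROI = healthcare savings / government
   costs. Events and deaths are reported undiscounted; HALYs and costs are
   discounted at 3% by default, with the first simulation year discounted
   with exponent 0 (a convention the source evidence does not fix; it is
   stated here for reproducibility).

Results are reported over 5-year, 10-year and population-lifetime horizons
(the closed adult cohorts are extinct or at age 100 after 80 years), in total
and by sex; combined-sex values are defined as female + male so sex-specific
results add up exactly.

## Stratification

The model uses 30 strata: 15 five-year age bands per sex with lower bounds
20, 25, ..., 90. The terminal band's rates apply to all ages from 90 to the
age-100 ceiling, so the oldest cohort is simulated for 10 years. Rates are
piecewise constant in single years of age within bands (step interpolation,
no smoothing).

# Key parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `rr_per_2e` | 1.23 | RR of incident IHD per 2%E intake above TMREL |
| `ln_rr_sd` | 0.054 | SD of log RR (≈ 95% CI 1.11–1.37 around 1.23) |
| `tmrel` | 0 | %E; minimum-risk intake |
| `post_intake` | point mass at 0%E | counterfactual intake |
| `discount_rate` | 0.03 | annual, HALYs and costs |
| `ce_threshold` | 374 | USD per HALY, strict `<` |
| `usd_to_ngn` | 358 | naira per USD (1 July 2019 average) |
| `industry_products` | 331 | products requiring reformulation |
| `industry_cost_per_product` | 32,000 | USD; £25,000 converted at 1.28 USD/GBP, a documented input since the source states "equivalent USD costs" without printing a rate |
| `industry_annual_frac` | 0.01 | recurring fraction of the initial outlay |
| `cost_cv` | 0.2 | SD as fraction of central value for normal cost draws |

Sensitivity toggles (`analysis_plan()`): discount 0%/6%; intake mean and SD
scaled ×0.5/×1.5; residual post-intervention intake 0.1 ± 0.01 %E; doubled
product count; no industry costs; monitoring ×1.5; and a partial-compliance
threshold analysis shifting the reference mean down by 0.05–0.20 %E.

# Uncertainty analysis

Monte Carlo (default n = 2000). Per iteration: stratum intake means are drawn
from lognormals moment-matched to each stratum's (mean, SD), and the PIF
integral is recentred at the drawn mean (drawing distribution parameters, the
standard usage, rather than individual intakes); relative risks are lognormal
(normal in log RR), independent per age group and shared across sexes and
arms; IHD unit costs are triangular (min, mode, max) using one common uniform
quantile across strata per cost type — fully correlated across strata and
marginally exact, since independent per-stratum draws would average away
population-level uncertainty; non-IHD and policy costs are normal with SD
equal to 20% of the central value, truncated at 0 (truncations are counted
and reported; the rate is negligible at CV 0.2). Both arms share all draws
(common random numbers). Point estimates and 95% uncertainty intervals are
the mean and 2.5th–97.5th percentiles across iterations; the probabilities of
being cost-saving and cost-effective are the fractions of iterations with net
cost < 0 and (cost-saving or ICER < threshold). Given a seed, results are
bit-for-bit reproducible, and with all input SDs at zero every iteration
reproduces the central run exactly.

# Numerical choices

- **PIF quadrature.** $E[RR(X)]$ under a lognormal with a log-linear RR is an
  $E[e^{\theta X}]$ moment, which the lognormal does not possess. As in
  standard distribution-shift PIF implementations the expectation is
  integrated over the central mass of the distribution — here between the
  $10^{-9}$ and $1 - 10^{-9}$ quantiles, with the integrand evaluated in log
  space — which is numerically indistinguishable from the nominal value at
  realistic intake CVs. Point masses bypass quadrature.
- **Threshold counterfactual.** The shifted counterfactual keeps the
  reference SD, but its CV is capped at 2: as the shifted mean approaches 0
  with the SD kept, the lognormal's RR expectation diverges. The cap does not
  bind for typical inputs (reference CV 0.3 gives cf CV ≈ 1 at the largest
  shift).
- **Disease-step degeneracy.** The $f = i$ case uses the series limit when
  $|f - i| < 10^{-12}$; $(1-e^{-r})/r$-type terms use series below $10^{-8}$.
  State mass $s + c + d$ is conserved to $10^{-12}$ per step.
- **Survivorship.** Exponential within-year hazard ($l\,e^{-m}$) rather than
  the $q = m/(1+m/2)$ conversion: it composes exactly with the
  continuous-time disease model.
- **Exact identities.** Combined-sex totals are defined as female + male, and
  the combined total healthcare cost as combined IHD + combined non-IHD, so
  the decomposition identity is bit-exact (the total's own sex additivity
  then holds to floating-point round-off, since addition is not
  associative). Naira values are an exact multiple of USD values.
- **CSV round-trip.** Doubles are written with 17 significant digits and
  parsed with strtod, so written inputs and results re-read bit-identically.
- **Degenerate inputs.** Zero-SD draws return the central value exactly (no
  `exp(log(x))` round trips); zero prevalence with zero mortality yields case
  fatality 0; HALYs are floored at 0.

# The synthetic-data generator

`generate_inputs()` produces a complete 30-stratum input set emulating the
*structure* of GBD-style exports for a populous lower-middle-income country
with low trans-fat intake: stratum mean intakes uniform in 0.25–0.31 %E with
CV 0.3; Gompertz all-cause mortality (rate 0.003 at age 20, log-slope 0.075,
male ratio 1.15); log-linear IHD incidence above an onset age of 30 (6×10⁻⁴
at onset, log-slope 0.06, male ratio 1.4 — scaled so the reference population
of 90 million adults experiences roughly 10⁵ IHD deaths per year, the
right national order of magnitude); flat case fatality 0.08; an exponentially
declining population pyramid; IHD unit costs of \$400 (acute) and \$150/year
(follow-up) with ±50% triangular bounds, and age-increasing non-IHD
per-capita expenditure from \$55.

Internal consistency is by construction: prevalence is obtained by
integrating the illness-death occupancy ODE $p' = (1-p)(i - fp)$ across age
with the banded rates (band value = $p$ at the band's lower age), and IHD
mortality is $f \times p$. A band entered at zero prevalence uses $f = 0$ for
that band, so the banded case fatality the model later derives as
$m_\text{IHD}/p$ is exactly the rate that generated the data. The test suite
verifies the recovered prevalence against an independent adaptive ODE oracle
within 5% at ages 40–80.

What the generator does *not* emulate: real GBD uncertainty correlations,
secular trends in rates (the model assumes stable rates, as the framework
does), age patterns of intake, subnational or socioeconomic heterogeneity,
and any specific country's actual values. Passing tests therefore demonstrate
the correctness and internal coherence of the machinery, not agreement with
any particular published estimate; with a country's real input tables
transcribed into the CSV schema, the same pipeline produces the corresponding
country results.

`generate_worked_toy()` is a 2-stratum fixture (both sexes, band 90) placed
at the disease equilibrium $p = i/f$, so its lifetable hazard is constant and
life expectancy has a closed geometric form used in exact tests.

# Problem sizes

The test suite runs the full 30-cohort pipeline repeatedly with small Monte
Carlo runs (up to 150 iterations) plus two 10⁶-sample PIF oracles; the
bundled analysis script runs the primary scenario at the full n = 2000
iterations. A central pipeline run takes ~0.15 s and the full Monte Carlo
about 90 s on one core.

# Known limitations

- Case fatality from $m/p$ is a stand-in for DisMod-style reconciliation;
  exact reproduction of any specific processed dataset is not guaranteed.
- Closed cohorts: no births or migration enter after baseline, so
  "population lifetime" means the lifetime of the baseline adult cohorts.
- The PIF applies to incidence from year 1 with no phase-in lag (the policy
  steady state); a lag hook exists but defaults to 0.
- No indirect/productivity costs; no currency-inflation arithmetic (inputs
  are assumed pre-inflated to a common year); only log-linear dose-response.
- Whether RR exponentiation uses intake above TMREL or absolute intake is
  moot at TMREL = 0 (the default); the implementation uses intake above
  TMREL.

# A minimal run

```{r example, eval = FALSE}
inputs <- generate_inputs(synth_config(seed = 1))
central <- run_pipeline(inputs, scenario())
mc <- run_monte_carlo(inputs, scenario(), n_iter = 2000, seed = 1)
mc$probabilities

# deterministic sensitivity analyses
plan <- analysis_plan()
out <- run_plan(inputs, plan, n_iter = 0)
out$comparison
```
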