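# IHD illness-death submodel.
#
# Three states, conditional on surviving causes other than IHD:
#   s: alive without IHD; c: alive with IHD; d: cumulative IHD deaths.
# Flows (continuous time, rates constant within a year of age):
#   ds/dt = -i s;   dc/dt = i s - f c;   dd/dt = f c
# where i is IHD incidence and f case fatality; remission is fixed at 0 (IHD
# is treated as chronic). One-year steps use the exact solution of this linear
# system, including the exact within-year occupancy integrals used for the
# IHD mortality rate among the living.

#' Disease state
#'
#' @param s Proportion alive without IHD.
#' @param c Proportion alive with IHD.
#' @param d Cumulative proportion dead from IHD.
#' @return A list of class `disease_state`. `s + c + d` is conserved by
#'   [step_disease()].
#' @export
disease_state <- function(s, c, d = 0) {
  if (any(c(s, c, d) < 0)) stop("disease state proportions must be >= 0")
  structure(list(s = s, c = c, d = d), class = "disease_state")
}

#' Disease transition rates
#'
#' @param incidence Annual IHD incidence rate `i` (>= 0).
#' @param case_fatality Annual case fatality rate `f` (>= 0).
#' @return A list of class `disease_rates` with fields `i`, `f` and `r`
#'   (remission, fixed at 0).
#' @export
disease_rates <- function(incidence, case_fatality) {
  if (incidence < 0 || case_fatality < 0) stop("disease rates must be >= 0")
  structure(list(i = incidence, f = case_fatality, r = 0),
            class = "disease_rates")
}

# (1 - exp(-r)) / r with the r -> 0 limit.
rexp1 <- function(r) {
  if (r < 1e-8) 1 - r / 2 + r^2 / 6 else (1 - exp(-r)) / r
}

# int_0^1 t exp(-i t) dt with the i -> 0 limit.
texp1 <- function(i) {
  if (i < 1e-4) 0.5 - i / 3 + i^2 / 8 else (1 - (1 + i) * exp(-i)) / i^2
}

# One-year advance with exact end-state and occupancy integrals.
# Returns s1, c1, d1 plus int_s = int_0^1 s(t) dt and int_c = int_0^1 c(t) dt.
disease_step_core <- function(s0, c0, i, f) {
  if (i < 0 || f < 0) stop("disease rates must be >= 0")
  s1 <- s0 * exp(-i)
  int_s <- s0 * rexp1(i)
  if (abs(f - i) < 1e-12) {
    # series limit at f = i: c(t) = c0 e^{-ft} + i s0 t e^{-it}
    c1 <- c0 * exp(-f) + i * s0 * exp(-i)
    int_c <- c0 * rexp1(f) + i * s0 * texp1(i)
  } else {
    c1 <- c0 * exp(-f) + i * s0 * (exp(-i) - exp(-f)) / (f - i)
    int_c <- c0 * rexp1(f) + i * s0 * (rexp1(i) - rexp1(f)) / (f - i)
  }
  list(s1 = s1, c1 = c1, delta_d = (s0 + c0) - (s1 + c1),
       int_s = int_s, int_c = int_c)
}

#' Advance the disease model one year
#'
#' Exact (closed-form) one-year solution of the illness-death system
#' `ds/dt = -is`, `dc/dt = is - fc`, `dd/dt = fc`:
#' `s1 = s0 e^{-i}`; `c1 = c0 e^{-f} + i s0 (e^{-i} - e^{-f})/(f - i)` for
#' `f != i`, with the series limit `c1 = c0 e^{-f} + i s0 e^{-i}` when
#' `|f - i| < 1e-12`; `d1` by conservation of `s + c + d`.
#'
#' @param state A [disease_state()].
#' @param rates A [disease_rates()].
#' @return The [disease_state()] one year later.
#' @export
#' @examples
#' step_disease(disease_state(1, 0), disease_rates(0.01, 0.1))
step_disease <- function(state, rates) {
  stopifnot(inherits(state, "disease_state"), inherits(rates, "disease_rates"))
  z <- disease_step_core(state$s, state$c, rates$i, rates$f)
  disease_state(z$s1, z$c1, state$d + z$delta_d)
}

#' Annual IHD mortality rate among the living
#'
#' The cause-specific death rate handed to the lifetable:
#' `f * cbar / (sbar + cbar)`, where `sbar`, `cbar` are the exact within-year
#' average state occupancies over the coming year. Equivalently, the year's
#' IHD deaths divided by the year's person-time alive.
#'
#' @param state A [disease_state()] at the start of the year.
#' @param rates A [disease_rates()].
#' @return Annual IHD death rate per person-year alive.
#' @export
ihd_mortality_rate <- function(state, rates) {
  stopifnot(inherits(state, "disease_state"), inherits(rates, "disease_rates"))
  if (state$s + state$c <= 0) stop("no one alive: s + c must be > 0")
  z <- disease_step_core(state$s, state$c, rates$i, rates$f)
  rates$f * z$int_c / (z$int_s + z$int_c)
}

#' Derive case fatality rates from prevalence and cause-specific mortality
#'
#' Stand-in derivation of the annual IHD case fatality rate per stratum as
#' `f = ihd_mort / ihd_prev` (cause-specific mortality among the prevalent
#' pool). Strata with zero mortality get `f = 0`; zero prevalence with
#' positive mortality is an error.
#'
#' @param epi The `epi` table of a `stratified_inputs` object (columns `sex`,
#'   `age_group`, `ihd_prev`, `ihd_mort`).
#' @return Tibble with columns `sex`, `age_group`, `case_fatality`.
#' @export
derive_case_fatality <- function(epi) {
  bad <- epi$ihd_mort > 0 & epi$ihd_prev <= 0
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("case fatality undefined: ihd_mort > 0 with ihd_prev = 0 for (%s, %d)",
                 epi$sex[k], epi$age_group[k]))
  }
  f <- ifelse(epi$ihd_mort > 0, epi$ihd_mort / epi$ihd_prev, 0)
  tibble::tibble(sex = epi$sex, age_group = epi$age_group, case_fatality = f)
}
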