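# Age-sex stratification used throughout: adults in 15 five-year bands per sex
# (20-24 .. 90-94), both sexes, 30 strata in all. Cohorts are simulated by
# single year of age up to the model ceiling of 100; the terminal band's rates
# apply to ages 90-99.

AGE_LOWER <- seq(20L, 90L, by = 5L)
SEXES <- c("female", "male")
MODEL_CEILING <- 100L

#' All model strata
#'
#' The model population is stratified by sex and 5-year age band (30 strata:
#' 15 bands per sex). Bands are closed-open intervals `[x, x + 5)` identified
#' by their lower bound in years; the terminal band (lower bound 90) supplies
#' the rates for all ages from 90 up to the model ceiling of 100, and cohorts
#' are simulated until extinction or age 100.
#'
#' @return A tibble with columns `sex` (`"female"`/`"male"`) and `age_group`
#'   (integer lower bound, 20, 25, ..., 90); 30 rows.
#' @export
#' @examples
#' all_strata()
all_strata <- function() {
  tidyr::expand_grid(sex = SEXES, age_group = AGE_LOWER)
}

# Map a single year of age to its 5-year band lower bound (>= 90 -> 90).
age_to_band <- function(age) {
  pmax(20L, pmin(5L * (as.integer(age) %/% 5L), 90L))
}

# Index of an age's band in AGE_LOWER (1..15).
age_band_index <- function(age) {
  match(age_to_band(age), AGE_LOWER)
}

horizon_label <- function(h) {
  ifelse(is.infinite(h), "lifetime", paste0(h, "y"))
}
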