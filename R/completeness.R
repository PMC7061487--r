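#' Completeness of death registration from a comparator CDR trend
#'
#' The observed crude death rate is compared with an externally estimated
#' CDR trend; the ratio (capped at 1) estimates the fraction of deaths the
#' registration system captured. The expected CDR is linearly interpolated
#' in year; a year beyond the trend ends uses the terminal value with a
#' warning. A ratio above 1 is capped with an over-completeness warning,
#' but the raw ratio is retained — exceeding the expected CDR is itself
#' diagnostically interesting.
#'
#' @param cdr_observed Observed CDR per 1,000.
#' @param comparator A `codqc_comparators` object.
#' @param year Data year.
#' @return List: `completeness`, `cdr_observed`, `cdr_expected`,
#'   `raw_ratio`, `notes` (character vector).
#' @export
completeness_from_comparator <- function(cdr_observed, comparator, year) {
  trend <- comparator$cdr_trend
  notes <- character()
  if (year < min(trend$year) || year > max(trend$year)) {
    warn("Year outside comparator CDR trend; using terminal trend value.")
    notes <- c(notes, "extrapolated_beyond_trend")
  }
  expected <- approx(trend$year, trend$cdr, xout = year, rule = 2)$y
  if (expected <= 0) abort("Expected CDR must be positive.", class = "codqc_input_error")
  ratio <- cdr_observed / expected
  if (ratio > 1) {
    warn(sprintf("Observed CDR exceeds expected (ratio %.3f); completeness capped at 1.", ratio))
    notes <- c(notes, "over_complete_capped")
  }
  list(
    completeness = min(1, ratio),
    cdr_observed = cdr_observed,
    cdr_expected = expected,
    raw_ratio = ratio,
    notes = notes
  )
}

#' Default illustrative coefficients for the empirical completeness model
#'
#' Placeholder values for worked examples and simulations. The model form
#' is log-linear in ln(observed 5q0), the proportion of the population aged
#' 65+, and child-registration completeness; published coefficients must be
#' supplied by the user for real-world application.
#'
#' @return Named numeric vector `c0`, `c1`, `c2`, `c3`.
#' @export
default_empirical_coefficients <- function() {
  c(c0 = 2.0, c1 = 0.1, c2 = 4.0, c3 = -0.3)
}

#' Empirical (comparator-free) completeness of death registration
#'
#' Predicts the CDR that would be expected given population ageing, the
#' observed level of child mortality, and the completeness of child death
#' registration:
#' predicted CDR = exp(c0 + c1 ln(5q0_obs) + c2 p65 + c3 c_child),
#' where p65 is the proportion (0-1) of the population aged 65 and over.
#' Completeness is the observed CDR over the prediction, capped at 1.
#'
#' @param deaths,population Validated tabulations.
#' @param child_completeness Child-registration completeness in (0, 1].
#' @param coefficients Named vector `c0..c3`
#'   (default [default_empirical_coefficients()], illustrative only).
#' @param a0,a1 Separation factors passed to the 5q0 calculation.
#' @return List: `completeness`, `cdr_observed`, `cdr_predicted`,
#'   `raw_ratio`, `q5_0_observed`, `pct65`, `notes`.
#' @export
completeness_empirical <- function(deaths, population, child_completeness,
                                   coefficients = default_empirical_coefficients(),
                                   a0 = 0.3, a1 = 1.4) {
  stopifnot(all(c("c0", "c1", "c2", "c3") %in% names(coefficients)))
  open_age <- attr(population, "open_age") %||% 85
  info <- age_group_info(open_age)
  old_groups <- info$age_group[info$lower >= 65]
  pct65 <- sum(population$count[population$age_group %in% old_groups]) / sum(population$count)

  d0 <- sum(deaths$count[deaths$age_group == "<1"])
  d1 <- sum(deaths$count[deaths$age_group == "1-4"])
  p0 <- sum(population$count[population$age_group == "<1"])
  p1 <- sum(population$count[population$age_group == "1-4"])
  m0 <- d0 / p0
  m1 <- d1 / p1
  q1_0 <- m0 / (1 + (1 - a0) * m0)
  q4_1 <- 4 * m1 / (1 + (4 - a1) * m1)
  q5_0 <- 1 - (1 - q1_0) * (1 - q4_1)
  if (q5_0 <= 0) abort("model undefined: observed 5q0 is zero.", class = "codqc_input_error")

  predicted <- exp(coefficients[["c0"]] + coefficients[["c1"]] * log(q5_0) +
    coefficients[["c2"]] * pct65 + coefficients[["c3"]] * child_completeness)
  cdr_obs <- crude_death_rate(deaths, population)
  ratio <- cdr_obs / predicted
  notes <- character()
  if (ratio > 1) {
    warn("Observed CDR exceeds empirical prediction; completeness capped at 1.")
    notes <- "over_complete_capped"
  }
  list(
    completeness = min(1, ratio),
    cdr_observed = cdr_obs,
    cdr_predicted = unname(predicted),
    raw_ratio = unname(ratio),
    q5_0_observed = q5_0,
    pct65 = pct65,
    notes = notes
  )
}

#' Death-weighted average of child and adult completeness
#'
#' Combines under-5 and 5-plus completeness into one summary figure,
#' weighting each by the estimated true number of deaths in its age block
#' (observed deaths divided by the block's completeness).
#'
#' @param child_completeness,adult_completeness Completeness in (0, 1].
#' @param deaths_under5,deaths_5plus Observed death counts in each block.
#' @return Weighted completeness (scalar).
#' @export
completeness_weighted <- function(child_completeness, adult_completeness,
                                  deaths_under5, deaths_5plus) {
  if (child_completeness <= 0 || adult_completeness <= 0) {
    abort("Completeness values must be positive.", class = "codqc_input_error")
  }
  est_u5 <- deaths_under5 / child_completeness
  est_5p <- deaths_5plus / adult_completeness
  if (est_u5 + est_5p == 0) abort("No deaths to weight.", class = "codqc_input_error")
  (child_completeness * est_u5 + adult_completeness * est_5p) / (est_u5 + est_5p)
}
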