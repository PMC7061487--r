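#' Age-sex tabulation (pyramid table)
#'
#' Counts and within-sex percentages by age group, for a death or
#' population tabulation. Unknown-age rows are kept as their own line; they
#' enter the percentages (the table describes the reported data) but are
#' excluded from rate denominators downstream.
#'
#' @param table A `codqc_deaths` or `codqc_population` tibble (any tibble
#'   with `sex`, `age_group`, `count` works).
#' @return A `codqc_pyramid` tibble: `sex`, `age_group`, `count`, `percent`.
#' @export
tabulate_age_sex <- function(table) {
  if (nrow(table) == 0 || sum(table$count) == 0) {
    abort("Empty table: nothing to tabulate.", class = "codqc_input_error")
  }
  open_age <- attr(table, "open_age") %||% 85
  out <- table |>
    group_by(.data$sex, .data$age_group) |>
    summarise(count = sum(.data$count), .groups = "drop_last") |>
    mutate(percent = 100 * .data$count / sum(.data$count)) |>
    ungroup() |>
    arrange(.data$sex, factor(.data$age_group, levels = c(age_ladder(open_age), "unknown")))
  structure(out, open_age = open_age, class = c("codqc_pyramid", class(out)))
}

#' Crude death rate
#'
#' Deaths per 1,000 population. Unknown-age and unknown-sex deaths are part
#' of the numerator: the CDR measures how many deaths were reported, not
#' how well they were described.
#'
#' @param deaths,population Validated tabulations for the same year.
#' @return CDR per 1,000 (scalar).
#' @export
crude_death_rate <- function(deaths, population) {
  p <- sum(population$count)
  if (p <= 0) abort("Total population is zero.", class = "codqc_input_error")
  1000 * sum(deaths$count) / p
}

#' Age-specific mortality rates by sex
#'
#' m_x = deaths / population per (sex, age group), with `log_rate = ln(m_x)`
#' where m_x > 0. Unknown-age or unknown-sex deaths are excluded from the
#' numerators (rates describe the identifiable data; no redistribution is
#' done before consistency checks). Bands with zero population but nonzero
#' deaths are flagged as anomalies rather than divided.
#'
#' @param deaths,population Validated tabulations.
#' @return A `codqc_rates` tibble: `sex`, `age_group`, `midpoint`, `deaths`,
#'   `population`, `rate`, `log_rate`, `anomaly`.
#' @export
age_specific_rates <- function(deaths, population) {
  open_age <- attr(population, "open_age") %||% 85
  info <- age_group_info(open_age)
  d <- deaths |>
    filter(.data$sex %in% c("male", "female"), .data$age_group != "unknown") |>
    group_by(.data$sex, .data$age_group) |>
    summarise(deaths = sum(.data$count), .groups = "drop")
  p <- population |>
    group_by(.data$sex, .data$age_group) |>
    summarise(population = sum(.data$count), .groups = "drop")
  out <- p |>
    left_join(d, by = c("sex", "age_group")) |>
    mutate(deaths = dplyr::coalesce(.data$deaths, 0)) |>
    left_join(info, by = "age_group") |>
    mutate(
      anomaly = .data$population <= 0 & .data$deaths > 0,
      rate = if_else(.data$population > 0, .data$deaths / .data$population, NA_real_),
      log_rate = if_else(!is.na(.data$rate) & .data$rate > 0, log(.data$rate), NA_real_)
    ) |>
    select("sex", "age_group", "midpoint", "deaths", "population", "rate", "log_rate", "anomaly") |>
    arrange(.data$sex, .data$midpoint)
  structure(out, open_age = open_age, class = c("codqc_rates", class(out)))
}

#' Gompertz-Makeham log-linearity check
#'
#' Adult mortality rates grow roughly exponentially with age, so ln(m_x)
#' against the age-band midpoint should be close to a straight line from
#' about age 30 upward. This fits that line by least squares per sex and
#' flags bands whose rate falls below the previous band's (non-monotone),
#' a classic signature of age misreporting or differential completeness.
#'
#' @param rates A `codqc_rates` table from [age_specific_rates()].
#' @param min_age Lowest band lower-bound included in the fit (default 30).
#' @return A `codqc_loglin` object: `$fits` (sex, slope, intercept,
#'   r_squared, n_bands) and `$flags` (sex, age_group, reason).
#' @export
log_linearity_check <- function(rates, min_age = 30) {
  open_age <- attr(rates, "open_age") %||% 85
  info <- age_group_info(open_age)
  eligible <- info$age_group[info$lower >= min_age]
  fits <- list()
  flags <- list()
  for (sx in unique(rates$sex)) {
    r <- rates |>
      filter(.data$sex == sx, .data$age_group %in% eligible, !is.na(.data$log_rate)) |>
      arrange(.data$midpoint)
    if (nrow(r) < 4) {
      abort(sprintf("insufficient_data: fewer than 4 usable bands at/above age %d for %s.", min_age, sx),
        class = "codqc_insufficient_data"
      )
    }
    fit <- lm(log_rate ~ midpoint, data = r)
    # suppress the "essentially perfect fit" note: exactly log-linear input
    # is a legitimate (and tested) case here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    fits[[sx]] <- tibble(
      sex = sx,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n_bands = nrow(r)
    )
    drop <- which(diff(r$rate) < 0) + 1
    if (length(drop)) {
      flags[[sx]] <- tibble(sex = sx, age_group = r$age_group[drop], reason = "non_monotone")
    }
  }
  structure(
    list(
      fits = bind_rows(fits),
      flags = if (length(flags)) bind_rows(flags) else tibble(sex = character(), age_group = character(), reason = character()),
      min_age = min_age
    ),
    class = "codqc_loglin"
  )
}

#' Excess-female-mortality check
#'
#' Female mortality above male mortality is rare at any age; at ages 5 and
#' over it usually signals a data problem. Flags every band (age >= 5)
#' where the female rate strictly exceeds the male rate (plus an optional
#' tolerance); under-5 bands are reported separately, not flagged.
#'
#' @param rates A `codqc_rates` table covering both sexes.
#' @param tolerance Relative excess ignored before flagging (default 0).
#' @return List with `flagged` and `under5` tibbles
#'   (`age_group`, `rate_female`, `rate_male`, `ratio`).
#' @export
sex_pattern_check <- function(rates, tolerance = 0) {
  wide <- rates |>
    select("sex", "age_group", "midpoint", "rate") |>
    tidyr::pivot_wider(names_from = "sex", values_from = "rate", names_prefix = "rate_")
  if (!all(c("rate_female", "rate_male") %in% names(wide))) {
    abort("Rates for both sexes are required.", class = "codqc_input_error")
  }
  wide <- wide |>
    mutate(
      ratio = if_else(.data$rate_male > 0, .data$rate_female / .data$rate_male, NA_real_),
      excess = !is.na(.data$rate_female) & !is.na(.data$rate_male) &
        .data$rate_female > .data$rate_male * (1 + tolerance)
    ) |>
    arrange(.data$midpoint)
  list(
    flagged = wide |> filter(.data$midpoint >= 5, .data$excess) |>
      select("age_group", "rate_female", "rate_male", "ratio"),
    under5 = wide |> filter(.data$midpoint < 5) |>
      select("age_group", "rate_female", "rate_male", "ratio")
  )
}

#' Under-five mortality and child-registration completeness
#'
#' Converts the observed under-1 and 1-4 death rates into probabilities of
#' dying using standard separation factors a0 and a1:
#' 1q0 = m0 / (1 + (1 - a0) m0), 4q1 = 4 m1 / (1 + (4 - a1) m1),
#' 5q0 = 1 - (1 - 1q0)(1 - 4q1). Child completeness is the observed 5q0
#' over the comparator estimate, capped at 1. When neonatal detail columns
#' are present, the split of under-5 deaths into early/late/post-neonatal
#' and 1-4 is reported.
#'
#' @param deaths,population Validated tabulations with "<1" and "1-4" rows.
#' @param comparator A `codqc_comparators` object (its `u5mr_estimate`).
#' @param a0,a1 Separation factors (defaults 0.3 and 1.4).
#' @return A `codqc_child` list: `q1_0`, `q4_1`, `q5_0`, `comparator_q5_0`,
#'   `child_completeness`, `m0`, `m1`, and `neonatal_split` (or NULL).
#' @export
child_mortality <- function(deaths, population, comparator, a0 = 0.3, a1 = 1.4) {
  need <- c("<1", "1-4")
  if (!all(need %in% deaths$age_group) || !all(need %in% population$age_group)) {
    abort("'<1' and '1-4' rows are required in both tables.", class = "codqc_input_error")
  }
  d0 <- sum(deaths$count[deaths$age_group == "<1"])
  d1 <- sum(deaths$count[deaths$age_group == "1-4"])
  p0 <- sum(population$count[population$age_group == "<1"])
  p1 <- sum(population$count[population$age_group == "1-4"])
  if (p0 <= 0 || p1 <= 0) abort("Under-5 population must be positive.", class = "codqc_input_error")
  m0 <- d0 / p0
  m1 <- d1 / p1
  q1_0 <- m0 / (1 + (1 - a0) * m0)
  q4_1 <- 4 * m1 / (1 + (4 - a1) * m1)
  q5_0 <- 1 - (1 - q1_0) * (1 - q4_1)
  comp <- comparator$u5mr_estimate$value
  if (is.null(comp) || is.na(comp) || comp <= 0) {
    abort("Comparator 5q0 must be positive.", class = "codqc_input_error")
  }
  neonatal <- NULL
  neo_cols <- c("early_neonatal", "late_neonatal", "post_neonatal")
  if (all(neo_cols %in% names(deaths)) && (d0 + d1) > 0) {
    u1 <- deaths$age_group == "<1"
    parts <- c(
      early_neonatal = sum(deaths$early_neonatal[u1], na.rm = TRUE),
      late_neonatal = sum(deaths$late_neonatal[u1], na.rm = TRUE),
      post_neonatal = sum(deaths$post_neonatal[u1], na.rm = TRUE),
      age_1_4 = d1
    )
    if (sum(parts[1:3]) > 0) neonatal <- parts / (d0 + d1)
  }
  structure(
    list(
      m0 = m0, m1 = m1, q1_0 = q1_0, q4_1 = q4_1, q5_0 = q5_0,
      comparator_q5_0 = comp,
      child_completeness = if (q5_0 > 0) min(1, q5_0 / comp) else 0,
      raw_ratio = q5_0 / comp,
      neonatal_split = neonatal,
      a0 = a0, a1 = a1
    ),
    class = "codqc_child"
  )
}
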