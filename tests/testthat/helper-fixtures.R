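# Shared fixtures, built in code. The perfect deterministic dataset is
# generated once per test run and reused.

the_fixtures <- new.env(parent = emptyenv())

perfect_sim <- function() {
  if (is.null(the_fixtures$perfect)) {
    the_fixtures$perfect <- simulate_dataset(seed = 1, size = 2e6, mode = "deterministic")
  }
  the_fixtures$perfect
}

small_sim <- function() {
  if (is.null(the_fixtures$small)) {
    the_fixtures$small <- simulate_dataset(seed = 1, size = 5e5, mode = "deterministic")
  }
  the_fixtures$small
}

default_meta <- function() {
  if (is.null(the_fixtures$meta)) the_fixtures$meta <- load_code_metadata()
  the_fixtures$meta
}

# Deaths table straight from a compact spec: list of (sex, age, code, count).
deaths_of <- function(..., year = 2015) {
  rows <- list(...)
  as_death_table(tibble::tibble(
    year = year,
    sex = sapply(rows, `[[`, 1),
    age_group = sapply(rows, `[[`, 2),
    icd_code = sapply(rows, `[[`, 3),
    count = as.numeric(sapply(rows, `[[`, 4))
  ))
}

# Uniform population over the full ladder, `count` persons per (sex, band).
flat_population <- function(count = 1000, year = 2015) {
  ladder <- age_ladder()
  as_population_table(tibble::tibble(
    year = year,
    sex = rep(c("male", "female"), each = length(ladder)),
    age_group = rep(ladder, 2),
    count = count
  ))
}

# A rates table built directly from a rate function of age midpoint,
# bypassing count rounding (for exact regression checks).
rates_from_fn <- function(fn, sex = "male") {
  info <- age_group_info()
  df <- tibble::tibble(
    sex = sex,
    age_group = info$age_group,
    midpoint = info$midpoint,
    deaths = NA_real_,
    population = NA_real_,
    rate = fn(info$midpoint),
    log_rate = ifelse(fn(info$midpoint) > 0, log(fn(info$midpoint)), NA_real_),
    anomaly = FALSE
  )
  structure(df, open_age = 85, class = c("codqc_rates", class(df)))
}
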