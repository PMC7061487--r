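test_that("age-sex tabulation yields within-sex percentages that sum to 100", {
  d <- deaths_of(
    list("male", "<1", "A09", 50),
    list("male", "85+", "I21", 50),
    list("female", "50-54", "I21", 20)
  )
  pyr <- tabulate_age_sex(d)
  expect_equal(pyr$percent[pyr$sex == "male"], c(50, 50))
  expect_equal(sum(pyr$count), sum(d$count))
  agg <- dplyr::summarise(dplyr::group_by(pyr, sex), p = sum(percent))
  expect_true(all(abs(agg$p - 100) < 1e-6))
  expect_error(tabulate_age_sex(d[0, ]), class = "codqc_input_error")
})

test_that("unknown-age deaths stay visible in the pyramid but out of rates", {
  d <- deaths_of(
    list("male", "50-54", "I21", 90),
    list("male", "unknown", "I21", 10)
  )
  pyr <- tabulate_age_sex(d)
  expect_true("unknown" %in% pyr$age_group)
  r <- age_specific_rates(d, flat_population(1000))
  expect_equal(sum(r$deaths), 90)
})

test_that("crude death rate is per 1000 with unknown-age deaths in the numerator", {
  pop <- flat_population(100000 / (2 * length(age_ladder())))
  d <- deaths_of(list("male", "50-54", "I21", 700), list("unknown", "unknown", "missing", 100))
  expect_equal(crude_death_rate(d, pop), 8.0)
  expect_equal(crude_death_rate(d[0, ], pop), 0)
  empty_pop <- flat_population(1)
  empty_pop$count <- 0
  expect_error(crude_death_rate(d, empty_pop), class = "codqc_input_error")
})

test_that("age-specific rates divide deaths by population per band", {
  pop <- flat_population(1000)
  d <- deaths_of(list("male", "50-54", "I21", 5))
  r <- age_specific_rates(d, pop)
  expect_equal(r$rate[r$sex == "male" & r$age_group == "50-54"], 0.005)
  zero <- r[r$sex == "male" & r$age_group == "20-24", ]
  expect_equal(zero$rate, 0)
  expect_true(is.na(zero$log_rate))
})

test_that("log-linearity fit recovers an exact Gompertz input", {
  r <- rates_from_fn(function(x) 1e-4 * exp(0.09 * x))
  fit <- log_linearity_check(r)
  expect_equal(fit$fits$slope, 0.09, tolerance = 1e-9)
  expect_equal(fit$fits$r_squared, 1, tolerance = 1e-9)
  expect_equal(nrow(fit$flags), 0)
})

test_that("a halved band is flagged non-monotone and sparse data errors", {
  f <- function(x) {
    out <- 1e-4 * exp(0.09 * x)
    out[x == 72.5] <- out[x == 72.5] / 2
    out
  }
  fit <- log_linearity_check(rates_from_fn(f))
  expect_true("70-74" %in% fit$flags$age_group)

  sparse <- rates_from_fn(function(x) ifelse(x > 80, 1e-3, 0))
  expect_error(log_linearity_check(sparse), "insufficient_data", class = "codqc_insufficient_data")
})

test_that("excess female mortality is flagged only at ages 5+", {
  base <- function(x) 1e-4 * exp(0.09 * x)
  r_eq <- dplyr::bind_rows(rates_from_fn(base, "male"), rates_from_fn(base, "female"))
  expect_equal(nrow(sex_pattern_check(r_eq)$flagged), 0)

  f_ex <- function(x) base(x) * ifelse(x == 32.5, 1.2, 1)
  r <- dplyr::bind_rows(rates_from_fn(base, "male"), rates_from_fn(f_ex, "female"))
  chk <- sex_pattern_check(r)
  expect_equal(chk$flagged$age_group, "30-34")
  expect_equal(nrow(chk$under5), 2)
})

test_that("child mortality converts rates to probabilities correctly", {
  # oracle: direct evaluation of the conversion formulas
  m0 <- 0.05
  m1 <- 0.005
  q1 <- m0 / (1 + (1 - 0.3) * m0)
  q4 <- 4 * m1 / (1 + (4 - 1.4) * m1)
  q5 <- 1 - (1 - q1) * (1 - q4)
  expect_lt(abs(q1 - 0.048309), 1e-6)
  expect_lt(abs(q4 - 0.019743), 1e-6)
  expect_lt(abs(q5 - 0.067098), 1e-6)

  pop <- flat_population(1000)
  d <- deaths_of(list("male", "<1", "A09", 50), list("male", "1-4", "A09", 5))
  comp <- list(u5mr_estimate = list(year = 2015, value = q5))
  res <- child_mortality(d, pop, comp)
  # <1 and 1-4 population pooled over both sexes (2000 each): m0 = 50/2000
  expect_equal(res$m0, 0.025)
  expect_equal(res$q5_0, 1 - (1 - res$q1_0) * (1 - res$q4_1), tolerance = 1e-12)

  d2 <- deaths_of(list("male", "<1", "A09", 100), list("male", "1-4", "A09", 10))
  res2 <- child_mortality(d2, pop, comp)
  expect_equal(res2$m0, m0)
  expect_equal(res2$q5_0, q5, tolerance = 1e-12)
  expect_equal(res2$child_completeness, 1.0)
})

test_that("the 5q0 identity holds to 1e-12 across random inputs", {
  set.seed(42)
  pop <- flat_population(10000)
  comp <- list(u5mr_estimate = list(year = 2015, value = 0.05))
  for (i in 1:50) {
    d <- deaths_of(
      list("male", "<1", "A09", sample(0:500, 1)),
      list("male", "1-4", "A09", sample(0:200, 1))
    )
    res <- child_mortality(d, pop, comp)
    expect_equal(res$q5_0, 1 - (1 - res$q1_0) * (1 - res$q4_1), tolerance = 1e-12)
  }
})

test_that("neonatal detail is split into fractions of under-5 deaths", {
  d <- as_death_table(tibble::tibble(
    year = 2015, sex = "female", age_group = c("<1", "1-4"),
    icd_code = "P10", count = c(80, 20),
    early_neonatal = c(40, 0), late_neonatal = c(20, 0), post_neonatal = c(20, 0)
  ))
  res <- child_mortality(d, flat_population(1000), list(u5mr_estimate = list(value = 0.05)))
  expect_equal(unname(res$neonatal_split), c(0.4, 0.2, 0.2, 0.2))
  expect_equal(sum(res$neonatal_split), 1, tolerance = 1e-9)
})
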