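test_that("population generation is deterministic with the stated structure", {
  p1 <- generate_population(1e6, ageing = 0.02, seed = 1)
  p2 <- generate_population(1e6, ageing = 0.02, seed = 1)
  expect_identical(p1, p2)
  expect_equal(sum(p1$count), 1e6)

  # strong ageing parameter: young, monotone-declining pyramid
  young <- generate_population(1e6, ageing = 0.05)
  m <- young$count[young$sex == "male"]
  # 5-year bands decline with age (the open interval pools 15 years, so it
  # is excluded from the monotonicity check)
  closed <- m[3:(length(m) - 1)]
  expect_true(all(diff(closed) < 0))

  # share aged 65+ matches the closed-form structure weights
  w <- population_structure_weights(0.02)
  info <- age_group_info()
  expected65 <- sum(w$weight[info$lower >= 65])
  observed65 <- sum(p1$count[p1$age_group %in% info$age_group[info$lower >= 65]]) / sum(p1$count)
  expect_equal(observed65, expected65, tolerance = 1e-5)

  expect_error(generate_population(0), class = "codqc_input_error")
})

test_that("deterministic deaths equal rounded population x rate per band", {
  pop <- generate_population(5e5)
  sch <- default_schedule()
  gen <- generate_true_deaths(pop, sch, mode = "deterministic")
  info <- age_group_info()
  for (sx in c("male", "female")) {
    div <- if (sx == "female") sch$sex_ratio else 1
    m <- (sch$lambda + sch$alpha * exp(sch$beta * info$midpoint)) / div
    m[1] <- sch$m0 / div
    m[2] <- sch$m1 / div
    p <- pop$count[pop$sex == sx][match(info$age_group, pop$age_group[pop$sex == sx])]
    expected <- round(p * m)
    observed <- sapply(info$age_group, function(a) {
      sum(gen$deaths$count[gen$deaths$sex == sx & gen$deaths$age_group == a])
    })
    expect_equal(unname(observed), unname(expected))
  }
})

test_that("a pure Gompertz schedule gives exactly log-linear band rates", {
  sch <- utils::modifyList(default_schedule(), list(lambda = 0))
  info <- age_group_info()
  adult <- info$lower >= 5
  m <- sch$alpha * exp(sch$beta * info$midpoint[adult])
  fit <- stats::lm(log(m) ~ info$midpoint[adult])
  expect_equal(unname(stats::coef(fit)[2]), sch$beta, tolerance = 1e-12)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1, tolerance = 1e-12)
})

test_that("poisson mode death counts are unbiased against expectations", {
  pop <- generate_population(2e5)
  sch <- default_schedule()
  totals <- sapply(1:20, function(s) {
    sum(generate_true_deaths(pop, sch, seed = s, mode = "poisson")$deaths$count)
  })
  expected <- sum(generate_true_deaths(pop, sch, mode = "deterministic")$truth$expected$expected)
  se <- sqrt(expected / 20)
  expect_lt(abs(mean(totals) - expected), 4 * se)
})

test_that("degradation with all defects zero is the identity", {
  sim <- small_sim()
  deg <- degrade(sim$deaths_true, default_defects(), mode = "deterministic")
  expect_equal(tibble::as_tibble(deg$deaths), tibble::as_tibble(sim$deaths_true))
})

test_that("deterministic defects are realized exactly up to rounding", {
  sim <- small_sim()
  total <- sum(sim$deaths_true$count)

  thin <- degrade(sim$deaths_true, list(completeness = 0.7), mode = "deterministic")
  expect_lte(abs(sum(thin$deaths$count) - 0.7 * total), 1)

  g <- degrade(sim$deaths_true, list(garbage = c(0.10, 0.05, 0.03, 0.02)), mode = "deterministic")
  expect_equal(sum(g$deaths$count), total) # recoding conserves totals
  typ <- typology_distributions(g$deaths, default_meta())
  expect_lt(max(abs(typ$by_severity$fraction - c(0.10, 0.05, 0.03, 0.02))), 1e-3)

  miss <- degrade(sim$deaths_true, list(missing_age = 0.1, missing_sex = 0.05), mode = "deterministic")
  expect_equal(agesex_component(miss$deaths), 0.85, tolerance = 1e-3)

  imp <- degrade(sim$deaths_true, list(implausible = 0.02), mode = "deterministic")
  expect_equal(plausibility_component(imp$deaths)$score, 0.98, tolerance = 1e-3)
})

test_that("stochastic garbage recoding matches the requested mix on average", {
  sim <- simulate_dataset(seed = 3, size = 2e5, mode = "poisson")
  mix <- c(0.08, 0.04, 0.02, 0.02)
  fr <- sapply(1:20, function(s) {
    deg <- degrade(sim$deaths_true, list(garbage = mix), seed = s, mode = "poisson")
    typology_distributions(deg$deaths, default_meta())$by_severity$fraction
  })
  # per-level SE of the mean over 20 draws is about 7e-4
  expect_lt(max(abs(rowMeans(fr) - mix)), 0.004)
})

test_that("identical seeds and configs produce byte-identical datasets", {
  a <- simulate_dataset(seed = 9, size = 1e5, mode = "poisson",
    defects = list(completeness = 0.8, garbage = c(0.05, 0, 0, 0)))
  b <- simulate_dataset(seed = 9, size = 1e5, mode = "poisson",
    defects = list(completeness = 0.8, garbage = c(0.05, 0, 0, 0)))
  expect_identical(tibble::as_tibble(a$deaths), tibble::as_tibble(b$deaths))
  expect_identical(a$truth$true_cdr, b$truth$true_cdr)
})

test_that("truth-derived comparators score undegraded data as perfect", {
  sim <- small_sim()
  comp <- sim$comparators
  cdr <- 1000 * sum(sim$deaths_true$count) / sim$truth$total_population
  expect_equal(completeness_from_comparator(cdr, comp, 2015)$completeness, 1.0)
  expect_equal(sum(comp$broad_group_envelope), 1, tolerance = 1e-9)
  mix <- broad_group_distribution(sim$deaths_true, default_meta())
  expect_equal(
    unname(comp$broad_group_envelope[c("group1", "group2", "group3")]),
    mix$fraction[match(c("group1", "group2", "group3"), mix$bin)],
    tolerance = 1e-9
  )
  expect_true(2015 >= min(comp$cdr_trend$year) && 2015 <= max(comp$cdr_trend$year))
  child <- child_mortality(sim$deaths_true, sim$population, comp)
  expect_equal(child$child_completeness, 1.0)
})

test_that("generated deaths respect the biological edit rules", {
  sim <- small_sim()
  expect_equal(plausibility_component(sim$deaths_true)$score, 1.0)
})
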