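test_that("usability distribution splits deaths three ways", {
  meta <- default_meta()
  d <- deaths_of(list("male", "60-64", "I21", 100))
  u <- usability_distribution(d, meta)
  expect_equal(u$fraction[u$usability == "usable"], 1.0)

  d2 <- deaths_of(list("male", "60-64", "I21", 50), list("male", "60-64", "R99", 50))
  u2 <- usability_distribution(d2, meta)
  expect_equal(u2$fraction[u2$usability == "usable"], 0.5)
  expect_equal(u2$fraction[u2$usability == "unusable"], 0.5)

  d3 <- deaths_of(list("male", "60-64", "missing", 10))
  u3 <- usability_distribution(d3, meta)
  expect_equal(u3$fraction[u3$usability == "insufficiently_specified"], 1.0)

  expect_error(usability_distribution(d[0, ], meta), class = "codqc_input_error")
})

test_that("broad-group distribution conserves totals overall and by age", {
  meta <- default_meta()
  d <- deaths_of(
    list("male", "<1", "A09", 30), list("male", "20-24", "V02", 20),
    list("male", "60-64", "I21", 40), list("male", "60-64", "R99", 10)
  )
  overall <- broad_group_distribution(d, meta)
  expect_equal(sum(overall$count), 100)
  expect_equal(sum(overall$fraction), 1, tolerance = 1e-9)
  expect_equal(overall$count[overall$bin == "group1"], 30)
  expect_equal(overall$count[overall$bin == "group3"], 20)

  by_age <- broad_group_distribution(d, meta, by_age = TRUE)
  agg <- dplyr::summarise(dplyr::group_by(by_age, bin), count = sum(count))
  expect_equal(
    agg$count[match(overall$bin, agg$bin)], overall$count
  )

  single <- broad_group_distribution(deaths_of(list("male", "<1", "A09", 5)), meta)
  expect_equal(single$fraction[single$bin == "group1"], 1.0)
})

test_that("epidemiological transition measure is the G1 share of G1+G2", {
  meta <- default_meta()
  comp <- list(broad_group_envelope = c(group1 = 0.3, group2 = 0.6, group3 = 0.1))
  d <- deaths_of(list("male", "<1", "A09", 50), list("male", "60-64", "I21", 50))
  m <- epi_transition_measure(broad_group_distribution(d, meta), comp)
  expect_equal(m$measure, 0.5)
  expect_equal(m$comparator_measure, 1 / 3)
  expect_equal(m$delta, 0.5 - 1 / 3)

  d2 <- deaths_of(list("male", "60-64", "I21", 50))
  expect_equal(epi_transition_measure(broad_group_distribution(d2, meta), comp)$measure, 0)

  d3 <- deaths_of(list("male", "20-24", "V02", 50))
  expect_false(epi_transition_measure(broad_group_distribution(d3, meta), comp)$defined)
})

test_that("typology histograms cover garbage deaths only, fractions of all deaths", {
  meta <- default_meta()
  d <- deaths_of(list("male", "60-64", "R99", 100), list("male", "60-64", "I21", 100))
  t <- typology_distributions(d, meta)
  expect_equal(t$by_category$count[t$by_category$category == 1], 100)
  expect_equal(t$by_severity$count[t$by_severity$severity == 1], 100)
  expect_equal(t$by_severity$fraction[t$by_severity$severity == 1], 0.5)
  expect_equal(t$garbage_deaths, 100)

  clean <- typology_distributions(deaths_of(list("male", "60-64", "I21", 5)), meta)
  expect_true(all(clean$by_category$count == 0))
  expect_true(all(clean$by_severity$count == 0))
})

test_that("package extraction ranks members by count with code tie-breaks", {
  meta <- default_meta()
  d <- deaths_of(
    list("male", "60-64", "A41", 6547), list("male", "60-64", "D65", 242),
    list("male", "60-64", "R02", 10), list("male", "60-64", "A40", 5),
    list("male", "60-64", "I10", 300)
  )
  pk <- extract_packages(d, meta)
  sepsis <- pk[pk$package == "sepsis", ]
  expect_equal(sepsis$code, c("A41", "D65", "R02", "A40"))
  expect_equal(sepsis$count, c(6547, 242, 10, 5))
  expect_equal(unique(sepsis$package_rank), 1)
  expect_equal(pk$package_rank[pk$package == "hypertension"][1], 2)

  # tie broken lexicographically
  tie <- extract_packages(deaths_of(
    list("male", "60-64", "D65", 7), list("male", "60-64", "A41", 7)
  ), meta)
  expect_equal(tie$code, c("A41", "D65"))

  one <- extract_packages(deaths_of(list("male", "60-64", "J96", 3)), meta)
  expect_equal(nrow(one), 1)
})

test_that("garbage redistribution is proportional within stratum and conserves totals", {
  meta <- default_meta()
  d <- deaths_of(
    list("male", "60-64", "I21", 30), # usable, group2
    list("male", "60-64", "A09", 70), # usable, group1
    list("male", "60-64", "A41", 100) # sepsis: targets group1;group2
  )
  # usable in stratum: group1 70, group2 30 -> the 100 garbage split 70/30
  res <- redistribute_garbage(d, meta)
  expect_equal(res$after$count[res$after$bin == "group1"], 70 + 70)
  expect_equal(res$after$count[res$after$bin == "group2"], 30 + 30)
  expect_equal(sum(res$after$count), sum(d$count), tolerance = 1e-9)
  expect_true(all(res$after$count >= 0))

  # empty stratum target mass falls back to the global distribution
  d2 <- deaths_of(
    list("male", "60-64", "A41", 10),
    list("female", "30-34", "A09", 3), list("female", "30-34", "I21", 1)
  )
  res2 <- redistribute_garbage(d2, meta)
  expect_equal(res2$after$count[res2$after$bin == "group1"], 3 + 7.5)
  expect_equal(sum(res2$after$count), 14, tolerance = 1e-9)

  # no usable deaths anywhere: equal split over the target set
  d3 <- deaths_of(list("male", "60-64", "A41", 10))
  res3 <- redistribute_garbage(d3, meta)
  expect_equal(res3$after$count[res3$after$bin == "group1"], 5)
  expect_equal(res3$after$count[res3$after$bin == "group2"], 5)

  # idempotent on garbage-free input
  clean <- deaths_of(list("male", "60-64", "I21", 10))
  res4 <- redistribute_garbage(clean, meta)
  expect_equal(res4$after$count, res4$before$count)
  expect_equal(nrow(res4$audit), 0)
})

test_that("redistribution recovers pre-injection group fractions on synthetic data", {
  sim <- small_sim()
  true_mix <- sim$truth$true_group_mix
  deg <- degrade(sim$deaths_true, list(garbage = c(0.1, 0.03, 0.03, 0.04)),
    mode = "deterministic"
  )
  res <- redistribute_garbage(deg$deaths, default_meta())
  after_mix <- res$after$fraction[match(names(true_mix), res$after$bin)]
  expect_equal(unname(after_mix), unname(true_mix), tolerance = 0.02)
  expect_equal(sum(res$after$count), sum(deg$deaths$count), tolerance = 1e-9)
})

test_that("leading causes flag garbage by severity and cap at n", {
  meta <- default_meta()
  d <- deaths_of(
    list("male", "60-64", "A41", 500),
    list("male", "60-64", "I21", 300),
    list("male", "60-64", "I64", 200)
  )
  lc <- leading_causes(d, meta)
  expect_equal(lc$flag[1], "red") # A41, severity 1
  expect_equal(lc$flag[lc$label == "Stroke, not specified as haemorrhage or infarction"], "orange")
  expect_equal(lc$flag[lc$label == "Acute myocardial infarction"], "none")
  expect_true(all(diff(lc$count) <= 0))

  clean <- leading_causes(deaths_of(list("male", "60-64", "I21", 10)), meta)
  expect_true(all(clean$flag == "none"))

  few <- leading_causes(d, meta, n = 50)
  expect_equal(nrow(few), 3)
})
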