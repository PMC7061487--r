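test_that("ICD-10 codes are normalized and malformed ones rejected", {
  v <- validate_icd10_code(c("i21.9", "A41", "1234", "J96", "missing"))
  expect_equal(v$code[1:2], c("I219", "A41"))
  expect_equal(v$status[3], "invalid_code")
  expect_true(is.na(v$code[3]))
  expect_equal(v$code[4], "J96")
  expect_equal(v$status[5], "missing")
})

test_that("death tables are normalized: keys summed, aliases mapped, errors hard", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "year,sex,age_group,icd_code,count",
    "2015,1,50-54,A41,3",
    "2015,male,50-54,a41,2",
    "2015,2,0,J12,4"
  ), f)
  d <- read_death_table(f)
  expect_equal(nrow(d), 2)
  expect_equal(d$count[d$icd_code == "A41"], 5)
  expect_equal(d$age_group[d$sex == "female"], "<1")
  expect_equal(sum(d$count), 9) # conservation

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,sex,age_group,icd_code,count", "2015,1,50-54,A41,-1"), f2)
  expect_error(read_death_table(f2), "row 1", class = "codqc_input_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,sex,age_group,count", "2015,1,50-54,3"), f3)
  expect_error(read_death_table(f3), "missing mandatory column", class = "codqc_input_error")
})

test_that("write/read round-trip is byte-identical on normalized content", {
  sim <- small_sim()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_death_table(sim$deaths, f1)
  write_death_table(read_death_table(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("population reader enforces the age ladder and merges duplicates", {
  pop <- flat_population(100)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(pop), f)
  p <- read_population_table(f)
  expect_setequal(unique(p$age_group), age_ladder())

  # duplicate key: summed with a warning
  dup <- dplyr::bind_rows(tibble::as_tibble(pop), tibble::as_tibble(pop)[1, ])
  readr::write_csv(dup, f)
  expect_warning(p2 <- read_population_table(f), "summed")
  expect_equal(sum(p2$count), sum(pop$count) + pop$count[1])

  # missing open-interval band: hard error
  readr::write_csv(tibble::as_tibble(pop)[pop$age_group != "85+", ], f)
  expect_error(read_population_table(f), "Incomplete age ladder", class = "codqc_input_error")
})

test_that("default metadata carries the canonical garbage classifications", {
  meta <- default_meta()
  a41 <- classify_code("A41", meta)
  expect_equal(a41$usability, "unusable")
  expect_equal(a41$severity_level, 1)
  expect_equal(a41$package, "sepsis")
  expect_equal(classify_code("I64", meta)$severity_level, 4)
  # all four sepsis-package members
  sep <- classify_code(c("A40", "A41", "D65", "R02"), meta)
  expect_true(all(sep$package == "sepsis"))
  # a 4-digit code resolves through its 3-character category
  expect_equal(classify_code("I219", meta)$usability, "usable")
})

test_that("overlapping metadata patterns are a hard error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "code_pattern,label,usability,broad_group,icd_error_category,severity_level,package,redistribution_targets",
    "A40-A41,Septicaemia,unusable,none,3,1,sepsis,group1;group2",
    "A41,Other septicaemia,unusable,none,3,1,sepsis,group1;group2"
  ), f)
  expect_error(load_code_metadata(f), "Overlapping", class = "codqc_input_error")
})

test_that("metadata expansion is total over declared ranges", {
  meta <- default_meta()
  map <- attr(meta, "expanded")
  # every category inside every declared range resolves to exactly one row
  expect_false(anyDuplicated(map$category) > 0)
  for (code in c("R00", "R47", "R99", "Y10", "Y34")) {
    expect_equal(sum(map$category == code), 1)
  }
})

test_that("unmapped codes fall back to insufficiently specified with a warning", {
  expect_warning(cls <- classify_code("Z99", default_meta()), "not in metadata")
  expect_equal(cls$usability, "insufficiently_specified")
  expect_equal(cls$severity_level, 3)
  expect_equal(cls$icd_error_category, 5)
})

test_that("comparator files validate their blocks", {
  comp <- load_comparators()
  expect_length(comp$reference_cause_list, 192)
  expect_true(all(diff(comp$cdr_trend$year) > 0))
  expect_equal(sum(comp$broad_group_envelope), 1, tolerance = 1e-9)

  bad <- list(
    cdr_trend = list(year = c(2000, 2005), cdr = c(8, 8)),
    u5mr_estimate = list(year = 2015, value = 0.03),
    broad_group_envelope = list(group1 = 0.3, group2 = 0.6, group3 = 0.2),
    reference_cause_list = c("A00", "A01")
  )
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(load_comparators(f), "sum to 1", class = "codqc_input_error")

  bad$broad_group_envelope$group3 <- 0.1
  bad$cdr_trend$year <- c(2005, 2000)
  yaml::write_yaml(bad, f)
  expect_error(load_comparators(f), "strictly increasing", class = "codqc_input_error")
})
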