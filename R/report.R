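#' Default assessment configuration
#'
#' Every tunable of the ten-step assessment in one list: the age ladder's
#' open interval, life-table separation factors, the log-linearity age
#' floor, the small-dataset warning threshold, the completeness method
#' feeding the composite, the empirical-model coefficients, the female
#' excess tolerance, and the component score transforms. All values are
#' echoed into the report for auditability.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    open_age = 85,
    a0 = 0.3, a1 = 1.4,
    loglin_min_age = 30,
    small_numbers_threshold = 4000,
    completeness_method = "comparator", # or "empirical" or "weighted"
    # the empirical completeness model runs only when coefficients are
    # supplied; no published defaults are bundled
    empirical_coefficients = NULL,
    female_excess_tolerance = 0,
    leading_n = 20,
    transforms = NULL
  )
}

#' Run the full ten-step quality assessment
#'
#' Executes every diagnostic step on a validated death tabulation:
#' age-sex structure (step 1), registration completeness (step 2), age and
#' sex consistency (steps 3-4), child mortality (step 5), cause usability,
#' broad groups, garbage typologies, packages and redistribution (steps
#' 6-8), leading causes (step 9) and the composite VSPI(Q) with gap
#' attribution (step 10). Steps needing a population (2-5) or comparators
#' are skipped with an explicit note when those inputs are absent. A
#' warning is recorded when the dataset holds fewer than 4,000 deaths,
#' below which several checks become unstable.
#'
#' @param deaths A `codqc_deaths` tibble (or path to a deaths CSV).
#' @param population Optional `codqc_population` tibble (or path).
#' @param comparators Optional `codqc_comparators` object (or path).
#' @param metadata Code metadata (default packaged table).
#' @param config Configuration overrides, merged over [default_config()].
#' @return A `codqc_report` object with elements `step1` ... `step10`,
#'   `warnings`, `skipped`, `config`.
#' @export
run_assessment <- function(deaths, population = NULL, comparators = NULL,
                           metadata = load_code_metadata(),
                           config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(deaths)) deaths <- read_death_table(deaths, list(open_age = cfg$open_age))
  if (is.character(population)) population <- read_population_table(population, list(open_age = cfg$open_age))
  if (is.character(comparators)) comparators <- load_comparators(comparators)
  if (nrow(deaths) == 0 || sum(deaths$count) == 0) {
    abort("Death table is empty.", class = "codqc_input_error")
  }
  warnings <- character()
  skipped <- character()
  total_deaths <- sum(deaths$count)
  if (total_deaths < cfg$small_numbers_threshold) {
    warnings <- c(warnings, sprintf(
      "small_numbers: only %d deaths (< %d); several checks are unstable at this size.",
      round(total_deaths), cfg$small_numbers_threshold
    ))
  }
  year <- deaths$year[1]
  has_pop <- !is.null(population)
  has_comp <- !is.null(comparators)

  report <- list()
  report$step1 <- list(
    deaths_pyramid = tabulate_age_sex(deaths),
    population_pyramid = if (has_pop) tabulate_age_sex(population) else NULL
  )

  child <- NULL
  if (has_pop) {
    cdr <- crude_death_rate(deaths, population)
    rates <- age_specific_rates(deaths, population)
    comp_comparator <- NULL
    if (has_comp) {
      comp_comparator <- withCallingHandlers(
        completeness_from_comparator(cdr, comparators, year),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      child <- child_mortality(deaths, population, comparators, a0 = cfg$a0, a1 = cfg$a1)
    } else {
      skipped <- c(skipped, "step2_comparator: no comparator set supplied")
      skipped <- c(skipped, "step5: no comparator set supplied")
    }
    comp_empirical <- NULL
    if (!is.null(child) && !is.null(cfg$empirical_coefficients)) {
      comp_empirical <- tryCatch(
        withCallingHandlers(
          completeness_empirical(deaths, population, child$child_completeness,
            coefficients = cfg$empirical_coefficients, a0 = cfg$a0, a1 = cfg$a1
          ),
          warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        ),
        error = function(e) NULL
      )
    }
    comp_weighted <- NULL
    if (!is.null(child) && !is.null(comp_comparator)) {
      d_u5 <- sum(deaths$count[deaths$age_group %in% c("<1", "1-4")])
      comp_weighted <- tryCatch(
        completeness_weighted(
          child$child_completeness, comp_comparator$completeness,
          d_u5, total_deaths - d_u5
        ),
        error = function(e) NULL
      )
    }
    report$step2 <- list(
      cdr_observed = cdr, comparator = comp_comparator,
      empirical = comp_empirical, weighted = comp_weighted
    )
    report$step3 <- list(
      rates = rates,
      loglin = tryCatch(log_linearity_check(rates, min_age = cfg$loglin_min_age),
        error = function(e) {
          skipped <<- c(skipped, paste0("step3_loglin: ", conditionMessage(e)))
          NULL
        }
      )
    )
    report$step4 <- sex_pattern_check(rates, tolerance = cfg$female_excess_tolerance)
    report$step5 <- child
  } else {
    skipped <- c(skipped, paste0(
      "step", 2:5, ": population table absent; rate-based checks not run"
    ))
  }

  usab <- usability_distribution(deaths, metadata)
  typ <- typology_distributions(deaths, metadata)
  report$step6 <- list(
    usability = usab,
    typology_category = typ$by_category,
    typology_severity = typ$by_severity,
    packages = extract_packages(deaths, metadata)
  )
  dist <- broad_group_distribution(deaths, metadata)
  redis <- redistribute_garbage(deaths, metadata)
  report$step7 <- list(
    broad_groups = dist,
    epi_transition = if (has_comp) epi_transition_measure(dist, comparators) else NULL,
    redistribution = redis
  )
  report$step8 <- list(broad_groups_by_age = broad_group_distribution(deaths, metadata, by_age = TRUE))
  report$step9 <- leading_causes(deaths, metadata, n = cfg$leading_n)

  plaus <- plausibility_component(deaths)
  s_completeness <- NA_real_
  if (has_pop && has_comp) {
    s_completeness <- switch(cfg$completeness_method,
      comparator = report$step2$comparator$completeness,
      empirical = report$step2$empirical$completeness %||% NA_real_,
      weighted = report$step2$weighted %||% NA_real_,
      abort("Unknown completeness_method.", class = "codqc_config_error")
    )
  }
  s <- c(
    completeness = s_completeness,
    garbage = garbage_component(typ$by_severity$fraction),
    detail = if (has_comp) detail_component(deaths, comparators$reference_cause_list) else NA_real_,
    agesex = agesex_component(deaths),
    plausibility = plaus$score
  )
  available <- !is.na(s)
  vspiq <- NULL
  if (all(available)) {
    vspiq <- vspiq_score(s, transforms = cfg$transforms)
  } else {
    skipped <- c(skipped, sprintf(
      "step10_composite: component(s) unavailable (%s); composite computed over available components only",
      paste(names(s)[!available], collapse = ", ")
    ))
    vspiq <- vspiq_score(replace(s, !available, 1), transforms = cfg$transforms)
    vspiq$partial <- TRUE
    vspiq$components$raw[!available] <- NA_real_
  }
  report$step10 <- list(components = s, vspiq = vspiq, plausibility_audit = plaus$violations)

  structure(
    list(
      steps = report, warnings = warnings, skipped = skipped,
      config = cfg, total_deaths = total_deaths, year = year,
      package_version = as.character(utils::packageVersion("codqc"))
    ),
    class = "codqc_report"
  )
}

#' @export
print.codqc_report <- function(x, ...) {
  cat(sprintf(
    "Mortality data-quality assessment (%d deaths, year %s)\n",
    round(x$total_deaths), x$year
  ))
  if (!is.null(x$steps$step10$vspiq)) {
    cat(sprintf("VSPI(Q): %.1f / 100%s\n", x$steps$step10$vspiq$composite,
      if (isTRUE(x$steps$step10$vspiq$partial)) " (partial)" else ""))
  }
  if (length(x$warnings)) cat("Warnings:\n", paste0("  - ", x$warnings, collapse = "\n"), "\n")
  if (length(x$skipped)) cat("Skipped:\n", paste0("  - ", x$skipped, collapse = "\n"), "\n")
  invisible(x)
}

#' Export an assessment report to disk
#'
#' Writes a machine-readable JSON master report plus one tidy CSV per step
#' table and the cleaned (normalized) death tabulation, with deterministic
#' file naming so re-exports are byte-identical.
#'
#' @param report A `codqc_report`.
#' @param out_dir Output directory (created if needed).
#' @param deaths Optional normalized `codqc_deaths` to write as
#'   `cleaned_deaths.csv`.
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(report, out_dir, deaths = NULL) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir), class = "codqc_input_error")
  }
  files <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(as_tibble(df), p)
    files <<- c(files, p)
  }
  st <- report$steps
  wr(st$step1$deaths_pyramid, "step1_deaths_pyramid.csv")
  if (!is.null(st$step1$population_pyramid)) wr(st$step1$population_pyramid, "step1_population_pyramid.csv")
  if (!is.null(st$step3)) wr(st$step3$rates, "step3_rates.csv")
  if (!is.null(st$step6)) {
    wr(st$step6$usability, "step6_usability.csv")
    wr(st$step6$typology_category, "step6_typology_category.csv")
    wr(st$step6$typology_severity, "step6_typology_severity.csv")
    wr(st$step6$packages, "step6_packages.csv")
  }
  if (!is.null(st$step7)) {
    wr(st$step7$broad_groups, "step7_broad_groups.csv")
    wr(st$step7$redistribution$after, "step7_redistributed.csv")
  }
  if (!is.null(st$step8)) wr(st$step8$broad_groups_by_age, "step8_broad_groups_by_age.csv")
  if (!is.null(st$step9)) wr(st$step9, "step9_leading_causes.csv")
  wr(st$step10$vspiq$components, "step10_vspiq_components.csv")
  if (!is.null(deaths)) {
    p <- file.path(out_dir, "cleaned_deaths.csv")
    write_death_table(deaths, p)
    files <- c(files, p)
  }
  master <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_to_list(report), master, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, master)
  invisible(files)
}

# Flatten the report into plain lists/data frames for JSON serialization.
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "codqc_loglin")) {
      return(list(fits = as.data.frame(x$fits), flags = as.data.frame(x$flags), min_age = x$min_age))
    }
    if (inherits(x, "codqc_vspiq")) {
      return(list(
        composite = x$composite, components = as.data.frame(x$components),
        partial = isTRUE(x$partial)
      ))
    }
    if (inherits(x, "codqc_child")) {
      return(x[c("m0", "m1", "q1_0", "q4_1", "q5_0", "comparator_q5_0", "child_completeness", "raw_ratio", "neonatal_split")])
    }
    if (is.data.frame(x)) {
      return(as.data.frame(x))
    }
    if (is.list(x)) {
      return(lapply(x, strip))
    }
    if (is.atomic(x) && !is.null(names(x))) {
      return(as.list(x))
    }
    x
  }
  list(
    steps = strip(report$steps),
    warnings = report$warnings,
    skipped = report$skipped,
    config = strip(report$config),
    total_deaths = report$total_deaths,
    year = report$year,
    package_version = report$package_version
  )
}

#' Recompute the VSPI(Q) composite from a stored report
#'
#' Reads the component scores stored in a `report.json` and recomputes the
#' composite, so a stored report can always be checked against its own
#' components.
#'
#' @param path Path to a `report.json` written by [export_report()].
#' @return A `codqc_vspiq` object.
#' @export
recompute_vspiq <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- obj$steps$step10$components
  s <- unlist(comps)
  s[is.na(s)] <- 1
  vspiq_score(s[c("completeness", "garbage", "detail", "agesex", "plausibility")])
}
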