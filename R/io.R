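#' Read and normalize a death tabulation
#'
#' Expects a delimited text file with columns `year`, `sex`, `age_group`,
#' `icd_code`, `count` (configurable names), plus optional neonatal detail
#' columns `early_neonatal`, `late_neonatal`, `post_neonatal` on `"<1"`
#' rows. Sex may be coded 1/2/9 or male/female/unknown; age labels are
#' mapped through an alias table (e.g. `"0"` to `"<1"`). ICD codes are
#' normalized (uppercased, dot-stripped); empty codes become `"missing"`.
#' Rows sharing a (year, sex, age_group, icd_code) key are summed.
#'
#' @param path File path.
#' @param format_config Optional list: `columns` (named vector mapping the
#'   standard names to the file's column names), `delim` (default ","),
#'   `open_age` (default 85).
#' @return A `codqc_deaths` tibble. Attribute `"report"` records the
#'   normalization (rows merged, counts in/out); malformed codes and
#'   negative counts are hard errors, not repairs.
#' @export
read_death_table <- function(path, format_config = list()) {
  cfg <- utils::modifyList(
    list(
      columns = c(
        year = "year", sex = "sex", age_group = "age_group",
        icd_code = "icd_code", count = "count"
      ),
      delim = ",", open_age = 85
    ),
    format_config
  )
  raw <- readr::read_delim(path, delim = cfg$delim, col_types = readr::cols(.default = readr::col_character()), na = character())
  miss <- setdiff(unname(cfg$columns), names(raw))
  if (length(miss)) {
    abort(sprintf("Death file missing mandatory column(s): %s", paste(miss, collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  df <- tibble(
    year = as.integer(raw[[cfg$columns[["year"]]]]),
    sex = normalize_sex(raw[[cfg$columns[["sex"]]]]),
    age_group = normalize_age_group(raw[[cfg$columns[["age_group"]]]], cfg$open_age),
    count = suppressWarnings(as.numeric(raw[[cfg$columns[["count"]]]]))
  )
  v <- validate_icd10_code(raw[[cfg$columns[["icd_code"]]]])
  if (any(v$status == "invalid_code")) {
    bad <- which(v$status == "invalid_code")[1]
    abort(sprintf("Invalid ICD-10 code '%s' at data row %d.", v$raw[bad], bad),
      class = "codqc_input_error"
    )
  }
  df$icd_code <- v$code
  if (anyNA(df$count) || any(df$count < 0) || any(df$count != floor(df$count))) {
    bad <- which(is.na(df$count) | df$count < 0 | df$count != floor(df$count))[1]
    abort(sprintf("Non-negative integer count required; offending data row %d.", bad),
      class = "codqc_input_error"
    )
  }
  neo_cols <- intersect(c("early_neonatal", "late_neonatal", "post_neonatal"), names(raw))
  for (nc in neo_cols) df[[nc]] <- suppressWarnings(as.numeric(raw[[nc]]))

  n_before <- nrow(df)
  out <- df |>
    group_by(.data$year, .data$sex, .data$age_group, .data$icd_code) |>
    summarise(across(dplyr::any_of(c("count", neo_cols)), \(x) sum(x, na.rm = TRUE)), .groups = "drop")
  if (length(neo_cols) == 3) {
    u1 <- out$age_group == "<1"
    neo_sum <- rowSums(out[u1, neo_cols, drop = FALSE])
    off <- which(abs(neo_sum - out$count[u1]) > 1e-9 & neo_sum > 0)
    if (length(off)) {
      abort("Neonatal detail does not sum to the '<1' count.", class = "codqc_input_error")
    }
  }
  report <- tibble(
    action = "merged_duplicate_keys",
    rows_in = n_before, rows_out = nrow(out),
    counts_in = sum(df$count), counts_out = sum(out$count)
  )
  new_death_table(out, open_age = cfg$open_age, report = report)
}

new_death_table <- function(df, open_age = 85, report = NULL) {
  df <- arrange(
    as_tibble(df),
    .data$year, .data$sex,
    factor(.data$age_group, levels = c(age_ladder(open_age), "unknown")),
    .data$icd_code
  )
  structure(df,
    open_age = open_age, report = report,
    class = c("codqc_deaths", class(as_tibble(df)))
  )
}

#' Write a normalized death tabulation
#'
#' Writes the canonical CSV form (stable column order and row sort) so that
#' read/write round-trips are byte-identical.
#'
#' @param deaths A `codqc_deaths` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_death_table <- function(deaths, path) {
  cols <- intersect(
    c("year", "sex", "age_group", "icd_code", "count", "early_neonatal", "late_neonatal", "post_neonatal"),
    names(deaths)
  )
  readr::write_csv(as_tibble(deaths)[cols], path)
  invisible(path)
}

#' Read and normalize a population tabulation
#'
#' As [read_death_table()] but without an ICD column, and with a complete
#' age-ladder requirement: every ladder band must be present for each sex.
#' Duplicate keys are summed with a warning.
#'
#' @inheritParams read_death_table
#' @return A `codqc_population` tibble.
#' @export
read_population_table <- function(path, format_config = list()) {
  cfg <- utils::modifyList(
    list(
      columns = c(year = "year", sex = "sex", age_group = "age_group", count = "count"),
      delim = ",", open_age = 85
    ),
    format_config
  )
  raw <- readr::read_delim(path, delim = cfg$delim, col_types = readr::cols(.default = readr::col_character()), na = character())
  miss <- setdiff(unname(cfg$columns), names(raw))
  if (length(miss)) {
    abort(sprintf("Population file missing mandatory column(s): %s", paste(miss, collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  df <- tibble(
    year = as.integer(raw[[cfg$columns[["year"]]]]),
    sex = normalize_sex(raw[[cfg$columns[["sex"]]]]),
    age_group = normalize_age_group(raw[[cfg$columns[["age_group"]]]], cfg$open_age),
    count = suppressWarnings(as.numeric(raw[[cfg$columns[["count"]]]]))
  )
  if (anyNA(df$count) || any(df$count < 0)) {
    bad <- which(is.na(df$count) | df$count < 0)[1]
    abort(sprintf("Non-negative count required; offending data row %d.", bad),
      class = "codqc_input_error"
    )
  }
  if (any(df$sex == "unknown")) {
    abort("Population rows must have sex male or female.", class = "codqc_input_error")
  }
  dup <- anyDuplicated(df[c("year", "sex", "age_group")]) > 0
  out <- df |>
    group_by(.data$year, .data$sex, .data$age_group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (dup) warn("Duplicate population keys summed.")
  ladder <- age_ladder(cfg$open_age)
  for (yr in unique(out$year)) {
    for (sx in unique(out$sex[out$year == yr])) {
      have <- out$age_group[out$year == yr & out$sex == sx]
      gap <- setdiff(ladder, have)
      if (length(gap)) {
        abort(sprintf(
          "Incomplete age ladder for %s %d: missing %s.",
          sx, yr, paste(gap, collapse = ", ")
        ), class = "codqc_input_error")
      }
    }
  }
  new_population_table(out, open_age = cfg$open_age)
}

new_population_table <- function(df, open_age = 85) {
  df <- arrange(
    as_tibble(df),
    .data$year, .data$sex, factor(.data$age_group, levels = age_ladder(open_age))
  )
  structure(df, open_age = open_age, class = c("codqc_population", class(as_tibble(df))))
}

#' Load a comparator set
#'
#' Comparators are external reference series used throughout the
#' assessment: an estimated crude-death-rate trend by year, an estimated
#' under-five mortality (5q0), the expected broad-cause-group envelope, and
#' the reference cause list for the cause-detail score (192 entries in the
#' packaged synthetic fixture). Stored as one YAML (or JSON) file with
#' blocks `cdr_trend`, `u5mr_estimate`, `broad_group_envelope`,
#' `reference_cause_list`.
#'
#' @param path Path to a comparator YAML/JSON file; `NULL` loads the
#'   packaged synthetic fixture.
#' @return A `codqc_comparators` list.
#' @export
load_comparators <- function(path = NULL) {
  path <- path %||% system.file("extdata", "comparators_synthetic.yaml", package = "codqc")
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  need <- c("cdr_trend", "u5mr_estimate", "broad_group_envelope", "reference_cause_list")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    abort(sprintf("Comparator file missing block(s): %s", paste(miss, collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  trend <- as_tibble(obj$cdr_trend)[c("year", "cdr")]
  trend$year <- as.numeric(trend$year)
  trend$cdr <- as.numeric(trend$cdr)
  if (any(diff(trend$year) <= 0)) {
    abort("cdr_trend years must be strictly increasing.", class = "codqc_input_error")
  }
  env <- unlist(obj$broad_group_envelope)[c("group1", "group2", "group3")]
  if (anyNA(env) || abs(sum(env) - 1) > 1e-9) {
    abort("broad_group_envelope must name group1/group2/group3 and sum to 1.",
      class = "codqc_input_error"
    )
  }
  refs <- as.character(unlist(obj$reference_cause_list))
  if (anyDuplicated(refs)) {
    abort("reference_cause_list entries must be unique.", class = "codqc_input_error")
  }
  new_comparators(
    cdr_trend = trend,
    u5mr_estimate = list(
      year = as.numeric(obj$u5mr_estimate$year),
      value = as.numeric(obj$u5mr_estimate$value)
    ),
    broad_group_envelope = env,
    reference_cause_list = refs
  )
}

new_comparators <- function(cdr_trend, u5mr_estimate, broad_group_envelope, reference_cause_list) {
  structure(
    list(
      cdr_trend = cdr_trend, u5mr_estimate = u5mr_estimate,
      broad_group_envelope = broad_group_envelope,
      reference_cause_list = reference_cause_list
    ),
    class = "codqc_comparators"
  )
}

#' Write a comparator set to YAML
#'
#' @param comparators A `codqc_comparators` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparators <- function(comparators, path) {
  obj <- list(
    cdr_trend = list(
      year = comparators$cdr_trend$year,
      cdr = comparators$cdr_trend$cdr
    ),
    u5mr_estimate = comparators$u5mr_estimate,
    broad_group_envelope = as.list(comparators$broad_group_envelope),
    reference_cause_list = comparators$reference_cause_list
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Build a validated death table from a data frame
#'
#' The in-memory counterpart of [read_death_table()]: normalizes sex codes,
#' age-group aliases and ICD codes, validates counts, and sums duplicate
#' keys.
#'
#' @param df Data frame with columns `year`, `sex`, `age_group`,
#'   `icd_code`, `count` (optional neonatal detail columns are kept).
#' @param open_age Open age interval lower bound (default 85).
#' @return A `codqc_deaths` tibble.
#' @export
#' @examples
#' as_death_table(data.frame(
#'   year = 2015, sex = "male", age_group = "50-54",
#'   icd_code = "I21", count = 5
#' ))
as_death_table <- function(df, open_age = 85) {
  stopifnot(all(c("year", "sex", "age_group", "icd_code", "count") %in% names(df)))
  v <- validate_icd10_code(df$icd_code)
  if (any(v$status == "invalid_code")) {
    abort(sprintf("Invalid ICD-10 code '%s'.", v$raw[v$status == "invalid_code"][1]),
      class = "codqc_input_error"
    )
  }
  if (any(df$count < 0) || any(df$count != floor(df$count))) {
    abort("Counts must be non-negative integers.", class = "codqc_input_error")
  }
  neo <- intersect(c("early_neonatal", "late_neonatal", "post_neonatal"), names(df))
  out <- tibble(
    year = as.integer(df$year),
    sex = normalize_sex(df$sex),
    age_group = normalize_age_group(df$age_group, open_age),
    icd_code = v$code,
    count = as.numeric(df$count)
  )
  for (nc in neo) out[[nc]] <- as.numeric(df[[nc]])
  out <- out |>
    group_by(.data$year, .data$sex, .data$age_group, .data$icd_code) |>
    summarise(across(dplyr::any_of(c("count", neo)), sum), .groups = "drop")
  new_death_table(out, open_age = open_age)
}

#' Build a validated population table from a data frame
#'
#' @param df Data frame with columns `year`, `sex`, `age_group`, `count`.
#' @param open_age Open age interval lower bound (default 85).
#' @return A `codqc_population` tibble.
#' @export
as_population_table <- function(df, open_age = 85) {
  stopifnot(all(c("year", "sex", "age_group", "count") %in% names(df)))
  out <- tibble(
    year = as.integer(df$year),
    sex = normalize_sex(df$sex),
    age_group = normalize_age_group(df$age_group, open_age),
    count = as.numeric(df$count)
  ) |>
    group_by(.data$year, .data$sex, .data$age_group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (any(out$count < 0)) abort("Counts must be non-negative.", class = "codqc_input_error")
  new_population_table(out, open_age = open_age)
}
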