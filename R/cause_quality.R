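# Classify every death row once; used by all step 6-9 operations.
classified_deaths <- function(deaths, metadata) {
  codes <- unique(deaths$icd_code)
  cls <- classify_code(codes, metadata)
  as_tibble(deaths) |> left_join(cls, by = c(icd_code = "code"))
}

#' Usability distribution of causes of death
#'
#' Three-way split of deaths into codes usable for public-health purposes,
#' unusable codes, and insufficiently specified codes. Deaths with no
#' recorded cause count as insufficiently specified.
#'
#' @param deaths A `codqc_deaths` tibble.
#' @param metadata A `codqc_metadata` table.
#' @return Tibble: `usability`, `count`, `fraction`.
#' @export
usability_distribution <- function(deaths, metadata = load_code_metadata()) {
  if (nrow(deaths) == 0 || sum(deaths$count) == 0) {
    abort("Empty death table.", class = "codqc_input_error")
  }
  lv <- c("usable", "unusable", "insufficiently_specified")
  classified_deaths(deaths, metadata) |>
    group_by(usability = factor(.data$usability, levels = lv)) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(usability, fill = list(count = 0)) |>
    mutate(usability = as.character(usability), fraction = .data$count / sum(.data$count))
}

#' Broad-cause-group distribution
#'
#' Five-way split of deaths over the three broad cause groups (group1
#' communicable/maternal/neonatal/nutritional, group2 non-communicable,
#' group3 injuries) plus the two garbage classes, optionally per age band.
#'
#' @inheritParams usability_distribution
#' @param by_age If `TRUE`, also return the split within each age group.
#' @return Tibble `bin`, `count`, `fraction` (plus `age_group` when
#'   `by_age`; fractions are within age group).
#' @export
broad_group_distribution <- function(deaths, metadata = load_code_metadata(), by_age = FALSE) {
  lv <- c("group1", "group2", "group3", "unusable", "insufficiently_specified")
  df <- classified_deaths(deaths, metadata) |>
    mutate(bin = factor(if_else(.data$usability == "usable", .data$broad_group, .data$usability), levels = lv))
  if (by_age) {
    df |>
      group_by(.data$age_group, .data$bin) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::complete(.data$age_group, .data$bin, fill = list(count = 0)) |>
      group_by(.data$age_group) |>
      mutate(fraction = ifelse(sum(.data$count) > 0, .data$count / sum(.data$count), 0)) |>
      ungroup() |>
      mutate(bin = as.character(.data$bin))
  } else {
    df |>
      group_by(.data$bin) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::complete(.data$bin, fill = list(count = 0)) |>
      mutate(bin = as.character(.data$bin), fraction = .data$count / sum(.data$count))
  }
}

#' Epidemiological-transition measure
#'
#' The share of group 1 (communicable) deaths among usable group 1 + group
#' 2 deaths, compared with the same measure computed from the comparator
#' envelope. A population progressing through the epidemiological
#' transition moves this measure towards 0.
#'
#' @param dist A non-age broad-group distribution from
#'   [broad_group_distribution()].
#' @param comparator A `codqc_comparators` object.
#' @return List: `measure`, `comparator_measure`, `delta`, `defined`.
#' @export
epi_transition_measure <- function(dist, comparator) {
  g1 <- dist$count[dist$bin == "group1"]
  g2 <- dist$count[dist$bin == "group2"]
  env <- comparator$broad_group_envelope
  comp <- unname(env[["group1"]] / (env[["group1"]] + env[["group2"]]))
  if (g1 + g2 == 0) {
    return(list(measure = NA_real_, comparator_measure = comp, delta = NA_real_, defined = FALSE))
  }
  m <- g1 / (g1 + g2)
  list(measure = m, comparator_measure = comp, delta = m - comp, defined = TRUE)
}

#' Garbage-code typology distributions
#'
#' Two histograms over garbage deaths: by ICD-error category (1 symptoms /
#' ill-defined, 2 impossible as underlying cause, 3 intermediate, 4
#' immediate, 5 insufficiently specified) and by policy-impact severity
#' level (1 very high to 4 low). Fractions are reported relative to all
#' deaths, so they feed the VSPI(Q) garbage component directly.
#'
#' @inheritParams usability_distribution
#' @return List of tibbles `by_category` (category, count, fraction) and
#'   `by_severity` (severity, count, fraction), plus `total_deaths` and
#'   `garbage_deaths`.
#' @export
typology_distributions <- function(deaths, metadata = load_code_metadata()) {
  df <- classified_deaths(deaths, metadata)
  total <- sum(df$count)
  g <- df |> filter(.data$usability != "usable")
  by_cat <- tibble(category = 1:5) |>
    left_join(
      g |> group_by(category = as.integer(.data$icd_error_category)) |>
        summarise(count = sum(.data$count), .groups = "drop"),
      by = "category"
    ) |>
    mutate(count = dplyr::coalesce(.data$count, 0), fraction = .data$count / total)
  by_sev <- tibble(severity = 1:4) |>
    left_join(
      g |> group_by(severity = as.integer(.data$severity_level)) |>
        summarise(count = sum(.data$count), .groups = "drop"),
      by = "severity"
    ) |>
    mutate(count = dplyr::coalesce(.data$count, 0), fraction = .data$count / total)
  list(
    by_category = by_cat, by_severity = by_sev,
    total_deaths = total, garbage_deaths = sum(g$count)
  )
}

#' Garbage packages ranked by importance
#'
#' Groups garbage deaths into their packages (e.g. sepsis, heart failure,
#' ill-defined) and ranks packages by total deaths; within each package the
#' member code categories are ranked by count (ties broken by code order),
#' so the specific certification practices driving each package are
#' immediately visible.
#'
#' @inheritParams usability_distribution
#' @return Tibble: `package`, `package_total`, `package_rank`, `rank`,
#'   `code`, `label`, `count`.
#' @export
extract_packages <- function(deaths, metadata = load_code_metadata()) {
  g <- classified_deaths(deaths, metadata) |>
    filter(.data$usability != "usable", .data$package != "none")
  if (nrow(g) == 0) {
    return(tibble(
      package = character(), package_total = numeric(), package_rank = integer(),
      rank = integer(), code = character(), label = character(), count = numeric()
    ))
  }
  members <- g |>
    group_by(.data$package, code = icd_category(.data$icd_code), .data$label) |>
    summarise(count = sum(.data$count), .groups = "drop")
  totals <- members |>
    group_by(.data$package) |>
    summarise(package_total = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$package_total), .data$package) |>
    mutate(package_rank = row_number())
  members |>
    left_join(totals, by = "package") |>
    arrange(.data$package_rank, desc(.data$count), .data$code) |>
    group_by(.data$package) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("package", "package_total", "package_rank", "rank", "code", "label", "count")
}

#' Proportional redistribution of garbage deaths
#'
#' Moves each garbage death mass onto the broad groups in its metadata
#' redistribution-target set, proportionally to the observed distribution
#' of usable deaths over those groups within the same (year, sex, age)
#' stratum. When the stratum has no usable deaths in the targets the
#' whole-dataset target distribution is used; when that is also empty the
#' mass is split equally (over the targets, or over all three groups when
#' the target set is empty). Totals are conserved exactly; redistributed
#' masses may be fractional.
#'
#' @inheritParams usability_distribution
#' @return List: `before` and `after` broad-group distributions, and
#'   `audit` (one row per garbage code x stratum x receiving group).
#' @export
redistribute_garbage <- function(deaths, metadata = load_code_metadata()) {
  df <- classified_deaths(deaths, metadata)
  groups <- c("group1", "group2", "group3")
  before <- broad_group_distribution(deaths, metadata)

  usable <- df |>
    filter(.data$usability == "usable") |>
    group_by(.data$year, .data$sex, .data$age_group, .data$broad_group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  global <- usable |>
    group_by(.data$broad_group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  global_vec <- setNames(rep(0, 3), groups)
  global_vec[global$broad_group] <- global$count

  garbage <- df |> filter(.data$usability != "usable", .data$count > 0)
  audit <- list()
  added <- setNames(rep(0, 3), groups)
  if (nrow(garbage) > 0) {
    # stratum lookup of usable counts per group
    key <- paste(usable$year, usable$sex, usable$age_group, usable$broad_group)
    uval <- setNames(usable$count, key)
    for (i in seq_len(nrow(garbage))) {
      row <- garbage[i, ]
      targets <- strsplit(row$redistribution_targets, ";", fixed = TRUE)[[1]]
      targets <- intersect(trimws(targets), groups)
      if (length(targets) == 0) targets <- groups
      w <- uval[paste(row$year, row$sex, row$age_group, targets)]
      w[is.na(w)] <- 0
      if (sum(w) <= 0) w <- global_vec[targets]
      if (sum(w) <= 0) w <- rep(1, length(targets))
      share <- row$count * w / sum(w)
      added[targets] <- added[targets] + share
      audit[[length(audit) + 1]] <- tibble(
        from_code = row$icd_code, year = row$year, sex = row$sex,
        age_group = row$age_group, to_group = targets, mass = unname(share)
      )
    }
  }
  after <- before |>
    mutate(
      count = dplyr::case_when(
        .data$bin %in% groups ~ .data$count + unname(added[.data$bin]),
        TRUE ~ 0
      )
    ) |>
    mutate(fraction = .data$count / sum(.data$count))
  list(
    before = before, after = after,
    audit = if (length(audit)) bind_rows(audit) else tibble(
      from_code = character(), year = integer(), sex = character(),
      age_group = character(), to_group = character(), mass = numeric()
    )
  )
}

#' Leading causes of death with garbage flags
#'
#' Aggregates deaths into the metadata's cause categories (usable causes
#' keep their category label; garbage codes keep their garbage-category
#' label) and returns the top `n` by count. Garbage entries are flagged
#' red when their severity level is 1-2 (largest policy impact) and orange
#' when 3-4.
#'
#' @inheritParams usability_distribution
#' @param n Number of leading causes to return (default 20).
#' @return Tibble: `rank`, `label`, `count`, `fraction`, `usability`,
#'   `severity_level`, `flag` ("none", "orange", "red").
#' @export
leading_causes <- function(deaths, metadata = load_code_metadata(), n = 20) {
  df <- classified_deaths(deaths, metadata)
  total <- sum(df$count)
  agg <- df |>
    group_by(.data$label, .data$usability) |>
    summarise(
      count = sum(.data$count),
      severity_level = suppressWarnings(max(.data$severity_level, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    mutate(severity_level = if_else(is.finite(.data$severity_level), as.numeric(.data$severity_level), NA_real_)) |>
    arrange(desc(.data$count), .data$label) |>
    mutate(
      rank = row_number(),
      fraction = .data$count / total,
      flag = dplyr::case_when(
        .data$usability == "usable" ~ "none",
        .data$severity_level <= 2 ~ "red",
        TRUE ~ "orange"
      )
    ) |>
    slice_head(n = n) |>
    select("rank", "label", "count", "fraction", "usability", "severity_level", "flag")
  agg
}
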