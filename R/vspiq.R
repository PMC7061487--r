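#' Garbage component of the VSPI(Q)
#'
#' Penalises garbage-coded deaths, with severity levels 1-3 (whose true
#' underlying cause is least recoverable) penalised exactly twice as much
#' per death as level 4:
#' S = clamp(1 - (2 (f1 + f2 + f3) + f4) / 2, 0, 1),
#' where f_l is the fraction of all deaths carrying a level-l garbage code.
#' A dataset consisting entirely of level-1 garbage scores 0; entirely
#' level-4 garbage scores 0.5.
#'
#' @param severity_fractions Numeric vector of length 4 (levels 1-4),
#'   fractions of all deaths; non-negative, summing to at most 1.
#' @return S_garbage in \[0, 1\].
#' @export
garbage_component <- function(severity_fractions) {
  f <- as.numeric(severity_fractions)
  if (length(f) != 4 || any(f < 0)) {
    abort("severity_fractions must be 4 non-negative fractions.", class = "codqc_input_error")
  }
  if (sum(f) > 1 + 1e-9) {
    abort("severity_fractions sum to more than 1.", class = "codqc_input_error")
  }
  s <- 1 - (2 * sum(f[1:3]) + f[4]) / 2
  min(max(s, 0), 1)
}

#' Cause-detail component of the VSPI(Q)
#'
#' The proportion of the reference cause list (192 causes in the packaged
#' fixture) for which at least one death appears in the data. Codes not on
#' the reference list do not contribute.
#'
#' @param deaths A `codqc_deaths` tibble.
#' @param reference_cause_list Character vector of reference cause codes
#'   (3-character ICD categories).
#' @return S_detail in \[0, 1\].
#' @export
detail_component <- function(deaths, reference_cause_list) {
  if (length(reference_cause_list) == 0) {
    abort("Reference cause list is empty.", class = "codqc_input_error")
  }
  present <- unique(icd_category(deaths$icd_code[deaths$count > 0]))
  length(intersect(reference_cause_list, present)) / length(reference_cause_list)
}

#' Age/sex-recording component of the VSPI(Q)
#'
#' One minus the fraction of deaths with unknown age or unknown sex; a
#' death missing both is counted once.
#'
#' @param deaths A `codqc_deaths` tibble.
#' @return S_agesex in \[0, 1\].
#' @export
agesex_component <- function(deaths) {
  total <- sum(deaths$count)
  if (total == 0) {
    return(1)
  }
  missing <- sum(deaths$count[deaths$age_group == "unknown" | deaths$sex == "unknown"])
  1 - missing / total
}

#' Biological-plausibility component of the VSPI(Q)
#'
#' One minus the fraction of deaths whose cause is biologically implausible
#' for the recorded age-sex category (e.g. a maternal cause on a male
#' death, a perinatal cause beyond infancy). Deaths with unknown age or
#' sex cannot be checked and are never counted as violations.
#'
#' @param deaths A `codqc_deaths` tibble.
#' @param edit_rules Rule table as from [default_edit_rules()].
#' @return List: `score`, `violations` (audit tibble), `violating_deaths`.
#' @export
plausibility_component <- function(deaths, edit_rules = default_edit_rules()) {
  total <- sum(deaths$count)
  open_age <- attr(deaths, "open_age") %||% 85
  info <- age_group_info(open_age)
  lower <- setNames(info$lower, info$age_group)
  upper <- setNames(info$upper, info$age_group)
  viol <- rep(FALSE, nrow(deaths))
  hits <- list()
  cat3 <- icd_category(deaths$icd_code)
  for (r in seq_len(nrow(edit_rules))) {
    in_range <- cat3 %in% expand_pattern(edit_rules$code_range[r])
    bad <- in_range
    rs <- edit_rules$required_sex[r]
    sex_bad <- if (!is.na(rs)) deaths$sex != rs & deaths$sex != "unknown" else FALSE
    age_bad <- rep(FALSE, nrow(deaths))
    if (!is.na(edit_rules$min_age[r]) || !is.na(edit_rules$max_age[r])) {
      known <- deaths$age_group != "unknown"
      lo <- lower[deaths$age_group]
      hi <- upper[deaths$age_group]
      amin <- edit_rules$min_age[r]
      amax <- edit_rules$max_age[r]
      # violation when the band lies entirely outside [min_age, max_age]
      out_band <- (!is.na(amax) & lo > amax) | (!is.na(amin) & !is.na(hi) & hi <= amin)
      age_bad <- known & dplyr::coalesce(out_band, FALSE)
    }
    bad <- in_range & (sex_bad | age_bad)
    if (any(bad)) {
      hits[[r]] <- tibble(
        rule = edit_rules$rule[r],
        icd_code = deaths$icd_code[bad],
        sex = deaths$sex[bad],
        age_group = deaths$age_group[bad],
        count = deaths$count[bad]
      )
    }
    viol <- viol | bad
  }
  violating <- sum(deaths$count[viol])
  list(
    score = if (total > 0) 1 - violating / total else 1,
    violations = if (length(hits)) bind_rows(hits) else tibble(
      rule = character(), icd_code = character(), sex = character(),
      age_group = character(), count = numeric()
    ),
    violating_deaths = violating
  )
}

# Build a transform function from knots, validating monotonicity and the
# pinned endpoints f(0) = 0, f(1) = 1. NULL means identity.
make_transform <- function(knots = NULL) {
  if (is.null(knots)) {
    return(identity)
  }
  k <- as_tibble(knots)
  if (!all(c("x", "y") %in% names(k))) {
    abort("Transform knots need columns x and y.", class = "codqc_config_error")
  }
  k <- arrange(k, .data$x)
  if (any(k$x < 0 | k$x > 1 | k$y < 0 | k$y > 1)) {
    abort("Transform knots must lie in [0,1]^2.", class = "codqc_config_error")
  }
  if (k$x[1] != 0 || k$x[nrow(k)] != 1 || k$y[1] != 0 || k$y[nrow(k)] != 1) {
    abort("Transforms must pin f(0) = 0 and f(1) = 1.", class = "codqc_config_error")
  }
  if (any(diff(k$y) < 0)) {
    abort("Transforms must be monotone non-decreasing.", class = "codqc_config_error")
  }
  function(x) approx(k$x, k$y, xout = x, rule = 2)$y
}

#' Composite VSPI(Q) score and gap decomposition
#'
#' Applies a monotone transform to each of the five component scores
#' (completeness, garbage, cause detail, age/sex recording, plausibility)
#' and multiplies the transformed scores into a single 0-100 composite.
#' The gap to 100 is attributed to components in proportion to their
#' transformed shortfall 1 - f_i(S_i).
#'
#' @param components Named numeric vector with entries `completeness`,
#'   `garbage`, `detail`, `agesex`, `plausibility`, each in \[0, 1\].
#' @param transforms Optional named list of knot tables (columns `x`, `y`)
#'   per component; omitted components use the identity transform.
#' @return A `codqc_vspiq` object: `composite`, `components` tibble (raw,
#'   transformed, gap_share), `transforms_used`.
#' @export
#' @examples
#' vspiq_score(c(
#'   completeness = 0.9, garbage = 1, detail = 1,
#'   agesex = 1, plausibility = 1
#' ))
vspiq_score <- function(components, transforms = NULL) {
  comp_names <- c("completeness", "garbage", "detail", "agesex", "plausibility")
  if (!all(comp_names %in% names(components))) {
    abort(sprintf("components must name: %s", paste(comp_names, collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  s <- as.numeric(components[comp_names])
  if (any(is.na(s)) || any(s < 0 | s > 1)) {
    abort("All component scores must be in [0, 1].", class = "codqc_input_error")
  }
  if (!is.null(transforms)) {
    extra <- setdiff(names(transforms), comp_names)
    if (length(extra)) {
      abort(sprintf("Unknown transform component(s): %s", paste(extra, collapse = ", ")),
        class = "codqc_config_error"
      )
    }
  }
  f <- purrr::map(comp_names, \(nm) make_transform(transforms[[nm]]))
  ts <- purrr::map2_dbl(f, s, \(fn, x) fn(x))
  composite <- 100 * prod(ts)
  shortfall <- 1 - ts
  gap <- if (sum(shortfall) > 0) shortfall / sum(shortfall) else rep(0, 5)
  structure(
    list(
      composite = composite,
      components = tibble(
        component = comp_names, raw = s, transformed = ts, gap_share = gap
      ),
      transforms_used = !purrr::map_lgl(comp_names, \(nm) is.null(transforms[[nm]]))
    ),
    class = "codqc_vspiq"
  )
}

#' @export
print.codqc_vspiq <- function(x, ...) {
  cat(sprintf("VSPI(Q) composite: %.1f / 100\n", x$composite))
  print(x$components, ...)
  invisible(x)
}
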