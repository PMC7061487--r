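#' Tidy a VSPI(Q) result
#'
#' @param x A `codqc_vspiq` object.
#' @param ... Unused.
#' @return Tibble: `component`, `raw`, `transformed`, `gap_share`.
#' @export
tidy.codqc_vspiq <- function(x, ...) x$components

#' One-row summary of a VSPI(Q) result
#'
#' @inheritParams tidy.codqc_vspiq
#' @return Tibble: `composite`, `n_components`, `partial`.
#' @export
glance.codqc_vspiq <- function(x, ...) {
  tibble(
    composite = x$composite,
    n_components = nrow(x$components),
    partial = isTRUE(x$partial)
  )
}

#' Tidy a log-linearity fit
#'
#' @param x A `codqc_loglin` object.
#' @param ... Unused.
#' @return The per-sex fit tibble (slope, intercept, r_squared, n_bands).
#' @export
tidy.codqc_loglin <- function(x, ...) x$fits

#' One-row summary of a log-linearity fit
#'
#' @inheritParams tidy.codqc_loglin
#' @return Tibble: `min_age`, `n_flags`, `min_r_squared`.
#' @export
glance.codqc_loglin <- function(x, ...) {
  tibble(
    min_age = x$min_age,
    n_flags = nrow(x$flags),
    min_r_squared = min(x$fits$r_squared)
  )
}

#' Tidy an assessment report into one scalar metric per row
#'
#' @param x A `codqc_report` object.
#' @param ... Unused.
#' @return Tibble: `step`, `metric`, `value`.
#' @export
tidy.codqc_report <- function(x, ...) {
  st <- x$steps
  rows <- list(tibble(step = "overall", metric = "total_deaths", value = x$total_deaths))
  if (!is.null(st$step2)) {
    rows[[length(rows) + 1]] <- tibble(
      step = "step2",
      metric = c("cdr_observed", "completeness_comparator", "completeness_empirical", "completeness_weighted"),
      value = c(
        st$step2$cdr_observed,
        st$step2$comparator$completeness %||% NA_real_,
        st$step2$empirical$completeness %||% NA_real_,
        st$step2$weighted %||% NA_real_
      )
    )
  }
  if (!is.null(st$step3$loglin)) {
    f <- st$step3$loglin$fits
    rows[[length(rows) + 1]] <- tibble(
      step = "step3",
      metric = paste0(rep(c("slope_", "r_squared_"), each = nrow(f)), f$sex),
      value = c(f$slope, f$r_squared)
    )
  }
  if (!is.null(st$step5)) {
    rows[[length(rows) + 1]] <- tibble(
      step = "step5",
      metric = c("q5_0", "comparator_q5_0", "child_completeness"),
      value = c(st$step5$q5_0, st$step5$comparator_q5_0, st$step5$child_completeness)
    )
  }
  rows[[length(rows) + 1]] <- tibble(
    step = "step6",
    metric = paste0("fraction_", st$step6$usability$usability),
    value = st$step6$usability$fraction
  )
  v <- st$step10$vspiq
  rows[[length(rows) + 1]] <- tibble(
    step = "step10",
    metric = c(paste0("S_", v$components$component), "composite"),
    value = c(v$components$raw, v$composite)
  )
  bind_rows(rows)
}

#' One-row summary of an assessment report
#'
#' @inheritParams tidy.codqc_report
#' @return Tibble with the headline quantities of the assessment.
#' @export
glance.codqc_report <- function(x, ...) {
  st <- x$steps
  tibble(
    total_deaths = x$total_deaths,
    year = x$year,
    cdr_observed = st$step2$cdr_observed %||% NA_real_,
    completeness = st$step2$comparator$completeness %||% NA_real_,
    q5_0 = st$step5$q5_0 %||% NA_real_,
    usable_fraction = st$step6$usability$fraction[st$step6$usability$usability == "usable"],
    vspiq = st$step10$vspiq$composite,
    n_warnings = length(x$warnings),
    n_skipped = length(x$skipped)
  )
}
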