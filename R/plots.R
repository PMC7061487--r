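#' Age-sex pyramid plot
#'
#' @param object A `codqc_pyramid` tibble from [tabulate_age_sex()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codqc_pyramid <- function(object, ...) {
  open_age <- attr(object, "open_age") %||% 85
  df <- as_tibble(object) |>
    filter(.data$sex %in% c("male", "female")) |>
    mutate(
      age_group = factor(.data$age_group, levels = c(age_ladder(open_age), "unknown")),
      signed = if_else(.data$sex == "male", -.data$percent, .data$percent)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed, y = .data$age_group, fill = .data$sex)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_x_continuous(labels = \(x) abs(x)) +
    ggplot2::labs(x = "% of sex total", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Age-specific mortality rates on a log scale
#'
#' @param object A `codqc_rates` tibble from [age_specific_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codqc_rates <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$rate), .data$rate > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$rate, colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age", y = "Death rate (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' VSPI(Q) gap-attribution plot
#'
#' Shows each component's share of the gap between the composite and 100,
#' the priority chart for improvement efforts.
#'
#' @param object A `codqc_vspiq` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codqc_vspiq <- function(object, ...) {
  df <- object$components |> arrange(desc(.data$gap_share))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gap_share,
    y = stats::reorder(.data$component, .data$gap_share)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = \(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Share of gap to 100",
      y = NULL,
      title = sprintf("VSPI(Q) = %.1f", object$composite)
    ) +
    ggplot2::theme_minimal()
}

#' Broad-cause-group distribution plot
#'
#' @param dist A broad-group distribution from [broad_group_distribution()]
#'   (overall or by age).
#' @return A ggplot object.
#' @export
plot_broad_groups <- function(dist) {
  lv <- c("group1", "group2", "group3", "unusable", "insufficiently_specified")
  df <- as_tibble(dist) |> mutate(bin = factor(.data$bin, levels = lv))
  if ("age_group" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$age_group, y = .data$fraction, fill = .data$bin)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "Fraction of deaths", fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction, fill = .data$bin)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::labs(x = NULL, y = "Fraction of deaths") +
      ggplot2::theme_minimal()
  }
}
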