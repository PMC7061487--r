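#' The standard age-group ladder
#'
#' Tabulations use "<1" and "1-4" for the under-five split and 5-year bands
#' from "5-9" up to an open interval (default "85+"). "unknown" is a valid
#' extra category for deaths of unstated age.
#'
#' @param open_age Lower bound of the open age interval (default 85).
#' @return Character vector of age-group labels, youngest first.
#' @export
#' @examples
#' age_ladder()
age_ladder <- function(open_age = 85) {
  if (open_age < 10 || open_age %% 5 != 0) {
    abort("`open_age` must be a multiple of 5 and at least 10.", class = "codqc_config_error")
  }
  lows <- seq(5, open_age - 5, by = 5)
  c("<1", "1-4", paste0(lows, "-", lows + 4), paste0(open_age, "+"))
}

#' Age-group midpoints and bounds
#'
#' Midpoint convention: "<1" = 0.5, "1-4" = 3, 5-year bands at their centre,
#' open interval at lower bound + 2.5.
#'
#' @inheritParams age_ladder
#' @return Tibble with columns `age_group`, `lower`, `upper`, `midpoint`.
#' @export
age_group_info <- function(open_age = 85) {
  ladder <- age_ladder(open_age)
  lows <- c(0, 1, seq(5, open_age, by = 5))
  ups <- c(1, 5, seq(10, open_age, by = 5), Inf)[seq_along(lows)]
  mids <- ifelse(is.finite(ups), (lows + ups) / 2, lows + 2.5)
  mids[1] <- 0.5
  mids[2] <- 3
  tibble(age_group = ladder, lower = lows, upper = ups, midpoint = mids)
}

# Aliases accepted on input, mapped onto ladder labels.
age_alias_table <- function(open_age = 85) {
  ladder <- age_ladder(open_age)
  alias <- c(
    "0" = "<1", "<1" = "<1", "0-0" = "<1", "under 1" = "<1", "infant" = "<1",
    "1-4" = "1-4", "01-04" = "1-4", "1_4" = "1-4",
    "unknown" = "unknown", "unk" = "unknown", "99" = "unknown"
  )
  alias[""] <- "unknown"
  for (lab in ladder[-c(1, 2)]) {
    alias[lab] <- lab
    alias[sub("-", "_", lab)] <- lab
  }
  open_lab <- ladder[length(ladder)]
  alias[sub("\\+", "plus", open_lab)] <- open_lab
  alias
}

normalize_age_group <- function(x, open_age = 85) {
  alias <- age_alias_table(open_age)
  key <- tolower(trimws(as.character(x)))
  out <- unname(alias[key])
  bad <- is.na(out)
  if (any(bad)) {
    abort(
      sprintf(
        "Unrecognized age group label(s): %s",
        paste(unique(x[bad]), collapse = ", ")
      ),
      class = "codqc_input_error"
    )
  }
  out
}

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(
    "1" = "male", "m" = "male", "male" = "male",
    "2" = "female", "f" = "female", "female" = "female",
    "9" = "unknown", "u" = "unknown", "unknown" = "unknown"
  )
  map[""] <- "unknown"
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad)) {
    abort(
      sprintf("Unrecognized sex code(s): %s", paste(unique(x[bad]), collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  out
}
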