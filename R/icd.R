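#' Validate and normalize an ICD-10 code
#'
#' Codes are stored uppercased and dot-stripped: a chapter letter, two
#' digits, and an optional third digit ("A41", "I219"). The special value
#' "missing" marks deaths with no recorded cause.
#'
#' @param raw Character vector of raw code strings.
#' @return Tibble with columns `raw`, `code` (normalized code or `NA`) and
#'   `status` ("ok", "missing", "invalid_code").
#' @export
#' @examples
#' validate_icd10_code(c("i21.9", "A41", "1234"))
validate_icd10_code <- function(raw) {
  if (length(raw) == 0) abort("`raw` must be non-empty.", class = "codqc_input_error")
  cleaned <- gsub("\\.", "", toupper(trimws(as.character(raw))))
  ok <- grepl("^[A-Z][0-9]{2}[0-9]?$", cleaned)
  missing <- tolower(trimws(as.character(raw))) %in% c("missing", "") | is.na(raw)
  tibble(
    raw = as.character(raw),
    code = dplyr::case_when(missing ~ "missing", ok ~ cleaned, TRUE ~ NA_character_),
    status = dplyr::case_when(missing ~ "missing", ok ~ "ok", TRUE ~ "invalid_code")
  )
}

# 3-character category of a normalized code ("I219" -> "I21").
icd_category <- function(code) substr(code, 1, 3)

# Full ordered grid of 3-character ICD categories, A00..Z99.
icd_grid <- function() {
  as.vector(t(outer(LETTERS, sprintf("%02d", 0:99), paste0)))
}

# Expand a pattern ("A41" or "A40-A41") into its 3-character categories.
expand_pattern <- function(pattern) {
  grid <- icd_grid()
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  parts <- toupper(trimws(parts))
  if (!all(grepl("^[A-Z][0-9]{2}$", parts)) || !length(parts) %in% c(1, 2)) {
    abort(sprintf("Malformed code pattern: '%s'", pattern), class = "codqc_input_error")
  }
  if (length(parts) == 1) {
    return(parts)
  }
  i <- match(parts, grid)
  if (i[1] > i[2]) {
    abort(sprintf("Descending code range: '%s'", pattern), class = "codqc_input_error")
  }
  grid[i[1]:i[2]]
}
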