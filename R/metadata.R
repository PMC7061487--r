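#' Load the ICD code-classification metadata
#'
#' The metadata table maps ICD-10 code patterns (exact 3-character categories
#' or inclusive ranges such as `"A40-A41"`) to a usability class, a broad
#' cause group, the two garbage typologies (ICD-error category 1-5 and
#' severity level 1-4), a garbage package, and redistribution targets. The
#' packaged default seeds canonical garbage entries (ill-defined R codes,
#' cardiac/respiratory failure, sepsis, unspecified cancer and stroke,
#' undetermined-intent injuries, ...) plus a 192-cause usable reference set,
#' and is fully user-replaceable.
#'
#' Patterns must be non-overlapping after expansion: an overlap is a hard
#' error, not a precedence rule.
#'
#' @param path Path to a metadata CSV; `NULL` uses the packaged default.
#' @return A `codqc_metadata` tibble with one row per pattern and an
#'   expansion map as attribute `"expanded"`.
#' @export
#' @examples
#' meta <- load_code_metadata()
#' classify_code("A41", meta)
load_code_metadata <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_metadata.csv", package = "codqc")
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      code_pattern = readr::col_character(),
      label = readr::col_character(),
      usability = readr::col_character(),
      broad_group = readr::col_character(),
      icd_error_category = readr::col_integer(),
      severity_level = readr::col_integer(),
      package = readr::col_character(),
      redistribution_targets = readr::col_character()
    ),
    na = c("", "NA")
  )
  required <- c(
    "code_pattern", "usability", "broad_group", "icd_error_category",
    "severity_level", "package", "redistribution_targets"
  )
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(sprintf("Metadata file missing column(s): %s", paste(miss, collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  if (!"label" %in% names(raw)) raw$label <- raw$code_pattern
  raw$label <- dplyr::coalesce(raw$label, raw$code_pattern)
  raw$package <- dplyr::coalesce(raw$package, "none")
  raw$redistribution_targets <- dplyr::coalesce(raw$redistribution_targets, "")

  bad_use <- !raw$usability %in% c("usable", "unusable", "insufficiently_specified")
  if (any(bad_use)) {
    abort(sprintf("Invalid usability value(s): %s", paste(unique(raw$usability[bad_use]), collapse = ", ")),
      class = "codqc_input_error"
    )
  }
  garbage <- raw$usability != "usable"
  if (any(garbage & (is.na(raw$icd_error_category) | is.na(raw$severity_level)))) {
    abort("Every unusable/insufficiently_specified row needs icd_error_category and severity_level.",
      class = "codqc_input_error"
    )
  }
  if (any(!garbage & !raw$broad_group %in% c("group1", "group2", "group3"))) {
    abort("Every usable row needs broad_group in group1/group2/group3.",
      class = "codqc_input_error"
    )
  }

  expanded <- purrr::map(raw$code_pattern, expand_pattern)
  flat <- unlist(expanded)
  if (anyDuplicated(flat)) {
    dup <- unique(flat[duplicated(flat)])
    owners <- purrr::map_chr(dup[1], function(d) {
      rows <- which(purrr::map_lgl(expanded, ~ d %in% .x))
      paste(raw$code_pattern[rows], collapse = "' and '")
    })
    abort(
      sprintf(
        "Overlapping code patterns: category %s is claimed by '%s'.",
        dup[1], owners
      ),
      class = "codqc_input_error"
    )
  }
  map <- tibble(
    category = flat,
    row = rep(seq_len(nrow(raw)), lengths(expanded))
  )
  structure(raw, expanded = map, class = c("codqc_metadata", class(raw)))
}

# Default classification for codes absent from the metadata: treated as
# insufficiently specified, ICD-error category 5, severity 3 (documented
# default; a warning is raised once per call site).
unmapped_classification <- function() {
  tibble(
    usability = "insufficiently_specified", broad_group = "none",
    icd_error_category = 5L, severity_level = 3L,
    package = "none", redistribution_targets = "", label = "Unclassified code"
  )
}

#' Classify ICD-10 codes against the metadata
#'
#' Total function: every code receives a classification. Codes absent from
#' the metadata (including the sentinel `"missing"`) fall back to
#' insufficiently specified, category 5, severity 3, with a warning naming
#' the unmapped categories.
#'
#' @param code Character vector of normalized ICD-10 codes.
#' @param metadata A `codqc_metadata` table from [load_code_metadata()].
#' @return Tibble with one row per input code: `code`, `label`, `usability`,
#'   `broad_group`, `icd_error_category`, `severity_level`, `package`,
#'   `redistribution_targets`.
#' @export
classify_code <- function(code, metadata = load_code_metadata()) {
  map <- attr(metadata, "expanded")
  idx <- map$row[match(icd_category(code), map$category)]
  unmapped <- is.na(idx) & code != "missing"
  if (any(unmapped)) {
    warn(sprintf(
      "%d code category(ies) not in metadata, classified as insufficiently specified (severity 3): %s",
      length(unique(icd_category(code[unmapped]))),
      paste(utils::head(unique(icd_category(code[unmapped])), 10), collapse = ", ")
    ))
  }
  fb <- unmapped_classification()
  out <- tibble(
    code = code,
    label = ifelse(is.na(idx), ifelse(code == "missing", "Missing cause", fb$label), metadata$label[idx]),
    usability = ifelse(is.na(idx), fb$usability, metadata$usability[idx]),
    broad_group = ifelse(is.na(idx), fb$broad_group, metadata$broad_group[idx]),
    icd_error_category = ifelse(is.na(idx), fb$icd_error_category, metadata$icd_error_category[idx]),
    severity_level = ifelse(is.na(idx), fb$severity_level, metadata$severity_level[idx]),
    package = ifelse(is.na(idx), fb$package, metadata$package[idx]),
    redistribution_targets = ifelse(is.na(idx), fb$redistribution_targets, metadata$redistribution_targets[idx])
  )
  out
}

#' Default biological-plausibility edit rules
#'
#' Bundled rules: maternal causes (O00-O99) require female sex and age
#' 10-54; prostate cancer (C61) male; cervical (C53) and ovarian (C56)
#' cancer female; perinatal causes (P00-P96) age under 1. Deaths with
#' unknown age or sex are never counted as violations (the attribute being
#' checked is unverifiable, and its absence is already penalised by the
#' age/sex component).
#'
#' @return Tibble with columns `code_range`, `required_sex`, `min_age`,
#'   `max_age`, `rule`.
#' @export
default_edit_rules <- function() {
  tibble(
    code_range = c("O00-O99", "C61", "C53", "C56", "P00-P96"),
    required_sex = c("female", "male", "female", "female", NA),
    min_age = c(10, NA, NA, NA, 0),
    max_age = c(54, NA, NA, NA, 0),
    rule = c(
      "maternal cause requires female aged 10-54",
      "prostate cancer requires male",
      "cervical cancer requires female",
      "ovarian cancer requires female",
      "perinatal cause requires age under 1"
    )
  )
}
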