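# Sample-level survey table I/O and validation.
#
# A survey is a wide tibble: metadata columns (sample_id, city, year,
# species, floral_origin, channel) followed by one numeric column per panel
# analyte (ug/kg). NA means non-detect; in files a non-detect is an empty
# cell or a sentinel string ("ND" by default, matched case-insensitively).

survey_meta_cols <- c("sample_id", "city", "year", "species",
                      "floral_origin", "channel")

known_species <- c("Apis mellifera", "Apis cerana")
known_channels <- c("apiary", "supermarket", "honey processing facility",
                    "bee product store")

squish <- function(x) gsub("\\s+", " ", trimws(x))

# Case-insensitive canonicalization against a closed label set.
canonicalize <- function(x, levels, what) {
  idx <- match(tolower(squish(x)), tolower(levels))
  if (anyNA(idx[!is.na(x)])) {
    bad <- unique(x[!is.na(x) & is.na(idx)])
    abort(sprintf("unknown %s label(s): %s", what, paste(bad, collapse = ", ")))
  }
  levels[idx]
}

#' Read a sample-level residue survey table
#'
#' @param path CSV file: the metadata columns `sample_id`, `city`, `year`,
#'   `species`, `floral_origin`, `channel`, then one column per panel
#'   analyte holding the measured concentration (ug/kg) or a non-detect
#'   cell.
#' @param panel Analyte panel from [read_panel()]; every analyte column in
#'   the file must appear in `panel$compound`.
#' @param nd Character vector of non-detect sentinels (case-insensitive);
#'   empty cells always count as non-detect.
#' @return A validated survey tibble with numeric analyte columns
#'   (`NA` = non-detect).
#' @export
read_survey <- function(path, panel = read_panel(), nd = "ND") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(survey_meta_cols, names(raw))
  if (length(missing)) {
    abort(paste0("survey file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  analyte_cols <- setdiff(names(raw), survey_meta_cols)
  unknown <- setdiff(analyte_cols, panel$compound)
  if (length(unknown)) {
    abort(paste0("analyte column not in panel: ", paste(unknown, collapse = ", ")))
  }
  out <- raw
  out$year <- as.integer(raw$year)
  for (col in c("city", "floral_origin")) out[[col]] <- squish(raw[[col]])
  out$species <- canonicalize(raw$species, known_species, "species")
  out$channel <- canonicalize(raw$channel, known_channels, "sale channel")
  nd_tokens <- tolower(c(nd, ""))
  for (col in analyte_cols) {
    cell <- trimws(raw[[col]])
    is_nd <- is.na(cell) | tolower(cell) %in% nd_tokens
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_nd & is.na(val)
    if (any(bad)) {
      abort(sprintf("column `%s`: unparseable value `%s` (sample %s)",
                    col, cell[bad][1], raw$sample_id[bad][1]))
    }
    val[is_nd] <- NA_real_
    neg <- !is.na(val) & val < 0
    if (any(neg)) {
      abort(sprintf("column `%s`: negative concentration (sample %s)",
                    col, raw$sample_id[neg][1]))
    }
    out[[col]] <- val
  }
  validate_survey(as_tibble(out), panel)
}

#' Validate a survey tibble against a panel
#'
#' Checks column structure, uniqueness of sample ids, label sets and
#' non-negativity of concentrations. Returns the table invisibly unchanged
#' so it can be used as a pipeline assertion.
#'
#' @inheritParams read_survey
#' @param survey A wide survey tibble as produced by [read_survey()] or
#'   [generate_survey()].
#' @return `survey`, invisibly.
#' @export
validate_survey <- function(survey, panel = read_panel()) {
  missing <- setdiff(survey_meta_cols, names(survey))
  if (length(missing)) {
    abort(paste0("survey lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(survey$sample_id)) abort("duplicate sample_id")
  analyte_cols <- setdiff(names(survey), survey_meta_cols)
  unknown <- setdiff(analyte_cols, panel$compound)
  if (length(unknown)) {
    abort(paste0("analyte column not in panel: ", paste(unknown, collapse = ", ")))
  }
  for (col in analyte_cols) {
    v <- survey[[col]]
    if (!is.numeric(v)) abort(sprintf("analyte column `%s` must be numeric", col))
    if (any(!is.na(v) & v < 0)) abort(sprintf("negative concentration in `%s`", col))
  }
  invisible(survey)
}

#' Write a survey tibble to CSV
#'
#' Non-detects (`NA`) are written as the `nd` sentinel so the file
#' round-trips through [read_survey()] unchanged.
#'
#' @inheritParams validate_survey
#' @param path Output file path.
#' @param nd Sentinel written for non-detect cells.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path, nd = "ND") {
  analyte_cols <- setdiff(names(survey), survey_meta_cols)
  out <- survey
  for (col in analyte_cols) {
    v <- survey[[col]]
    out[[col]] <- ifelse(is.na(v), nd, sprintf("%.15g", v))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
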