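# Positivity classification and treatment of left-censored measurements.
#
# A measurement is "positive" only at or above the method LOQ; numeric
# values below the LOQ are "trace" (quantified but below the positivity
# threshold); NA is a non-detect. Following the SCOOP convention, a
# non-detect enters risk calculations as LOD/2.

#' Concentration bin labels
#'
#' The four bins used to describe positive-sample concentrations:
#' `[0, 10)`, `[10, 100)`, `[100, 1000]`, `(1000, Inf)` ug/kg.
#' The 10 and 100 boundaries are left-closed; 1000 belongs to the third
#' bin so that ">1000" means strictly greater.
#' @export
concentration_bins <- c("<10", "10–100", "100–1000", ">1000")

#' Classify a raw measurement against LOD/LOQ
#'
#' @param value Numeric concentration (ug/kg); `NA` marks a non-detect.
#' @param lod,loq Method limits of detection and quantitation (ug/kg);
#'   recycled against `value`.
#' @return Character vector in `{"positive", "trace", "non-detect"}`.
#' @export
#' @examples
#' classify_residue(c(NA, 0.5, 7890), lod = 0.35, loq = 1.0)
classify_residue <- function(value, lod, loq) {
  if (any(!is.na(value) & value < 0)) abort("negative concentration")
  if (any(loq < lod)) abort("LOQ below LOD")
  ifelse(is.na(value), "non-detect", ifelse(value >= loq, "positive", "trace"))
}

#' Pivot a wide survey into a classified long table
#'
#' Produces the sample x analyte long table the summary and risk modules
#' consume: one row per measurement with its censoring status and the
#' analyte's LOD/LOQ attached.
#'
#' @inheritParams validate_survey
#' @return A tibble with the survey metadata columns plus `analyte`,
#'   `value` (NA for non-detect), `status`, `lod`, `loq`.
#' @export
classify_survey <- function(survey, panel = read_panel()) {
  validate_survey(survey, panel)
  analyte_cols <- setdiff(names(survey), survey_meta_cols)
  if (!length(analyte_cols)) abort("survey has no analyte columns")
  long <- tidyr::pivot_longer(survey, cols = dplyr::all_of(analyte_cols),
                              names_to = "analyte", values_to = "value")
  long <- dplyr::left_join(long, panel[, c("compound", "lod", "loq")],
                           by = c(analyte = "compound"))
  long$status <- classify_residue(long$value, long$lod, long$loq)
  as_tibble(long)
}

#' Substitute LOD/2 for non-detects
#'
#' Applies the SCOOP rule: non-detect cells take the value LOD/2 and are
#' flagged `substituted`; positive and trace values pass through
#' numerically unchanged (optionally traces can also be substituted as a
#' sensitivity mode). The operation is idempotent.
#'
#' @param classified Long table from [classify_survey()].
#' @param traces_as_nondetect If `TRUE`, trace values (below LOQ) are also
#'   replaced by LOD/2, for sensitivity checks of the censoring convention.
#' @return `classified` with `value` filled and a logical `substituted`
#'   column.
#' @export
substitute_lod_half <- function(classified, traces_as_nondetect = FALSE) {
  nd <- classified$status == "non-detect" |
    (traces_as_nondetect & classified$status == "trace")
  classified$substituted <- nd
  classified$value <- ifelse(nd, classified$lod / 2, classified$value)
  classified
}

#' Bin a concentration into the survey's reporting bins
#'
#' @param value Non-negative concentration(s), ug/kg.
#' @return Factor with levels [concentration_bins].
#' @export
#' @examples
#' bin_concentration(c(2.6, 100, 7890))
bin_concentration <- function(value) {
  if (any(is.na(value)) || any(value < 0)) abort("values must be non-negative")
  lab <- ifelse(value < 10, concentration_bins[1],
         ifelse(value < 100, concentration_bins[2],
         ifelse(value <= 1000, concentration_bins[3], concentration_bins[4])))
  factor(lab, levels = concentration_bins)
}

#' Flag compliance with a uniform residue limit
#'
#' The EU and Japan apply a uniform 10 ug/kg limit for these residues in
#' honey; a sample complies when its concentration does not exceed the
#' limit (boundary inclusive).
#'
#' @param value Non-negative concentration(s), ug/kg.
#' @param limit Uniform limit, ug/kg.
#' @return Logical: `TRUE` when compliant.
#' @export
uniform_limit_flag <- function(value, limit = 10) {
  if (any(is.na(value)) || any(value < 0)) abort("values must be non-negative")
  value <= limit
}
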