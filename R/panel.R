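#' Read an analyte panel table
#'
#' The panel lists the per-compound constants of the validated LC-MS/MS
#' method: retention time (min), linearity range (ug/L), regression
#' coefficient, limit of detection and quantitation (ug/kg), and matrix
#' effect (%). The shipped default covers the 13-fluoroquinolone panel of
#' the five-year Zhejiang honey monitoring survey the package models.
#'
#' @param path CSV file with columns `compound`, `retention_time`,
#'   `linearity_low`, `linearity_high`, `r_squared`, `lod`, `loq`,
#'   `matrix_effect`. `NULL` (default) loads the shipped panel.
#' @return A tibble, one row per compound, keyed by `compound`.
#' @export
#' @examples
#' panel <- read_panel()
#' panel[panel$compound == "ciprofloxacin", c("lod", "loq")]
read_panel <- function(path = NULL) {
  path <- path %||% path_extdata("fq_panel.csv")
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("compound", "retention_time", "linearity_low", "linearity_high",
                "r_squared", "lod", "loq", "matrix_effect")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    abort(paste0("panel file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(panel$compound)) {
    abort("panel compound names must be unique")
  }
  if (any(!is.finite(panel$lod) | panel$lod <= 0)) {
    abort("every LOD must be a positive number")
  }
  bad <- panel$compound[panel$loq < panel$lod]
  if (length(bad)) {
    abort(paste0("LOQ below LOD for: ", paste(bad, collapse = ", ")))
  }
  if (any(panel$r_squared <= 0 | panel$r_squared > 1)) {
    abort("r_squared must lie in (0, 1]")
  }
  as_tibble(panel)
}

#' Read an acceptable-daily-intake (ADI) registry
#'
#' @param path CSV file with columns `compound` and `adi`
#'   (ug per kg body weight per day). `NULL` loads the shipped registry for
#'   the four fluoroquinolones detected in the survey (ciprofloxacin 0.15,
#'   enrofloxacin 6.2, norfloxacin 14, ofloxacin 3.2).
#' @return A tibble with columns `compound` and `adi`.
#' @export
read_adi <- function(path = NULL) {
  path <- path %||% path_extdata("fq_adi.csv")
  adi <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("compound", "adi") %in% names(adi))) {
    abort("ADI file needs columns `compound` and `adi`")
  }
  if (nrow(adi) && any(!is.finite(adi$adi) | adi$adi <= 0)) {
    abort("every ADI must be strictly positive")
  }
  if (anyDuplicated(adi$compound)) abort("duplicate compound in ADI registry")
  as_tibble(adi)
}

#' Read an age-group exposure-parameter table
#'
#' One row per age group with the arithmetic mean and SD of daily honey
#' intake (kg/day) and body weight (kg) from a 24-h-recall-style dietary
#' survey, plus the number of respondents. The shipped default is a
#' synthetic stand-in (see `generate_exposure_params()`): the underlying
#' dietary-recall appendix of the source survey is not public.
#'
#' @param path CSV with columns `age_group`, `intake_mean`, `intake_sd`,
#'   `bw_mean`, `bw_sd`, `n_surveyed`; `NULL` loads the synthetic default.
#' @return A tibble, one row per age group.
#' @export
read_exposure_params <- function(path = NULL) {
  path <- path %||% path_extdata("exposure_params_synthetic.csv")
  ep <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("age_group", "intake_mean", "intake_sd", "bw_mean", "bw_sd",
                "n_surveyed")
  missing <- setdiff(required, names(ep))
  if (length(missing)) {
    abort(paste0("exposure file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(ep$age_group)) abort("age_group must be unique")
  num <- c("intake_mean", "intake_sd", "bw_mean", "bw_sd")
  if (any(sapply(ep[num], function(x) any(!is.finite(x) | x <= 0)))) {
    abort("all intake/body-weight means and SDs must be strictly positive")
  }
  as_tibble(ep)
}

#' Read reported stratum mean residues
#'
#' Point summaries (all-sample mean, SD, maximum; ug/kg) of fluoroquinolone
#' residues reported for the 2014-2018 Zhejiang honey survey, overall and
#' for selected floral-origin and sale-channel strata. These serve as ready
#' inputs for point-estimate risk assessment when the sample-level table is
#' unavailable.
#'
#' @param path CSV with columns `compound`, `stratum_type`, `stratum`,
#'   `mean_residue`, `sd_residue`, `max_residue`; `NULL` loads the shipped
#'   table.
#' @return A tibble.
#' @export
read_reported_means <- function(path = NULL) {
  path <- path %||% path_extdata("reported_residue_means.csv")
  rm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  if (!all(c("compound", "mean_residue") %in% names(rm))) {
    abort("reported-means file needs `compound` and `mean_residue`")
  }
  as_tibble(rm)
}
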