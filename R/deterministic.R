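# Point-estimate (deterministic) chronic exposure assessment.
#
# EDI = C * K / BW, with C the all-sample mean residue after LOD/2
# substitution (ug/kg), K the average daily honey consumption (kg/day) and
# BW the consumer body weight (kg); HQ = EDI / ADI, acceptable below 1.

#' Default adult point-exposure parameters
#'
#' Average daily honey consumption 0.01 kg/day and adult body weight
#' 60 kg, the standard point values for Chinese consumers.
#' @export
adult_point_params <- list(intake = 0.01, body_weight = 60)

#' Estimated daily intake (EDI)
#'
#' @param c_mean Mean residue concentration, ug/kg.
#' @param intake Daily honey consumption, kg/day.
#' @param bw Body weight, kg.
#' @return EDI in ug per kg body weight per day (exact quotient, no
#'   internal rounding).
#' @export
#' @examples
#' edi(1.06)  # ciprofloxacin all-sample mean -> 1.77e-4 (3 s.f.)
edi <- function(c_mean, intake = adult_point_params$intake,
                bw = adult_point_params$body_weight) {
  assert_scalar_number(intake, "intake", 0, strict = TRUE)
  assert_scalar_number(bw, "bw", 0, strict = TRUE)
  if (any(c_mean < 0, na.rm = TRUE)) abort("c_mean must be non-negative")
  c_mean * intake / bw
}

#' Hazard quotient (HQ)
#'
#' `rounded` first rounds the EDI to 3 significant figures, matching the
#' convention of published point-estimate tables whose HQ cells are
#' computed from the printed (rounded) EDI rather than the full-precision
#' quotient.
#'
#' @param edi Estimated daily intake, ug/kg bw/day.
#' @param adi Acceptable daily intake, ug/kg bw/day (> 0).
#' @param rounded Round the EDI to 3 significant figures before dividing.
#' @return Dimensionless hazard quotient; values below 1 are acceptable.
#' @export
hazard_quotient <- function(edi, adi, rounded = FALSE) {
  if (any(!is.finite(adi) | adi <= 0)) abort("ADI must be strictly positive")
  if (rounded) edi <- signif(edi, 3)
  edi / adi
}

#' Worst-case exposure as a percentage of the ADI
#'
#' Point assessment substituting the maximum observed concentration for
#' the mean: `100 * (c_max * intake / bw) / adi`.
#'
#' @param c_max Highest concentration found, ug/kg.
#' @inheritParams edi
#' @inheritParams hazard_quotient
#' @return Percent of the ADI.
#' @export
#' @examples
#' worst_case_pct_adi(7890, adi = 14)  # 9.39% for norfloxacin
worst_case_pct_adi <- function(c_max, intake = adult_point_params$intake,
                               bw = adult_point_params$body_weight, adi) {
  if (any(!is.finite(adi) | adi <= 0)) abort("ADI must be strictly positive")
  100 * edi(c_max, intake, bw) / adi
}

#' Deterministic risk assessment over a survey
#'
#' For each detected compound (and optionally each stratum) computes the
#' all-sample mean residue after LOD/2 substitution, the EDI, the HQ, and
#' the worst-case %ADI from the stratum maximum. Compounds never detected
#' anywhere in the survey are omitted; a detected compound with no ADI
#' yields an `NA` HQ with a warning.
#'
#' @param classified Long table from [classify_survey()], substituted via
#'   [substitute_lod_half()] (applied automatically if not yet done).
#' @param adi ADI registry tibble from [read_adi()].
#' @param group_by Optional stratum column name; `NULL` for overall rows.
#' @inheritParams edi
#' @inheritParams hazard_quotient
#' @return A tibble: `stratum`, `analyte`, `n`, `c_mean`, `c_sd`, `c_max`,
#'   `edi`, `hq`, `worst_case_pct_adi`, `acceptable`.
#' @export
assess_deterministic <- function(classified, adi = read_adi(),
                                 group_by = NULL,
                                 intake = adult_point_params$intake,
                                 bw = adult_point_params$body_weight,
                                 rounded = FALSE) {
  if (!nrow(classified)) abort("empty survey")
  if (!nrow(adi)) abort("ADI registry is empty; cannot assess risk")
  if (!"substituted" %in% names(classified)) {
    classified <- substitute_lod_half(classified)
  }
  detected <- unique(classified$analyte[classified$status == "positive"])
  if (!length(detected)) abort("no compound is positive in this survey")
  adi_map <- stats::setNames(adi$adi, adi$compound)
  no_adi <- setdiff(detected, names(adi_map))
  if (length(no_adi)) {
    warn(paste0("detected compound(s) without ADI: ",
                paste(no_adi, collapse = ", ")))
  }

  cl <- classified[classified$analyte %in% detected, ]
  cl$.stratum <- if (is.null(group_by)) "overall" else as.character(cl[[group_by]])
  res <- cl |>
    dplyr::group_by(stratum = .data$.stratum, analyte = .data$analyte) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$sample_id),
                     c_mean = mean(.data$value), c_sd = sd(.data$value),
                     c_max = max(.data$value), .groups = "drop")
  res$edi <- edi(res$c_mean, intake, bw)
  this_adi <- unname(adi_map[res$analyte])
  res$hq <- ifelse(is.na(this_adi), NA_real_,
                   hazard_quotient(res$edi, ifelse(is.na(this_adi), 1, this_adi),
                                   rounded = rounded))
  res$worst_case_pct_adi <- ifelse(
    is.na(this_adi), NA_real_,
    100 * edi(res$c_max, intake, bw) / ifelse(is.na(this_adi), 1, this_adi))
  res$acceptable <- res$hq < 1
  res
}
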