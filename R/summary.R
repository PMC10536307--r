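# Survey summarization: detection frequencies, positive-sample
# concentration statistics, co-occurrence and stratified comparisons.

pos_stats <- function(values) {
  if (!length(values)) {
    return(tibble(mean_pos = NA_real_, sd_pos = NA_real_, max_pos = NA_real_,
                  bin_lt10 = 0L, bin_10_100 = 0L, bin_100_1000 = 0L,
                  bin_gt1000 = 0L))
  }
  bins <- table(bin_concentration(values))
  tibble(mean_pos = mean(values),
         sd_pos = if (length(values) > 1) sd(values) else NA_real_,
         max_pos = max(values),
         bin_lt10 = as.integer(bins[[1]]), bin_10_100 = as.integer(bins[[2]]),
         bin_100_1000 = as.integer(bins[[3]]), bin_gt1000 = as.integer(bins[[4]]))
}

#' Detection-frequency and concentration summary table
#'
#' One row per stratum x analyte, plus an "any FQ" row per stratum in which
#' a sample counts as positive when at least one analyte is positive.
#' Positive-sample statistics (`mean_pos`, `sd_pos`, `max_pos`, bin counts)
#' are computed over positive values only — never over substituted
#' non-detects; the "any FQ" row pools each positive (sample, analyte)
#' value as one observation.
#'
#' @param classified Long table from [classify_survey()].
#' @param group_by Optional name of a stratum column (`"species"`,
#'   `"channel"`, `"floral_origin"`, `"city"`, `"year"`); `NULL` summarizes
#'   the whole survey as stratum `"overall"`.
#' @return A tibble with columns `stratum`, `analyte`, `n`, `n_positive`,
#'   `detection_rate` (percent), positive-value statistics and bin counts.
#' @export
detection_table <- function(classified, group_by = NULL) {
  if (!nrow(classified)) abort("empty survey")
  if (!is.null(group_by) && !group_by %in% names(classified)) {
    abort(sprintf("no stratum column `%s`", group_by))
  }
  cl <- classified
  cl$.stratum <- if (is.null(group_by)) "overall" else as.character(cl[[group_by]])

  per_analyte <- cl |>
    dplyr::group_by(.data$.stratum, .data$analyte) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$sample_id),
      n_positive = sum(.data$status == "positive"),
      pos_stats(.data$value[.data$status == "positive"]),
      .groups = "drop"
    )

  any_fq <- cl |>
    dplyr::group_by(.data$.stratum) |>
    dplyr::summarise(
      analyte = "any FQ",
      n = dplyr::n_distinct(.data$sample_id),
      n_positive = dplyr::n_distinct(
        .data$sample_id[.data$status == "positive"]),
      pos_stats(.data$value[.data$status == "positive"]),
      .groups = "drop"
    )

  out <- dplyr::bind_rows(per_analyte, any_fq)
  out$detection_rate <- 100 * out$n_positive / out$n
  out <- dplyr::rename(out, stratum = ".stratum")
  dplyr::relocate(out, "stratum", "analyte", "n", "n_positive",
                  "detection_rate")
}

#' Co-occurrence profile of positive samples
#'
#' Counts how many distinct analytes are positive per sample and reports
#' the distribution over positive samples (so a survey with 44 single- and
#' 3 multi-compound positives reports 93.6% / 6.4%).
#'
#' @param classified Long table from [classify_survey()].
#' @return A tibble with `n_compounds`, `n_samples`, `pct` (percent of
#'   positive samples); zero rows when nothing is positive.
#' @export
cooccurrence_profile <- function(classified) {
  per_sample <- classified |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_compounds = sum(.data$status == "positive"),
                     .groups = "drop") |>
    dplyr::filter(.data$n_compounds > 0)
  if (!nrow(per_sample)) {
    return(tibble(n_compounds = integer(), n_samples = integer(),
                  pct = numeric()))
  }
  prof <- per_sample |>
    dplyr::count(.data$n_compounds, name = "n_samples")
  prof$pct <- 100 * prof$n_samples / sum(prof$n_samples)
  prof
}

#' Compare residue levels or detection frequencies across strata
#'
#' Concentration mode applies the tie-corrected Kruskal–Wallis test to the
#' positive-sample concentrations by stratum; frequency mode applies the
#' Pearson Chi-square test (no continuity correction by default) to the
#' positive/total contingency table of samples.
#'
#' @param classified Long table from [classify_survey()].
#' @param grouping Name of the stratum column to compare.
#' @param mode `"concentration"` or `"frequency"`.
#' @param correct Apply the Yates continuity correction in frequency mode.
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble: `grouping`, `test`, `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
compare_groups <- function(classified, grouping,
                           mode = c("concentration", "frequency"),
                           correct = FALSE, alpha = 0.05) {
  mode <- match.arg(mode)
  if (!grouping %in% names(classified)) {
    abort(sprintf("no stratum column `%s`", grouping))
  }
  g <- classified[[grouping]]
  if (is.factor(g) && any(table(g) == 0)) abort("a group has zero samples")
  if (dplyr::n_distinct(g) < 2) abort("need at least two non-empty groups")

  if (mode == "concentration") {
    pos <- classified[classified$status == "positive", ]
    if (nrow(pos) < 2) abort("fewer than two positive values")
    if (dplyr::n_distinct(pos[[grouping]]) < 2) {
      abort("positives occur in fewer than two groups")
    }
    ht <- kruskal.test(pos$value, factor(pos[[grouping]]))
    test <- "kruskal_wallis"
  } else {
    per_sample <- classified |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(group = dplyr::first(.data[[grouping]]),
                       pos = any(.data$status == "positive"),
                       .groups = "drop")
    tab <- table(per_sample$group, factor(per_sample$pos, c(FALSE, TRUE)))
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    test <- "chi_square"
  }
  tibble(grouping = grouping, test = test,
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value),
         significant = unname(ht$p.value) < alpha)
}

#' Uniform-limit compliance summary
#'
#' Fraction of all samples whose maximum measured residue exceeds the
#' uniform limit (non-detects never exceed it).
#'
#' @param classified Long table from [classify_survey()].
#' @param limit Uniform limit, ug/kg.
#' @return One-row tibble with `n`, `n_noncompliant`, `pct_noncompliant`.
#' @export
compliance_summary <- function(classified, limit = 10) {
  per_sample <- classified |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      over = any(!is.na(.data$value) & !uniform_limit_flag(
        .data$value[!is.na(.data$value)], limit)),
      .groups = "drop")
  tibble(n = nrow(per_sample), n_noncompliant = sum(per_sample$over),
         pct_noncompliant = 100 * sum(per_sample$over) / nrow(per_sample))
}
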