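# Synthetic survey and exposure-parameter generators.
#
# The generator emulates the statistical structure of the five-year
# Zhejiang honey monitoring survey: 681 samples (521 Apis mellifera, 160
# Apis cerana), ~6.9% of samples positive for at least one
# fluoroquinolone, four detected compounds with marginal rates
# 4.9%/2.2%/0.29%/0.15%, heavy-tailed positive concentrations with a
# single extreme norfloxacin value (7890 ug/kg), and co-occurrence counts
# of 44 single- / 2 double- / 1 triple-compound positives among 47.
#
# Contamination is modelled at the sample level: a sample carries
# residues with probability p_any; a contaminated sample receives 1-3
# distinct compounds (weights from the co-occurrence counts) chosen with
# probability proportional to the marginal rates. With
# p_any = sum(p) / E[compounds per positive sample] this reproduces the
# marginal per-compound rates and the overall rate simultaneously, which
# fully independent per-compound sampling cannot do.

default_detection_prob <- c(norfloxacin = 0.049, ciprofloxacin = 0.022,
                            ofloxacin = 0.0029, enrofloxacin = 0.0015)

#' Synthetic survey generator configuration
#'
#' Defaults emulate the study conditions of the monitored survey; the
#' positive-concentration lognormal bodies are chosen so the expected
#' LOD/2-substituted all-sample means land near the reported
#' point-assessment inputs (see [read_reported_means()]).
#'
#' @param n_samples Number of honey samples.
#' @param detection_prob Named marginal positivity probability per
#'   compound (zero-probability compounds may be omitted).
#' @param positive_mean,positive_sd Named arithmetic mean/SD (ug/kg) of
#'   the lognormal positive-concentration body per detectable compound.
#' @param inject_max Named vector: after generation, one positive value of
#'   each named compound is replaced by this extreme (the survey's single
#'   7890 ug/kg norfloxacin maximum by default). `NULL` disables.
#' @param multi_weights Weights over the number of distinct compounds
#'   (1, 2, 3, ...) in a contaminated sample.
#' @param p_any Probability that a sample is contaminated at all;
#'   `NULL` derives it from `detection_prob` and `multi_weights` so the
#'   marginal rates are preserved.
#' @param city_weights,year_weights,species_weights,channel_weights,floral_weights
#'   Named sampling weights for the stratum labels (normalized
#'   internally).
#' @return A list of class `fq_survey_gen_config`.
#' @export
survey_gen_config <- function(
    n_samples = 681,
    detection_prob = default_detection_prob,
    positive_mean = c(norfloxacin = 92, ciprofloxacin = 41.3,
                      ofloxacin = 6.8, enrofloxacin = 2.6),
    positive_sd = c(norfloxacin = 180, ciprofloxacin = 61,
                    ofloxacin = 4.3, enrofloxacin = 1.3),
    inject_max = c(norfloxacin = 7890),
    multi_weights = c("1" = 44, "2" = 2, "3" = 1),
    p_any = NULL,
    city_weights = c(Hangzhou = 1, Ningbo = 1, Wenzhou = 1, Jiaxing = 1,
                     Huzhou = 1, Shaoxing = 1, Jinhua = 1, Quzhou = 1,
                     Taizhou = 1, Lishui = 1),
    year_weights = c("2014" = 82, "2015" = 153, "2016" = 115,
                     "2017" = 189, "2018" = 142),
    species_weights = c("Apis mellifera" = 521, "Apis cerana" = 160),
    channel_weights = c("apiary" = 502, "supermarket" = 70,
                        "honey processing facility" = 67,
                        "bee product store" = 42),
    floral_weights = c(rape = 35, acacia = 12, multiflower = 12, citrus = 8,
                       loquat = 8, linden = 5, chaste = 5, jujube = 3,
                       "Chinese milk vetch" = 2, honeysuckle = 2,
                       motherwort = 1, other = 7)) {
  assert_scalar_number(n_samples, "n_samples", 1)
  if (any(detection_prob < 0 | detection_prob > 1)) {
    abort("detection probabilities must lie in [0, 1]")
  }
  active <- names(detection_prob)[detection_prob > 0]
  if (!all(active %in% names(positive_mean)) ||
      !all(active %in% names(positive_sd))) {
    abort("every detectable compound needs positive_mean and positive_sd")
  }
  if (any(positive_mean <= 0) || any(positive_sd < 0)) {
    abort("positive-concentration means must be > 0 and SDs >= 0")
  }
  for (w in list(city_weights, year_weights, species_weights,
                 channel_weights, floral_weights, multi_weights)) {
    if (any(w < 0) || sum(w) <= 0 || is.null(names(w))) {
      abort("stratum weights must be named, non-negative, with positive sum")
    }
  }
  # a sample can hold at most as many distinct compounds as are detectable
  k <- pmin(as.numeric(names(multi_weights)), base::max(1, length(active)))
  mean_multiplicity <- sum(k * multi_weights) / sum(multi_weights)
  if (is.null(p_any)) p_any <- sum(detection_prob) / mean_multiplicity
  if (p_any < 0 || p_any > 1) abort("p_any must lie in [0, 1]")
  select_weights <- calibrate_selection_weights(
    detection_prob[active], p_any, k, multi_weights)
  structure(list(
    n_samples = as.integer(n_samples), detection_prob = detection_prob,
    positive_mean = positive_mean, positive_sd = positive_sd,
    inject_max = inject_max, multi_weights = multi_weights, p_any = p_any,
    select_weights = select_weights,
    city_weights = city_weights, year_weights = year_weights,
    species_weights = species_weights, channel_weights = channel_weights,
    floral_weights = floral_weights), class = "fq_survey_gen_config")
}

# Probability that each item is included in k successive weighted draws
# without replacement (exact, by enumeration; panels have <= 4 detectable
# compounds and k <= 3, so this is tiny).
inclusion_prob <- function(w, k) {
  out <- stats::setNames(numeric(length(w)), names(w))
  rec <- function(avail, k, p) {
    if (k == 0 || !length(avail)) return()
    tot <- sum(w[avail])
    for (j in avail) {
      pj <- p * w[j] / tot
      out[j] <<- out[j] + pj
      rec(setdiff(avail, j), k - 1, pj)
    }
  }
  rec(seq_along(w), base::min(k, length(w)), 1)
  out
}

# Fixed-point adjustment of the compound-selection weights so that the
# generator's exact marginal positivity per compound equals the nominal
# detection probabilities (plain weighted sampling without replacement
# under-selects the dominant compound in multi-compound samples).
calibrate_selection_weights <- function(p, p_any, k_levels, multi_weights) {
  if (!length(p) || p_any == 0) return(p)
  if (length(p) == 1) return(stats::setNames(1, names(p)))
  pk <- multi_weights / sum(multi_weights)
  target <- p / p_any  # required average inclusion probability
  if (any(target > 1 + 1e-9)) {
    abort("detection probabilities infeasible for the given p_any")
  }
  avg_incl <- function(v) {
    Reduce(`+`, lapply(seq_along(k_levels),
                       function(i) pk[i] * inclusion_prob(v, k_levels[i])))
  }
  v <- p
  for (it in 1:100) {
    cur <- avg_incl(v)
    if (base::max(abs(cur - target)) < 1e-12) break
    v <- v * target / cur
    v <- v / sum(v)
  }
  v
}

draw_labels <- function(weights, n) {
  if (length(weights) == 1) return(rep(names(weights), n))
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a synthetic residue survey
#'
#' @param cfg Configuration from [survey_gen_config()].
#' @param seed Optional integer seed; the output is deterministic given
#'   the seed.
#' @param panel Analyte panel ([read_panel()]): positive draws are floored
#'   at the compound LOQ and every panel compound gets a column.
#' @return A wide survey tibble that passes [validate_survey()].
#' @export
generate_survey <- function(cfg = survey_gen_config(), seed = NULL,
                            panel = read_panel()) {
  if (!inherits(cfg, "fq_survey_gen_config")) {
    abort("`cfg` must come from survey_gen_config()")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  meta <- tibble(
    sample_id = sprintf("SYN%05d", seq_len(n)),
    city = draw_labels(cfg$city_weights, n),
    year = as.integer(draw_labels(cfg$year_weights, n)),
    species = draw_labels(cfg$species_weights, n),
    floral_origin = draw_labels(cfg$floral_weights, n),
    channel = draw_labels(cfg$channel_weights, n))

  conc <- matrix(NA_real_, nrow = n, ncol = nrow(panel),
                 dimnames = list(NULL, panel$compound))
  p <- cfg$detection_prob[cfg$detection_prob > 0]
  w <- cfg$select_weights
  loq <- stats::setNames(panel$loq, panel$compound)
  if (length(p) && cfg$p_any > 0) {
    contaminated <- which(runif(n) < cfg$p_any)
    k_levels <- as.integer(names(cfg$multi_weights))
    for (i in contaminated) {
      k <- if (length(k_levels) == 1) k_levels else
        sample(k_levels, 1, prob = cfg$multi_weights)
      k <- base::min(k, length(p))
      comps <- if (length(p) == 1) names(p) else
        sample(names(w), k, prob = w)
      for (cp in comps) {
        spec <- lognormal_spec(cfg$positive_mean[[cp]], cfg$positive_sd[[cp]])
        conc[i, cp] <- base::max(sample_lognormal(spec, 1), loq[[cp]])
      }
    }
  }
  for (cp in names(cfg$inject_max)) {
    idx <- which(!is.na(conc[, cp]))
    if (!length(idx)) idx <- sample.int(n, 1)
    target <- idx[which.max(conc[idx, cp])]
    conc[target, cp] <- cfg$inject_max[[cp]]
  }
  out <- dplyr::bind_cols(meta, as_tibble(conc))
  validate_survey(out, panel)
  out
}

#' Exposure-parameter generator configuration
#'
#' Synthetic 24-h-recall dietary survey of 1956 respondents across four
#' age groups. The default group parameters are invented stand-ins for an
#' unavailable regional dietary survey; they place the adult
#' intake/body-weight ratio above the children's and adolescents', the
#' qualitative pattern observed for honey consumption in the region.
#'
#' @param groups Tibble with `age_group`, `intake_mean`, `intake_sd`
#'   (kg/day), `bw_mean`, `bw_sd` (kg), `n` per group.
#' @return A list of class `fq_exposure_gen_config`.
#' @export
exposure_gen_config <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- tibble(
      age_group = c("children 4-11", "adolescents 12-18", "adults 19-64",
                    "older adults 65+"),
      intake_mean = c(0.004, 0.009, 0.015, 0.014),
      intake_sd = c(0.0025, 0.006, 0.010, 0.009),
      bw_mean = c(25, 50, 62, 60),
      bw_sd = c(6, 10, 10, 9),
      n = c(320L, 310L, 980L, 346L))
  }
  required <- c("age_group", "intake_mean", "intake_sd", "bw_mean", "bw_sd", "n")
  missing <- setdiff(required, names(groups))
  if (length(missing)) {
    abort(paste0("groups lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(groups$age_group)) abort("age_group must be unique")
  num <- c("intake_mean", "intake_sd", "bw_mean", "bw_sd")
  if (any(sapply(groups[num], function(x) any(x <= 0)))) {
    abort("means and SDs must be strictly positive")
  }
  if (any(groups$n < 1)) abort("each group needs at least one respondent")
  structure(list(groups = groups), class = "fq_exposure_gen_config")
}

#' Generate a synthetic age-group exposure-parameter table
#'
#' Simulates individual lognormal 24-h-recall intake and body-weight
#' records per age group and reports their sample means and SDs, so that
#' downstream lognormal moment inversion is a true parameter-recovery
#' exercise rather than an identity.
#'
#' @param cfg Configuration from [exposure_gen_config()].
#' @param seed Optional integer seed.
#' @param keep_individuals Attach the individual draws as attribute
#'   `"individuals"`.
#' @return A tibble compatible with [read_exposure_params()].
#' @export
generate_exposure_params <- function(cfg = exposure_gen_config(),
                                     seed = NULL, keep_individuals = FALSE) {
  if (!inherits(cfg, "fq_exposure_gen_config")) {
    abort("`cfg` must come from exposure_gen_config()")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  indiv <- list()
  for (i in seq_len(nrow(cfg$groups))) {
    g <- cfg$groups[i, ]
    ik <- sample_lognormal(lognormal_spec(g$intake_mean, g$intake_sd), g$n)
    bw <- sample_lognormal(lognormal_spec(g$bw_mean, g$bw_sd), g$n)
    rows[[i]] <- tibble(age_group = g$age_group,
                        intake_mean = mean(ik), intake_sd = sd(ik),
                        bw_mean = mean(bw), bw_sd = sd(bw),
                        n_surveyed = g$n)
    if (keep_individuals) {
      indiv[[i]] <- tibble(age_group = g$age_group, intake = ik,
                           body_weight = bw)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_individuals) attr(out, "individuals") <- dplyr::bind_rows(indiv)
  out
}

#' Calibrate the generator to target all-sample mean residues
#'
#' Inverts the censored-mean moment equation
#' `target = p * E[positive] + (1 - p) * LOD/2` for the positive-body mean
#' of each targeted compound, so a survey generated at the calibrated
#' configuration reproduces the target LOD/2-substituted all-sample mean
#' in expectation. The calibrated compound's injected extreme is removed
#' (a single injected value is not part of the expectation) and its
#' positive SD is set equal to the mean (unit coefficient of variation)
#' unless the target table provides one.
#'
#' @param targets Tibble with `compound`, `mean` (target all-sample
#'   substituted mean, ug/kg) and optionally `detection_rate` (fraction)
#'   and `sd` (positive-body SD).
#' @param panel Analyte panel providing LODs.
#' @param base Configuration to calibrate.
#' @return A calibrated `fq_survey_gen_config`.
#' @export
calibrate_survey_config <- function(targets, panel = read_panel(),
                                    base = survey_gen_config()) {
  if (!all(c("compound", "mean") %in% names(targets))) {
    abort("targets need columns `compound` and `mean`")
  }
  cfg <- base
  for (i in seq_len(nrow(targets))) {
    cp <- targets$compound[i]
    target <- targets$mean[i]
    if (!cp %in% panel$compound) abort(sprintf("unknown compound `%s`", cp))
    if ("detection_rate" %in% names(targets) && !is.na(targets$detection_rate[i])) {
      cfg$detection_prob[[cp]] <- targets$detection_rate[i]
    }
    p <- if (cp %in% names(cfg$detection_prob)) cfg$detection_prob[[cp]] else 0
    lod <- panel$lod[panel$compound == cp]
    floor_mean <- (1 - p) * lod / 2
    if (p == 0) {
      # nothing to invert: the substituted mean is pinned at LOD/2, which
      # any target at or below the floor trivially satisfies
      if (target > lod / 2 + 1e-12) {
        abort(sprintf("`%s`: target %g infeasible with detection probability 0",
                      cp, target))
      }
      next
    }
    if (target < floor_mean) {
      abort(sprintf("`%s`: target mean %g below censoring floor %g",
                    cp, target, floor_mean))
    }
    mu_pos <- (target - floor_mean) / p
    cfg$positive_mean[[cp]] <- mu_pos
    cfg$positive_sd[[cp]] <-
      if ("sd" %in% names(targets) && !is.na(targets$sd[i]))
        targets$sd[i] else mu_pos
    cfg$inject_max <- cfg$inject_max[setdiff(names(cfg$inject_max), cp)]
  }
  # rebuild so p_any and the selection weights are re-derived from the
  # (possibly updated) detection probabilities
  survey_gen_config(
    n_samples = cfg$n_samples, detection_prob = cfg$detection_prob,
    positive_mean = cfg$positive_mean, positive_sd = cfg$positive_sd,
    inject_max = cfg$inject_max, multi_weights = cfg$multi_weights,
    city_weights = cfg$city_weights, year_weights = cfg$year_weights,
    species_weights = cfg$species_weights,
    channel_weights = cfg$channel_weights,
    floral_weights = cfg$floral_weights)
}
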