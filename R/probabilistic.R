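# Monte Carlo probabilistic exposure assessment.
#
# Per compound x age group: residue concentration C follows a triangular
# distribution fitted to the substituted survey values; daily intake K and
# body weight BW follow lognormal distributions parameterized from
# arithmetic means/SDs by exact moment inversion. Each iteration computes
# EDI = C*K/BW and HQ = EDI/ADI; quantiles (P50/P95 by default) summarize
# the HQ distribution.

#' Triangular distribution specification
#'
#' @param min,mode,max Parameters in ug/kg with `0 <= min <= mode <= max`.
#'   A degenerate spec (`min == max`) is allowed and samples a constant.
#' @return An object of class `fq_triangular`.
#' @export
triangular_spec <- function(min, mode, max) {
  for (nm in c("min", "mode", "max")) {
    assert_scalar_number(get(nm), nm, 0)
  }
  if (min > mode || mode > max) abort("need min <= mode <= max")
  structure(list(min = min, mode = mode, max = max), class = "fq_triangular")
}

#' Fit a triangular distribution to concentrations
#'
#' Anchors the minimum and maximum at the sample range and sets the mode
#' by method of moments (`3 * mean - min - max`), clipped into the range:
#' heavily censored surveys, whose mean sits at the LOD/2 floor, get a
#' mode at the minimum.
#'
#' @param values At least 3 non-negative concentrations (ug/kg), typically
#'   the LOD/2-substituted all-sample values of one compound.
#' @param anchor_zero Anchor the minimum at 0 instead of `min(values)`.
#' @return An `fq_triangular` spec.
#' @export
fit_triangular <- function(values, anchor_zero = FALSE) {
  if (length(values) < 3 || any(is.na(values))) {
    abort("need at least 3 non-missing values")
  }
  if (any(values < 0)) abort("values must be non-negative")
  a <- if (anchor_zero) 0 else min(values)
  b <- max(values)
  m <- 3 * mean(values) - a - b
  triangular_spec(a, base::min(base::max(m, a), b), b)
}

#' Triangular cumulative distribution function
#'
#' @param q Quantiles.
#' @param spec An `fq_triangular` spec.
#' @return `P(X <= q)`.
#' @export
ptriangular <- function(q, spec) {
  a <- spec$min; b <- spec$max; m <- spec$mode
  if (b == a) return(as.numeric(q >= a))
  p <- numeric(length(q))
  left <- q > a & q < m
  right <- q >= m & q < b
  p[left] <- (q[left] - a)^2 / ((b - a) * (m - a))
  p[right] <- 1 - (b - q[right])^2 / ((b - a) * (b - m))
  p[q >= b] <- 1
  p
}

#' Sample from a triangular distribution
#'
#' Inverse-CDF sampling from the current RNG stream.
#'
#' @param spec An `fq_triangular` spec.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_triangular <- function(spec, n) {
  a <- spec$min; b <- spec$max; m <- spec$mode
  if (b == a) return(rep(a, n))
  u <- runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Lognormal specification from arithmetic mean and SD
#'
#' Exact moment inversion: `sdlog = sqrt(log(1 + (sd/mean)^2))`,
#' `meanlog = log(mean) - sdlog^2 / 2`, so that samples recover the given
#' arithmetic mean and SD. `sd = 0` gives a degenerate constant spec,
#' used to reduce the simulation to the deterministic case.
#'
#' @param mean Arithmetic mean (> 0), native units (kg/day or kg).
#' @param sd Arithmetic standard deviation (>= 0).
#' @return An object of class `fq_lognormal` with `meanlog` and `sdlog`.
#' @export
lognormal_spec <- function(mean, sd) {
  assert_scalar_number(mean, "mean", 0, strict = TRUE)
  assert_scalar_number(sd, "sd", 0)
  sdlog <- sqrt(log1p((sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  structure(list(mean = mean, sd = sd, meanlog = meanlog, sdlog = sdlog),
            class = "fq_lognormal")
}

#' Sample from a lognormal specification
#'
#' @param spec An `fq_lognormal` spec.
#' @param n Number of draws.
#' @return Numeric vector of length `n`; a constant `spec$mean` when
#'   `sd = 0`.
#' @export
sample_lognormal <- function(spec, n) {
  if (spec$sdlog == 0) return(rep(spec$mean, n))
  rlnorm(n, spec$meanlog, spec$sdlog)
}

# Asymptotic standard error of an empirical quantile, via the density at
# the quantile: se = sqrt(p(1-p)/n) / f(q).
quantile_se <- function(x, p) {
  if (sd(x) == 0) return(0)
  q <- quantile(x, p, type = 1, names = FALSE)
  d <- density(x)
  f <- stats::approx(d$x, d$y, xout = q, rule = 2)$y
  sqrt(p * (1 - p) / length(x)) / base::max(f, .Machine$double.eps)
}

#' Monte Carlo simulation of the hazard quotient
#'
#' Draws C (triangular), K and BW (lognormal) independently, computes
#' per-iteration `EDI = C*K/BW` and `HQ = EDI/ADI`, and reports inverse
#' empirical-CDF (type-1) quantiles. Reproducible given `seed`.
#'
#' @param conc `fq_triangular` spec for the residue concentration (ug/kg).
#' @param intake `fq_lognormal` spec for daily honey intake (kg/day).
#' @param bw `fq_lognormal` spec for body weight (kg).
#' @param adi Acceptable daily intake (> 0), ug/kg bw/day.
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @param quantiles Probabilities strictly inside (0, 1).
#' @param keep_draws Keep the per-iteration draws (needed for sensitivity
#'   analysis) as a list-column `draws`.
#' @return One-row tibble with `edi_p*` and `hq_p*` columns for each
#'   requested quantile, `mc_se_p95`-style standard error for the largest
#'   quantile, `n_iter` and `seed`.
#' @export
simulate_hq <- function(conc, intake, bw, adi, n_iter = 10000, seed = NULL,
                        quantiles = c(0.5, 0.95), keep_draws = FALSE) {
  if (!inherits(conc, "fq_triangular")) abort("`conc` must be a triangular spec")
  if (!inherits(intake, "fq_lognormal") || !inherits(bw, "fq_lognormal")) {
    abort("`intake` and `bw` must be lognormal specs")
  }
  assert_scalar_number(adi, "adi", 0, strict = TRUE)
  assert_scalar_number(n_iter, "n_iter", 1)
  if (any(quantiles <= 0 | quantiles >= 1)) {
    abort("quantiles must lie strictly inside (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  cs <- sample_triangular(conc, n_iter)
  ks <- sample_lognormal(intake, n_iter)
  bs <- sample_lognormal(bw, n_iter)
  edi_i <- cs * ks / bs
  hq_i <- edi_i / adi

  quantiles <- sort(quantiles)
  qe <- quantile(edi_i, quantiles, type = 1, names = FALSE)
  qh <- quantile(hq_i, quantiles, type = 1, names = FALSE)
  tag <- format(100 * quantiles, trim = TRUE)
  out <- tibble(!!!stats::setNames(as.list(qe), paste0("edi_p", tag)),
                !!!stats::setNames(as.list(qh), paste0("hq_p", tag)))
  out[[paste0("mc_se_p", tag[length(tag)])]] <-
    quantile_se(hq_i, quantiles[length(quantiles)])
  out$n_iter <- as.integer(n_iter)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  if (keep_draws) {
    out$draws <- list(tibble(concentration = cs, intake = ks,
                             body_weight = bs, edi = edi_i, hq = hq_i))
  }
  out
}

#' Probabilistic risk assessment grid over a survey
#'
#' Fits a triangular spec per detected compound from the LOD/2-substituted
#' all-sample concentrations, builds lognormal intake and body-weight
#' specs per age group by moment inversion, and simulates every compound x
#' age-group cell. Each cell uses its own sub-seed derived from `seed` and
#' the cell labels, so cells are independent of grid composition.
#'
#' @param classified Long table from [classify_survey()] (substituted
#'   automatically if needed).
#' @param adi ADI registry tibble from [read_adi()]; detected compounds
#'   without an ADI are skipped with a warning.
#' @param exposure Age-group parameter tibble from
#'   [read_exposure_params()]; rows with missing parameters are skipped
#'   with a warning.
#' @param conc_specs Optional tibble overriding the fitted concentration
#'   distribution, with columns `analyte`, `min`, `mode`, `max` and
#'   optionally `age_group` for per-age-group overrides.
#' @inheritParams simulate_hq
#' @return A tibble, one row per compound x age group, with the
#'   [simulate_hq()] columns plus `analyte`, `age_group` and `acceptable`
#'   (`TRUE` when the HQ at the largest requested quantile is below 1).
#' @export
assess_probabilistic <- function(classified, adi = read_adi(),
                                 exposure = read_exposure_params(),
                                 n_iter = 10000, seed = 1,
                                 quantiles = c(0.5, 0.95),
                                 keep_draws = FALSE, conc_specs = NULL) {
  if (!nrow(classified)) abort("empty survey")
  if (!"substituted" %in% names(classified)) {
    classified <- substitute_lod_half(classified)
  }
  adi_map <- stats::setNames(adi$adi, adi$compound)
  detected <- unique(classified$analyte[classified$status == "positive"])
  if (!length(detected)) abort("no compound is positive in this survey")
  skip <- setdiff(detected, names(adi_map))
  if (length(skip)) {
    warn(paste0("skipping compound(s) without ADI: ",
                paste(skip, collapse = ", ")))
  }
  compounds <- intersect(detected, names(adi_map))

  lookup_spec <- function(compound, age_group) {
    if (!is.null(conc_specs)) {
      hit <- conc_specs[conc_specs$analyte == compound, ]
      if ("age_group" %in% names(hit) && nrow(hit) > 1) {
        hit <- hit[hit$age_group == age_group, ]
      }
      if (nrow(hit)) {
        return(triangular_spec(hit$min[1], hit$mode[1], hit$max[1]))
      }
    }
    fit_triangular(classified$value[classified$analyte == compound])
  }

  rows <- list()
  for (compound in compounds) {
    for (i in seq_len(nrow(exposure))) {
      grp <- exposure[i, ]
      if (anyNA(grp[c("intake_mean", "intake_sd", "bw_mean", "bw_sd")])) {
        warn(sprintf("age group `%s` lacks parameters; skipped",
                     grp$age_group))
        next
      }
      cell <- simulate_hq(
        conc = lookup_spec(compound, grp$age_group),
        intake = lognormal_spec(grp$intake_mean, grp$intake_sd),
        bw = lognormal_spec(grp$bw_mean, grp$bw_sd),
        adi = unname(adi_map[[compound]]),
        n_iter = n_iter,
        seed = stream_seed(seed, compound, grp$age_group),
        quantiles = quantiles, keep_draws = keep_draws)
      cell <- dplyr::bind_cols(tibble(analyte = compound,
                                      age_group = grp$age_group), cell)
      rows[[length(rows) + 1]] <- cell
    }
  }
  out <- dplyr::bind_rows(rows)
  hq_cols <- grep("^hq_p", names(out), value = TRUE)
  out$acceptable <- out[[hq_cols[length(hq_cols)]]] < 1
  out
}
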