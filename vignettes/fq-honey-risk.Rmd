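---
title: "Assessing consumer exposure to fluoroquinolone residues in honey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing consumer exposure to fluoroquinolone residues in honey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqrisk)
```

## The problem

Fluoroquinolones (FQs) are broad-spectrum antibiotics whose use in
beekeeping is banned or tightly restricted in most jurisdictions, yet
residues keep turning up in honey monitoring programmes. A residue survey
of this kind produces a heavily left-censored table: most samples are
non-detects, a few carry quantifiable residues, and a very small number
carry extreme concentrations (the motivating five-year provincial survey
of 681 honey samples found four of thirteen panel FQs in 6.9% of samples,
with a single norfloxacin value of 7890 µg·kg⁻¹ dominating the tail).
`fqrisk` turns such a table into consumer risk estimates in two standard
ways — a deterministic point assessment and a Monte Carlo probabilistic
assessment — plus the survey summaries regulators expect alongside them.

## Censoring model

Positivity is defined at the limit of quantitation: a measurement is
*positive* only when it is at or above the analyte's LOQ; a reported
number below the LOQ is a *trace* (kept numerically but not counted as a
detection); an empty cell is a *non-detect*. For risk calculations,
non-detects are substituted by LOD/2 (the SCOOP convention). Trace values
enter risk means at their reported value by default, because only
non-detection is substituted; `substitute_lod_half(traces_as_nondetect =
TRUE)` provides the alternative convention as a sensitivity mode, since
published summaries rarely state which was used.

Concentration bins are `[0,10)`, `[10,100)`, `[100,1000]` and `(1000,∞)`
µg·kg⁻¹. The source survey describes values "over 1000" and "between 100
and 1000", which does not pin down the boundaries; we fix the 10 and 100
boundaries left-closed and make ">1000" strictly greater, and document
rather than infer that choice. Compliance with the 10 µg·kg⁻¹ uniform
limit used in the EU and Japan is boundary-inclusive: exactly 10 µg·kg⁻¹
complies.

## Deterministic assessment

For each compound the chronic estimated daily intake is

$$\mathrm{EDI} = \frac{C \times K}{BW},$$

with \(C\) the **all-sample** mean residue after LOD/2 substitution
(µg·kg⁻¹), \(K = 0.01\) kg·day⁻¹ the average adult honey consumption and
\(BW = 60\) kg the adult body weight (both overridable). The hazard
quotient is \(\mathrm{HQ} = \mathrm{EDI}/\mathrm{ADI}\), acceptable below
1. The all-sample convention (rather than positives-only) is forced by
the arithmetic of the published tables: the ciprofloxacin mean entering
the published EDI (1.06 µg·kg⁻¹) is far below its positives-only mean
(41.3 µg·kg⁻¹). `hazard_quotient(rounded = TRUE)` first rounds the EDI to
3 significant figures; published tables compute their HQ cells from the
printed EDI, and e.g. the ofloxacin cell (4.75 × 10⁻⁶) is reproducible
only that way (full precision gives 4.74 × 10⁻⁶). The worst-case scenario
replaces the mean by the maximum observed concentration and reports the
result as a percentage of the ADI.

Stratified assessments (`group_by = "species"`, `"floral_origin"`,
`"channel"`) use the per-stratum all-sample mean. A few cells of the
published stratified tables are internally inconsistent (their printed
EDI does not equal mean × K/BW); we reproduce only self-consistent cells
in tests and treat the rest as typographic.

## Probabilistic assessment

Per compound × age group, one Monte Carlo iteration draws a concentration
\(C\) from a triangular distribution, an intake \(K\) and a body weight
\(BW\) from lognormal distributions (all mutually independent), and
computes \(\mathrm{HQ} = (C \cdot K / BW)/\mathrm{ADI}\). Choices that
matter:

* **Triangular fit.** `fit_triangular()` anchors the minimum and maximum
  at the range of the LOD/2-substituted all-sample values and places the
  mode by method of moments (\(3\bar{x} - a - b\)), clipped into the
  range — heavily censored compounds get a mode at the minimum. The
  source survey says only that a triangular distribution was fitted, so
  the anchoring is our choice; `anchor_zero = TRUE` gives the alternative
  \(a = 0\) anchor. All samples (not positives only) feed the fit, for
  consistency with the deterministic \(C\).
* **Lognormal moment inversion.** Dietary surveys report arithmetic
  means and SDs, so `lognormal_spec()` inverts the moments exactly:
  \(\sigma^2 = \ln(1 + sd^2/m^2)\), \(\mu = \ln m - \sigma^2/2\).
  `sd = 0` degenerates to a constant, which reduces the whole simulation
  to the deterministic case — a property the tests exploit as an oracle.
* **Quantiles.** Inverse empirical CDF (type-1 order statistic), P50 and
  P95 by default, at least 10,000 iterations by default. The Monte Carlo
  standard error of the top quantile is estimated as
  \(\sqrt{p(1-p)/n}/\hat f(q_p)\) with a kernel density estimate of
  \(\hat f\).
* **Reproducibility.** Every grid cell derives its own sub-seed from the
  run seed and the cell labels, so results are bit-reproducible and
  adding a compound or age group never changes another cell's draws.
* **Age-group concentration.** The optional `conc_specs` argument lets
  the concentration distribution differ by age group, for workflows whose
  exposure appendix specifies it; by default one fitted distribution per
  compound is shared across groups.

Sensitivity follows the contribution-to-variance convention of
spreadsheet risk simulators: the Spearman rank correlation \(\rho_i\) of
each input with the HQ, reported signed, with contributions
\(100\rho_i^2/\sum_j \rho_j^2\). No Sobol-style decomposition is
attempted; the rank-correlation measure is what the tornado charts in
this literature show.

## The synthetic study

The package ships no real sample-level data (the source survey's
appendix is not public), so `generate_survey()` emulates the study
conditions: 681 samples; species 521:160 *Apis mellifera*:*Apis cerana*;
years 2014–2018 with the published counts; channels 502/70/67/42; ten
producing cities; marginal positivity norfloxacin 4.9%, ciprofloxacin
2.2%, ofloxacin 0.29%, enrofloxacin 0.15%; lognormal positive
concentrations floored at the LOQ, with one injected norfloxacin extreme
of 7890 µg·kg⁻¹. The default positive-body means/SDs are set so the
expected substituted all-sample means land near the published point
inputs (e.g. norfloxacin ≈ 16.1, ciprofloxacin ≈ 1.06 µg·kg⁻¹).

Contamination is generated at the **sample level**: a sample is
contaminated with probability `p_any`, and a contaminated sample receives
1–3 distinct compounds with weights 44:2:1 (the survey's observed
co-occurrence counts). Independent per-compound Bernoulli draws at the
published marginal rates would put the expected any-FQ rate at 7.4%,
irreconcilable with the published 6.9% overall rate; the two-level model
reproduces the marginals, the overall rate and the 93.6%/6.4%
single/multi split simultaneously. Because weighted sampling without
replacement under-selects the dominant compound in multi-compound
samples, the selection weights are adjusted by an exact
inclusion-probability fixed point so the marginal rates are honest.
`calibrate_survey_config()` closes the loop analytically: it inverts
\(m = p\,\mathrm{E}[X^+] + (1-p)\,\mathrm{LOD}/2\) for the positive-body
mean so a target all-sample mean is met in expectation (the calibrated
compound's injected extreme is removed, as a single injected value is
not part of the expectation, and its positive SD defaults to the mean,
i.e. unit CV).

The exposure-parameter generator simulates lognormal 24-h-recall records
for 1956 respondents in four age groups and reports their sample moments,
so downstream moment inversion is a genuine recovery exercise. The group
parameters are invented stand-ins (flagged synthetic in the shipped
file): intakes of 4/9/15/14 g·day⁻¹ and body weights of 25/50/62/60 kg
for children 4–11, adolescents 12–18, adults 19–64 and older adults 65+,
which place the adult intake/body-weight ratio above the children's and
adolescents' — the qualitative age pattern the source survey reports.
Absolute probabilistic results under these defaults are therefore
illustrative, not estimates of any real population's exposure.

What the synthetic study deliberately does not model: correlation between
contamination and strata (the real survey found channel and species
differences), temporal or spatial structure, measurement error around the
reported concentrations, and any correlation among compounds beyond
co-occurrence counts. Passing tests on synthetic data therefore validate
the *machinery* — censoring rules, estimators, samplers, seeds — not the
epidemiology of any particular real survey.

## Problem sizes and tolerances

The test suite and the reproduction script run at the study's own sizes:
681-sample surveys (50 replicates for generator calibration checks), a
100,000-sample survey for the law-of-large-numbers calibration check,
10,000-iteration simulations (20 replicate seeds for the P95 stability
check, which requires a coefficient of variation below 2%). Point
estimates are compared to published cells at ±1 unit in the last printed
significant figure, absorbing the truncation-vs-rounding ambiguity of the
published tables; sampler checks use 3–4 standard-error bands and the 1%
Kolmogorov–Smirnov critical value.

## Known limitations

* Simple LOD/2 substitution only — no Kaplan–Meier or maximum-likelihood
  censored estimators, matching the convention of the modelled survey.
* One-dimensional Monte Carlo: variability and uncertainty are not
  separated.
* No multiple-testing correction across stratum comparisons, and no
  post-hoc pairwise tests.
* ADIs are taken as given; no carcinogenic slope factors are modelled.
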