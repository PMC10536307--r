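# fqrisk

Censoring-aware summarization of veterinary antibiotic residue surveys of
honey, and consumer dietary risk assessment — deterministic and Monte
Carlo probabilistic — for fluoroquinolone (FQ) residues.

Residue monitoring tables are heavily left-censored: most honey samples
are non-detects, positivity is defined at the method's limit of
quantitation (LOQ), and risk conventions substitute LOD/2 for
non-detects. `fqrisk` models that workflow end to end for a 13-compound
FQ panel:

* **Survey summaries** — detection frequencies per compound and stratum
  (species, floral origin, sale channel, city, year), positive-sample
  concentration statistics, concentration bins, co-occurrence profiles,
  compliance with the 10 µg·kg⁻¹ EU/Japan uniform limit, and stratum
  comparisons (Kruskal–Wallis on concentrations, Chi-square on detection
  frequencies).
* **Deterministic risk** — estimated daily intake
  EDI = C·K/BW (C the LOD/2-substituted all-sample mean residue, K the
  daily honey intake, BW body weight) and hazard quotient HQ = EDI/ADI,
  acceptable below 1, plus the worst-case %ADI from the maximum observed
  concentration. Defaults: K = 0.01 kg·day⁻¹, BW = 60 kg.
* **Probabilistic risk** — Monte Carlo HQ distributions per compound ×
  age group with triangular concentration and lognormal intake /
  body-weight inputs (exact moment inversion from arithmetic mean/SD),
  P50/P95 quantiles, seeded substreams, and rank-correlation
  contribution-to-variance sensitivity analysis.
* **Synthetic study** — a generator that emulates a five-year, 681-sample
  provincial survey (≈6.9% overall positivity, four detected compounds,
  one extreme norfloxacin value of 7890 µg·kg⁻¹), so every stage runs and
  is tested without external data.

## Worked example

```r
library(fqrisk)

panel  <- read_panel()                      # 13-FQ method constants (LOD/LOQ ...)
survey <- generate_survey(survey_gen_config(), seed = 42, panel = panel)
cl     <- substitute_lod_half(classify_survey(survey, panel))

dt <- detection_table(cl)
dt[dt$n_positive > 0, c("analyte", "n", "n_positive", "detection_rate")]
#>   analyte           n n_positive detection_rate
#> 1 ciprofloxacin   681         13           1.91
#> 2 norfloxacin     681         30           4.41
#> 3 any FQ          681         43           6.31

assess_deterministic(cl, read_adi())
#>   analyte       c_mean      edi       hq worst_case_pct_adi acceptable
#> 1 ciprofloxacin  0.886 0.000148 0.000984              31.7  TRUE
#> 2 norfloxacin   14.2   0.00236  0.000168               9.39 TRUE
```

In this draw, 43 of 681 samples (6.3%) are positive for at least one FQ.
The norfloxacin all-sample substituted mean of 14.2 µg·kg⁻¹ gives an EDI
of 2.4 × 10⁻³ µg·kg⁻¹ bw·day⁻¹ and an HQ of 1.7 × 10⁻⁴ — four orders of
magnitude below the acceptability threshold of 1 — while even the
worst-case scenario (the injected 7890 µg·kg⁻¹ maximum) reaches only
9.39% of the ADI.

```r
mc <- assess_probabilistic(cl, read_adi(), read_exposure_params(),
                           n_iter = 10000, seed = 42, keep_draws = TRUE)
mc[mc$analyte == "norfloxacin", c("age_group", "hq_p50", "hq_p95", "acceptable")]
#>   age_group         hq_p50 hq_p95 acceptable
#> 1 children 4-11     0.0209 0.0961 TRUE
#> 2 adolescents 12-18 0.0229 0.107  TRUE
#> 3 adults 19-64      0.0323 0.148  TRUE
#> 4 older adults 65+  0.0305 0.137  TRUE

sensitivity_table(mc[mc$analyte == "norfloxacin" &
                     mc$age_group == "adults 19-64", ])
#>   input           rho contribution_pct
#> 1 concentration  0.808            69.2
#> 2 intake         0.520            28.7
#> 3 body_weight   -0.141             2.11
```

The P95 hazard quotients stay well below 1 for every age group, with
adults highest (their intake/body-weight ratio is largest under the
shipped synthetic exposure parameters). The sensitivity decomposition
attributes ~69% of the HQ variance to the residue concentration and only
~2% to body weight, the typical ordering for heavy-tailed residue
surveys.

Real surveys are read with `read_survey("survey.csv", panel)` (non-detect
cells empty or `"ND"`); a thin command-line wrapper over the same
functions ships in `inst/cli/fqrisk.R`.

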