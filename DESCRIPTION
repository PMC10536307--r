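Package: fqrisk
Title: Fluoroquinolone Residue Surveys and Consumer Dietary Risk Assessment in Honey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for summarizing left-censored veterinary antibiotic residue
    surveys of honey and assessing consumer dietary risk. Provides censoring-aware
    survey summarization (positivity at the limit of quantitation, LOD/2
    substitution for non-detects, concentration binning, uniform-limit compliance),
    deterministic chronic exposure assessment (estimated daily intake and hazard
    quotients per compound and stratum), Monte Carlo probabilistic assessment with
    triangular residue-concentration and lognormal intake and body-weight inputs,
    rank-correlation contribution-to-variance sensitivity analysis, and a synthetic
    survey generator that emulates the statistical structure of a five-year
    fluoroquinolone monitoring survey so that every stage runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
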