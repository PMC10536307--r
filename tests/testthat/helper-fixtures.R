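# Fixtures are built in code: small wide surveys with fixed metadata, and
# engineered surveys with exact positive counts.

fixture_panel <- read_panel()
fixture_adi <- read_adi()

# Wide survey from a named list of analyte value vectors (NA = non-detect).
make_survey <- function(values, n = length(values[[1]]),
                        channel = "apiary", species = "Apis mellifera",
                        floral = "rape") {
  meta <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    city = "Hangzhou",
    year = 2016L,
    species = rep_len(species, n),
    floral_origin = rep_len(floral, n),
    channel = rep_len(channel, n))
  dplyr::bind_cols(meta, tibble::as_tibble(lapply(values, as.numeric)))
}

# Survey with exactly `n_pos` positive samples for one analyte.
survey_with_positives <- function(n, n_pos, analyte = "norfloxacin",
                                  value = 50) {
  v <- rep(NA_real_, n)
  if (n_pos > 0) v[seq_len(n_pos)] <- value
  make_survey(stats::setNames(list(v), analyte), n = n)
}

classified_fixture <- function(survey) {
  substitute_lod_half(classify_survey(survey, fixture_panel))
}

# tolerance of +/- 1 unit in the last of 3 printed significant figures
tol_last_digit <- function(x, digits = 3) {
  10^(floor(log10(abs(x))) - digits + 1)
}
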