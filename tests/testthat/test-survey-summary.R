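test_that("detection frequency reproduces counts (47 positive of 681 -> 6.9%)", {
  cl <- classified_fixture(survey_with_positives(681, 47))
  dt <- detection_table(cl)
  any_fq <- dt[dt$analyte == "any FQ", ]
  expect_equal(any_fq$n, 681)
  expect_equal(any_fq$n_positive, 47)
  expect_equal(round(any_fq$detection_rate, 1), 6.9)
})

test_that("an all-non-detect survey has zero rate and empty statistics", {
  cl <- classified_fixture(survey_with_positives(10, 0))
  dt <- detection_table(cl)
  expect_true(all(dt$detection_rate == 0))
  expect_true(all(is.na(dt$mean_pos)))
  expect_equal(nrow(cooccurrence_profile(cl)), 0)
  expect_error(detection_table(cl[0, ]), "empty")
})

test_that("per-compound rates fall in the exact binomial band of the generator", {
  cfg <- survey_gen_config(
    detection_prob = c(norfloxacin = 0.05),
    positive_mean = c(norfloxacin = 92), positive_sd = c(norfloxacin = 180),
    inject_max = NULL, multi_weights = c("1" = 1))
  counts <- vapply(1:20, function(seed) {
    survey <- generate_survey(cfg, seed = seed, panel = fixture_panel)
    sum(!is.na(survey$norfloxacin))
  }, numeric(1))
  band <- qbinom(c(0.005, 0.995), 20 * 681, 0.05)
  expect_gte(sum(counts), band[1])
  expect_lte(sum(counts), band[2])
})

test_that("co-occurrence profile reports the single/multi split over positives", {
  # 44 single-, 2 double-, 1 triple-compound positives among 47
  nor <- c(rep(50, 44 + 2 + 1), rep(NA, 634))
  cip <- c(rep(NA, 44), rep(30, 2 + 1), rep(NA, 634))
  ofl <- c(rep(NA, 46), 5, rep(NA, 634))
  cl <- classified_fixture(make_survey(list(
    norfloxacin = nor, ciprofloxacin = cip, ofloxacin = ofl)))
  prof <- cooccurrence_profile(cl)
  expect_equal(prof$n_samples, c(44, 2, 1))
  expect_equal(round(prof$pct[prof$n_compounds == 1], 1), 93.6)
  expect_equal(round(sum(prof$pct[prof$n_compounds > 1]), 1), 6.4)
})

test_that("frequency comparison matches the closed-form Pearson statistic", {
  # species contingency 41/480 vs 6/154 positives/negatives
  nor <- c(rep(50, 41), rep(NA, 480), rep(40, 6), rep(NA, 154))
  survey <- make_survey(list(norfloxacin = nor),
                        species = c(rep("Apis mellifera", 521),
                                    rep("Apis cerana", 160)))
  cl <- classified_fixture(survey)
  res <- compare_groups(cl, "species", mode = "frequency")

  # independent oracle: Pearson X^2 from first principles on the 2x2 table
  obs <- matrix(c(41, 480, 6, 154), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  x2 <- sum((obs - expected)^2 / expected)
  expect_equal(res$statistic, x2, tolerance = 1e-12)
  expect_equal(res$test, "chi_square")
  expect_equal(res$df, 1)
})

test_that("concentration comparison flags a large distributional shift", {
  set.seed(7)
  lo <- pmax(round(rlnorm(40, log(20), 0.3), 2), 2)
  hi <- pmax(round(rlnorm(40, log(400), 0.3), 2), 2)
  survey <- make_survey(list(norfloxacin = c(lo, hi)),
                        channel = c(rep("apiary", 40), rep("supermarket", 40)))
  cl <- classified_fixture(survey)
  shifted <- compare_groups(cl, "channel", mode = "concentration")
  expect_true(shifted$significant)

  same <- make_survey(list(norfloxacin = rep(c(10, 20, 30), 4)),
                      channel = rep(c("apiary", "supermarket"), each = 6))
  res_same <- compare_groups(classified_fixture(same), "channel",
                             mode = "concentration")
  expect_false(res_same$significant)
})

test_that("comparison rejects degenerate groupings", {
  cl <- classified_fixture(survey_with_positives(6, 1))
  expect_error(compare_groups(cl, "channel"), "two non-empty groups")
  one_pos <- make_survey(list(norfloxacin = c(40, NA, NA, NA)),
                         channel = c("apiary", "apiary", "supermarket",
                                     "supermarket"))
  expect_error(compare_groups(classified_fixture(one_pos), "channel",
                              mode = "concentration"), "positive")
})

test_that("stratified tables aggregate consistently to the overall table", {
  survey <- generate_survey(survey_gen_config(), seed = 3,
                            panel = fixture_panel)
  cl <- classified_fixture(survey)
  overall <- detection_table(cl)
  by_channel <- detection_table(cl, group_by = "channel")
  for (a in c("norfloxacin", "any FQ")) {
    expect_equal(sum(by_channel$n[by_channel$analyte == a]),
                 overall$n[overall$analyte == a])
    expect_equal(sum(by_channel$n_positive[by_channel$analyte == a]),
                 overall$n_positive[overall$analyte == a])
  }
})

test_that("positive-sample statistics never include substituted values", {
  survey <- make_survey(list(norfloxacin = c(100, 200, NA, NA)))
  cl <- classified_fixture(survey)
  dt <- detection_table(cl)
  nor <- dt[dt$analyte == "norfloxacin", ]
  expect_equal(nor$mean_pos, 150)  # not pulled down by the two LOD/2 values
  expect_equal(nor$max_pos, 200)
})

test_that("compliance summary counts samples above the uniform limit", {
  survey <- make_survey(list(norfloxacin = c(7890, 2.6, NA, 10)))
  cs <- compliance_summary(classify_survey(survey, fixture_panel))
  expect_equal(cs$n_noncompliant, 1)
  expect_equal(cs$pct_noncompliant, 25)
})
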