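test_that("triangular fitting anchors the range and clips the mode", {
  spec <- fit_triangular(c(0, 1, 2))
  expect_equal(c(spec$min, spec$mode, spec$max), c(0, 1, 2))
  # heavy censoring drags the moment mode below the minimum -> clipped
  heavy <- c(rep(0.175, 60), 10)
  spec2 <- fit_triangular(heavy)
  expect_equal(spec2$mode, spec2$min)
  spec3 <- fit_triangular(c(5, 5, 5))
  expect_equal(unique(sample_triangular(spec3, 100)), 5)
  expect_error(fit_triangular(c(1, 2)), "3")
})

test_that("triangular sampling matches the closed-form distribution", {
  spec <- triangular_spec(0, 0, 1)
  set.seed(101)
  x <- sample_triangular(spec, 1e5)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1 / 3), 3 * se)

  set.seed(102)
  y <- sample_triangular(triangular_spec(2, 5, 11), 1e4)
  ks <- suppressWarnings(stats::ks.test(
    y, function(q) ptriangular(q, triangular_spec(2, 5, 11))))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(1e4))  # 1% critical value
})

test_that("lognormal moment inversion recovers arithmetic moments", {
  spec <- lognormal_spec(60, 10)
  set.seed(103)
  x <- sample_lognormal(spec, 1e5)
  expect_lt(abs(mean(x) - 60), 3 * sd(x) / sqrt(length(x)))
  expect_lt(abs(sd(x) - 10) / 10, 0.05)
  # closed-form median is exp(meanlog)
  med_se <- 1.2533 * sd(x) / sqrt(length(x))
  expect_lt(abs(median(x) - exp(spec$meanlog)), 4 * med_se)
  # zero-variance limit collapses to the mean
  expect_equal(sample_lognormal(lognormal_spec(60, 0), 5), rep(60, 5))
})

test_that("degenerate distributions reduce the simulation to the point estimate", {
  mc <- simulate_hq(triangular_spec(1.06, 1.06, 1.06),
                    lognormal_spec(0.01, 0), lognormal_spec(60, 0),
                    adi = 0.15, n_iter = 1000, seed = 1)
  point <- hazard_quotient(edi(1.06), 0.15)
  expect_equal(mc$hq_p50, point)
  expect_equal(mc$hq_p95, point)
  expect_equal(mc$mc_se_p95, 0)
})

test_that("HQ quantiles scale linearly with the concentration distribution", {
  base <- triangular_spec(1, 20, 400)
  dbl <- triangular_spec(2, 40, 800)
  k <- lognormal_spec(0.01, 0.006)
  bw <- lognormal_spec(60, 10)
  m1 <- simulate_hq(base, k, bw, adi = 14, n_iter = 5000, seed = 42)
  m2 <- simulate_hq(dbl, k, bw, adi = 14, n_iter = 5000, seed = 42)
  expect_equal(m2$hq_p50, 2 * m1$hq_p50)
  expect_equal(m2$hq_p95, 2 * m1$hq_p95)
})

test_that("the same seed reproduces the simulation bit for bit", {
  args <- list(triangular_spec(0.175, 0.175, 7890),
               lognormal_spec(0.015, 0.01), lognormal_spec(62, 10),
               adi = 14, n_iter = 2000, seed = 99, keep_draws = TRUE)
  m1 <- do.call(simulate_hq, args)
  m2 <- do.call(simulate_hq, args)
  expect_identical(m1, m2)
})

test_that("concentration and intake streams are independent", {
  m <- simulate_hq(triangular_spec(0.175, 10, 7890),
                   lognormal_spec(0.015, 0.01), lognormal_spec(62, 10),
                   adi = 14, n_iter = 2e4, seed = 17, keep_draws = TRUE)
  d <- m$draws[[1]]
  set.seed(18)
  perm <- sample.int(nrow(d))
  hq_perm <- d$concentration[perm] * d$intake / d$body_weight / 14
  q_orig <- quantile(d$hq, c(0.5, 0.95), type = 1)
  q_perm <- quantile(hq_perm, c(0.5, 0.95), type = 1)
  expect_equal(unname(q_perm), unname(q_orig), tolerance = 0.05)
})

test_that("the assessment grid orders quantiles and age groups sensibly", {
  survey <- generate_survey(survey_gen_config(), seed = 21,
                            panel = fixture_panel)
  cl <- classified_fixture(survey)
  mc <- assess_probabilistic(cl, fixture_adi, read_exposure_params(),
                             n_iter = 2000, seed = 7)
  expect_true(all(mc$hq_p50 <= mc$hq_p95))
  expect_true(all(mc$hq_p95 > 0))
  # adults have a higher intake/body-weight ratio than children
  for (a in unique(mc$analyte)) {
    adult <- mc$hq_p95[mc$analyte == a & mc$age_group == "adults 19-64"]
    child <- mc$hq_p95[mc$analyte == a & mc$age_group == "children 4-11"]
    expect_gt(adult, child)
  }
})

test_that("a degenerate grid reproduces the deterministic table", {
  survey <- generate_survey(survey_gen_config(), seed = 23,
                            panel = fixture_panel)
  cl <- classified_fixture(survey)
  det <- assess_deterministic(cl, fixture_adi)
  exposure <- tibble::tibble(age_group = "adults point", intake_mean = 0.01,
                             intake_sd = 1e-12, bw_mean = 60, bw_sd = 1e-12,
                             n_surveyed = 1)
  specs <- tibble::tibble(analyte = det$analyte, min = det$c_mean,
                          mode = det$c_mean, max = det$c_mean)
  mc <- assess_probabilistic(cl, fixture_adi, exposure, n_iter = 500,
                             seed = 1, conc_specs = specs)
  merged <- merge(det, mc, by = "analyte")
  expect_equal(merged$hq_p95, merged$hq, tolerance = 1e-6)
})

test_that("invalid specifications fail before sampling", {
  expect_error(triangular_spec(3, 2, 5), "min <= mode <= max")
  expect_error(triangular_spec(-1, 0, 1), ">= 0")
  expect_error(lognormal_spec(0, 1), "> 0")
  expect_error(simulate_hq(triangular_spec(0, 1, 2), lognormal_spec(1, 1),
                           lognormal_spec(60, 5), adi = -1), "adi")
  expect_error(simulate_hq(triangular_spec(0, 1, 2), lognormal_spec(1, 1),
                           lognormal_spec(60, 5), adi = 1,
                           quantiles = c(0, 0.5)), "quantiles")
})
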