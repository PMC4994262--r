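test_that("quantile calibration reproduces printed medians and quartiles", {
  # lognormal: WBC-like summary
  p <- calibrate_spec(8.5, 6.7, 10.9, "lognormal")
  expect_equal(p$location, log(8.5), tolerance = 1e-12)
  expect_equal(p$scale, (log(10.9) - log(6.7)) / (2 * qnorm(0.75)),
               tolerance = 1e-12)
  expect_equal(p$scale, 0.3606, tolerance = 1e-3)
  # a two-parameter lognormal pins the median and the quartile ratio
  expect_equal(qlnorm(0.5, p$location, p$scale), 8.5, tolerance = 1e-12)
  expect_equal(qlnorm(0.75, p$location, p$scale) /
                 qlnorm(0.25, p$location, p$scale),
               10.9 / 6.7, tolerance = 1e-12)

  # normal: temperature-like summary
  q <- calibrate_spec(36.4, 36.0, 36.8, "normal")
  expect_equal(q$location, 36.4)
  expect_equal(q$scale, 0.593, tolerance = 1e-3)
  expect_equal(qnorm(c(0.25, 0.5, 0.75), q$location, q$scale),
               c(36.0, 36.4, 36.8), tolerance = 1e-10)

  # unit-normal identity
  u <- calibrate_spec(0, -qnorm(0.75), qnorm(0.75), "normal")
  expect_equal(u$location, 0)
  expect_equal(u$scale, 1, tolerance = 1e-12)

  expect_error(calibrate_spec(1, 2, 3, "normal"), "q25 < median")
  expect_error(calibrate_spec(0.5, -1, 2, "lognormal"), "positive")
})

test_that("simulated marginals, availability, and prevalence match the configuration", {
  # class-conditional marginals are checked on a case-enriched draw so the
  # septic class carries enough observations to resolve a median to 5%
  cfg <- cohort_config(calibrated_features(), n_encounters = 100000,
                       prevalence = 0.5, seed = 101)
  coh <- simulate_cohort(cfg)

  # per-class medians and quartiles within 5% relative of targets
  sep <- coh$sepsis == 1
  expect_equal(median(coh$wbc_k[sep], na.rm = TRUE), 14.3, tolerance = 0.05)
  expect_equal(median(coh$wbc_k[!sep], na.rm = TRUE), 8.5, tolerance = 0.05)
  expect_equal(median(coh$temp_c[!sep], na.rm = TRUE), 36.4, tolerance = 0.05)
  expect_equal(median(coh$hr[!sep], na.rm = TRUE), 86, tolerance = 0.05)
  expect_equal(unname(quantile(coh$wbc_k[sep], c(0.25, 0.75), na.rm = TRUE)),
               c(9.8, 20.6), tolerance = 0.05)

  # informative lab availability: 22% non-septic, 53% septic, within 1 pp
  expect_lt(abs(mean(!is.na(coh$wbc_k[!sep])) - 0.22), 0.01)
  expect_lt(abs(mean(!is.na(coh$wbc_k[sep])) - 0.53), 0.01)
  expect_lt(abs(mean(is.na(coh$lactate[!sep])) - 0.97), 0.01)

  # mean BP is the parent composition wherever both parents are observed
  both <- !is.na(coh$sbp) & !is.na(coh$dbp)
  expect_equal(coh$mean_bp[both], (coh$sbp[both] + 2 * coh$dbp[both]) / 3)
  expect_true(all(coh$age_years >= 14))

  # pooled-mode prevalence within binomial 99% bounds at the study rate
  cfg2 <- default_cohort_config(seed = 102, calendar = FALSE,
                                n_encounters = 100000)
  coh2 <- simulate_cohort(cfg2)
  n <- nrow(coh2)
  expect_lt(abs(sum(coh2$sepsis) - n * 0.0038),
            qnorm(0.995) * sqrt(n * 0.0038 * (1 - 0.0038)))
})

test_that("same seed and config give a byte-identical cohort", {
  cfg <- default_cohort_config(seed = 7, calendar = FALSE, n_encounters = 500)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- default_cohort_config(seed = 8, calendar = FALSE, n_encounters = 500)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("degenerate and independence cases behave by construction", {
  feats <- calibrated_features()
  cfg0 <- cohort_config(feats, n_encounters = 5000, prevalence = 0, seed = 3)
  coh0 <- simulate_cohort(cfg0)
  expect_true(all(coh0$sepsis == 0))
  expect_lt(abs(mean(coh0$nurse_flag) - cfg0$flag_fpr), 0.01)

  cfg <- default_cohort_config(seed = 11, calendar = FALSE,
                               n_encounters = 100000)
  coh <- simulate_cohort(cfg)
  ok <- coh$sepsis == 0 & !is.na(coh$temp_c) & !is.na(coh$hr)
  expect_lt(abs(cor(coh$temp_c[ok], coh$hr[ok])), 0.02)

  # the dependence knob induces positive within-class correlation
  cfgc <- default_cohort_config(seed = 11, calendar = FALSE,
                                n_encounters = 20000,
                                class_correlation = 0.5)
  cohc <- simulate_cohort(cfgc)
  okc <- cohc$sepsis == 0 & !is.na(cohc$temp_c) & !is.na(cohc$hr)
  expect_gt(cor(cohc$temp_c[okc], cohc$hr[okc]), 0.3)
})

test_that("calendar replay reproduces monthly volumes exactly", {
  cal <- study_calendar()
  expect_equal(sum(cal$encounters), 93773)
  expect_equal(sum(cal$sepsis), 352)
  expect_equal(sum(cal$days), 456)
  expect_equal(100 * sum(cal$sepsis) / sum(cal$encounters), 0.38,
               tolerance = 0.02)

  months <- replay_calendar(cal, strict = TRUE)
  cfg <- cohort_config(calibrated_features(), months = months, seed = 5)
  coh <- simulate_cohort(cfg)
  got <- tapply(coh$sepsis, coh$month_index, sum)
  expect_equal(as.numeric(got), as.numeric(cal$sepsis))
  expect_equal(as.numeric(table(coh$month_index)),
               as.numeric(cal$encounters))

  one <- replay_calendar(data.frame(encounters = 100, sepsis = 1))
  coh1 <- simulate_cohort(cohort_config(calibrated_features(),
                                        months = one, seed = 2))
  expect_equal(nrow(coh1), 100)
  expect_equal(sum(coh1$sepsis), 1)

  expect_error(replay_calendar(data.frame(encounters = 10, sepsis = 20)),
               "more sepsis")
  expect_error(replay_calendar(data.frame(encounters = 1, sepsis = 0),
                               strict = TRUE), "15")
})

test_that("encounter CSV round-trips with empty missing fields", {
  cfg <- default_cohort_config(seed = 9, calendar = FALSE, n_encounters = 200)
  coh <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$wbc_k, coh$wbc_k, tolerance = 1e-12)
  expect_identical(is.na(back$lactate), is.na(coh$lactate))
  expect_identical(back$sepsis, coh$sepsis)
  header <- readLines(path, n = 1)
  expect_match(header, "^encounter_id,month_index,age_years,female,sbp,dbp")
})
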