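test_that("concordance AUC handles separation, ties, and enumerated pairs", {
  expect_equal(auc_continuous(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_continuous(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  # 6 pairs: 0.8 beats all three; 0.3 beats 0.2, ties 0.3 -> 4.5/6
  expect_equal(auc_continuous(c(0.8, 0.3, 0.5, 0.2, 0.3),
                              c(1, 1, 0, 0, 0)), 0.75)
  expect_error(auc_continuous(1:4, rep(1, 4)), "both classes")
})

test_that("rank concordance equals trapezoidal ROC area and pROC on random instances", {
  for (seed in 1:40) {
    inst <- random_score_instance(n = sample(5:500, 1), seed = seed)
    expect_equal(auc_continuous(inst$scores, inst$labels),
                 oracle_trapezoid_auc(inst$scores, inst$labels),
                 tolerance = 1e-12)
  }
  inst <- random_score_instance(n = 300, seed = 99)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(inst$labels, inst$scores,
                                             quiet = TRUE,
                                             direction = "<")))
  expect_equal(auc_continuous(inst$scores, inst$labels), proc_auc,
               tolerance = 1e-12)
})

test_that("binary-alert AUC identity holds and matches the concordance route", {
  expect_equal(binary_auc(0.543, 0.031), 0.756)
  expect_equal(binary_auc(0.216, 0.004), 0.606)
  expect_equal(binary_auc(1, 0), 1)
  expect_error(binary_auc(1.2, 0), "\\[0, 1\\]")

  # a binary alert vector treated as a score gives exactly (sens+spec)/2
  for (seed in 1:10) {
    inst <- random_score_instance(n = 80, seed = seed)
    alert <- as.integer(inst$scores >= 0.5)
    r <- confusion_report(inst$scores, inst$labels, 0.5, days = 1)
    expect_equal(auc_continuous(alert, inst$labels),
                 binary_auc(r$sensitivity, r$fpr), tolerance = 1e-12)
  }
})

test_that("confusion reports enumerate the 2x2 table and its derived metrics", {
  r <- confusion_report(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0), 0.5, days = 2)
  expect_equal(r[c("tp", "fp", "fn", "tn")], list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$fpr, 0.5)
  expect_equal(r$ppv, 0.5)
  expect_equal(r$fp_per_day, 0.5)
  expect_equal(r$tp + r$fp + r$tn + r$fn, 4)

  # always-alert and never-alert boundaries
  sc <- runif(50); lab <- rep(c(0, 1), 25)
  r0 <- confusion_report(sc, lab, 0, days = 5)
  expect_equal(r0$sensitivity, 1)
  expect_equal(r0$specificity, 0)
  r1 <- confusion_report(sc, lab, 2, days = 5)
  expect_equal(r1$sensitivity, 0)
  expect_equal(r1$npv, 0.5)  # 1 - prevalence
  expect_error(confusion_report(sc, lab, 0.5, days = 0), "positive")

  expect_equal(fp_per_day_from_rate(0.073, 93421, 456), 14.96, tolerance = 1e-3)
  expect_equal(fp_per_day_from_rate(0, 1000, 10), 0)
})

test_that("threshold searches match exhaustive cutpoint enumeration", {
  pos <- c(0.9, 0.7, 0.2); neg <- c(0.5, 0.1)
  sc <- c(pos, neg); lab <- c(1, 1, 1, 0, 0)
  expect_equal(threshold_for_sensitivity(sc, lab, 1.0), 0.2)
  expect_equal(threshold_for_sensitivity(sc, lab, 0.66), 0.7)
  expect_equal(threshold_for_sensitivity(sc, lab, 0.68), 0.2)

  sc2 <- c(0.9, 0.8, 0.6, 0.4); lab2 <- c(1, 0, 0, 0)
  expect_equal(threshold_for_fp_budget(sc2, lab2, 1, days = 1), 0.8)
  expect_equal(threshold_for_fp_budget(sc2, lab2, 100, days = 1), 0.4)
  expect_equal(threshold_for_fp_budget(sc2, lab2, 0, days = 1), 0.9)

  expect_equal(threshold_max_binary_auc(sc, lab), 0.7)
  sep <- c(1, 2, 10, 11); lab4 <- c(0, 0, 1, 1)
  expect_equal(threshold_max_binary_auc(sep, lab4), 10)

  for (seed in 1:25) {
    inst <- random_score_instance(n = sample(10:200, 1), seed = 200 + seed)
    tgt <- runif(1, 0.05, 1)
    expect_identical(
      threshold_for_sensitivity(inst$scores, inst$labels, tgt),
      oracle_threshold_for_sensitivity(inst$scores, inst$labels, tgt))
    bud <- runif(1, 0, 20)
    expect_identical(
      threshold_for_fp_budget(inst$scores, inst$labels, bud, days = 3),
      oracle_threshold_for_fp_budget(inst$scores, inst$labels, bud, days = 3))
    expect_identical(
      threshold_max_binary_auc(inst$scores, inst$labels),
      oracle_threshold_max_binary_auc(inst$scores, inst$labels))
  }
})

test_that("incremental true positives partition septic detections", {
  lab <- c(1, 1, 1, 0, 0)
  r <- incremental_tp(c(1, 1, 0, 1, 0), c(0, 1, 1, 0, 1), lab)
  expect_equal(r, list(model_only = 1, screen_only = 1, both = 1))
  same <- incremental_tp(c(1, 0, 1, 0, 0), c(1, 0, 1, 0, 0), lab)
  expect_equal(same$model_only + same$screen_only, 0)
  none <- incremental_tp(c(1, 1, 0, 1, 0), rep(0, 5), lab)
  expect_equal(none$screen_only, 0)
  expect_equal(none$model_only, 2)
  expect_error(incremental_tp(1, c(1, 0), c(1, 0)), "equal length")
})

test_that("the SIRS rule counts observed components and treats missing as unsatisfied", {
  d <- data.frame(temp_c = c(39, NA, 37), hr = c(100, NA, 95),
                  rr = c(22, NA, 21), wbc_k = c(15, NA, NA))
  expect_equal(sirs_criteria(d), c(4, 0, 2))
  expect_equal(sirs_rule(d, k = 2), c(1L, 0L, 1L))
  expect_equal(sirs_rule(d, k = 4), c(1L, 0L, 0L))
  expect_equal(sirs_rule(d, k = 1)[2], 0L)
  # hypothermia and leukopenia count as abnormal
  d2 <- data.frame(temp_c = 35, hr = 50, rr = 10, wbc_k = 3)
  expect_equal(sirs_criteria(d2), 2)
  expect_error(sirs_rule(d, k = 5), "between 1 and 4")
})

test_that("coefficient of variation uses the sample SD and guards its domain", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(4, 6)), 0)
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("monthly performance pools back to whole-cohort metrics", {
  cfg <- default_cohort_config(seed = 61)
  coh <- simulate_cohort(cfg)
  m <- nb_fit(coh, coh$sepsis, default_feature_set())
  s <- nb_score(m, coh)
  mp <- monthly_performance(coh, s, 0.05, coh$nurse_flag, cfg$months)

  expect_equal(nrow(mp$months), 15)
  expect_equal(sum(mp$months$encounters), nrow(coh))
  expect_equal(sum(mp$months$sepsis), sum(coh$sepsis))
  expect_equal(mp$months$sepsis, cfg$months$sepsis)

  pooled <- confusion_report(s, coh$sepsis, 0.05, sum(cfg$months$days))
  tp_by_month <- mp$months$model_sens * mp$months$sepsis
  expect_equal(sum(tp_by_month), pooled$tp, tolerance = 1e-9)
  fp_by_month <- mp$months$model_fp_day * cfg$months$days
  expect_equal(sum(fp_by_month), pooled$fp, tolerance = 1e-9)

  # summary rows
  cvrow <- mp$summary[mp$summary$stat == "cv", ]
  expect_equal(cvrow$rate, coefficient_of_variation(mp$months$rate))
})

test_that("degenerate months are marked undefined and excluded from CV", {
  enc <- data.frame(month_index = rep(0:1, each = 50),
                    sepsis = c(rep(0L, 50), rep(c(1L, 0L), 25)))
  sc <- runif(100)
  cal <- data.frame(month = c("a", "b"), days = c(30, 30))
  mp <- monthly_performance(enc, sc, 0.5, rep(0L, 100), cal)
  expect_true(is.na(mp$months$cont_auc[1]))  # single-class month
  expect_false(is.na(mp$months$cont_auc[2]))

  # two identical months -> CV zero for every defined metric
  enc2 <- data.frame(month_index = rep(0:1, each = 50),
                     sepsis = rep(rep(c(1L, 0L), 25), 2))
  sc2 <- rep(runif(50), 2)
  fl2 <- rep(rbinom(50, 1, 0.3), 2)
  mp2 <- monthly_performance(enc2, sc2, 0.5, fl2, cal)
  cv2 <- mp2$summary[mp2$summary$stat == "cv", -1]
  expect_true(all(abs(unlist(cv2)) < 1e-12, na.rm = TRUE))
})
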