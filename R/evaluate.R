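#' Concordance AUC of a continuous score
#'
#' Probability that a randomly chosen septic encounter scores higher than a
#' randomly chosen non-septic one, with ties counted one half -- the
#' Mann-Whitney form of the area under the empirical ROC curve, computed
#' from midranks in O(n log n).
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector (1 = septic).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_continuous(c(0.8, 0.3, 0.5, 0.2, 0.3), c(1, 1, 0, 0, 0))  # 0.75
#' @export
auc_continuous <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a single-threshold binary alert
#'
#' A binary alert's ROC curve has one interior vertex, so its area is
#' `(sensitivity + specificity) / 2`. This identity links published
#' operating points (sensitivity, false positive rate) to the AUC column of
#' an alert-performance table.
#'
#' @param sensitivity,fpr Proportions in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @examples
#' binary_auc(0.543, 0.031)  # 0.756, the triage-nurse comparator
#' @export
binary_auc <- function(sensitivity, fpr) {
  if (any(c(sensitivity, fpr) < 0) || any(c(sensitivity, fpr) > 1)) {
    stop("sensitivity and fpr must lie in [0, 1]")
  }
  (sensitivity + (1 - fpr)) / 2
}

#' Operating-point report for a binary alert
#'
#' Dichotomizes scores at a threshold (the alert fires when score >=
#' threshold), tabulates the confusion matrix, and derives the full set of
#' alert metrics: sensitivity, specificity, false positive rate, predictive
#' values, binary AUC, and the alert-burden metric false positives per day.
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector (1 = septic).
#' @param threshold Alert cutoff; ties alert.
#' @param days Calendar days spanned by the cohort (for FP/day).
#' @param screen_flags Optional concurrent binary screen; when given, the
#'   incremental true-positive counts of model vs screen are included.
#' @return An object of class `alert_report` (also a list): `threshold`,
#'   counts `tp`, `fp`, `tn`, `fn`, proportions `sensitivity`,
#'   `specificity`, `fpr`, `ppv`, `npv`, `binary_auc`, and `fp_per_day`;
#'   plus `incremental` when `screen_flags` is supplied.
#' @export
confusion_report <- function(scores, labels, threshold, days,
                             screen_flags = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (days <= 0) stop("days must be positive")
  alert <- as.integer(scores >= threshold)
  tp <- sum(alert == 1L & labels == 1L)
  fp <- sum(alert == 1L & labels == 0L)
  tn <- sum(alert == 0L & labels == 0L)
  fn <- sum(alert == 0L & labels == 1L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  rep <- list(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec, fpr = 1 - spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    binary_auc = (sens + spec) / 2,
    fp_per_day = fp / days, days = days
  )
  if (!is.null(screen_flags)) {
    rep$incremental <- incremental_tp(alert, screen_flags, labels)
  }
  structure(rep, class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf(
    paste0("Alert at threshold %.3f: sens %.1f%%, fpr %.1f%%, AUC %.3f, ",
           "PPV %.1f%%, NPV %.1f%%, %.2f FP/day\n"),
    x$threshold, 100 * x$sensitivity, 100 * x$fpr, x$binary_auc,
    100 * x$ppv, 100 * x$npv, x$fp_per_day))
  if (!is.null(x$incremental)) {
    cat(sprintf("  incremental TP: model %d, screen %d, both %d\n",
                x$incremental$model_only, x$incremental$screen_only,
                x$incremental$both))
  }
  invisible(x)
}

#' False-positive alerts per day from a rate
#'
#' @param fpr False positive rate (proportion of non-septic encounters that
#'   alert).
#' @param n_negative Number of non-septic encounters.
#' @param days Calendar days.
#' @return Expected false-positive alerts per day.
#' @examples
#' fp_per_day_from_rate(0.047, 93421, 456)  # about 9.6 alerts/day
#' @export
fp_per_day_from_rate <- function(fpr, n_negative, days) {
  if (days <= 0) stop("days must be positive")
  if (fpr < 0 || n_negative < 0) stop("inputs must be non-negative")
  fpr * n_negative / days
}

threshold_candidates <- function(scores) c(sort(unique(scores)), Inf)

# vectorized #{x >= t} for each t, via binary search on the sorted vector;
# exact under the tie convention because no float arithmetic touches t
count_ge <- function(sorted_x, t) {
  length(sorted_x) - findInterval(t, sorted_x, left.open = TRUE)
}

#' Threshold searches over observed score cutpoints
#'
#' All searches enumerate the candidate cutpoints -- the unique observed
#' scores plus infinity -- with the alert firing at score >= threshold; no
#' interpolation between observed scores is performed.
#'
#' `threshold_for_sensitivity` returns the largest cutpoint whose
#' sensitivity still meets the target (the fewest alerts compatible with the
#' sensitivity goal). `threshold_for_fp_budget` returns the smallest
#' cutpoint whose false-positive burden stays within the stated alerts/day
#' budget (the most sensitive alert the budget allows).
#' `threshold_max_binary_auc` returns the cutpoint maximizing
#' (sensitivity + specificity) / 2, ties broken toward the higher threshold
#' (fewer alerts).
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector (1 = septic).
#' @param target Sensitivity target in `(0, 1]`.
#' @param max_fp_per_day Alerts/day budget (> 0, or 0 for a zero-FP alert).
#' @param days Calendar days.
#' @return A threshold on the score scale (possibly `Inf`).
#' @export
threshold_for_sensitivity <- function(scores, labels, target) {
  labels <- as.integer(labels)
  if (target <= 0 || target > 1) stop("target must lie in (0, 1]")
  pos <- sort(scores[labels == 1L])
  if (length(pos) == 0L) stop("no septic encounters")
  cand <- threshold_candidates(scores)
  sens <- count_ge(pos, cand) / length(pos)
  ok <- cand[sens >= target]
  if (length(ok) == 0L) stop("sensitivity target unreachable")
  max(ok)
}

#' @rdname threshold_for_sensitivity
#' @export
threshold_for_fp_budget <- function(scores, labels, max_fp_per_day, days) {
  labels <- as.integer(labels)
  if (days <= 0) stop("days must be positive")
  if (max_fp_per_day < 0) stop("budget must be non-negative")
  neg <- sort(scores[labels == 0L])
  cand <- threshold_candidates(scores)
  fp_day <- count_ge(neg, cand) / days
  min(cand[fp_day <= max_fp_per_day])
}

#' @rdname threshold_for_sensitivity
#' @export
threshold_max_binary_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- sort(scores[labels == 1L]); neg <- sort(scores[labels == 0L])
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present")
  }
  cand <- threshold_candidates(scores)
  bauc <- (count_ge(pos, cand) / length(pos) +
             1 - count_ge(neg, cand) / length(neg)) / 2
  max(cand[bauc >= max(bauc) - 1e-12])
}

#' Incremental true positives of two concurrent alert systems
#'
#' Among septic encounters only, counts those detected by the model alert
#' alone, by the concurrent screen alone, and by both -- the accounting used
#' to ask whether an automated alert and a human triage screen find the same
#' patients.
#'
#' @param model_alerts,screen_flags Binary alert vectors.
#' @param labels Binary outcome vector (1 = septic).
#' @return List with counts `model_only`, `screen_only`, `both`.
#' @export
incremental_tp <- function(model_alerts, screen_flags, labels) {
  if (length(model_alerts) != length(screen_flags) ||
      length(model_alerts) != length(labels)) {
    stop("input vectors must have equal length")
  }
  sep <- as.integer(labels) == 1L
  m <- as.integer(model_alerts)[sep] == 1L
  s <- as.integer(screen_flags)[sep] == 1L
  list(model_only = sum(m & !s), screen_only = sum(!m & s), both = sum(m & s))
}

#' SIRS component count and k-of-4 screening rule
#'
#' Counts satisfied Systemic Inflammatory Response Syndrome components among
#' the *observed* values of each encounter: temperature > 38 or < 36 C,
#' heart rate > 90/min, respiratory rate > 20/min, WBC > 12 or < 4 (10^3/uL).
#' A missing component counts as unsatisfied. `sirs_rule` alerts when at
#' least `k` components are met; the published "SIRS-derived" comparator's
#' exact conjuncts were not specified, so `k` is configurable and no default
#' is claimed to reproduce its printed operating point.
#'
#' @param data Encounter data frame with columns `temp_c`, `hr`, `rr`,
#'   `wbc_k` (missing as `NA`).
#' @param k Number of components required to alert, 1 to 4.
#' @param params Named list of cutoffs: `temp_high`, `temp_low`, `hr`, `rr`,
#'   `wbc_high`, `wbc_low`.
#' @return `sirs_criteria` returns an integer count per row; `sirs_rule` a
#'   binary alert vector.
#' @export
sirs_criteria <- function(data,
                          params = list(temp_high = 38, temp_low = 36,
                                        hr = 90, rr = 20,
                                        wbc_high = 12, wbc_low = 4)) {
  met <- function(x) !is.na(x) & x
  met(data$temp_c > params$temp_high | data$temp_c < params$temp_low) +
    met(data$hr > params$hr) +
    met(data$rr > params$rr) +
    met(data$wbc_k > params$wbc_high | data$wbc_k < params$wbc_low)
}

#' @rdname sirs_criteria
#' @export
sirs_rule <- function(data, k = 2L,
                      params = list(temp_high = 38, temp_low = 36,
                                    hr = 90, rr = 20,
                                    wbc_high = 12, wbc_low = 4)) {
  if (k < 1L || k > 4L) stop("k must be between 1 and 4")
  as.integer(sirs_criteria(data, params) >= k)
}

#' Sweep alert thresholds into a performance table
#'
#' Convenience wrapper producing one [confusion_report()] row per threshold,
#' in the layout of a published alert-performance table.
#'
#' @param scores,labels,days As in [confusion_report()].
#' @param thresholds Numeric vector of cutoffs.
#' @param labels_for Optional row labels.
#' @param screen_flags Optional concurrent screen for incremental TP columns.
#' @return A data frame with one row per threshold.
#' @export
threshold_sweep <- function(scores, labels, thresholds, days,
                            screen_flags = NULL, labels_for = NULL) {
  rows <- lapply(thresholds, function(t) {
    r <- confusion_report(scores, labels, t, days, screen_flags)
    out <- data.frame(
      cutoff = t, sens_pct = 100 * r$sensitivity, fpr_pct = 100 * r$fpr,
      auc = r$binary_auc, spec_pct = 100 * r$specificity,
      ppv_pct = 100 * r$ppv, npv_pct = 100 * r$npv,
      fp_per_day = r$fp_per_day
    )
    if (!is.null(screen_flags)) {
      out$inc_tp_screen <- r$incremental$screen_only
      out$inc_tp_model <- r$incremental$model_only
    }
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels_for)) rownames(out) <- labels_for
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' stability metric used to compare month-to-month variability of screening
#' performance measures.
#'
#' @param values Numeric vector, at least 2 values, non-zero mean.
#' @return The CV as a fraction of the mean.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(values) / m
}

#' Monthly performance and stability summary
#'
#' Splits a scored cohort by calendar month and reports, per month, the
#' encounter volume, sepsis rate, continuous AUC of the score, the binary
#' alert's sensitivity / false positive rate / FP-per-day / AUC at the given
#' threshold, and the same operating metrics for a concurrent screen; then
#' summarizes each metric across months with min, max, and coefficient of
#' variation. A month containing a single outcome class gets `NA` for its
#' AUC and sensitivity and is excluded from those metrics' CV.
#'
#' @param encounters Encounter data frame with a `month_index` column
#'   (0-based) and a `sepsis` column.
#' @param scores Model scores, one per encounter.
#' @param threshold Alert cutoff.
#' @param screen_flags Binary concurrent-screen vector (e.g.
#'   `encounters$nurse_flag`).
#' @param calendar Data frame with one row per month index in order,
#'   containing at least `days` (and optionally `month` labels).
#' @return An object of class `monthly_performance`: `months` (per-month
#'   data frame) and `summary` (min/max/cv rows).
#' @export
monthly_performance <- function(encounters, scores, threshold, screen_flags,
                                calendar) {
  stopifnot(nrow(encounters) == length(scores),
            length(screen_flags) == length(scores),
            "days" %in% names(calendar))
  idx <- encounters$month_index
  if (any(idx < 0L) || any(idx >= nrow(calendar))) {
    stop("encounter month_index outside the calendar")
  }
  labels <- as.integer(encounters$sepsis)
  alert <- as.integer(scores >= threshold)

  one_month <- function(i) {
    in_m <- idx == (i - 1L)
    lab <- labels[in_m]; sc <- scores[in_m]
    al <- alert[in_m]; fl <- as.integer(screen_flags)[in_m]
    days <- calendar$days[i]
    n <- sum(in_m); n1 <- sum(lab == 1L); n0 <- n - n1
    both <- n1 > 0L && n0 > 0L
    sens <- function(a) if (n1 > 0L) sum(a == 1L & lab == 1L) / n1 else NA_real_
    fpr <- function(a) if (n0 > 0L) sum(a == 1L & lab == 0L) / n0 else NA_real_
    data.frame(
      month = if (!is.null(calendar$month)) calendar$month[i] else as.character(i),
      encounters = n, per_day = n / days, sepsis = n1, rate = n1 / n,
      cont_auc = if (both) auc_continuous(sc, lab) else NA_real_,
      model_sens = sens(al), model_fpr = fpr(al),
      model_fp_day = sum(al == 1L & lab == 0L) / days,
      model_auc = if (both) binary_auc(sens(al), fpr(al)) else NA_real_,
      screen_sens = sens(fl), screen_fpr = fpr(fl),
      screen_fp_day = sum(fl == 1L & lab == 0L) / days,
      screen_auc = if (both) binary_auc(sens(fl), fpr(fl)) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  months <- do.call(rbind, lapply(seq_len(nrow(calendar)), one_month))

  metrics <- setdiff(names(months), c("month", "encounters", "per_day", "sepsis"))
  summarise <- function(fun) {
    vapply(metrics, function(m) {
      v <- months[[m]][!is.na(months[[m]])]
      if (length(v) == 0L) NA_real_ else fun(v)
    }, numeric(1))
  }
  cv_row <- vapply(metrics, function(m) {
    v <- months[[m]][!is.na(months[[m]])]
    if (length(v) < 2L || mean(v) == 0) NA_real_ else coefficient_of_variation(v)
  }, numeric(1))
  summary <- rbind(
    data.frame(stat = "min", t(summarise(min))),
    data.frame(stat = "max", t(summarise(max))),
    data.frame(stat = "cv", t(cv_row))
  )
  structure(list(months = months, summary = summary),
            class = "monthly_performance")
}

#' @export
print.monthly_performance <- function(x, ...) {
  cat("Monthly alert performance\n")
  print(x$months, row.names = FALSE, digits = 3)
  cat("Summary (min / max / CV):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
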