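#' Load the packaged printed-table fixtures
#'
#' Machine-readable transcription of the published study summaries shipped
#' with the package: the per-feature, per-class point estimates, quartiles
#' and availability (`table1`); the alert operating-point rows (`table2`);
#' the 15 monthly performance rows with their min/max/CV summary
#' (`table3`); and the headline constants (93,773 encounters, 352 septic,
#' 456 study days, ~208 encounters/day).
#'
#' @param path Optional path to an alternative fixture file.
#' @return A list with elements `constants`, `table1`, `table2`, `table3`,
#'   `notes`, `version`, of class `printed_tables`.
#' @export
printed_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_tables.json",
                        package = "sepsisalert", mustWork = TRUE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$constants <- lapply(obj$constants, as.numeric)
  structure(obj, class = "printed_tables")
}

#' Arithmetic consistency audit of the printed tables
#'
#' Recomputes, from the fixture values alone, every quantity that the
#' printed tables determine arithmetically, and compares each with the
#' printed number: the binary-AUC identity (sens + spec)/2 for every alert
#' row; pooled prevalence and encounter totals from the monthly counts; the
#' false-positive-rate target implied by a 15-alerts/day budget; FP/day
#' reconstructions from printed rates; the coefficients of variation of the
#' monthly sepsis rate, continuous AUC, and alert sensitivity; and the
#' overall alert sensitivity reconstructed from monthly true-positive
#' counts.
#'
#' @param tables Fixtures from [printed_tables()].
#' @return A data frame with columns `check`, `computed`, `printed`,
#'   `tolerance`, `pass`.
#' @export
consistency_audit <- function(tables = printed_tables()) {
  ct <- tables$constants
  rows <- list()
  add <- function(check, computed, printed, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, computed = computed, printed = printed,
      tolerance = tolerance, pass = abs(computed - printed) <= tolerance,
      stringsAsFactors = FALSE)
  }

  for (r in tables$table2) {
    add(paste0("binary_auc_", r$label),
        binary_auc(r$sens_pct / 100, r$fpr_pct / 100), r$auc, 0.001)
  }

  m <- tables$table3$months
  encs <- vapply(m, function(x) x$encounters, numeric(1))
  seps <- vapply(m, function(x) x$sepsis, numeric(1))
  add("total_encounters", sum(encs), ct$total_encounters, 0)
  add("total_sepsis", sum(seps), ct$septic_encounters, 0)
  add("encounter_split", ct$nonseptic_encounters + ct$septic_encounters,
      ct$total_encounters, 0)
  add("pooled_prevalence_pct", 100 * sum(seps) / sum(encs), 0.38, 0.005)
  add("target_fpr_pct",
      100 * ct$fp_per_day_budget / ct$encounters_per_day, 7.2, 0.05)

  cut05 <- tables$table2[[which(vapply(tables$table2, function(r) r$label,
                                       character(1)) == "Cut05")]]
  fpc15 <- tables$table2[[which(vapply(tables$table2, function(r) r$label,
                                       character(1)) == "FPC15")]]
  # printed rates carry 1 decimal in percent: +/-0.05 pp propagates to
  # roughly +/-0.10 alerts/day
  add("fp_per_day_Cut05",
      fp_per_day_from_rate(cut05$fpr_pct / 100, ct$nonseptic_encounters,
                           ct$study_days), cut05$fp_per_day, 0.15)
  add("fp_per_day_FPC15",
      fp_per_day_from_rate(fpc15$fpr_pct / 100, ct$nonseptic_encounters,
                           ct$study_days), fpc15$fp_per_day, 0.15)

  rate <- seps / encs
  cont_auc <- vapply(m, function(x) x$cont_auc, numeric(1))
  sens <- vapply(m, function(x) x$model_sens_pct, numeric(1))
  add("monthly_rate_cv_pct", 100 * coefficient_of_variation(rate),
      tables$table3$summary$cv$rate_pct_cv_pct, 0.005)
  add("monthly_cont_auc_cv", coefficient_of_variation(cont_auc),
      tables$table3$summary$cv$cont_auc_cv, 0.0005)
  add("monthly_model_sens_cv_pct", 100 * coefficient_of_variation(sens),
      tables$table3$summary$cv$model_sens_cv_pct, 0.05)

  tp <- round(sens / 100 * seps)
  add("overall_sensitivity_pct", 100 * sum(tp) / sum(seps),
      cut05$sens_pct, 0.05)

  do.call(rbind, rows)
}
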