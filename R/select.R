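#' Selection configuration for forward stepwise search
#'
#' @param candidates Character vector of candidate feature columns.
#' @param n_bootstrap Bootstrap replicates per out-of-bag AUC estimate.
#' @param improvement_tol Minimum gain in mean out-of-bag AUC required to
#'   accept another feature.
#' @param preference_order Optional ranked character vector; when the top
#'   candidates at a step are statistically equivalent (within
#'   `equivalence_band` of the best), the one ranked highest here wins --
#'   the mechanism by which clinician preference for more easily attained
#'   parameters enters the search.
#' @param equivalence_band AUC width within which candidates are treated as
#'   equivalent for preference tie-breaking.
#' @param stratified Stratify the bootstrap by class (recommended: the
#'   outcome is rare, so unstratified in-bag samples would often lack septic
#'   cases).
#' @param max_features Optional cap on the number of accepted features.
#' @param seed Integer seed governing all bootstrap draws.
#' @param sd_floor Passed through to [nb_fit()].
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(candidates, n_bootstrap = 200L,
                             improvement_tol = 0.002,
                             preference_order = NULL,
                             equivalence_band = 0.005,
                             stratified = TRUE, max_features = NULL,
                             seed = 1L, sd_floor = 1e-6) {
  if (length(candidates) == 0L) stop("candidate list is empty")
  if (n_bootstrap < 2L) stop("n_bootstrap must be at least 2")
  if (improvement_tol < 0 || equivalence_band < 0) {
    stop("tolerances must be non-negative")
  }
  if (!is.null(preference_order) &&
      !all(preference_order %in% candidates)) {
    stop("preference_order must be a subset of candidates")
  }
  structure(
    list(candidates = candidates, n_bootstrap = as.integer(n_bootstrap),
         improvement_tol = improvement_tol,
         preference_order = preference_order,
         equivalence_band = equivalence_band,
         stratified = isTRUE(stratified), max_features = max_features,
         seed = as.integer(seed), sd_floor = sd_floor),
    class = "selection_config"
  )
}

#' Bootstrap out-of-bag AUC of a feature set
#'
#' For each replicate, a bootstrap sample is drawn (within each class when
#' `stratified`), a naive Bayes model is fitted on the in-bag rows, the rows
#' never drawn (the out-of-bag set) are scored, and the concordance AUC of
#' those scores is computed. Replicates whose out-of-bag set lacks one of
#' the classes -- or whose in-bag sample leaves a low-availability feature
#' with fewer than two observed values in a class -- are redrawn, up to a
#' bounded number of retries.
#'
#' @param data Encounter data frame.
#' @param labels Binary outcome vector.
#' @param features Feature set to evaluate.
#' @param n_bootstrap Number of replicates.
#' @param stratified Stratify resampling by class.
#' @param seed Integer seed.
#' @param sd_floor Passed to [nb_fit()].
#' @param max_retries Redraw budget per replicate.
#' @return List with `mean_auc` and the numeric vector `replicate_auc`.
#' @export
oob_auc <- function(data, labels, features, n_bootstrap = 200L,
                    stratified = TRUE, seed = 1L, sd_floor = 1e-6,
                    max_retries = 10L) {
  labels <- as.integer(labels)
  n <- nrow(data)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  idx0 <- which(labels == 0L); idx1 <- which(labels == 1L)
  draw_bag <- function() {
    if (stratified) {
      c(sample(idx0, length(idx0), replace = TRUE),
        sample(idx1, length(idx1), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
  }
  aucs <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    ok <- FALSE
    for (try in seq_len(max_retries + 1L)) {
      bag <- draw_bag()
      oob <- setdiff(seq_len(n), bag)
      if (length(unique(labels[oob])) < 2L) next
      fit <- tryCatch(
        nb_fit(data[bag, , drop = FALSE], labels[bag], features,
               sd_floor = sd_floor),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      aucs[b] <- auc_continuous(nb_score(fit, data[oob, , drop = FALSE]),
                                labels[oob])
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not form a valid bootstrap replicate after ",
           max_retries + 1L, " attempts")
    }
  }
  list(mean_auc = mean(aucs), replicate_auc = aucs)
}

#' Forward stepwise feature selection by out-of-bag AUC
#'
#' Starting from the empty model (baseline AUC 0.5), every remaining
#' candidate is evaluated by [oob_auc()] when added to the current set; all
#' candidates at a step share the same bootstrap replicates so comparisons
#' are paired. The best candidate is accepted if its gain over the current
#' mean out-of-bag AUC is at least `improvement_tol`; when several
#' candidates lie within `equivalence_band` of the best, the one ranked
#' highest in `preference_order` is taken instead. The search stops when no
#' candidate clears the tolerance, the feature cap is reached, or the
#' candidates are exhausted. Deterministic given the configuration seed.
#'
#' @param data Encounter data frame.
#' @param labels Binary outcome vector.
#' @param config A [selection_config()].
#' @return An object of class `selection_trace`: `steps` (one entry per
#'   accepted feature, with the per-candidate mean out-of-bag AUCs
#'   considered), `final_features`, `final_auc`, and `stopped_reason`
#'   (`"tolerance"`, `"max_features"`, or `"exhausted"`).
#' @export
forward_select <- function(data, labels, config) {
  stopifnot(inherits(config, "selection_config"))
  remaining <- config$candidates
  current <- character(0)
  current_auc <- 0.5
  steps <- list()
  reason <- "exhausted"
  step_no <- 0L

  while (length(remaining) > 0L) {
    if (!is.null(config$max_features) &&
        length(current) >= config$max_features) {
      reason <- "max_features"
      break
    }
    step_no <- step_no + 1L
    step_seed <- (config$seed + 7919L * step_no) %% .Machine$integer.max
    cand_auc <- vapply(remaining, function(f) {
      oob_auc(data, labels, c(current, f),
              n_bootstrap = config$n_bootstrap,
              stratified = config$stratified,
              seed = step_seed, sd_floor = config$sd_floor)$mean_auc
    }, numeric(1))
    best_auc <- max(cand_auc)
    pick <- names(cand_auc)[which.max(cand_auc)]
    if (!is.null(config$preference_order)) {
      equiv <- names(cand_auc)[cand_auc >= best_auc - config$equivalence_band]
      pref <- intersect(config$preference_order, equiv)
      if (length(pref)) pick <- pref[1L]
    }
    if (cand_auc[[pick]] - current_auc < config$improvement_tol) {
      reason <- "tolerance"
      break
    }
    current <- c(current, pick)
    current_auc <- cand_auc[[pick]]
    remaining <- setdiff(remaining, pick)
    steps[[length(steps) + 1L]] <- list(
      feature = pick, mean_oob_auc = current_auc,
      candidate_auc = cand_auc
    )
  }
  if (length(remaining) == 0L && reason == "exhausted") reason <- "exhausted"
  structure(
    list(steps = steps, final_features = current, final_auc = current_auc,
         stopped_reason = reason, seed = config$seed),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward stepwise selection trace\n")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: + %-12s mean OOB AUC %.4f\n",
                i, s$feature, s$mean_oob_auc))
  }
  cat(sprintf("  stopped: %s; final set: %s\n", x$stopped_reason,
              if (length(x$final_features))
                paste(x$final_features, collapse = ", ") else "(empty)"))
  invisible(x)
}

#' Serialize a selection trace to JSON
#'
#' @param trace A `selection_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
trace_write <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  obj <- list(
    steps = lapply(trace$steps, function(s) {
      list(feature = s$feature, mean_oob_auc = s$mean_oob_auc,
           candidate_auc = as.list(s$candidate_auc))
    }),
    final_features = trace$final_features,
    final_auc = trace$final_auc,
    stopped_reason = trace$stopped_reason,
    seed = trace$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
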