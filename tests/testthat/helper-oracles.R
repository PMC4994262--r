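# Independent oracles used to cross-check the package's own implementations.
# These are deliberately naive: trapezoidal ROC integration, a direct
# (non-log) two-class Bayes product, and exhaustive cutpoint searches.

oracle_trapezoid_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(ths, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

oracle_posterior <- function(model, row) {
  f <- model$features
  l1 <- model$prior
  l0 <- 1 - model$prior
  for (i in seq_len(nrow(f))) {
    x <- row[[f$name[i]]]
    if (is.null(x) || is.na(x)) next
    l1 <- l1 * stats::dnorm(x, f$mean_septic[i], f$sd_septic[i])
    l0 <- l0 * stats::dnorm(x, f$mean_nonseptic[i], f$sd_nonseptic[i])
  }
  l1 / (l1 + l0)
}

oracle_cutpoints <- function(scores) c(sort(unique(scores)), Inf)

oracle_threshold_for_sensitivity <- function(scores, labels, target) {
  pos <- scores[labels == 1]
  cand <- oracle_cutpoints(scores)
  best <- -Inf
  for (t in cand) if (mean(pos >= t) >= target && t > best) best <- t
  best
}

oracle_threshold_for_fp_budget <- function(scores, labels, budget, days) {
  neg <- scores[labels == 0]
  cand <- oracle_cutpoints(scores)
  best <- Inf
  for (t in cand) if (sum(neg >= t) / days <= budget && t < best) best <- t
  best
}

oracle_threshold_max_binary_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cand <- oracle_cutpoints(scores)
  bauc <- vapply(cand, function(t) (mean(pos >= t) + mean(neg < t)) / 2,
                 numeric(1))
  max(cand[bauc >= max(bauc) - 1e-12])
}

# hand-built one/two-feature models for posterior arithmetic
toy_model <- function(prior = 0.5,
                      features = data.frame(
                        name = "x", mean_nonseptic = 0, sd_nonseptic = 1,
                        mean_septic = 2, sd_septic = 1,
                        stringsAsFactors = FALSE)) {
  structure(list(prior = prior, sd_floor = 1e-6, features = features),
            class = "sepsis_nb")
}

# balanced binormal toy cohort: one informative feature (separation d) plus
# pure-noise columns
binormal_cohort <- function(n = 2000, d = 2, n_noise = 2, seed = 1) {
  withr::local_seed(seed)
  labels <- rep(c(0L, 1L), each = n / 2)
  df <- data.frame(signal = stats::rnorm(n, mean = d * labels))
  for (i in seq_len(n_noise)) {
    df[[paste0("noise", i)]] <- stats::rnorm(n)
  }
  list(data = df, labels = labels)
}

random_score_instance <- function(n, seed) {
  withr::local_seed(seed)
  n1 <- sample(1:(n - 1), 1)
  labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  # coarse grid forces ties so the ties-count-half convention is exercised
  scores <- round(stats::runif(n), 2)
  list(scores = scores, labels = labels)
}
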