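#' Fit a Gaussian naive Bayes sepsis model
#'
#' Estimates, for each requested feature, the class-conditional mean and
#' standard deviation among septic and non-septic encounters, using only the
#' non-missing values of that feature within each class. The class prior is
#' the training prevalence unless overridden. This is the model form used
#' for first-hour ED sepsis screening: no coefficients, just per-feature
#' class-conditional Gaussians whose separation drives the posterior.
#'
#' @param data Data frame of encounters; missing values as `NA`.
#' @param labels Binary outcome vector (1 = septic), same length as
#'   `nrow(data)`.
#' @param features Character vector of column names to model.
#' @param sd_floor Lower bound applied to every fitted SD, preventing
#'   degenerate densities from (near-)constant columns.
#' @param prior Optional explicit prior probability of sepsis; defaults to
#'   the training prevalence.
#' @return An object of class `sepsis_nb`: a list with `prior`, `sd_floor`,
#'   and a `features` data frame holding per-feature class-conditional
#'   `mean_nonseptic`, `sd_nonseptic`, `mean_septic`, `sd_septic` and the
#'   per-class observation counts.
#' @examples
#' d <- data.frame(x = c(100, 120, 80, 90))
#' m <- nb_fit(d, c(1, 1, 0, 0), "x")
#' m$features
#' @export
nb_fit <- function(data, labels, features, sd_floor = 1e-6, prior = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(data), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit the model (class absent)")
  }
  if (length(features) == 0L) stop("at least one feature is required")
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (sd_floor <= 0) stop("sd_floor must be positive")

  sep <- labels == 1L
  stats_for <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NULL)
    c(mean = mean(x), sd = max(stats::sd(x), sd_floor), n = length(x))
  }
  rows <- lapply(features, function(f) {
    x <- data[[f]]
    s0 <- stats_for(x[!sep]); s1 <- stats_for(x[sep])
    if (is.null(s0) || is.null(s1)) {
      stop("feature '", f, "' has fewer than 2 observed values in a class")
    }
    data.frame(name = f,
               mean_nonseptic = s0[["mean"]], sd_nonseptic = s0[["sd"]],
               mean_septic = s1[["mean"]], sd_septic = s1[["sd"]],
               n_nonseptic = s0[["n"]], n_septic = s1[["n"]],
               stringsAsFactors = FALSE)
  })
  structure(
    list(prior = if (is.null(prior)) mean(labels) else prior,
         sd_floor = sd_floor,
         features = do.call(rbind, rows)),
    class = "sepsis_nb"
  )
}

#' @export
print.sepsis_nb <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes sepsis model (prior %.4g, %d features)\n",
              x$prior, nrow(x$features)))
  print(x$features[, c("name", "mean_nonseptic", "sd_nonseptic",
                       "mean_septic", "sd_septic")], row.names = FALSE)
  invisible(x)
}

#' Posterior probability of sepsis for encounters
#'
#' Computes P(sepsis | observed features) under the fitted model. The
#' likelihood for each class is the product of Gaussian densities of the
#' *observed* features only; a missing feature contributes nothing to either
#' class, so informatively missing labs are handled natively, without
#' imputation. All arithmetic is in log space: the log prior odds plus the
#' sum of per-feature log density ratios, mapped back through the logistic
#' function. An encounter with every feature missing scores exactly the
#' prior.
#'
#' @param model A fitted [nb_fit()] model.
#' @param data A data frame of encounters (any subset of model features may
#'   be missing; for `nb_posterior` a single row or named list).
#' @return `nb_score` returns a numeric vector of posteriors, one per row,
#'   in row order; `nb_posterior` a single probability.
#' @export
nb_score <- function(model, data) {
  stopifnot(inherits(model, "sepsis_nb"))
  if (is.null(dim(data))) data <- as.data.frame(data)
  if (nrow(data) == 0L) return(numeric(0))
  missing_cols <- setdiff(model$features$name, names(data))
  if (length(missing_cols)) {
    stop("data lacks model feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  f <- model$features
  logodds <- rep(stats::qlogis(model$prior), nrow(data))
  for (i in seq_len(nrow(f))) {
    x <- data[[f$name[i]]]
    d <- stats::dnorm(x, f$mean_septic[i], f$sd_septic[i], log = TRUE) -
      stats::dnorm(x, f$mean_nonseptic[i], f$sd_nonseptic[i], log = TRUE)
    d[is.na(d)] <- 0
    logodds <- logodds + d
  }
  stats::plogis(logodds)
}

#' @rdname nb_score
#' @export
nb_posterior <- function(model, data) {
  if (is.null(dim(data))) data <- as.data.frame(data)
  stopifnot(nrow(data) == 1L)
  nb_score(model, data)[[1L]]
}

#' Serialize and restore a fitted model
#'
#' JSON round trip of the model parameters (prior, SD floor, per-feature
#' class-conditional means and SDs). Numbers are written at full precision
#' so the round trip is lossless.
#'
#' @param model A `sepsis_nb` model.
#' @param path File path.
#' @return `nb_read` returns the restored `sepsis_nb`; `nb_write` returns
#'   `path` invisibly.
#' @export
nb_write <- function(model, path) {
  stopifnot(inherits(model, "sepsis_nb"))
  obj <- list(prior = model$prior, sd_floor = model$sd_floor,
              features = model$features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname nb_write
#' @export
nb_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(prior = obj$prior, sd_floor = obj$sd_floor,
         features = as.data.frame(obj$features)),
    class = "sepsis_nb"
  )
}

#' Default modeled feature sets
#'
#' The two published five-feature candidate sets for the deployed alert:
#' `"abstract"` (mean blood pressure, temperature, age, heart rate, WBC) and
#' `"results"` (temperature, heart rate, respiratory rate, WBC, mean
#' arterial pressure). The source report lists both without reconciling
#' them; `"abstract"` is the package default and both are available.
#'
#' @param which `"abstract"` or `"results"`.
#' @return Character vector of feature column names.
#' @export
default_feature_set <- function(which = c("abstract", "results")) {
  which <- match.arg(which)
  switch(which,
    abstract = c("mean_bp", "temp_c", "age_years", "hr", "wbc_k"),
    results = c("temp_c", "hr", "rr", "wbc_k", "mean_bp")
  )
}
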