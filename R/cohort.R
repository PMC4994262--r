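#' Calibrate a two-parameter family to a printed median and quartiles
#'
#' Converts a (median, q25, q75) summary -- the form in which first-hour ED
#' vitals and labs are usually published -- into the location and scale of a
#' parametric family that reproduces those quantiles exactly.
#'
#' For the `"normal"` family the location is the median and the scale is
#' IQR / (2 * qnorm(0.75)) (approximately IQR / 1.349). For `"lognormal"`
#' the same identities are applied on the log scale, so the log-location is
#' `log(median)` and the log-scale is `(log(q75) - log(q25)) / 1.349`.
#'
#' @param median,q25,q75 Printed median and quartiles, `q25 < median < q75`.
#' @param family `"normal"` or `"lognormal"`.
#' @return A list with elements `location` and `scale` (log-scale parameters
#'   for the lognormal family).
#' @examples
#' calibrate_spec(8.5, 6.7, 10.9, "lognormal")
#' calibrate_spec(36.4, 36.0, 36.8, "normal")
#' @export
calibrate_spec <- function(median, q25, q75, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (!(q25 < median && median < q75)) {
    stop("quantiles must satisfy q25 < median < q75")
  }
  z <- 2 * stats::qnorm(0.75)
  if (family == "lognormal") {
    if (q25 <= 0) stop("lognormal calibration requires positive quartiles")
    list(location = log(median), scale = (log(q75) - log(q25)) / z)
  } else {
    list(location = median, scale = (q75 - q25) / z)
  }
}

#' Class-conditional feature specification
#'
#' Describes how one physiological feature is generated in septic and
#' non-septic encounters: a two-parameter family per class, a per-class
#' availability (the probability the value is measured within the first
#' hour), and optional physical clamps.
#'
#' @param name Column name of the feature.
#' @param family `"normal"` or `"lognormal"` (location/scale are on the log
#'   scale for the latter).
#' @param location,scale Length-2 numeric vectors `c(nonseptic, septic)`.
#' @param availability Length-2 probabilities `c(nonseptic, septic)` that the
#'   value is observed.
#' @param lower,upper Optional physical clamps applied to generated values.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, family, location, scale, availability,
                         lower = -Inf, upper = Inf) {
  family <- match.arg(family, c("normal", "lognormal"))
  stopifnot(length(location) == 2, length(scale) == 2, length(availability) == 2)
  if (any(scale <= 0)) stop("scale must be positive in both classes")
  if (any(availability < 0 | availability > 1)) {
    stop("availability must lie in [0, 1]")
  }
  if (lower >= upper) stop("bounds must be ordered")
  structure(
    list(name = name, family = family,
         location = as.numeric(location), scale = as.numeric(scale),
         availability = as.numeric(availability),
         lower = lower, upper = upper),
    class = "feature_spec"
  )
}

#' Theoretical per-class moments of a feature specification
#'
#' Mean and SD of the clamped generating distribution for each class,
#' computed by numerical integration over the latent quantile scale. Used by
#' parameter-recovery checks: a fitted Gaussian summary of generated data
#' should converge to these values, not to the raw location/scale (which for
#' the lognormal family live on the log scale).
#'
#' @param spec A [feature_spec()].
#' @return A list with numeric vectors `mean` and `sd`, each `c(nonseptic,
#'   septic)`.
#' @export
feature_spec_moments <- function(spec) {
  one <- function(cls) {
    # integrate on the latent standard-normal scale; the lognormal branch
    # avoids qlnorm(pnorm(z)) which overflows to Inf once pnorm saturates
    g <- function(z) {
      v <- if (spec$family == "lognormal") {
        exp(spec$location[cls] + spec$scale[cls] * z)
      } else {
        spec$location[cls] + spec$scale[cls] * z
      }
      pmin(pmax(v, spec$lower), spec$upper)
    }
    # +/-12 latent SDs: the omitted tail mass is < 1e-26 for any log-scale
    # arising from printed quartiles, and finite bounds keep exp() in range
    m1 <- stats::integrate(function(z) g(z) * stats::dnorm(z),
                           -12, 12, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(z) g(z)^2 * stats::dnorm(z),
                           -12, 12, rel.tol = 1e-10)$value
    c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
  }
  a <- one(1); b <- one(2)
  list(mean = c(a["mean"], b["mean"]), sd = c(a["sd"], b["sd"]))
}

#' Cohort generating configuration
#'
#' Full parameterization of the two-class generative model behind
#' [simulate_cohort()]: prevalence (or an exact monthly calendar), the
#' class-conditional feature specifications, the class-conditional rates of
#' the two concurrent triage indicators, an optional within-class dependence
#' knob, and the seed.
#'
#' @param features A list of [feature_spec()] objects.
#' @param n_encounters Cohort size (ignored when `months` is supplied).
#' @param prevalence Sepsis prevalence for pooled (Bernoulli) label draws.
#' @param months Optional calendar: a data frame with columns `month`
#'   (label), `encounters`, `sepsis`, and optionally `days`; labels are drawn
#'   with exact per-month counts.
#' @param screen_sensitivity,screen_fpr Class-conditional rates of the triage
#'   screen indicator.
#' @param flag_sensitivity,flag_fpr Class-conditional rates of the triage
#'   nurse identification flag (the comparator screen).
#' @param female_rate Length-2 probabilities `c(nonseptic, septic)`.
#' @param class_correlation Within-class dependence in `[0, 1)` shared across
#'   continuous features via a Gaussian one-factor copula; 0 gives
#'   class-conditional independence.
#' @param seed Integer seed; all draws derive from it in a fixed order.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(features, n_encounters = 10000, prevalence = 0.0038,
                          months = NULL,
                          screen_sensitivity = 0.619, screen_fpr = 0.068,
                          flag_sensitivity = 0.543, flag_fpr = 0.031,
                          female_rate = c(0.582, 0.537),
                          class_correlation = 0, seed = 1L) {
  probs <- c(prevalence, screen_sensitivity, screen_fpr,
             flag_sensitivity, flag_fpr, female_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (class_correlation < 0 || class_correlation >= 1) {
    stop("class_correlation must lie in [0, 1)")
  }
  if (!is.null(months)) {
    months <- as.data.frame(months)
    stopifnot(all(c("month", "encounters", "sepsis") %in% names(months)))
    if (any(months$sepsis > months$encounters)) {
      stop("calendar has a month with more sepsis cases than encounters")
    }
    n_encounters <- sum(months$encounters)
  }
  nm <- vapply(features, function(f) f$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate feature names")
  structure(
    list(features = features, n_encounters = as.integer(n_encounters),
         prevalence = prevalence, months = months,
         screen_sensitivity = screen_sensitivity, screen_fpr = screen_fpr,
         flag_sensitivity = flag_sensitivity, flag_fpr = flag_fpr,
         female_rate = female_rate,
         class_correlation = class_correlation, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Feature specifications calibrated to the published cohort summaries
#'
#' Builds the default list of [feature_spec()] objects from the packaged
#' printed-table fixtures: right-skewed positive features (age, heart rate,
#' WBC, lactate) use the lognormal family, pressures and temperature the
#' normal family, each calibrated so its median and quartiles match the
#' printed per-class values. Respiratory rate has no printed distribution and
#' ships with documented synthetic defaults (non-septic N(16, 3^2), septic
#' N(24, 6^2)) because the SIRS comparator needs it.
#'
#' @param tables Printed tables as returned by [printed_tables()].
#' @return Named list of `feature_spec` objects.
#' @export
calibrated_features <- function(tables = printed_tables()) {
  fam <- c(age_years = "lognormal", sbp = "normal", dbp = "normal",
           mean_bp = "normal", temp_c = "normal", hr = "lognormal",
           wbc_k = "lognormal", lactate = "lognormal")
  clamps <- list(age_years = c(14, Inf), temp_c = c(30, 43),
                 lactate = c(0, Inf))
  t1 <- tables$table1
  specs <- lapply(names(fam), function(nm) {
    row <- t1[[which(vapply(t1, function(r) r$name, character(1)) == nm)]]
    ns <- calibrate_spec(row$nonseptic$est, row$nonseptic$q25, row$nonseptic$q75, fam[[nm]])
    sp <- calibrate_spec(row$septic$est, row$septic$q25, row$septic$q75, fam[[nm]])
    cl <- clamps[[nm]] %||% c(-Inf, Inf)
    feature_spec(nm, fam[[nm]],
                 location = c(ns$location, sp$location),
                 scale = c(ns$scale, sp$scale),
                 availability = c(row$nonseptic$avail, row$septic$avail),
                 lower = cl[1], upper = cl[2])
  })
  specs <- c(specs, list(
    feature_spec("rr", "normal", location = c(16, 24), scale = c(3, 6),
                 availability = c(0.95, 0.97), lower = 4, upper = 80)
  ))
  names(specs) <- vapply(specs, function(f) f$name, character(1))
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 15-month study calendar
#'
#' Monthly encounter and sepsis counts from the published monthly-performance
#' table, with the number of calendar days in each month (456 days total,
#' April 2009 through June 2010).
#'
#' @param tables Printed tables as returned by [printed_tables()].
#' @return A data frame with columns `month`, `encounters`, `sepsis`, `days`.
#' @export
study_calendar <- function(tables = printed_tables()) {
  m <- tables$table3$months
  df <- data.frame(
    month = vapply(m, function(r) r$month, character(1)),
    encounters = vapply(m, function(r) r$encounters, numeric(1)),
    sepsis = vapply(m, function(r) r$sepsis, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$days <- days_in_month(df$month)
  df
}

days_in_month <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  m <- as.integer(substr(label, 5, 6))
  first <- as.Date(sprintf("%04d-%02d-01", y, m))
  nxt <- as.Date(sprintf("%04d-%02d-01", y + (m == 12L), (m %% 12L) + 1L))
  as.integer(nxt - first)
}

#' Build a calendar configuration from monthly count pairs
#'
#' Turns per-month (encounters, sepsis) counts into the `months` field of a
#' [cohort_config()], reproducing the study's monthly volumes exactly when
#' fed the published counts.
#'
#' @param counts A data frame (or matrix) with columns `encounters` and
#'   `sepsis`, optionally `month` and `days`.
#' @param strict If `TRUE`, require exactly 15 rows (the study's calendar).
#' @return A data frame suitable for `cohort_config(months = )`.
#' @export
replay_calendar <- function(counts, strict = FALSE) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("encounters", "sepsis") %in% names(counts)))
  if (strict && nrow(counts) != 15L) {
    stop("strict calendar replay expects 15 monthly rows")
  }
  if (any(counts$sepsis > counts$encounters)) {
    stop("calendar has a month with more sepsis cases than encounters")
  }
  if (is.null(counts$month)) {
    counts$month <- sprintf("m%02d", seq_len(nrow(counts)))
  }
  if (is.null(counts$days)) {
    counts$days <- rep(30L, nrow(counts))
  }
  counts[, c("month", "encounters", "sepsis", "days")]
}

#' Default study-calibrated cohort configuration
#'
#' The packaged generating model: printed-table feature calibrations,
#' screen/flag rates, prevalence 0.38%, and (by default) the exact 15-month
#' calendar of encounter and sepsis counts.
#'
#' @param seed Integer seed.
#' @param calendar Use the exact monthly calendar (`TRUE`, the default) or a
#'   pooled Bernoulli cohort of `n_encounters`.
#' @param n_encounters Cohort size in pooled mode.
#' @param class_correlation Within-class dependence knob, see [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, calendar = TRUE,
                                  n_encounters = 10000,
                                  class_correlation = 0) {
  tables <- printed_tables()
  cohort_config(
    features = calibrated_features(tables),
    n_encounters = n_encounters,
    prevalence = tables$constants$septic_encounters /
      tables$constants$total_encounters,
    months = if (calendar) study_calendar(tables) else NULL,
    class_correlation = class_correlation,
    seed = seed
  )
}

#' Simulate a synthetic ED cohort
#'
#' Draws one encounter table from the two-class generative model in a
#' `cohort_config`. Labels come first (exact per-month counts in calendar
#' mode, Bernoulli(prevalence) otherwise), then each feature in configuration
#' order: a latent standard-normal draw (optionally sharing a within-class
#' common factor when `class_correlation > 0`) is pushed through the
#' class-conditional quantile function, clamped, and masked missing with
#' probability 1 - availability(class). Mean blood pressure is then
#' recomputed as (SBP + 2 DBP) / 3 wherever both parents are observed, so
#' that it is only drawn from its own marginal when a parent is missing.
#' Finally the screen and nurse-flag indicators and sex are drawn with their
#' class-conditional rates.
#'
#' Deterministic given `config$seed`: the same configuration always yields a
#' byte-identical table.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per encounter and columns
#'   `encounter_id`, `month_index`, `age_years`, `female`, `sbp`, `dbp`,
#'   `mean_bp`, `temp_c`, `hr`, `rr`, `wbc_k`, `lactate`, `screen`,
#'   `nurse_flag`, `sepsis`. Missing values are `NA`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  if (!is.null(config$months)) {
    cal <- config$months
    month_index <- rep(seq_len(nrow(cal)) - 1L, cal$encounters)
    sepsis <- unlist(lapply(seq_len(nrow(cal)), function(i) {
      n <- cal$encounters[i]; s <- cal$sepsis[i]
      sample(c(rep(1L, s), rep(0L, n - s)))
    }))
  } else {
    month_index <- rep(0L, config$n_encounters)
    sepsis <- stats::rbinom(config$n_encounters, 1L, config$prevalence)
  }
  n <- length(sepsis)
  cls <- sepsis + 1L  # 1 = non-septic, 2 = septic

  rho <- config$class_correlation
  common <- if (rho > 0) stats::rnorm(n) else numeric(n)

  vals <- list()
  for (f in config$features) {
    z <- stats::rnorm(n)
    if (rho > 0) z <- sqrt(rho) * common + sqrt(1 - rho) * z
    p <- stats::pnorm(z)
    v <- if (f$family == "lognormal") {
      stats::qlnorm(p, f$location[cls], f$scale[cls])
    } else {
      stats::qnorm(p, f$location[cls], f$scale[cls])
    }
    v <- pmin(pmax(v, f$lower), f$upper)
    miss <- stats::runif(n) >= f$availability[cls]
    v[miss] <- NA_real_
    vals[[f$name]] <- v
  }

  if (all(c("sbp", "dbp", "mean_bp") %in% names(vals))) {
    both <- !is.na(vals$sbp) & !is.na(vals$dbp)
    vals$mean_bp[both] <- (vals$sbp[both] + 2 * vals$dbp[both]) / 3
  }

  female <- stats::rbinom(n, 1L, config$female_rate[cls])
  screen <- stats::rbinom(n, 1L,
    ifelse(sepsis == 1L, config$screen_sensitivity, config$screen_fpr))
  nurse_flag <- stats::rbinom(n, 1L,
    ifelse(sepsis == 1L, config$flag_sensitivity, config$flag_fpr))

  out <- data.frame(
    encounter_id = sprintf("E%07d", seq_len(n)),
    month_index = month_index,
    age_years = vals$age_years %||% NA_real_,
    female = female,
    sbp = vals$sbp %||% NA_real_,
    dbp = vals$dbp %||% NA_real_,
    mean_bp = vals$mean_bp %||% NA_real_,
    temp_c = vals$temp_c %||% NA_real_,
    hr = vals$hr %||% NA_real_,
    rr = vals$rr %||% NA_real_,
    wbc_k = vals$wbc_k %||% NA_real_,
    lactate = vals$lactate %||% NA_real_,
    screen = screen,
    nurse_flag = nurse_flag,
    sepsis = sepsis,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(vals),
                   c("age_years", "sbp", "dbp", "mean_bp", "temp_c", "hr",
                     "rr", "wbc_k", "lactate"))
  for (nm in extra) out[[nm]] <- vals[[nm]]
  out
}

#' Read and write encounter tables
#'
#' CSV round trip for the encounter layout produced by [simulate_cohort()]:
#' missing physiological values are written as empty fields.
#'
#' @param cohort An encounter data frame.
#' @param path File path.
#' @return `read_cohort` returns the encounter data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(encounter_id = "character"))
}
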