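# Synthetic NHANES-like cohort generator. Anthropometrics are multivariate
# lognormal per sex, built from a two-factor (overall body size, central
# adiposity) loading model, which guarantees a positive semi-definite
# covariance and realistic correlations (waist-weight ~ 0.9, waist-hip
# ~ 0.85). These are synthetic design values, not survey estimates.
# Condition prevalence is linear (percent, clipped to [0, 100]) or logistic
# in the z-scores of chosen biomarkers, so every fit has a closed-form or
# simulable ground truth.

synthetic_measurements <- function() {
  c("weight", "height", "waist_circ", "hip_circ", "thigh_circ",
    "max_calf_circ", "bicep_circ", "upper_arm_len", "leg_len",
    "total_fat_mass")
}

default_anthro_model <- function() {
  vars <- synthetic_measurements()
  loadings <- rbind(  # size, adiposity factor loadings on the log scale
    weight         = c(0.120, 0.140),
    height         = c(0.035, 0.000),
    waist_circ     = c(0.060, 0.130),
    hip_circ       = c(0.050, 0.080),
    thigh_circ     = c(0.040, 0.080),
    max_calf_circ  = c(0.040, 0.050),
    bicep_circ     = c(0.050, 0.070),
    upper_arm_len  = c(0.045, 0.000),
    leg_len        = c(0.050, 0.000),
    total_fat_mass = c(0.060, 0.350))
  resid <- c(0.05, 0.015, 0.03, 0.05, 0.04, 0.04, 0.04, 0.02, 0.03, 0.15)
  sigma <- loadings %*% t(loadings) + diag(resid^2)
  dimnames(sigma) <- list(vars, vars)
  means <- list(
    male = log(c(weight = 85, height = 176, waist_circ = 100,
                 hip_circ = 104, thigh_circ = 53, max_calf_circ = 40,
                 bicep_circ = 34, upper_arm_len = 37, leg_len = 41,
                 total_fat_mass = 24)),
    female = log(c(weight = 75, height = 162, waist_circ = 94,
                   hip_circ = 108, thigh_circ = 52, max_calf_circ = 38,
                   bicep_circ = 31, upper_arm_len = 34.5, leg_len = 38,
                   total_fat_mass = 28)))
  list(male = list(mean = means$male, cov = sigma),
       female = list(mean = means$female, cov = sigma))
}

default_prevalence_models <- function() {
  list(
    hypertension = list(intercept = 35,
                        coef = c(waist_circ = 20, weight = -12)),
    arthritis = list(intercept = 25, coef = c(bmi = 8)),
    diabetes = list(intercept = 22, coef = c(waist_circ = 14, weight = -8)),
    high_cholesterol = list(intercept = 30, coef = c(whr = 10)),
    coronary_heart_disease = list(intercept = 8, coef = c(waist_circ = 2)),
    cancer = list(intercept = 10, coef = c(whtr = 1.5)))
}

default_age_weights <- function() {
  ages <- 20:110
  w <- ifelse(ages < 60, 1, pmax(0.005, 1 - (ages - 60) / 40))
  data.frame(age = ages, weight = w)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines a reproducible NHANES-like cohort: per-sex multivariate lognormal
#' anthropometrics, an adult age distribution on 20-110, per-condition
#' prevalence models linear (percent scale, clipped to [0, 100]) or logistic
#' in the z-scores of chosen biomarkers, field-wise missingness, and a
#' smoker flag. Identical config and seed yield bit-identical cohorts.
#'
#' Each prevalence model is a list with \code{intercept} (percent for
#' \code{link = "linear"}, log-odds for \code{"logistic"}), \code{coef}
#' (named vector of slopes per z-scored biomarker; percentage points per SD
#' for linear, log-odds per SD for logistic), optional \code{link}
#' (default \code{"linear"}) and optional \code{age_mult}, a function of age
#' multiplying the slope term — used to emulate age-varying sensitivity.
#' For the linear link the ground-truth NORSE of a modelled biomarker is its
#' coefficient (see \code{\link{ground_truth_norse}}); the default
#' intercepts and slopes keep the clipped probability mass below 1\%.
#'
#' @param n participants per sex.
#' @param seed integer seed.
#' @param anthro per-sex list with \code{mean} (log-scale named vector) and
#'   \code{cov} (log-scale covariance); default the built-in two-factor
#'   model.
#' @param prevalence named list of per-condition models; default six
#'   conditions mirroring the built-in condition set.
#' @param age_weights data frame \code{age}, \code{weight}: sampling weights
#'   over integer ages 20-110.
#' @param missing_rates named vector of per-column missingness probabilities
#'   (applied completely at random); defaults: 0.02 on measurements, 0.01 on
#'   condition and smoker flags. Use \code{missing_rates = 0} for none.
#' @param smoker_rate per-sex smoking probability.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n = 50000, seed = 1,
                             anthro = default_anthro_model(),
                             prevalence = default_prevalence_models(),
                             age_weights = default_age_weights(),
                             missing_rates = NULL,
                             smoker_rate = c(male = 0.4, female = 0.3)) {
  stopifnot(n >= 1, length(seed) == 1)
  for (sx in c("male", "female")) {
    m <- anthro[[sx]]
    if (is.null(m$mean) || is.null(m$cov) ||
        length(m$mean) != nrow(m$cov) || nrow(m$cov) != ncol(m$cov)) {
      stop_norse("anthro model needs conforming mean and cov per sex",
                 "norse_config_error")
    }
    ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop_norse("anthropometric covariance is not positive semi-definite",
                 "norse_config_error")
    }
  }
  if (is.null(missing_rates)) {
    missing_rates <- c(
      stats::setNames(rep(0.02, length(synthetic_measurements()) + 2),
                      c(synthetic_measurements(), "trunk_fat_mass",
                        "lean_mass")),
      stats::setNames(rep(0.01, length(condition_columns()) + 1),
                      c(condition_columns(), "smoker_flag")))
  } else if (length(missing_rates) == 1 && is.null(names(missing_rates))) {
    missing_rates <- stats::setNames(
      rep(missing_rates, length(synthetic_measurements()) +
            length(condition_columns()) + 3),
      c(synthetic_measurements(), "trunk_fat_mass", "lean_mass",
        condition_columns(), "smoker_flag"))
  }
  for (cn in names(prevalence)) {
    prevalence[[cn]]$link <- prevalence[[cn]]$link %||% "linear"
    stopifnot(prevalence[[cn]]$link %in% c("linear", "logistic"))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 anthro = anthro, prevalence = prevalence,
                 age_weights = age_weights, missing_rates = missing_rates,
                 smoker_rate = smoker_rate),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> n = %d per sex, seed = %d, %d conditions\n",
              x$n, x$seed, length(x$prevalence)))
  invisible(x)
}

#' Generate a synthetic participant cohort
#'
#' Draws a cohort from a \code{\link{synthetic_config}}: per-sex lognormal
#' anthropometrics, trunk fat as a logit-normal share of total fat, lean
#' mass as 93\% of fat-free weight, ages from the configured distribution,
#' Bernoulli condition flags from the prevalence models (evaluated on
#' z-scores standardized within sex over the full generated population), a
#' smoker flag, and completely-at-random missingness.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param registry registry used to derive the biomarkers the prevalence
#'   models reference.
#' @return a validated \code{participant_table} data frame with 2 * n rows.
#' @export
#' @examples
#' pop <- generate_population(synthetic_config(n = 500, seed = 42))
#' table(pop$sex)
generate_population <- function(config, registry = biomarker_registry()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  parts <- lapply(c("male", "female"), function(sx) {
    m <- config$anthro[[sx]]
    logs <- MASS::mvrnorm(config$n, mu = m$mean, Sigma = m$cov)
    d <- as.data.frame(exp(logs))
    names(d) <- names(m$mean)
    d$total_fat_mass <- pmin(d$total_fat_mass, 0.6 * d$weight)
    trunk_share <- stats::plogis(stats::rnorm(config$n, 0.1, 0.25))
    d$trunk_fat_mass <- d$total_fat_mass * trunk_share
    d$lean_mass <- 0.93 * (d$weight - d$total_fat_mass)
    d$sex <- sx
    d$age <- sample(config$age_weights$age, config$n, replace = TRUE,
                    prob = config$age_weights$weight)
    d$smoker_flag <- stats::rbinom(config$n, 1, config$smoker_rate[[sx]])
    # condition flags from the prevalence models, on within-sex z-scores
    for (cn in names(config$prevalence)) {
      mod <- config$prevalence[[cn]]
      eta <- rep(0, config$n)
      for (b in names(mod$coef)) {
        zb <- derive_biomarker(d, b, registry, standardize = TRUE)$zscores
        eta <- eta + mod$coef[[b]] * zb
      }
      if (!is.null(mod$age_mult)) eta <- eta * mod$age_mult(d$age)
      p <- if (mod$link == "logistic") {
        stats::plogis(mod$intercept + eta)
      } else {
        pmin(100, pmax(0, mod$intercept + eta)) / 100
      }
      d[[cn]] <- stats::rbinom(config$n, 1, p)
    }
    d
  })
  pop <- rbind(parts[[1]], parts[[2]])
  pop$participant_id <- sprintf("S%06d", seq_len(nrow(pop)))
  # missingness last, completely at random, never on id/sex/age
  for (col in names(config$missing_rates)) {
    r <- config$missing_rates[[col]]
    if (r > 0 && col %in% names(pop)) {
      pop[[col]][stats::runif(nrow(pop)) < r] <- NA
    }
  }
  front <- c("participant_id", "sex", "age")
  pop <- pop[, c(front, setdiff(names(pop), front))]
  participant_table(pop)
}

#' Ground-truth NORSE under a synthetic prevalence model
#'
#' For a linear-link model the prevalence is
#' intercept + coefficient * z(biomarker) (percent), so the true NORSE — the
#' change in prevalence per SD of the biomarker — is the coefficient itself
#' (clipping is ignored; default configurations keep clipped mass below
#' 1\%). With an age-multiplier and an age range, the coefficient is scaled
#' by the mean multiplier over the configured age distribution restricted to
#' that range. For a logistic link the population-averaged derivative is
#' computed by Monte Carlo over a freshly generated cohort:
#' 100 * b * mean(p * (1 - p)). A biomarker absent from the model has
#' ground truth 0.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param biomarker,condition model selector.
#' @param age_range optional age restriction for age-modulated models.
#' @param sex sex whose cohort is simulated for the logistic case.
#' @param nsim Monte Carlo size for the logistic case.
#' @param seed seed for the logistic Monte Carlo (default derived from the
#'   config seed).
#' @return scalar ground-truth NORSE (percentage points per SD).
#' @export
ground_truth_norse <- function(config, biomarker, condition,
                               age_range = NULL, sex = "male",
                               nsim = 100000, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  mod <- config$prevalence[[condition]]
  if (is.null(mod)) {
    stop_norse(sprintf("condition '%s' not in config", condition),
               "norse_config_error")
  }
  if (!biomarker %in% names(mod$coef)) return(0)
  b <- mod$coef[[biomarker]]
  age_scale <- 1
  if (!is.null(mod$age_mult)) {
    aw <- config$age_weights
    if (!is.null(age_range)) {
      aw <- aw[aw$age >= age_range[1] & aw$age <= age_range[2], ]
    }
    age_scale <- sum(aw$weight * mod$age_mult(aw$age)) / sum(aw$weight)
  }
  if (mod$link == "linear") return(b * age_scale)
  # logistic: Monte Carlo population-average derivative
  sim_cfg <- config
  sim_cfg$n <- as.integer(nsim)
  sim_cfg$seed <- as.integer(seed %||% (config$seed + 7919L))
  sim_cfg$missing_rates <- stats::setNames(numeric(0), character(0))
  pop <- generate_population(sim_cfg)
  d <- pop[pop$sex == sex, , drop = FALSE]
  eta <- rep(mod$intercept, nrow(d))
  for (bm in names(mod$coef)) {
    eta <- eta + mod$coef[[bm]] *
      derive_biomarker(d, bm, standardize = TRUE)$zscores
  }
  p <- stats::plogis(eta)
  100 * b * mean(p * (1 - p)) * age_scale
}
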