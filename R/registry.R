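#' Biomarker registry
#'
#' The registry holds the definitions of the 23 built-in body-composition
#' biomarkers plus any user additions. Each definition gives the biomarker's
#' name, its group (\code{regional}, \code{global} or \code{non_composition}),
#' the raw measurement columns it needs, its units, and the formula mapping a
#' participant row to a scalar. All raw measurements are taken in canonical
#' units: lengths and circumferences in cm, masses in kg, age in years.
#'
#' Built-in derived indices (every formula can be overridden with
#' \code{\link{register_biomarker}}):
#' \itemize{
#'   \item \code{bmi} weight / height_m^2 (kg/m^2)
#'   \item \code{whr} waist / hip
#'   \item \code{whtr} waist / height
#'   \item \code{wthr} waist / thigh
#'   \item \code{wethr} weight (kg) / thigh (cm)
#'   \item \code{absi} waist_m / (bmi^(2/3) * height_m^(1/2))
#'   \item \code{rfm} 64 - 20 * height / waist, + 12 for women
#'   \item \code{bai} hip_cm / height_m^1.5 - 18
#'   \item \code{pi} weight / height_m^3 (ponderal index, kg/m^3)
#'   \item \code{pbf} 100 * total_fat_mass / weight (percent body fat)
#'   \item \code{ptf} 100 * trunk_fat_mass / weight (percent trunk fat;
#'     denominator switchable to \code{total_fat_mass})
#'   \item \code{fmi} total_fat_mass / height_m^2
#'   \item \code{ffmi} lean_mass / height_m^2
#'   \item \code{ftl} total_fat_mass / lean_mass
#' }
#' Raw measurements (waist, hip, thigh, calf and bicep circumference, upper
#' arm and leg length, height, weight) pass through unchanged. The derived
#' indices are the standard published formulas for these names; sources vary
#' in minor conventions (e.g. the trunk-fat denominator), hence the override
#' hook.
#'
#' @param ptf_denominator column used as the denominator of percent trunk
#'   fat: body weight (default) or total fat mass.
#' @return an object of class \code{biomarker_registry}: a named list of
#'   \code{biomarker_definition} objects.
#' @export
#' @examples
#' reg <- biomarker_registry()
#' length(reg)            # 23
#' reg$whr$required
biomarker_registry <- function(ptf_denominator = c("weight", "total_fat_mass")) {
  ptf_denominator <- match.arg(ptf_denominator)
  defs <- list(
    # -- regional composition -------------------------------------------
    def_bm("whr", "Waist-to-hip ratio", "regional", c("waist_circ", "hip_circ"),
           "", function(d) d$waist_circ / d$hip_circ),
    def_bm("wthr", "Waist-to-thigh ratio", "regional", c("waist_circ", "thigh_circ"),
           "", function(d) d$waist_circ / d$thigh_circ),
    def_bm("absi", "A Body Shape Index", "regional",
           c("waist_circ", "weight", "height"), "m^{11/6} kg^{-2/3}",
           function(d) {
             bmi <- d$weight / (d$height / 100)^2
             (d$waist_circ / 100) / (bmi^(2 / 3) * (d$height / 100)^(1 / 2))
           }),
    def_bm("rfm", "Relative Fat Mass", "regional",
           c("waist_circ", "height", "sex"), "%",
           function(d) 64 - 20 * d$height / d$waist_circ +
             12 * (d$sex == "female")),
    def_bm("wethr", "Weight-to-thigh ratio", "regional",
           c("weight", "thigh_circ"), "kg/cm",
           function(d) d$weight / d$thigh_circ),
    def_bm("whtr", "Waist-to-height ratio", "regional",
           c("waist_circ", "height"), "",
           function(d) d$waist_circ / d$height),
    def_bm("bai", "Body Adiposity Index", "regional",
           c("hip_circ", "height"), "%",
           function(d) d$hip_circ / (d$height / 100)^1.5 - 18),
    def_bm("ptf", "Percent trunk fat", "regional",
           c("trunk_fat_mass", ptf_denominator), "%",
           function(d) 100 * d$trunk_fat_mass / d[[ptf_denominator]]),
    def_bm("waist_circ", "Waist circumference", "regional", "waist_circ",
           "cm", function(d) d$waist_circ),
    def_bm("hip_circ", "Hip circumference", "regional", "hip_circ",
           "cm", function(d) d$hip_circ),
    # -- global composition ---------------------------------------------
    def_bm("pbf", "Percent body fat", "global",
           c("total_fat_mass", "weight"), "%",
           function(d) 100 * d$total_fat_mass / d$weight),
    def_bm("ftl", "Fat-to-lean ratio", "global",
           c("total_fat_mass", "lean_mass"), "",
           function(d) d$total_fat_mass / d$lean_mass),
    def_bm("fmi", "Fat mass index", "global",
           c("total_fat_mass", "height"), "kg/m^2",
           function(d) d$total_fat_mass / (d$height / 100)^2),
    def_bm("pi", "Ponderal index", "global", c("weight", "height"),
           "kg/m^3", function(d) d$weight / (d$height / 100)^3),
    def_bm("bmi", "Body mass index", "global", c("weight", "height"),
           "kg/m^2", function(d) d$weight / (d$height / 100)^2),
    def_bm("weight", "Body weight", "global", "weight", "kg",
           function(d) d$weight),
    def_bm("ffmi", "Fat-free mass index", "global",
           c("lean_mass", "height"), "kg/m^2",
           function(d) d$lean_mass / (d$height / 100)^2),
    # -- non-composition --------------------------------------------------
    def_bm("upper_arm_len", "Upper arm length", "non_composition",
           "upper_arm_len", "cm", function(d) d$upper_arm_len),
    def_bm("bicep_circ", "Bicep circumference", "non_composition",
           "bicep_circ", "cm", function(d) d$bicep_circ),
    def_bm("max_calf_circ", "Maximal calf circumference", "non_composition",
           "max_calf_circ", "cm", function(d) d$max_calf_circ),
    def_bm("thigh_circ", "Thigh circumference", "non_composition",
           "thigh_circ", "cm", function(d) d$thigh_circ),
    def_bm("height", "Standing height", "non_composition", "height",
           "cm", function(d) d$height),
    def_bm("leg_len", "Upper leg length", "non_composition", "leg_len",
           "cm", function(d) d$leg_len)
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  structure(defs, class = "biomarker_registry")
}

def_bm <- function(name, label, group, required, units, formula) {
  stopifnot(group %in% c("regional", "global", "non_composition"))
  structure(
    list(name = name, label = label, group = group,
         required = required, units = units, formula = formula),
    class = "biomarker_definition")
}

#' Add or override a biomarker definition
#'
#' @param registry a \code{\link{biomarker_registry}}.
#' @param name biomarker name (replaces an existing entry of the same name).
#' @param group one of \code{"regional"}, \code{"global"},
#'   \code{"non_composition"}.
#' @param required character vector of participant-table columns the formula
#'   reads.
#' @param formula function of a data frame returning one scalar per row.
#' @param units unit string (empty for unit-less ratios).
#' @param label human-readable label.
#' @return the modified registry.
#' @export
register_biomarker <- function(registry, name, group, required, formula,
                               units = "", label = name) {
  stopifnot(inherits(registry, "biomarker_registry"), is.function(formula))
  registry[[name]] <- def_bm(name, label, group, required, units, formula)
  structure(registry, class = "biomarker_registry")
}

#' @export
print.biomarker_registry <- function(x, ...) {
  cat("<biomarker_registry> ", length(x), " biomarkers\n", sep = "")
  for (g in c("regional", "global", "non_composition")) {
    nm <- names(x)[vapply(x, `[[`, "", "group") == g]
    cat("  ", g, ": ", paste(nm, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' List registered biomarker names
#'
#' @param registry a \code{\link{biomarker_registry}}.
#' @param group optional group filter.
#' @return character vector of names in registry order.
#' @export
list_biomarkers <- function(registry = biomarker_registry(), group = NULL) {
  nm <- names(registry)
  if (!is.null(group)) {
    nm <- nm[vapply(registry, `[[`, "", "group") %in% group]
  }
  nm
}

#' Derive a biomarker from raw measurements
#'
#' Applies a registered formula row-wise to a participant table. A value is
#' missing exactly when any required measurement is missing for that row;
#' zero or negative measurements are treated as invalid and yield a missing
#' value with a warning. The population mean and standard deviation (and
#' z-scores, see \code{\link{zscore}}) are computed over the non-missing
#' values of the rows supplied, i.e. of the analysis population after any
#' filtering.
#'
#' @param table participant data frame (see \code{\link{participant_table}}).
#' @param biomarker a biomarker name present in \code{registry}, or a
#'   \code{biomarker_definition}.
#' @param registry a \code{\link{biomarker_registry}}.
#' @param standardize if \code{TRUE} (default) also populate mu, sigma and
#'   z-scores via \code{\link{zscore}} when at least two distinct values
#'   exist.
#' @param sd_type standard-deviation convention for sigma: population
#'   (divide by n, default) or sample (divide by n - 1).
#' @return an object of class \code{biomarker_vector}: list with fields
#'   \code{name}, \code{values}, \code{mu}, \code{sigma}, \code{zscores},
#'   \code{n} (non-missing count), \code{units}, \code{group}.
#' @export
#' @examples
#' tbl <- data.frame(sex = "male", age = 40, waist_circ = 85, hip_circ = 100)
#' derive_biomarker(tbl, "whr")$values  # 0.85
derive_biomarker <- function(table, biomarker,
                             registry = biomarker_registry(),
                             standardize = TRUE,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  def <- if (inherits(biomarker, "biomarker_definition")) {
    biomarker
  } else {
    if (!biomarker %in% names(registry)) {
      stop_norse(sprintf("unknown biomarker '%s' (not in registry)", biomarker),
                 "norse_registry_error")
    }
    registry[[biomarker]]
  }
  missing_cols <- setdiff(def$required, names(table))
  if (length(missing_cols)) {
    stop_norse(sprintf("table lacks column(s) required by '%s': %s",
                       def$name, paste(missing_cols, collapse = ", ")),
               "norse_registry_error")
  }
  num_req <- setdiff(def$required, "sex")
  ok <- rep(TRUE, nrow(table))
  n_invalid <- 0L
  for (col in num_req) {
    v <- table[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      n_invalid <- n_invalid + sum(bad)
      ok <- ok & !bad
    }
    ok <- ok & !is.na(v)
  }
  if ("sex" %in% def$required) ok <- ok & !is.na(table$sex)
  if (n_invalid > 0) {
    warning(sprintf("%s: %d non-positive measurement(s) set to missing",
                    def$name, n_invalid), call. = FALSE)
  }
  values <- rep(NA_real_, nrow(table))
  if (any(ok)) values[ok] <- def$formula(table[ok, , drop = FALSE])
  vec <- structure(
    list(name = def$name, values = values, mu = NA_real_, sigma = NA_real_,
         zscores = rep(NA_real_, length(values)), n = sum(!is.na(values)),
         units = def$units, group = def$group),
    class = "biomarker_vector")
  fin <- values[!is.na(values)]
  if (standardize && length(unique(fin)) >= 2) {
    vec <- zscore(vec, sd_type = sd_type)
  }
  vec
}

#' Standardize a biomarker vector
#'
#' Computes mu and sigma over non-missing values and the per-participant
#' z-scores (value - mu) / sigma. Sigma uses the population convention by
#' default. Re-standardizing an already z-scored vector returns the same
#' z-scores (mu 0, sigma 1).
#'
#' @param vector a \code{biomarker_vector} (or bare numeric vector, which is
#'   wrapped).
#' @param sd_type population (default) or sample standard deviation.
#' @return the vector with \code{mu}, \code{sigma}, \code{zscores} filled.
#' @export
zscore <- function(vector, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.numeric(vector)) {
    vector <- structure(
      list(name = "x", values = as.numeric(vector), mu = NA_real_,
           sigma = NA_real_, zscores = rep(NA_real_, length(vector)),
           n = sum(!is.na(vector)), units = "", group = NA_character_),
      class = "biomarker_vector")
  }
  stopifnot(inherits(vector, "biomarker_vector"))
  fin <- vector$values[!is.na(vector$values)]
  if (length(fin) < 2) {
    stop_norse("need at least 2 non-missing values to standardize",
               "norse_degenerate_error")
  }
  mu <- mean(fin)
  sigma <- stat_sd(fin, sd_type)
  if (!is.finite(sigma) || sigma <= 0) {
    stop_norse(sprintf("degenerate distribution for '%s': sigma = 0",
                       vector$name), "norse_degenerate_error")
  }
  vector$mu <- mu
  vector$sigma <- sigma
  vector$zscores <- (vector$values - mu) / sigma
  vector
}

#' @export
print.biomarker_vector <- function(x, ...) {
  cat(sprintf("<biomarker_vector> %s: n = %d, mu = %.4g, sigma = %.4g\n",
              x$name, x$n, x$mu, x$sigma))
  invisible(x)
}

#' All unordered pairs of biomarkers
#'
#' Enumerates the C(k, 2) unordered pairs of distinct biomarker names in a
#' deterministic order (first name varies slowest, following input order).
#' 23 biomarkers give 253 pairs.
#'
#' @param names character vector of distinct biomarker names.
#' @return data frame with columns \code{x} and \code{y}, one row per pair.
#' @export
#' @examples
#' nrow(list_pairs(list_biomarkers()))  # 253
list_pairs <- function(names) {
  if (anyDuplicated(names)) {
    stop_norse("biomarker names must be distinct", "norse_registry_error")
  }
  k <- length(names)
  if (k < 2) {
    return(data.frame(x = character(), y = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(k, 2)
  data.frame(x = names[idx[1, ]], y = names[idx[2, ]],
             stringsAsFactors = FALSE)
}
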