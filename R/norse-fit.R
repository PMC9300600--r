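#' Fit a normalized-sensitivity (NORSE) model
#'
#' The main fitting function. A 1D model \code{condition ~ biomarker}
#' estimates how condition prevalence (percent) changes per unit of the
#' biomarker (the sensitivity S) and per standard deviation of it (the
#' normalized score N = sigma * S), from a prevalence map binned at
#' half-standard-deviation cell width. A 2D model
#' \code{condition ~ x_biomarker + y_biomarker} bins jointly, scores every
#' row (along x) and column (along y) separately, aggregates them into
#' x/y scores, and reports their difference, the NORSE separation
#' (y score minus x score).
#'
#' The analysis population is listwise per fit: rows passing the sex/age
#' filter with non-missing values for every model biomarker and the
#' condition flag. The biomarker mean and standard deviation are computed on
#' that population. Scores are invariant under positive affine rescaling of
#' any biomarker, and flip sign when a biomarker is negated.
#'
#' @param formula \code{condition ~ biomarker} or
#'   \code{condition ~ x + y}; names refer to registry biomarkers (raw
#'   measurements are themselves registered).
#' @param data participant data frame (see \code{\link{participant_table}}).
#' @param sex \code{"male"}, \code{"female"} or \code{NULL} (both sexes
#'   pooled).
#' @param age_range inclusive age bounds; default adult range 20-110.
#' @param exclude_flags flag columns whose value 1 removes a row (e.g.
#'   \code{"smoker_flag"}).
#' @param registry biomarker registry.
#' @param min_cell,min_frac map suppression thresholds (40 and 0.2\%).
#' @param method slope estimator, see \code{\link{estimate_sensitivity}}.
#' @param aggregate 2D slice aggregation (when \code{scores_2d = "slices"}),
#'   weighted (default) or unweighted.
#' @param scores_2d how the aggregated 2D x/y scores are estimated:
#'   \code{"gradient"} (default) fits the 2D prevalence gradient jointly
#'   over cells, so correlated biomarkers control for each other;
#'   \code{"slices"} averages the per-row / per-column slopes. Per-slice
#'   scores are reported either way.
#' @param sd_type population (default) or sample standard deviation.
#' @return an object of class \code{norse} (additionally \code{norse_2d} for
#'   two biomarkers) with components \code{norse} (named score vector),
#'   \code{sensitivity}, \code{sigma}, \code{mu}, \code{separation} (2D),
#'   \code{row_norse}/\code{col_norse} (2D per-slice scores), \code{dmap},
#'   \code{pmap}, \code{n_used}, \code{condition}, \code{biomarkers},
#'   \code{call}.
#' @seealso \code{\link{rank_norse_1d}}, \code{\link{rank_norse_2d}},
#'   \code{\link{age_stratified_norse}}
#' @export
#' @examples
#' pop <- generate_population(synthetic_config(n = 4000, seed = 1))
#' fit <- norse(hypertension ~ waist_circ, pop, sex = "male")
#' coef(fit)
norse <- function(formula, data, sex = NULL, age_range = c(20, 110),
                  exclude_flags = character(),
                  registry = biomarker_registry(), min_cell = 40,
                  min_frac = 0.002, method = c("wls", "fd"),
                  aggregate = c("weighted", "unweighted"),
                  scores_2d = c("gradient", "slices"),
                  sd_type = c("population", "sample")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  scores_2d <- match.arg(scores_2d)
  sd_type <- match.arg(sd_type)
  if (!inherits(formula, "formula") || length(formula) != 3) {
    stop_norse("formula must be condition ~ biomarker or condition ~ x + y",
               "norse_formula_error")
  }
  condition <- all.vars(formula[[2]])
  biomarkers <- all.vars(formula[[3]])
  if (length(condition) != 1 || !length(biomarkers) %in% 1:2) {
    stop_norse("formula must be condition ~ biomarker or condition ~ x + y",
               "norse_formula_error")
  }
  if (!condition %in% names(data)) {
    stop_norse(sprintf("condition '%s' not in table", condition),
               "norse_map_error")
  }
  filt <- analysis_filter(sex = sex, age_range = age_range,
                          exclude_flags = exclude_flags)
  d <- apply_filter(data, filt)
  raw <- lapply(biomarkers, function(b)
    derive_biomarker(d, b, registry, standardize = FALSE))
  keep <- !is.na(d[[condition]])
  for (v in raw) keep <- keep & !is.na(v$values)
  if (sum(keep) < 2) {
    stop_norse("insufficient analysis population after listwise filtering",
               "norse_insufficient_support")
  }
  d <- d[keep, , drop = FALSE]
  vecs <- lapply(raw, function(v) {
    v$values <- v$values[keep]
    v$n <- sum(!is.na(v$values))
    v$zscores <- rep(NA_real_, length(v$values))
    zscore(v, sd_type = sd_type)
  })
  grids <- lapply(vecs, make_grid)
  flags <- d[[condition]]
  pmap <- build_pmap(vecs, flags, grids, condition = condition,
                     min_cell = min_cell, min_frac = min_frac)
  dmap <- build_dmap(vecs, grids, min_cell = min_cell, min_frac = min_frac)
  out <- list(
    condition = condition, biomarkers = biomarkers, sex = sex,
    age_range = age_range, exclude_flags = exclude_flags,
    mu = vapply(vecs, `[[`, 0, "mu"), sigma = vapply(vecs, `[[`, 0, "sigma"),
    dmap = dmap, pmap = pmap, method = method, registry = registry,
    sd_type = sd_type, call = match.call())
  names(out$mu) <- names(out$sigma) <- biomarkers
  if (length(biomarkers) == 1) {
    est <- estimate_sensitivity(pmap, method = method)
    out$norse <- stats::setNames(est$norse, biomarkers)
    out$sensitivity <- stats::setNames(est$sensitivity, biomarkers)
    out$intercept <- est$intercept
    out$n_used <- est$n_used
    out$cells_used <- est$cells_used
    class(out) <- "norse"
  } else {
    ex <- estimate_sensitivity(pmap, axis = 1, method = method,
                               aggregate = aggregate)
    ey <- estimate_sensitivity(pmap, axis = 2, method = method,
                               aggregate = aggregate)
    if (scores_2d == "gradient") {
      gr <- estimate_gradient_2d(pmap)
      xy <- c(gr$x_norse, gr$y_norse)
    } else {
      xy <- c(ex$norse, ey$norse)
    }
    out$norse <- stats::setNames(xy, biomarkers)
    out$sensitivity <- stats::setNames(xy / out$sigma, biomarkers)
    out$separation <- out$norse[[2]] - out$norse[[1]]
    out$scores_2d <- scores_2d
    out$row_norse <- ex$slice_norse   # one per y bin: slope along x
    out$row_n <- ex$slice_n
    out$col_norse <- ey$slice_norse   # one per x bin: slope along y
    out$col_n <- ey$slice_n
    out$n_used <- max(ex$n_used, ey$n_used)
    out$aggregate <- aggregate
    class(out) <- c("norse_2d", "norse")
  }
  out
}

#' @export
print.norse <- function(x, digits = 1, ...) {
  kind <- if (inherits(x, "norse_2d")) "2D" else "1D"
  cat(sprintf("NORSE %s model: %s ~ %s\n", kind, x$condition,
              paste(x$biomarkers, collapse = " + ")))
  cat(sprintf("  population: %s, age %g-%g, n = %d\n",
              x$sex %||% "both sexes", x$age_range[1], x$age_range[2],
              x$pmap$n_tot))
  sc <- round_half_away(x$norse, digits)
  cat("  NORSE: ", paste(sprintf("%s = %.*f", names(sc), digits, sc),
                         collapse = ", "), "\n", sep = "")
  if (inherits(x, "norse_2d")) {
    cat(sprintf("  NORSE separation (y - x): %.*f\n", digits,
                round_half_away(x$separation, digits)))
  }
  invisible(x)
}

#' @export
summary.norse <- function(object, ...) {
  s <- list(fit = object,
            norse = object$norse, sensitivity = object$sensitivity,
            sigma = object$sigma, mu = object$mu, n_used = object$n_used,
            n_tot = object$pmap$n_tot,
            suppressed_cells = sum(object$pmap$suppressed),
            total_cells = length(object$pmap$n_cell))
  if (inherits(object, "norse_2d")) {
    s$separation <- object$separation
    s$row_norse <- object$row_norse
    s$col_norse <- object$col_norse
  }
  class(s) <- "summary.norse"
  s
}

#' @export
print.summary.norse <- function(x, digits = 2, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  sigma: %s\n",
              paste(sprintf("%s = %.4g", names(x$sigma), x$sigma),
                    collapse = ", ")))
  cat(sprintf("  sensitivity (%% per unit): %s\n",
              paste(sprintf("%s = %.4g", names(x$sensitivity),
                            x$sensitivity), collapse = ", ")))
  cat(sprintf("  cells: %d (%d suppressed)\n", x$total_cells,
              x$suppressed_cells))
  if (!is.null(x$row_norse)) {
    cat("  row NORSE (along x, per y bin):",
        paste(format_masked(x$row_norse), collapse = " "), "\n")
    cat("  column NORSE (along y, per x bin):",
        paste(format_masked(x$col_norse), collapse = " "), "\n")
  }
  invisible(x)
}

# display convention: scores below 2 in magnitude are hidden (shown as dots)
# in printouts and map annotations; they still enter every aggregate
format_masked <- function(x, digits = 1, mask_below = 2) {
  out <- sprintf("%.*f", digits, round_half_away(x, digits))
  out[is.na(x)] <- "na"
  out[!is.na(x) & abs(x) < mask_below] <- "."
  out
}

#' @export
coef.norse <- function(object, ...) object$norse

#' Predicted prevalence from a fitted 1D NORSE model
#'
#' Evaluates the fitted count-weighted regression line of prevalence on the
#' biomarker at new values, clipped to [0, 100]. Values may be given as a
#' numeric vector of raw biomarker values or as a data frame of raw
#' measurements from which the biomarker is derived.
#'
#' @param object a 1D \code{norse} fit.
#' @param newdata numeric vector or data frame.
#' @param ... unused.
#' @return predicted prevalence in percent.
#' @export
predict.norse <- function(object, newdata, ...) {
  if (inherits(object, "norse_2d")) {
    stop_norse("predict is defined for 1D fits; use the p-map for 2D lookup",
               "norse_formula_error")
  }
  b <- object$biomarkers
  values <- if (is.data.frame(newdata)) {
    derive_biomarker(newdata, b, object$registry, standardize = FALSE)$values
  } else {
    as.numeric(newdata)
  }
  z <- (values - object$mu[[b]]) / object$sigma[[b]]
  pmin(100, pmax(0, object$intercept + object$norse[[b]] * z))
}

#' @export
residuals.norse <- function(object, ...) {
  if (inherits(object, "norse_2d")) {
    stop_norse("residuals are defined for 1D fits", "norse_formula_error")
  }
  g <- object$pmap$grids[[1]]
  fitted <- object$intercept + object$norse[[1]] * g$z_centers
  r <- object$pmap$prevalence - fitted
  r[object$pmap$suppressed] <- NA_real_
  r
}
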