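# Core slope machinery: prevalence (percent) regressed on per-cell biomarker
# values over non-suppressed cells. Working in z-units, the slope IS the
# normalized sensitivity (percent prevalence per SD); dividing by sigma
# gives the raw sensitivity in percent per biomarker unit.

wls_slope <- function(x, y, w) {
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  if (sxx <= 0) return(c(slope = NA_real_, intercept = NA_real_))
  sxy <- sum(w * (x - xm) * (y - ym))
  c(slope = sxy / sxx, intercept = ym - (sxy / sxx) * xm)
}

# count-weighted mean of local slopes between consecutive usable cells;
# alternative estimator behind the strategy switch
fd_slope <- function(x, y, w) {
  n <- length(x)
  d <- (y[-1] - y[-n]) / (x[-1] - x[-n])
  wd <- (w[-1] + w[-n]) / 2
  c(slope = sum(wd * d) / sum(wd), intercept = NA_real_)
}

slope_1d <- function(x, prevalence, n_cell, suppressed,
                     method = c("wls", "fd"), min_cells = 2) {
  method <- match.arg(method)
  use <- !suppressed & n_cell > 0 & !is.na(prevalence) & !is.na(x)
  if (sum(use) < min_cells || length(unique(x[use])) < 2) {
    return(list(ok = FALSE, slope = NA_real_, intercept = NA_real_,
                n_used = sum(n_cell[use]), cells_used = sum(use)))
  }
  est <- switch(method,
                wls = wls_slope(x[use], prevalence[use], n_cell[use]),
                fd = fd_slope(x[use], prevalence[use], n_cell[use]))
  list(ok = is.finite(est[["slope"]]), slope = est[["slope"]],
       intercept = est[["intercept"]], n_used = sum(n_cell[use]),
       cells_used = sum(use))
}

# per-cell regression abscissa in z units for one axis of a pmap
pmap_abscissa <- function(pmap, axis, abscissa) {
  g <- pmap$grids[[axis]]
  centers <- if (length(pmap$grids) == 1) {
    g$z_centers
  } else if (axis == 1) {
    matrix(g$z_centers, nrow = g$nbins, ncol = pmap$grids[[2]]$nbins)
  } else {
    matrix(g$z_centers, nrow = pmap$grids[[1]]$nbins, ncol = g$nbins,
           byrow = TRUE)
  }
  if (abscissa == "center" || is.null(pmap$z_mean)) return(centers)
  zm <- pmap$z_mean[[axis]]
  ifelse(is.na(zm), centers, zm)
}

#' Estimate the sensitivity of prevalence to a biomarker from a p-map
#'
#' The sensitivity S is the derivative of condition prevalence (in percent)
#' with respect to the biomarker. It is estimated as the count-weighted
#' least-squares slope of per-cell prevalence on the per-cell biomarker
#' abscissa, over non-suppressed cells. The default abscissa is the
#' within-cell mean biomarker value, which keeps the estimator exactly
#' unbiased when prevalence is linear in the biomarker (regressing on
#' geometric cell centers attenuates the slope when the within-cell value
#' distribution is non-uniform); the center abscissa remains available. The
#' normalized score (NORSE) is sigma * S, the percentage-point change in
#' prevalence per one standard deviation of the biomarker. For 2D maps,
#' \code{axis} selects the direction: slices (rows of constant y for axis 1,
#' columns of constant x for axis 2) are estimated individually, then
#' aggregated by a count-weighted mean.
#'
#' @param pmap a \code{\link{build_pmap}} result.
#' @param axis 1 (x) or 2 (y); ignored for 1D maps.
#' @param method slope estimator: \code{"wls"} count-weighted least squares
#'   (default) or \code{"fd"} count-weighted mean of local finite
#'   differences.
#' @param aggregate for 2D, how slice scores combine: count-weighted
#'   (default) or unweighted mean.
#' @param abscissa per-cell regressor: within-cell mean value
#'   (\code{"mean"}, default; falls back to centers for maps built without
#'   member values) or geometric cell center (\code{"center"}).
#' @return list with \code{sensitivity} (percent per biomarker unit),
#'   \code{norse} (percent per SD), \code{sigma}, \code{n_used},
#'   \code{cells_used}, and for 2D \code{slice_norse} (per-slice scores) and
#'   \code{slice_n}.
#' @export
estimate_sensitivity <- function(pmap, axis = 1, method = c("wls", "fd"),
                                 aggregate = c("weighted", "unweighted"),
                                 abscissa = c("mean", "center")) {
  stopifnot(inherits(pmap, "norse_pmap"))
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  abscissa <- match.arg(abscissa)
  x <- pmap_abscissa(pmap, if (length(pmap$grids) == 1) 1 else axis,
                     abscissa)
  if (length(pmap$grids) == 1) {
    g <- pmap$grids[[1]]
    est <- slope_1d(x, pmap$prevalence, pmap$n_cell, pmap$suppressed,
                    method)
    if (!est$ok) {
      stop_norse(sprintf(
        "insufficient support: fewer than 2 usable cells for %s ~ %s",
        pmap$condition, g$name), "norse_insufficient_support")
    }
    return(list(norse = est$slope, sensitivity = est$slope / g$sigma,
                sigma = g$sigma, n_used = est$n_used,
                cells_used = est$cells_used, intercept = est$intercept,
                axis = 1L, method = method))
  }
  g <- pmap$grids[[axis]]
  nslice <- if (axis == 1) ncol(pmap$n_cell) else nrow(pmap$n_cell)
  slice_norse <- rep(NA_real_, nslice)
  slice_n <- rep(0, nslice)
  for (s in seq_len(nslice)) {
    est <- if (axis == 1) {
      slope_1d(x[, s], pmap$prevalence[, s], pmap$n_cell[, s],
               pmap$suppressed[, s], method)
    } else {
      slope_1d(x[s, ], pmap$prevalence[s, ], pmap$n_cell[s, ],
               pmap$suppressed[s, ], method)
    }
    if (est$ok) {
      slice_norse[s] <- est$slope
      slice_n[s] <- est$n_used
    }
  }
  ok <- !is.na(slice_norse)
  if (!any(ok)) {
    stop_norse(sprintf(
      "insufficient support: no usable %s slice for %s",
      if (axis == 1) "row" else "column", pmap$condition),
      "norse_insufficient_support")
  }
  w <- if (aggregate == "weighted") slice_n[ok] else rep(1, sum(ok))
  norse <- sum(w * slice_norse[ok]) / sum(w)
  list(norse = norse, sensitivity = norse / g$sigma, sigma = g$sigma,
       n_used = sum(slice_n[ok]), cells_used = sum(ok),
       slice_norse = slice_norse, slice_n = slice_n,
       axis = as.integer(axis), method = method)
}

#' Estimate the 2D prevalence gradient from a p-map
#'
#' Count-weighted bivariate least squares of per-cell prevalence on the two
#' per-cell biomarker abscissas over non-suppressed cells, estimating the
#' gradient of prevalence with respect to both z-scored biomarkers jointly.
#' Unlike slicewise slopes, the joint fit controls each axis for the other,
#' so correlated biomarkers do not bias one another's score.
#'
#' @param pmap a 2D \code{\link{build_pmap}} result.
#' @param abscissa within-cell mean values (default) or cell centers.
#' @return list with \code{x_norse}, \code{y_norse} (percent prevalence per
#'   SD), \code{intercept}, \code{n_used}, \code{cells_used}.
#' @export
estimate_gradient_2d <- function(pmap, abscissa = c("mean", "center")) {
  stopifnot(inherits(pmap, "norse_pmap"), length(pmap$grids) == 2)
  abscissa <- match.arg(abscissa)
  zx <- pmap_abscissa(pmap, 1, abscissa)
  zy <- pmap_abscissa(pmap, 2, abscissa)
  use <- !pmap$suppressed & pmap$n_cell > 0 & !is.na(pmap$prevalence) &
    !is.na(zx) & !is.na(zy)
  if (sum(use) < 3) {
    stop_norse("insufficient support: fewer than 3 usable cells for a 2D gradient",
               "norse_insufficient_support")
  }
  X <- cbind(1, as.vector(zx[use]), as.vector(zy[use]))
  w <- as.vector(pmap$n_cell[use])
  y <- as.vector(pmap$prevalence[use])
  xtx <- crossprod(X * sqrt(w))
  if (kappa(xtx) > 1e12) {
    stop_norse("degenerate 2D support: abscissas are collinear",
               "norse_insufficient_support")
  }
  beta <- solve(xtx, crossprod(X, w * y))
  list(x_norse = beta[2], y_norse = beta[3], intercept = beta[1],
       n_used = sum(w), cells_used = sum(use))
}
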