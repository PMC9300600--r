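#' Build a binning grid with cell side half a standard deviation
#'
#' Map cells have side sigma/2 on every axis so that maps of different
#' biomarkers are visually comparable. Edges are anchored at the population
#' mean: edge k sits at mu + k * sigma / 2 for integer k, and the grid spans
#' the full non-missing data range. Bins are half-open [left, right);
#' internally binning happens on z-scores (edges at k/2), which makes grid
#' membership equivariant under positive affine rescaling of the biomarker.
#'
#' @param vector a standardized \code{biomarker_vector} (from
#'   \code{\link{derive_biomarker}} / \code{\link{zscore}}).
#' @return object of class \code{bin_grid}: name, mu, sigma, k range,
#'   \code{edges} and \code{centers} in raw units, \code{z_edges},
#'   \code{z_centers}, \code{nbins}.
#' @export
make_grid <- function(vector) {
  stopifnot(inherits(vector, "biomarker_vector"))
  if (!is.finite(vector$sigma) || vector$sigma <= 0) {
    stop_norse(sprintf("degenerate grid for '%s': sigma must be > 0",
                       vector$name), "norse_degenerate_error")
  }
  z <- vector$zscores[!is.na(vector$zscores)]
  if (!length(z)) stop_norse("no data to grid", "norse_degenerate_error")
  k_lo <- floor(min(z) / 0.5)
  k_hi <- floor(max(z) / 0.5)  # index of topmost populated bin
  k <- k_lo:(k_hi + 1)
  structure(
    list(name = vector$name, mu = vector$mu, sigma = vector$sigma,
         k_lo = k_lo, k_hi = k_hi, nbins = k_hi - k_lo + 1L,
         z_edges = k * 0.5,
         z_centers = (k_lo:k_hi) * 0.5 + 0.25,
         edges = vector$mu + k * 0.5 * vector$sigma,
         centers = vector$mu + ((k_lo:k_hi) * 0.5 + 0.25) * vector$sigma),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %s: %d bins of width sigma/2 = %.4g, range [%.4g, %.4g]\n",
              x$name, x$nbins, x$sigma / 2, x$edges[1],
              x$edges[length(x$edges)]))
  invisible(x)
}

# bin index (1-based) of each z-score on a grid; NA off-grid or missing
bin_index <- function(zscores, grid) {
  i <- floor(zscores / 0.5) - grid$k_lo + 1
  i[!is.na(i) & (i < 1 | i > grid$nbins)] <- NA_integer_
  as.integer(i)
}

as_axis_list <- function(x, what) {
  if (inherits(x, what)) list(x) else x
}

#' Build a population distribution map (d-map)
#'
#' Counts participants per grid cell over one or two biomarkers. Rows with a
#' missing value on any map axis are excluded from the map total. Cells
#' failing the small-count suppression rule (\code{n_cell} below
#' \code{min_cell}, or a cell fraction below \code{min_frac}) are flagged;
#' suppression affects display and downstream slope estimation, never the
#' stored counts.
#'
#' @param vectors a standardized \code{biomarker_vector} or list of two (x,
#'   y).
#' @param grids matching \code{bin_grid}(s); built with \code{\link{make_grid}}
#'   if omitted.
#' @param min_cell,min_frac suppression thresholds (defaults 40 and 0.2\%).
#' @param suppress apply the suppression mask to d-maps (default TRUE, as
#'   for p-maps).
#' @return object of class \code{norse_dmap}: grids, \code{n_cell} (vector
#'   or matrix), \code{n_tot}, \code{fraction}, \code{suppressed}.
#' @export
build_dmap <- function(vectors, grids = NULL, min_cell = 40,
                       min_frac = 0.002, suppress = TRUE) {
  vectors <- as_axis_list(vectors, "biomarker_vector")
  if (is.null(grids)) grids <- lapply(vectors, make_grid)
  grids <- as_axis_list(grids, "bin_grid")
  stopifnot(length(vectors) %in% 1:2, length(grids) == length(vectors))
  idx <- Map(function(v, g) bin_index(v$zscores, g), vectors, grids)
  keep <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  n_tot <- sum(keep)
  if (n_tot == 0) stop_norse("empty population for map", "norse_map_error")
  if (length(vectors) == 1) {
    n_cell <- tabulate(idx[[1]][keep], nbins = grids[[1]]$nbins)
  } else {
    nx <- grids[[1]]$nbins
    ny <- grids[[2]]$nbins
    flat <- (idx[[2]][keep] - 1L) * nx + idx[[1]][keep]
    n_cell <- matrix(tabulate(flat, nbins = nx * ny), nrow = nx, ncol = ny)
  }
  suppressed <- n_cell < min_cell | n_cell / n_tot < min_frac
  if (!suppress) suppressed[] <- FALSE
  structure(
    list(grids = grids, n_cell = n_cell, n_tot = n_tot,
         fraction = n_cell / n_tot, suppressed = suppressed,
         min_cell = min_cell, min_frac = min_frac,
         axes = vapply(grids, `[[`, "", "name")),
    class = "norse_dmap")
}

#' Build a condition prevalence map (p-map)
#'
#' Per grid cell over one or two biomarkers: the number of participants
#' n_cell, the number positive for the condition n_cond, and the prevalence
#' 100 * n_cond / n_cell in percent. Rows with a missing axis value or a
#' missing condition flag are excluded. Cells with n_cell < \code{min_cell}
#' or cell fraction < \code{min_frac} are suppressed (left empty in
#' displays and ignored by slope estimation).
#'
#' @param vectors a standardized \code{biomarker_vector} or list of two.
#' @param condition_flags numeric vector of 0/1/NA, one per participant.
#' @param grids matching grid(s); built from the vectors if omitted.
#' @param condition condition name for labelling.
#' @param min_cell,min_frac suppression thresholds.
#' @return object of class \code{norse_pmap}: grids, \code{n_cell},
#'   \code{n_cond}, \code{prevalence} (percent; NA where n_cell = 0),
#'   \code{suppressed}, \code{n_tot}, \code{condition}, and \code{z_mean}
#'   (per axis, the within-cell mean z-score, used as the default regression
#'   abscissa by \code{\link{estimate_sensitivity}}).
#' @export
build_pmap <- function(vectors, condition_flags, grids = NULL,
                       condition = "condition", min_cell = 40,
                       min_frac = 0.002) {
  vectors <- as_axis_list(vectors, "biomarker_vector")
  if (is.null(grids)) grids <- lapply(vectors, make_grid)
  grids <- as_axis_list(grids, "bin_grid")
  stopifnot(length(vectors) %in% 1:2, length(grids) == length(vectors))
  if (!all(condition_flags %in% c(0, 1) | is.na(condition_flags))) {
    stop_norse("condition flags must be 0, 1 or missing", "norse_map_error")
  }
  idx <- Map(function(v, g) bin_index(v$zscores, g), vectors, grids)
  keep <- Reduce(`&`, lapply(idx, function(i) !is.na(i))) &
    !is.na(condition_flags)
  n_tot <- sum(keep)
  if (n_tot == 0) stop_norse("empty population for map", "norse_map_error")
  flags <- condition_flags[keep]
  if (length(vectors) == 1) {
    i1 <- idx[[1]][keep]
    nb <- grids[[1]]$nbins
    n_cell <- tabulate(i1, nbins = nb)
    n_cond <- as.numeric(tapply_sum(flags, i1, nb))
    z_mean <- list(ifelse(n_cell > 0,
                          tapply_sum(vectors[[1]]$zscores[keep], i1, nb) /
                            pmax(n_cell, 1), NA_real_))
  } else {
    nx <- grids[[1]]$nbins
    ny <- grids[[2]]$nbins
    flat <- (idx[[2]][keep] - 1L) * nx + idx[[1]][keep]
    n_cell <- matrix(tabulate(flat, nbins = nx * ny), nrow = nx)
    n_cond <- matrix(tapply_sum(flags, flat, nx * ny), nrow = nx)
    z_mean <- lapply(vectors, function(v) {
      s <- matrix(tapply_sum(v$zscores[keep], flat, nx * ny), nrow = nx)
      ifelse(n_cell > 0, s / pmax(n_cell, 1), NA_real_)
    })
  }
  prevalence <- ifelse(n_cell > 0, 100 * n_cond / n_cell, NA_real_)
  if (is.matrix(n_cell)) prevalence <- matrix(prevalence, nrow = nrow(n_cell))
  suppressed <- n_cell < min_cell | n_cell / n_tot < min_frac
  structure(
    list(grids = grids, condition = condition, n_cell = n_cell,
         n_cond = n_cond, prevalence = prevalence, suppressed = suppressed,
         z_mean = z_mean, n_tot = n_tot, min_cell = min_cell,
         min_frac = min_frac, axes = vapply(grids, `[[`, "", "name")),
    class = "norse_pmap")
}

tapply_sum <- function(x, index, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, group = index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.norse_dmap <- function(x, ...) {
  cat(sprintf("<norse_dmap> %s: n_tot = %d, %s cells (%d suppressed)\n",
              paste(x$axes, collapse = " x "), x$n_tot,
              paste(dim(as.matrix(x$n_cell)), collapse = " x "),
              sum(x$suppressed)))
  invisible(x)
}

#' @export
print.norse_pmap <- function(x, ...) {
  cat(sprintf("<norse_pmap> %s ~ %s: n_tot = %d, %d suppressed cells\n",
              x$condition, paste(x$axes, collapse = " x "), x$n_tot,
              sum(x$suppressed)))
  invisible(x)
}

map_cells_df <- function(x) {
  is2d <- length(x$grids) == 2
  gx <- x$grids[[1]]
  if (is2d) {
    gy <- x$grids[[2]]
    ix <- rep(seq_len(gx$nbins), gy$nbins)
    iy <- rep(seq_len(gy$nbins), each = gx$nbins)
    out <- data.frame(
      x_lo = gx$edges[ix], x_hi = gx$edges[ix + 1],
      y_lo = gy$edges[iy], y_hi = gy$edges[iy + 1],
      n_cell = as.vector(x$n_cell))
  } else {
    ix <- seq_len(gx$nbins)
    out <- data.frame(x_lo = gx$edges[ix], x_hi = gx$edges[ix + 1],
                      n_cell = as.vector(x$n_cell))
  }
  if (inherits(x, "norse_pmap")) {
    out$n_cond <- as.vector(x$n_cond)
    out$prevalence <- as.vector(x$prevalence)
  } else {
    out$fraction <- as.vector(x$fraction)
  }
  out$suppressed <- as.vector(x$suppressed)
  out
}

#' @export
as.data.frame.norse_dmap <- function(x, ...) map_cells_df(x)

#' @export
as.data.frame.norse_pmap <- function(x, ...) map_cells_df(x)

#' Export a map to CSV or JSON
#'
#' One row/record per cell with bin bounds, counts, prevalence or fraction,
#' and the suppression flag.
#'
#' @param map a \code{norse_dmap} or \code{norse_pmap}.
#' @param path output file; format chosen by extension (.csv or .json).
#' @return the path, invisibly.
#' @export
write_map <- function(map, path) {
  df <- map_cells_df(map)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
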