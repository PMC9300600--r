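# Map renderers, base graphics. d-maps use a white-blue-purple ramp (white
# = 0% of the population); p-maps a grey-green-yellow-red ramp (green = low
# prevalence). Suppressed cells are left blank. Row/column NORSE scores are
# printed at the row ends (blue) and column ends (brown); scores below 2 in
# magnitude are hidden from the display (they still enter all aggregates).

dmap_palette <- function(n = 100) {
  grDevices::colorRampPalette(c("white", "#5B8DC8", "#5E3A87"))(n)
}

pmap_palette <- function(n = 100) {
  grDevices::colorRampPalette(c("grey80", "forestgreen", "yellow",
                                "red"))(n)
}

render_map <- function(values, grids, palette, annotations, main,
                       side_labels = NULL, top_labels = NULL,
                       zlim = NULL) {
  vals <- as.matrix(values)
  if (all(is.na(vals))) {
    stop_norse("map is empty: every cell is suppressed or unpopulated",
               "norse_map_error")
  }
  nx <- nrow(vals)
  ny <- ncol(vals)
  is2d <- length(grids) == 2
  zlim <- zlim %||% range(vals, na.rm = TRUE)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  op <- graphics::par(mar = c(4.5, 4.5, 3, if (is.null(side_labels)) 2 else 5))
  on.exit(graphics::par(op))
  graphics::image(x = seq_len(nx), y = seq_len(ny), z = vals,
                  col = palette, zlim = zlim, axes = FALSE,
                  xlab = grid_label(grids[[1]]),
                  ylab = if (is2d) grid_label(grids[[2]]) else "",
                  main = main)
  graphics::axis(1, at = seq_len(nx) - 0.5,
                 labels = signif(grids[[1]]$edges[seq_len(nx)], 3),
                 las = 2, cex.axis = 0.7)
  if (is2d) {
    graphics::axis(2, at = seq_len(ny) - 0.5,
                   labels = signif(grids[[2]]$edges[seq_len(ny)], 3),
                   las = 1, cex.axis = 0.7)
  }
  graphics::box()
  if (!is.null(annotations) && length(vals) <= 400) {
    xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    txt <- as.vector(as.matrix(annotations))
    keep <- !is.na(txt) & txt != ""
    graphics::text(xy$x[keep], xy$y[keep], txt[keep], cex = 0.6)
  }
  if (!is.null(side_labels)) {  # per-row scores (along x), blue
    lab <- format_masked(side_labels)
    lab[lab %in% c(".", "na")] <- ""
    graphics::mtext(lab, side = 4, at = seq_len(ny), las = 1,
                    col = "blue3", cex = 0.7, line = 0.5)
  }
  if (!is.null(top_labels)) {   # per-column scores (along y), brown
    lab <- format_masked(top_labels)
    lab[lab %in% c(".", "na")] <- ""
    graphics::mtext(lab, side = 3, at = seq_len(nx), col = "darkorange3",
                    cex = 0.7, line = 0.2)
  }
  invisible(NULL)
}

grid_label <- function(g) {
  if (nzchar(g$units %||% "")) paste0(g$name, " (", g$units, ")") else g$name
}

#' Render a distribution map
#'
#' Heatmap of per-cell population fractions (white-blue-purple, white = 0).
#' Cells are annotated with their count and percent of the map total;
#' suppressed cells are blank.
#'
#' @param dmap a \code{\link{build_dmap}} result.
#' @param main plot title.
#' @return invisibly, NULL. Errors if every cell is suppressed.
#' @export
render_dmap <- function(dmap, main = NULL) {
  stopifnot(inherits(dmap, "norse_dmap"))
  vals <- as.matrix(dmap$fraction)
  vals[as.matrix(dmap$suppressed)] <- NA
  ann <- matrix(sprintf("%d\n%.1f%%", as.matrix(dmap$n_cell), 100 * vals),
                nrow = nrow(vals))
  ann[is.na(vals)] <- ""
  render_map(vals, dmap$grids, dmap_palette(),
             ann, main %||% paste("d-map:", paste(dmap$axes, collapse = " x ")),
             zlim = c(0, max(vals, na.rm = TRUE)))
}

#' Render a prevalence map
#'
#' Heatmap of per-cell condition prevalence (grey-green-yellow-red, green =
#' low). Cells show prevalence in percent; suppressed cells are blank.
#' Optional per-row NORSE scores print at row ends in blue and per-column
#' scores at column ends in brown, with scores of magnitude below
#' \code{mask_below} hidden.
#'
#' @param pmap a \code{\link{build_pmap}} result.
#' @param row_norse,col_norse optional per-row / per-column scores (as in a
#'   2D \code{\link{norse}} fit).
#' @param main plot title.
#' @return invisibly, NULL. Errors if every cell is suppressed.
#' @export
render_pmap <- function(pmap, row_norse = NULL, col_norse = NULL,
                        main = NULL) {
  stopifnot(inherits(pmap, "norse_pmap"))
  vals <- as.matrix(pmap$prevalence)
  vals[as.matrix(pmap$suppressed)] <- NA
  ann <- matrix(sprintf("%.1f%%", vals), nrow = nrow(vals))
  ann[is.na(vals)] <- ""
  render_map(vals, pmap$grids, pmap_palette(), ann,
             main %||% sprintf("p-map: %s ~ %s", pmap$condition,
                               paste(pmap$axes, collapse = " x ")),
             side_labels = row_norse, top_labels = col_norse,
             zlim = c(0, max(vals, na.rm = TRUE)))
}

#' Plot a fitted NORSE model
#'
#' For 1D fits, plots per-cell prevalence against the biomarker with point
#' size proportional to cell count and the fitted count-weighted line
#' (\code{type = "fit"}), or the underlying p-map / d-map heatmaps. For 2D
#' fits, draws the p-map with row and column NORSE annotations.
#'
#' @param x a \code{norse} fit.
#' @param type \code{"fit"} (1D only), \code{"pmap"} or \code{"dmap"}.
#' @param ... unused.
#' @return x, invisibly.
#' @export
plot.norse <- function(x, type = c("fit", "pmap", "dmap"), ...) {
  type <- match.arg(type)
  if (inherits(x, "norse_2d") && type == "fit") type <- "pmap"
  if (type == "dmap") {
    render_dmap(x$dmap)
  } else if (type == "pmap") {
    render_pmap(x$pmap,
                row_norse = x$row_norse, col_norse = x$col_norse,
                main = sprintf("%s ~ %s (%s)", x$condition,
                               paste(x$biomarkers, collapse = " x "),
                               x$sex %||% "both sexes"))
  } else {
    g <- x$pmap$grids[[1]]
    use <- !x$pmap$suppressed & x$pmap$n_cell > 0
    plot(g$centers[use], x$pmap$prevalence[use],
         cex = 0.5 + 2 * sqrt(x$pmap$n_cell[use] / max(x$pmap$n_cell)),
         pch = 19, col = "grey40", xlab = grid_label(g),
         ylab = "prevalence (%)",
         main = sprintf("%s ~ %s: NORSE = %.1f", x$condition,
                        x$biomarkers, round_half_away(x$norse[[1]], 1)))
    graphics::abline(a = x$intercept - x$norse[[1]] * x$mu[[1]] / x$sigma[[1]],
                     b = x$norse[[1]] / x$sigma[[1]], col = "red3", lwd = 2)
  }
  invisible(x)
}
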