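#' Default age brackets
#'
#' Ten-year brackets from 20 to 80 plus an open 80+ bracket, partitioning
#' the adult range 20-110.
#'
#' @return numeric vector of bracket edges.
#' @export
default_age_brackets <- function() c(20, 30, 40, 50, 60, 70, 80, 110)

#' Age-stratified NORSE curve
#'
#' Refits the 1D model within consecutive age brackets, per sex. Brackets
#' are half-open [lo, hi) except the last, which is closed at the top so the
#' brackets partition the requested range. The biomarker mean and standard
#' deviation are recomputed on each stratum's analysis population. Strata
#' with fewer than \code{min_n} usable participants, or with insufficient
#' map support, are reported as unavailable (missing score) rather than
#' raising an error.
#'
#' @param data participant data frame.
#' @param biomarker,condition model, as in \code{\link{norse}}.
#' @param brackets bracket edges (length k + 1 for k brackets); default
#'   10-year brackets 20-80 plus 80+.
#' @param sexes sexes analysed separately.
#' @param min_n minimum analysis population per stratum (default 100).
#' @param registry,min_cell,min_frac,method,sd_type fit parameters.
#' @return object of class \code{norse_age_curve}: data frame \code{curve}
#'   with one row per (sex, bracket): \code{age_lo}, \code{age_hi},
#'   \code{age_mid}, \code{norse}, \code{n_used}, \code{available}.
#' @export
age_stratified_norse <- function(data, biomarker, condition,
                                 brackets = default_age_brackets(),
                                 sexes = c("male", "female"), min_n = 100,
                                 registry = biomarker_registry(),
                                 min_cell = 40, min_frac = 0.002,
                                 method = "wls", sd_type = "population") {
  stopifnot(length(brackets) >= 2, !is.unsorted(brackets))
  k <- length(brackets) - 1
  rows <- list()
  for (sx in sexes) {
    for (i in seq_len(k)) {
      lo <- brackets[i]
      hi <- brackets[i + 1]
      d <- apply_filter(data, analysis_filter(sex = sx, age_range = c(lo, hi)))
      if (i < k) d <- d[d$age < hi, , drop = FALSE]  # half-open except last
      est <- list(norse = NA_real_, n_used = 0L)
      if (nrow(d) >= min_n) {
        values <- tryCatch(suppressWarnings(
          derive_biomarker(d, biomarker, registry,
                           standardize = FALSE)$values),
          norse_error = function(e) NULL)
        if (!is.null(values)) {
          keep <- !is.na(values) & !is.na(d[[condition]])
          if (sum(keep) >= min_n) {
            est <- fit_1d_values(values, d[[condition]], sd_type, min_cell,
                                 min_frac, method)
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx, age_lo = lo, age_hi = hi, age_mid = (lo + hi) / 2,
        norse = est$norse, n_used = est$n_used,
        available = !is.na(est$norse))
    }
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  structure(list(curve = curve, biomarker = biomarker,
                 condition = condition, brackets = brackets),
            class = "norse_age_curve")
}

#' @export
print.norse_age_curve <- function(x, digits = 1, ...) {
  cat(sprintf("Age-stratified NORSE: %s ~ %s\n", x$condition, x$biomarker))
  c2 <- x$curve
  c2$norse <- round_half_away(c2$norse, digits)
  print(c2, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.norse_age_curve <- function(x, ...) x$curve

#' @export
plot.norse_age_curve <- function(x, ...) {
  cv <- x$curve[x$curve$available, ]
  if (!nrow(cv)) stop_norse("no available strata to plot", "norse_map_error")
  sexes <- unique(cv$sex)
  cols <- stats::setNames(c("steelblue", "firebrick")[seq_along(sexes)],
                          sexes)
  plot(range(cv$age_mid), range(cv$norse), type = "n",
       xlab = "age (bracket midpoint, years)",
       ylab = "NORSE (% prevalence per SD)",
       main = sprintf("%s ~ %s by age", x$condition, x$biomarker), ...)
  for (sx in sexes) {
    s <- cv[cv$sex == sx, ]
    graphics::lines(s$age_mid, s$norse, col = cols[sx], lwd = 2)
    graphics::points(s$age_mid, s$norse, col = cols[sx], pch = 19)
  }
  graphics::legend("topright", legend = sexes, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
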