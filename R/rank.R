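# Ranking tables: aggregate per-(biomarker, sex, condition) scores into the
# report layout — per-sex averages across conditions, a cross-sex ranking
# key, and per-condition column averages. Averages are computed on unrounded
# scores; half-away-from-zero rounding is applied only when formatting.

#' Build a 1D ranking table from per-condition NORSE scores
#'
#' Takes a long table of scores — one row per (biomarker, sex, condition) —
#' and computes, per biomarker and sex, the average score across conditions;
#' per biomarker, the cross-sex ranking key (mean of the per-sex averages);
#' and per sex and condition, the column average across biomarkers. Rows are
#' sorted by descending ranking key. All averaging is done on unrounded
#' values.
#'
#' @param scores data frame with columns \code{biomarker}, \code{sex},
#'   \code{condition}, \code{norse} (and optionally \code{group},
#'   \code{n_used}).
#' @return object of class \code{norse_ranking}: \code{scores} (the input),
#'   \code{per_sex} (wide, one row per biomarker and sex with per-condition
#'   columns and \code{avg_norse}), \code{ranking} (biomarker,
#'   per-sex averages, cross-sex \code{key}, rank), \code{column_avg} (sex,
#'   condition, mean over biomarkers).
#' @export
#' @examples
#' scores <- data.frame(
#'   biomarker = "whr", sex = rep(c("male", "female"), each = 6),
#'   condition = rep(condition_columns(), 2),
#'   norse = c(14.3, 10.8, 11.5, 12.4, 3.3, 2.7,
#'             13.4, 9.6, 7.9, 10.6, 1.2, 3.2))
#' norse_ranking_table(scores)$ranking  # avgs 9.2 / 7.7, key 8.4 (rounded)
norse_ranking_table <- function(scores) {
  stopifnot(all(c("biomarker", "sex", "condition", "norse") %in%
                  names(scores)))
  conditions <- unique(scores$condition)
  sexes <- unique(scores$sex)
  biomarkers <- unique(scores$biomarker)
  per_sex <- do.call(rbind, lapply(sexes, function(sx) {
    do.call(rbind, lapply(biomarkers, function(b) {
      s <- scores[scores$sex == sx & scores$biomarker == b, ]
      row <- as.list(stats::setNames(
        s$norse[match(conditions, s$condition)], conditions))
      row$avg_norse <- mean(unlist(row), na.rm = TRUE)
      cbind(data.frame(biomarker = b, sex = sx), as.data.frame(row))
    }))
  }))
  key <- vapply(biomarkers, function(b) {
    mean(per_sex$avg_norse[per_sex$biomarker == b], na.rm = TRUE)
  }, 0)
  ranking <- data.frame(biomarker = biomarkers, key = key)
  for (sx in sexes) {
    m <- per_sex[per_sex$sex == sx, ]
    ranking[[paste0("avg_", sx)]] <- m$avg_norse[match(biomarkers, m$biomarker)]
  }
  ranking <- ranking[order(-ranking$key), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  column_avg <- do.call(rbind, lapply(sexes, function(sx) {
    data.frame(sex = sx, condition = conditions,
               avg_norse = vapply(conditions, function(cn) {
                 mean(scores$norse[scores$sex == sx &
                                     scores$condition == cn], na.rm = TRUE)
               }, 0))
  }))
  rownames(column_avg) <- NULL
  structure(list(scores = scores, per_sex = per_sex, ranking = ranking,
                 column_avg = column_avg, conditions = conditions,
                 sexes = sexes),
            class = "norse_ranking")
}

#' @export
print.norse_ranking <- function(x, digits = 1, ...) {
  cat("NORSE 1D biomarker ranking (", nrow(x$ranking), " biomarkers, ",
      length(x$conditions), " conditions)\n", sep = "")
  r <- x$ranking
  num <- vapply(r, is.numeric, TRUE)
  r[num] <- lapply(r[num], round_half_away, digits = digits)
  print(r[, c("rank", "biomarker", setdiff(names(r),
                                           c("rank", "biomarker", "key")),
              "key")], row.names = FALSE)
  cat("column averages (Avg NORSE):\n")
  ca <- x$column_avg
  ca$avg_norse <- round_half_away(ca$avg_norse, digits)
  print(ca, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.norse_ranking <- function(x, ...) x$ranking

# internal: NORSE for precomputed raw values + flags, NA on thin support
fit_1d_values <- function(values, flags, sd_type = "population",
                          min_cell = 40, min_frac = 0.002, method = "wls") {
  keep <- !is.na(values) & !is.na(flags)
  if (sum(keep) < 2 || length(unique(values[keep])) < 2) {
    return(list(norse = NA_real_, n_used = 0L))
  }
  vec <- structure(
    list(name = "b", values = values[keep], mu = NA_real_, sigma = NA_real_,
         zscores = rep(NA_real_, sum(keep)), n = sum(keep), units = "",
         group = NA_character_), class = "biomarker_vector")
  vec <- zscore(vec, sd_type = sd_type)
  pm <- build_pmap(vec, flags[keep], condition = "c",
                   min_cell = min_cell, min_frac = min_frac)
  est <- tryCatch(estimate_sensitivity(pm, method = method),
                  norse_insufficient_support = function(e) NULL)
  if (is.null(est)) return(list(norse = NA_real_, n_used = 0L))
  list(norse = est$norse, n_used = est$n_used)
}

#' Rank 1D biomarker models by average NORSE
#'
#' Fits every (biomarker, condition, sex) 1D model on its listwise analysis
#' population and assembles the ranking table: per-condition scores, per-sex
#' averages, the cross-sex average used as ranking key, and per-condition
#' column averages. Biomarkers underivable for both sexes are dropped with a
#' warning; individual fits with insufficient support contribute missing
#' values.
#'
#' @param data participant data frame.
#' @param biomarkers names to rank (default: all 23 registered).
#' @param conditions condition columns (default: the built-in six).
#' @param sexes sexes analysed separately (default male and female).
#' @param age_range,exclude_flags population filters.
#' @param registry biomarker registry.
#' @param min_cell,min_frac,method,sd_type passed to the underlying fits.
#' @return a \code{\link{norse_ranking_table}} object; its \code{scores}
#'   component holds the long per-fit results including \code{n_used}.
#' @export
rank_norse_1d <- function(data, biomarkers = list_biomarkers(registry),
                          conditions = condition_columns(),
                          sexes = c("male", "female"),
                          age_range = c(20, 110),
                          exclude_flags = character(),
                          registry = biomarker_registry(),
                          min_cell = 40, min_frac = 0.002,
                          method = "wls", sd_type = "population") {
  conditions <- intersect(conditions, names(data))
  rows <- list()
  derivable <- stats::setNames(logical(length(biomarkers)), biomarkers)
  for (sx in sexes) {
    d <- apply_filter(data, analysis_filter(sex = sx, age_range = age_range,
                                            exclude_flags = exclude_flags))
    for (b in biomarkers) {
      values <- tryCatch(
        suppressWarnings(
          derive_biomarker(d, b, registry, standardize = FALSE)$values),
        norse_registry_error = function(e) NULL)
      if (is.null(values) || sum(!is.na(values)) < 2) next
      derivable[b] <- TRUE
      for (cn in conditions) {
        est <- fit_1d_values(values, d[[cn]], sd_type, min_cell, min_frac,
                             method)
        rows[[length(rows) + 1]] <- data.frame(
          biomarker = b, sex = sx, condition = cn, norse = est$norse,
          n_used = est$n_used,
          group = registry[[b]]$group %||% NA_character_)
      }
    }
  }
  if (any(!derivable)) {
    warning("excluded underivable biomarker(s): ",
            paste(names(derivable)[!derivable], collapse = ", "),
            call. = FALSE)
  }
  norse_ranking_table(do.call(rbind, rows))
}

#' Build a 2D separation table from per-condition x/y NORSE scores
#'
#' Long input, one row per (pair, sex, condition) with the aggregated x and
#' y scores of the 2D model. Computes the per-condition separation (y - x),
#' per-sex averages of x, y and separation across conditions, and the
#' cross-sex average separation used as ranking key. Averaging is on
#' unrounded values.
#'
#' @param scores data frame with columns \code{x}, \code{y}, \code{sex},
#'   \code{condition}, \code{x_norse}, \code{y_norse}.
#' @return object of class \code{norse_ranking_2d} with \code{scores} (input
#'   plus \code{separation}), \code{per_sex} (pair x sex averages) and
#'   \code{ranking} (pair, per-sex separation averages, cross-sex
#'   \code{key}, rank).
#' @export
norse_separation_table <- function(scores) {
  stopifnot(all(c("x", "y", "sex", "condition", "x_norse", "y_norse") %in%
                  names(scores)))
  scores$separation <- scores$y_norse - scores$x_norse
  scores$pair <- paste(scores$x, scores$y, sep = ":")
  pairs <- unique(scores$pair)
  sexes <- unique(scores$sex)
  per_sex <- do.call(rbind, lapply(sexes, function(sx) {
    do.call(rbind, lapply(pairs, function(p) {
      s <- scores[scores$sex == sx & scores$pair == p, ]
      data.frame(pair = p, x = s$x[1], y = s$y[1], sex = sx,
                 x_avg = mean(s$x_norse, na.rm = TRUE),
                 y_avg = mean(s$y_norse, na.rm = TRUE),
                 sep_avg = mean(s$separation, na.rm = TRUE))
    }))
  }))
  key <- vapply(pairs, function(p) {
    mean(per_sex$sep_avg[per_sex$pair == p], na.rm = TRUE)
  }, 0)
  ranking <- data.frame(pair = pairs,
                        x = per_sex$x[match(pairs, per_sex$pair)],
                        y = per_sex$y[match(pairs, per_sex$pair)],
                        key = key)
  for (sx in sexes) {
    m <- per_sex[per_sex$sex == sx, ]
    ranking[[paste0("sep_", sx)]] <- m$sep_avg[match(pairs, m$pair)]
  }
  ranking <- ranking[order(-ranking$key), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(scores = scores, per_sex = per_sex, ranking = ranking,
                 sexes = sexes),
            class = "norse_ranking_2d")
}

#' @export
print.norse_ranking_2d <- function(x, digits = 1, n = 10, ...) {
  cat("NORSE 2D model ranking by separation (", nrow(x$ranking),
      " pairs)\n", sep = "")
  r <- utils::head(x$ranking, n)
  num <- vapply(r, is.numeric, TRUE)
  r[num] <- lapply(r[num], round_half_away, digits = digits)
  print(r[, c("rank", "x", "y", setdiff(names(r),
                                        c("rank", "x", "y", "pair", "key")),
              "key")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.norse_ranking_2d <- function(x, ...) x$ranking

#' Rank 2D biomarker models by average NORSE separation
#'
#' Fits the 2D model of every biomarker pair for every condition and sex,
#' and ranks pairs by the cross-sex average NORSE separation. Pairs default
#' to all unordered combinations of the registered biomarkers
#' (\code{\link{list_pairs}}); 23 biomarkers give 253 pairs. Fits with
#' insufficient support contribute missing values.
#'
#' @param data participant data frame.
#' @param pairs data frame with columns \code{x}, \code{y}; default all
#'   pairs of \code{biomarkers}.
#' @param biomarkers names used to build the default pairs.
#' @param conditions,sexes,age_range,exclude_flags,registry population and
#'   model setup as in \code{\link{rank_norse_1d}}.
#' @param min_cell,min_frac,method,aggregate,scores_2d,sd_type fit
#'   parameters, as in \code{\link{norse}}.
#' @return a \code{\link{norse_separation_table}} object.
#' @export
rank_norse_2d <- function(data, pairs = NULL,
                          biomarkers = list_biomarkers(registry),
                          conditions = condition_columns(),
                          sexes = c("male", "female"),
                          age_range = c(20, 110),
                          exclude_flags = character(),
                          registry = biomarker_registry(),
                          min_cell = 40, min_frac = 0.002, method = "wls",
                          aggregate = "weighted", scores_2d = "gradient",
                          sd_type = "population") {
  if (is.null(pairs)) pairs <- list_pairs(biomarkers)
  conditions <- intersect(conditions, names(data))
  need <- unique(c(pairs$x, pairs$y))
  rows <- list()
  for (sx in sexes) {
    d <- apply_filter(data, analysis_filter(sex = sx, age_range = age_range,
                                            exclude_flags = exclude_flags))
    values <- lapply(stats::setNames(need, need), function(b)
      tryCatch(suppressWarnings(
        derive_biomarker(d, b, registry, standardize = FALSE)$values),
        norse_registry_error = function(e) rep(NA_real_, nrow(d))))
    for (i in seq_len(nrow(pairs))) {
      bx <- pairs$x[i]; by <- pairs$y[i]
      for (cn in conditions) {
        est <- fit_2d_values(values[[bx]], values[[by]], d[[cn]], sd_type,
                             min_cell, min_frac, method, aggregate,
                             scores_2d)
        rows[[length(rows) + 1]] <- data.frame(
          x = bx, y = by, sex = sx, condition = cn,
          x_norse = est$x_norse, y_norse = est$y_norse, n_used = est$n_used)
      }
    }
  }
  norse_separation_table(do.call(rbind, rows))
}

fit_2d_values <- function(xv, yv, flags, sd_type = "population",
                          min_cell = 40, min_frac = 0.002, method = "wls",
                          aggregate = "weighted", scores_2d = "gradient") {
  keep <- !is.na(xv) & !is.na(yv) & !is.na(flags)
  bad <- list(x_norse = NA_real_, y_norse = NA_real_, n_used = 0L)
  if (sum(keep) < 2 || length(unique(xv[keep])) < 2 ||
      length(unique(yv[keep])) < 2) {
    return(bad)
  }
  mk <- function(v) {
    zscore(structure(
      list(name = "b", values = v[keep], mu = NA_real_, sigma = NA_real_,
           zscores = rep(NA_real_, sum(keep)), n = sum(keep), units = "",
           group = NA_character_), class = "biomarker_vector"),
      sd_type = sd_type)
  }
  pm <- build_pmap(list(mk(xv), mk(yv)), flags[keep], condition = "c",
                   min_cell = min_cell, min_frac = min_frac)
  if (scores_2d == "gradient") {
    gr <- tryCatch(estimate_gradient_2d(pm),
                   norse_insufficient_support = function(e) NULL)
    if (is.null(gr)) return(bad)
    return(list(x_norse = gr$x_norse, y_norse = gr$y_norse,
                n_used = gr$n_used))
  }
  ex <- tryCatch(estimate_sensitivity(pm, 1, method, aggregate),
                 norse_insufficient_support = function(e) NULL)
  ey <- tryCatch(estimate_sensitivity(pm, 2, method, aggregate),
                 norse_insufficient_support = function(e) NULL)
  if (is.null(ex) || is.null(ey)) return(bad)
  list(x_norse = ex$norse, y_norse = ey$norse,
       n_used = max(ex$n_used, ey$n_used))
}

#' Export a ranking table to CSV or JSON
#'
#' @param ranking a \code{norse_ranking} or \code{norse_ranking_2d}.
#' @param path output file (.csv or .json by extension).
#' @param what \code{"ranking"} (default), \code{"scores"} (long per-fit
#'   table) or \code{"per_sex"}.
#' @return the path, invisibly.
#' @export
write_ranking <- function(ranking, path, what = c("ranking", "scores",
                                                  "per_sex")) {
  what <- match.arg(what)
  df <- ranking[[what]]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
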