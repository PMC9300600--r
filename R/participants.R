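#' Participant table schema
#'
#' Analyses run on a plain data frame with these canonical columns (units:
#' cm, kg, years). Only \code{participant_id}, \code{sex} and \code{age} are
#' mandatory; any measurement or flag may be missing per participant.
#'
#' \itemize{
#'   \item \code{participant_id} opaque identifier
#'   \item \code{sex} \code{"male"} or \code{"female"}
#'   \item \code{age} years
#'   \item measurements: \code{weight}, \code{height}, \code{waist_circ},
#'     \code{hip_circ}, \code{thigh_circ}, \code{max_calf_circ},
#'     \code{bicep_circ}, \code{upper_arm_len}, \code{leg_len},
#'     \code{total_fat_mass}, \code{trunk_fat_mass}, \code{lean_mass}
#'   \item condition flags (0/1/NA): \code{hypertension}, \code{diabetes},
#'     \code{high_cholesterol}, \code{arthritis},
#'     \code{coronary_heart_disease}, \code{cancer}
#'   \item \code{smoker_flag} 0/1/NA
#' }
#'
#' @param table data frame to validate.
#' @return the validated table, invisibly classed as
#'   \code{participant_table}.
#' @export
participant_table <- function(table) {
  req <- c("participant_id", "sex", "age")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop_norse(paste("participant table lacks mandatory column(s):",
                     paste(missing_cols, collapse = ", ")),
               "norse_schema_error")
  }
  table$sex <- as.character(table$sex)
  bad_sex <- !is.na(table$sex) & !table$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop_norse("sex must be 'male' or 'female'", "norse_schema_error")
  }
  for (col in intersect(measurement_columns(), names(table))) {
    v <- table[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop_norse(sprintf("column '%s' has non-positive measurements", col),
                 "norse_schema_error")
    }
  }
  for (col in intersect(c(condition_columns(), "smoker_flag"), names(table))) {
    v <- table[[col]]
    if (any(!is.na(v) & !v %in% c(0, 1))) {
      stop_norse(sprintf("flag column '%s' must be 0, 1 or missing", col),
                 "norse_schema_error")
    }
  }
  class(table) <- unique(c("participant_table", class(table)))
  invisible(table)
}

measurement_columns <- function() {
  c("weight", "height", "waist_circ", "hip_circ", "thigh_circ",
    "max_calf_circ", "bicep_circ", "upper_arm_len", "leg_len",
    "total_fat_mass", "trunk_fat_mass", "lean_mass")
}

#' Names of the six built-in health conditions
#' @return character vector.
#' @export
condition_columns <- function() {
  c("hypertension", "arthritis", "diabetes", "high_cholesterol",
    "coronary_heart_disease", "cancer")
}

#' Analysis filter
#'
#' A pure row predicate bundling the population filters an analysis applies:
#' sex selection, adult age range, and named exclusion flags (e.g. dropping
#' smokers via \code{smoker_flag}). Applying a filter twice equals applying
#' it once.
#'
#' @param sex \code{"male"}, \code{"female"} or \code{NULL} for both.
#' @param age_range numeric length-2, inclusive bounds; default the adult
#'   range 20-110 years.
#' @param exclude_flags character vector of flag columns; rows with flag
#'   value 1 are removed (missing flag values are kept).
#' @return object of class \code{analysis_filter}.
#' @export
analysis_filter <- function(sex = NULL, age_range = c(20, 110),
                            exclude_flags = character()) {
  stopifnot(is.null(sex) || sex %in% c("male", "female"),
            length(age_range) == 2, age_range[1] <= age_range[2])
  structure(list(sex = sex, age_range = age_range,
                 exclude_flags = exclude_flags),
            class = "analysis_filter")
}

#' Apply an analysis filter
#'
#' @param table participant data frame.
#' @param filter an \code{\link{analysis_filter}}.
#' @param verbose log input/output row counts to stderr.
#' @return the filtered table.
#' @export
apply_filter <- function(table, filter, verbose = FALSE) {
  stopifnot(inherits(filter, "analysis_filter"))
  n0 <- nrow(table)
  keep <- !is.na(table$age) &
    table$age >= filter$age_range[1] & table$age <= filter$age_range[2]
  if (!is.null(filter$sex)) {
    keep <- keep & !is.na(table$sex) & table$sex == filter$sex
  }
  for (fl in filter$exclude_flags) {
    if (!fl %in% names(table)) {
      stop_norse(sprintf("exclusion flag '%s' not in table", fl),
                 "norse_schema_error")
    }
    keep <- keep & (is.na(table[[fl]]) | table[[fl]] != 1)
  }
  out <- table[keep, , drop = FALSE]
  if (verbose) {
    message(sprintf("filter: %d -> %d rows (sex=%s, age %g-%g%s)",
                    n0, nrow(out), filter$sex %||% "both",
                    filter$age_range[1], filter$age_range[2],
                    if (length(filter$exclude_flags))
                      paste0(", excluding ",
                             paste(filter$exclude_flags, collapse = "+"))
                    else ""))
  }
  out
}

#' Read a participant table from CSV (or SAS transport)
#'
#' Reads a participant-level file into the canonical schema. A mapping
#' config renames source columns and recodes questionnaire-style flags
#' (e.g. 1 = yes, 2 = no) to 0/1/NA. Files ending in \code{.xpt} are read
#' with \code{foreign::read.xport} when the \pkg{foreign} package is
#' available; the core path is plain CSV.
#'
#' @param path file path (.csv or .xpt).
#' @param mapping optional list with elements \code{columns} (named list:
#'   canonical name -> source name) and \code{flag_recode} (named list per
#'   flag column: list(yes = source value(s), no = source value(s)); any
#'   other source value becomes missing).
#' @param verbose log the row count.
#' @return a validated \code{participant_table} data frame.
#' @export
read_participants <- function(path, mapping = NULL, verbose = FALSE) {
  if (!file.exists(path)) {
    stop_norse(sprintf("file not found: %s", path), "norse_io_error")
  }
  if (grepl("\\.xpt$", path, ignore.case = TRUE)) {
    if (!requireNamespace("foreign", quietly = TRUE)) {
      stop_norse("reading .xpt requires the 'foreign' package",
                 "norse_io_error")
    }
    raw <- foreign::read.xport(path)
    names(raw) <- tolower(names(raw))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(mapping$columns)) {
    for (canon in names(mapping$columns)) {
      src <- mapping$columns[[canon]]
      if (!src %in% names(raw)) {
        stop_norse(sprintf("mapped source column '%s' (-> %s) not in file",
                           src, canon), "norse_io_error")
      }
      raw[[canon]] <- raw[[src]]
      if (src != canon) raw[[src]] <- NULL
    }
  }
  if (!is.null(mapping$sex_recode)) {
    sr <- mapping$sex_recode
    sx <- rep(NA_character_, nrow(raw))
    sx[raw$sex %in% sr$male] <- "male"
    sx[raw$sex %in% sr$female] <- "female"
    raw$sex <- sx
  }
  if (!is.null(mapping$flag_recode)) {
    for (col in names(mapping$flag_recode)) {
      rc <- mapping$flag_recode[[col]]
      v <- raw[[col]]
      out <- rep(NA_real_, length(v))
      out[v %in% rc$yes] <- 1
      out[v %in% rc$no] <- 0
      raw[[col]] <- out
    }
  }
  if (verbose) message(sprintf("read %d rows from %s", nrow(raw), path))
  participant_table(raw)
}

#' Write a participant table to CSV
#'
#' The written file round-trips through \code{\link{read_participants}}.
#'
#' @param table participant data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_participants <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
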