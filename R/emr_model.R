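#' @title Coded-EMR data model
#' @description
#' Every stage of the pipeline consumes the same four tables extracted
#' from a clinic EMR:
#'
#' * `patients`: `patient_id`, `clinic_id`, `birth_date`, `gender`
#'   (`M`/`F`/`other` or missing), `active_flag` (the EMR's own marker)
#' * `encounters`: `patient_id`, `encounter_date`
#' * `medications`: `patient_id`, `drug_code` (ATC, or missing for
#'   free-text/custom prescriptions), `drug_name`, `start_date`,
#'   `end_date` (missing = open-ended)
#' * `problems`: `patient_id`, `problem_code` (required), `code_system`
#'   (`ICD9`/`ICD10`), `documented_date`
#'
#' Missing values are empty fields in CSV and nulls in JSON-lines; an
#' empty `drug_code` means "uncoded".  `birth_date` is kept as the raw
#' stored string because one of the data-quality probes measures
#' *invalid* (present but unusable) dates of birth, which a strict parse
#' at load time would erase.
#' @name emr_model
NULL

emr_schema <- list(
  patients    = c("patient_id", "clinic_id", "birth_date", "gender", "active_flag"),
  encounters  = c("patient_id", "encounter_date"),
  medications = c("patient_id", "drug_code", "drug_name", "start_date", "end_date"),
  problems    = c("patient_id", "problem_code", "code_system", "documented_date")
)

atc_pattern <- "^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$"

empty_table <- function(table) {
  cols <- emr_schema[[table]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  coerce_table(df, table)
}

coerce_table <- function(df, table) {
  df <- df[, emr_schema[[table]], drop = FALSE]
  chr <- function(x) { x <- as.character(x); x[!is.na(x) & !nzchar(trimws(x))] <- NA; x }
  df$patient_id <- chr(df$patient_id)
  switch(table,
    patients = {
      df$clinic_id <- chr(df$clinic_id)
      df$birth_date <- chr(df$birth_date)   # raw; see ?emr_model
      df$gender <- chr(df$gender)
      af <- df$active_flag
      if (!is.logical(af)) af <- toupper(trimws(as.character(af))) %in% c("TRUE", "T", "1", "YES")
      df$active_flag <- af
    },
    encounters = df$encounter_date <- parse_iso_date(df$encounter_date),
    medications = {
      df$drug_code <- chr(df$drug_code)
      df$drug_name <- chr(df$drug_name)
      df$start_date <- parse_iso_date(df$start_date)
      df$end_date <- parse_iso_date(df$end_date)
    },
    problems = {
      df$problem_code <- chr(df$problem_code)
      df$code_system <- chr(df$code_system)
      df$documented_date <- parse_iso_date(df$documented_date)
    })
  rownames(df) <- NULL
  df
}

# Row-level invariant checks; returns character vector of reasons ("" = ok).
row_problems <- function(df, table, known_patients = NULL) {
  n <- nrow(df)
  why <- character(n)
  flag <- function(bad, reason) {
    bad <- bad & !nzchar(why)
    why[bad] <<- reason
  }
  flag(is.na(df$patient_id), "missing patient_id")
  switch(table,
    patients = {
      flag(duplicated(df$patient_id), "duplicate patient_id")
      flag(!is.na(df$gender) & !df$gender %in% c("M", "F", "other"),
           "gender not one of M/F/other")
    },
    encounters = flag(is.na(df$encounter_date), "invalid encounter_date"),
    medications = {
      flag(is.na(df$start_date), "invalid start_date")
      flag(!is.na(df$drug_code) & !grepl(atc_pattern, df$drug_code),
           "drug_code not a valid ATC code")
      flag(!is.na(df$start_date) & !is.na(df$end_date) & df$start_date > df$end_date,
           "start_date after end_date")
    },
    problems = {
      flag(is.na(df$problem_code), "missing problem_code")
      flag(is.na(df$code_system) | !df$code_system %in% c("ICD9", "ICD10"),
           "code_system not ICD9/ICD10")
      flag(is.na(df$documented_date), "invalid documented_date")
    })
  why
}

#' Assemble a validated per-clinic dataset
#'
#' Rows violating table invariants are *rejected with a per-row report*
#' (attached as the `"rejected"` attribute and surfaced via a warning),
#' never silently dropped.  Unresolvable foreign keys — encounter,
#' medication or problem rows whose `patient_id` names no patient — are a
#' harder failure and raise an error listing the offending ids, because
#' they indicate a broken extract rather than ordinary missingness.
#'
#' @param clinic_id Clinic identifier.
#' @param patients,encounters,medications,problems Data frames in the
#'   [emr_model] schema (missing tables default to empty).
#' @param arm Optional trial arm, `"control"` or `"intervention"`.
#' @param n_physicians Optional physician head-count; determines
#'   `size_stratum` (`"small"` below 4 physicians, else `"large"`).
#' @return An object of class `clinic_dataset`.
#' @export
clinic_dataset <- function(clinic_id, patients = NULL, encounters = NULL,
                           medications = NULL, problems = NULL,
                           arm = NA_character_, n_physicians = NA_integer_) {
  tabs <- list(patients = patients, encounters = encounters,
               medications = medications, problems = problems)
  rejected <- list()
  for (nm in names(tabs)) {
    df <- tabs[[nm]]
    if (is.null(df)) { tabs[[nm]] <- empty_table(nm); next }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    missing_cols <- setdiff(emr_schema[[nm]], names(df))
    if (length(missing_cols)) {
      stop("schema error in ", nm, ": missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df <- coerce_table(df, nm)
    why <- row_problems(df, nm)
    if (any(nzchar(why))) {
      bad <- nzchar(why)
      rej <- df[bad, , drop = FALSE]
      rej$reason <- why[bad]
      rejected[[nm]] <- rej
      df <- df[!bad, , drop = FALSE]
      rownames(df) <- NULL
    }
    tabs[[nm]] <- df
  }
  ids <- tabs$patients$patient_id
  for (nm in c("encounters", "medications", "problems")) {
    orphan <- setdiff(tabs[[nm]]$patient_id, ids)
    if (length(orphan)) {
      stop("referential error in ", nm, ": unknown patient_id(s) ",
           paste(utils::head(orphan, 10L), collapse = ", "),
           if (length(orphan) > 10L) " ..." else "", call. = FALSE)
    }
  }
  if (!is.na(arm)) arm <- match.arg(arm, c("control", "intervention"))
  n_physicians <- as.integer(n_physicians)
  size_stratum <- if (is.na(n_physicians)) NA_character_ else
    if (n_physicians < 4L) "small" else "large"
  ds <- structure(
    list(clinic_id = as.character(clinic_id),
         patients = tabs$patients, encounters = tabs$encounters,
         medications = tabs$medications, problems = tabs$problems,
         arm = arm, n_physicians = n_physicians, size_stratum = size_stratum),
    class = "clinic_dataset")
  if (length(rejected)) {
    attr(ds, "rejected") <- rejected
    warning(sprintf("clinic %s: rejected %d invalid row(s); see attr(x, 'rejected')",
                    ds$clinic_id, sum(vapply(rejected, nrow, 0L))), call. = FALSE)
  }
  ds
}

#' @export
print.clinic_dataset <- function(x, ...) {
  cat(sprintf("<clinic_dataset> %s%s\n", x$clinic_id,
              if (!is.na(x$arm)) paste0(" [", x$arm, ", ", x$size_stratum, "]") else ""))
  cat(sprintf("  patients: %d | encounters: %d | medications: %d | problems: %d\n",
              nrow(x$patients), nrow(x$encounters),
              nrow(x$medications), nrow(x$problems)))
  invisible(x)
}

table_paths <- function(dir, format) {
  ext <- if (format == "csv") ".csv" else ".jsonl"
  setNames(file.path(dir, paste0(names(emr_schema), ext)), names(emr_schema))
}

read_table_file <- function(path, table, format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                          check.names = FALSE)
  } else {
    con <- file(path, "r")
    on.exit(close(con))
    df <- jsonlite::stream_in(con, verbose = FALSE)
    if (nrow(df) == 0L) df <- as.data.frame(setNames(
      rep(list(character(0)), length(emr_schema[[table]])), emr_schema[[table]]))
  }
  missing_cols <- setdiff(emr_schema[[table]], names(df))
  if (length(missing_cols)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a clinic dataset from per-table files
#'
#' @param dir Directory containing `patients`, `encounters`, `medications`
#'   and `problems` files (`.csv` or `.jsonl` according to `format`).
#'   Alternatively pass `paths`, a named list/vector with one path per table.
#' @param clinic_id Clinic identifier (defaults to the directory name).
#' @param format `"csv"` or `"jsonl"` (JSON-lines with identical field names).
#' @param paths Optional explicit per-table paths, overriding `dir`.
#' @inheritParams clinic_dataset
#' @return A validated `clinic_dataset`; invalid rows are reported via the
#'   `"rejected"` attribute.
#' @export
read_clinic_dataset <- function(dir = NULL, clinic_id = NULL,
                                format = c("csv", "jsonl"), paths = NULL,
                                arm = NA_character_, n_physicians = NA_integer_) {
  format <- match.arg(format)
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- table_paths(dir, format)
    if (is.null(clinic_id)) clinic_id <- basename(normalizePath(dir, mustWork = FALSE))
  }
  paths <- as.list(paths)
  stopifnot(all(names(emr_schema) %in% names(paths)))
  if (is.null(clinic_id)) stop("clinic_id required when reading from explicit paths")
  tabs <- lapply(names(emr_schema), function(nm)
    read_table_file(paths[[nm]], nm, format))
  names(tabs) <- names(emr_schema)
  clinic_dataset(clinic_id, tabs$patients, tabs$encounters,
                 tabs$medications, tabs$problems,
                 arm = arm, n_physicians = n_physicians)
}

fmt_date_col <- function(x) {
  if (inherits(x, "Date")) format(x, "%Y-%m-%d") else as.character(x)
}

#' Write a clinic dataset to per-table files
#'
#' Inverse of [read_clinic_dataset()]: reading the written files
#' reproduces the dataset field-for-field.  Missing values are written as
#' empty fields (CSV) or nulls (JSON-lines), so a missing gender stays
#' missing rather than becoming a distinct empty-string category.
#'
#' @param ds A `clinic_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"jsonl"`.
#' @return Invisibly, the named vector of files written.
#' @export
write_clinic_dataset <- function(ds, dir, format = c("csv", "jsonl")) {
  stopifnot(inherits(ds, "clinic_dataset"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- table_paths(dir, format)
  for (nm in names(emr_schema)) {
    df <- ds[[nm]]
    for (col in names(df)) if (inherits(df[[col]], "Date")) df[[col]] <- fmt_date_col(df[[col]])
    if (format == "csv") {
      utils::write.csv(df, paths[[nm]], row.names = FALSE, na = "")
    } else {
      con <- file(paths[[nm]], "w")
      jsonlite::stream_out(df, con, verbose = FALSE)
      close(con)
    }
  }
  invisible(paths)
}
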