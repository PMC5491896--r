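#' @title Aggregate-only distributed queries
#' @description
#' Measurement runs *inside* each clinic; only aggregate answers — a
#' numerator/denominator pair per measure and window — ever cross the
#' clinic boundary, in the style of hQuery-type distributed query
#' networks.  The privacy contract is enforced by the shape of the
#' answer record itself: it has no slots for patient identifiers, birth
#' dates or any record-level field, so nothing patient-level *can* be
#' serialized.
#' @name aggregation
NULL

answer_row <- function(clinic_id, measure_id, window, numerator, denominator) {
  data.frame(clinic_id = clinic_id, measure_id = measure_id, window = window,
             numerator = as.integer(numerator), denominator = as.integer(denominator),
             stringsAsFactors = FALSE)
}

#' Compute a clinic's aggregate answers
#'
#' Runs [measure_pips()] for each window and [run_all_probes()] locally,
#' and serializes only aggregate numerator/denominator pairs: one row
#' per rule per window, a `"total"` row per window, and one row per
#' probe (window `"current"`, evaluated at `ref_date`).
#'
#' Small-cell suppression (masking numerators of 1-4) is available but
#' *off* by default; the study network did not suppress, but real
#' deployments often must.
#'
#' @param ds A `clinic_dataset`.
#' @param lib A `rule_library`.
#' @param windows List of [measurement_window()]s (e.g. [study_windows()]).
#' @param ref_date Reference date for the probe suite.
#' @param codesets Named list of [codeset]s.
#' @param suppress_small_cells If `TRUE`, numerators in 1..4 are masked
#'   to `NA` before anything leaves the clinic.
#' @return A data frame of aggregate answers with attributes `clinic_id`,
#'   `arm` and `library_version`.
#' @export
clinic_respond <- function(ds, lib, windows, ref_date,
                           codesets = default_codesets(),
                           suppress_small_cells = FALSE) {
  rows <- list()
  for (w in windows) {
    pc <- measure_pips(ds, lib, w)
    rows[[length(rows) + 1L]] <-
      answer_row(ds$clinic_id, pc$per_rule$rule_id, w$label,
                 pc$per_rule$fired, pc$per_rule$eligible)
    rows[[length(rows) + 1L]] <-
      answer_row(ds$clinic_id, "total", w$label,
                 pc$totals$numerator, pc$totals$denominator)
  }
  probes <- run_all_probes(ds, ref_date, codesets)
  rows[[length(rows) + 1L]] <-
    answer_row(ds$clinic_id, probes$probe_id, "current",
               probes$numerator, probes$denominator)
  out <- do.call(rbind, rows)
  if (suppress_small_cells) {
    out$numerator[out$numerator >= 1L & out$numerator <= 4L] <- NA_integer_
  }
  attr(out, "clinic_id") <- ds$clinic_id
  attr(out, "arm") <- ds$arm
  attr(out, "library_version") <- lib$version
  out
}

#' Write a clinic's answers to a JSON file
#'
#' @param answers Output of [clinic_respond()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_answers <- function(answers, path) {
  payload <- list(clinic_id = attr(answers, "clinic_id"),
                  arm = attr(answers, "arm"),
                  library_version = attr(answers, "library_version"),
                  answers = answers)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}

#' Collect clinic answer files into a hub view
#'
#' Groups answers by arm, clinic and window and forms arm-level totals by
#' *exact integer summation* of clinic answers (conservation: an arm
#' total is nothing but the sum of its clinics).  A duplicate
#' (clinic, measure, window) triple is an error — it would double-count.
#'
#' @param paths Character vector of answer-file paths, or a list of
#'   answer data frames from [clinic_respond()].
#' @param arms Optional named vector mapping clinic ids to arms, for
#'   answers that do not carry their arm.
#' @return An object of class `hub_collection` with elements `answers`
#'   (all rows, with `arm`), `arm_totals` (per arm x window x measure)
#'   and `provenance`.
#' @export
hub_collect <- function(paths, arms = NULL) {
  pieces <- lapply(paths, function(p) {
    if (is.character(p)) {
      payload <- jsonlite::read_json(p, simplifyVector = TRUE)
      ans <- payload$answers
      ans$numerator <- as.integer(ans$numerator)
      ans$denominator <- as.integer(ans$denominator)
      ans$arm <- if (!is.null(payload$arm)) payload$arm else NA_character_
      attr(ans, "library_version") <- payload$library_version
      ans
    } else {
      ans <- p
      ans$arm <- if (!is.null(attr(p, "arm"))) attr(p, "arm") else NA_character_
      ans
    }
  })
  versions <- unique(unlist(lapply(pieces, attr, "library_version")))
  answers <- do.call(rbind, lapply(pieces, function(x) {
    x[c("clinic_id", "measure_id", "window", "numerator", "denominator", "arm")]
  }))
  key <- paste(answers$clinic_id, answers$measure_id, answers$window, sep = "\r")
  if (anyDuplicated(key)) {
    d <- answers[duplicated(key), , drop = FALSE]
    stop("duplicate answer(s) for (clinic, measure, window): ",
         paste(utils::head(paste(d$clinic_id, d$measure_id, d$window, sep = "/"), 5L),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(arms)) {
    answers$arm <- ifelse(is.na(answers$arm),
                          unname(arms[answers$clinic_id]), answers$arm)
  }
  if (any(is.na(answers$arm))) {
    stop("arm unknown for clinic(s): ",
         paste(unique(answers$clinic_id[is.na(answers$arm)]), collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(cbind(numerator, denominator) ~ arm + window + measure_id,
                          data = answers, FUN = sum)
  structure(list(answers = answers,
                 arm_totals = agg,
                 provenance = list(library_version = versions,
                                   n_clinics = length(unique(answers$clinic_id)),
                                   collected_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "hub_collection")
}

#' @export
print.hub_collection <- function(x, ...) {
  tot <- x$arm_totals[x$arm_totals$measure_id == "total", , drop = FALSE]
  cat(sprintf("<hub_collection> %d clinics, rule library %s\n",
              x$provenance$n_clinics,
              paste(x$provenance$library_version, collapse = "/")))
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %-12s %-9s %6d / %-7d (%.2f%%)\n", tot$arm[i], tot$window[i],
                tot$numerator[i], tot$denominator[i],
                100 * tot$numerator[i] / tot$denominator[i]))
  }
  invisible(x)
}

#' Arm-level PIP counts in the shape the trial statistics consume
#'
#' @param hub A `hub_collection`.
#' @return Data frame with `clinic_id`, `arm`, `window`, `fired`,
#'   `eligible` — one row per clinic per measurement window.
#' @export
hub_pip_counts <- function(hub) {
  a <- hub$answers
  a <- a[a$measure_id == "total" & a$window %in% c("baseline", "treatment"), ,
         drop = FALSE]
  data.frame(clinic_id = a$clinic_id, arm = a$arm, window = a$window,
             fired = a$numerator, eligible = a$denominator,
             stringsAsFactors = FALSE)
}
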