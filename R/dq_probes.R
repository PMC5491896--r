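#' Patients calculated as active
#'
#' The EMR's own "active" flag is unreliable (clinics rarely deactivate
#' departed patients), so every data-quality probe restricts to patients
#' *calculated* as active: at least one encounter in the 24 months up to
#' and including `ref_date` (closed interval; see [months_before()] for
#' the month-arithmetic convention).
#'
#' @param ds A `clinic_dataset`.
#' @param ref_date Reference date (the study-end date, supplied
#'   explicitly for reproducibility — never "today").
#' @return Character vector of patient ids.
#' @export
calculated_active <- function(ds, ref_date) {
  ref_date <- parse_iso_date(ref_date)
  lo <- months_before(ref_date, 24)
  enc <- ds$encounters
  keep <- !is.na(enc$encounter_date) & enc$encounter_date >= lo &
    enc$encounter_date <= ref_date
  unique(enc$patient_id[keep])
}

current_meds <- function(ds, ref_date, patient_ids = NULL) {
  meds <- ds$medications
  cur <- !is.na(meds$start_date) & meds$start_date <= ref_date &
    (is.na(meds$end_date) | meds$end_date >= ref_date)
  meds <- meds[cur, , drop = FALSE]
  if (!is.null(patient_ids)) meds <- meds[meds$patient_id %in% patient_ids, , drop = FALSE]
  meds
}

recent_problems <- function(ds, ref_date, patient_ids = NULL, months = 12) {
  lo <- months_before(ref_date, months)
  probs <- ds$problems
  keep <- !is.na(probs$documented_date) & probs$documented_date >= lo &
    probs$documented_date <= ref_date
  probs <- probs[keep, , drop = FALSE]
  if (!is.null(patient_ids)) probs <- probs[probs$patient_id %in% patient_ids, , drop = FALSE]
  probs
}

# Invalid date of birth: present but unparsable, in the future relative
# to ref_date, or implying age > 120 years.  Disjoint from "no DOB".
invalid_dob <- function(birth_date, ref_date) {
  raw <- as.character(birth_date)
  present <- !is.na(raw) & nzchar(trimws(raw))
  d <- parse_iso_date(raw)
  age <- age_at(raw, ref_date)
  present & (is.na(d) | d > ref_date | (!is.na(age) & age > 120))
}

concordance_probe <- function(ds, ref_date, active_ids, drug_cs, dx_cs, codesets) {
  meds <- current_meds(ds, ref_date, active_ids)
  on_drug <- unique(meds$patient_id[code_matches(meds$drug_code, codesets[[drug_cs]])])
  probs <- ds$problems[ds$problems$patient_id %in% on_drug &
                         !is.na(ds$problems$documented_date) &
                         ds$problems$documented_date <= ref_date, , drop = FALSE]
  with_dx <- unique(probs$patient_id[code_matches(probs$problem_code, codesets[[dx_cs]])])
  c(num = length(with_dx), den = length(on_drug))
}

dq_probe_descriptions <- c(
  dq1  = "% of flagged-active patients with >=1 encounter in the past 24 months",
  dq2  = "% of calculated-active patients with no documented gender",
  dq3  = "% of calculated-active patients with an invalid date of birth",
  dq4  = "% of calculated-active patients with no documented date of birth",
  dq5  = "% of current medications that are coded",
  dq6  = "% of calculated-active patients with no current medications",
  dq7  = "% of problems documented in the past 12 months with a diagnostic code",
  dq8  = "% of calculated-active patients aged >=12 with >=1 problem documented in the past 12 months",
  dq9  = "% of calculated-active patients aged >=12 with diabetes on the problem list",
  dq10 = "% of patients currently on tiotropium with COPD on the problem list",
  dq11 = "% of patients currently on levothyroxine with hypothyroidism on the problem list",
  dq12 = "% of patients currently on an anti-gout medication with gout on the problem list"
)

#' Run one data-quality probe
#'
#' The twelve probes assess completeness and concordance of the three
#' EMR areas the rules depend on — demographics, medications and the
#' problem list (see `dq_probe_descriptions` via [run_all_probes()]).
#' They measure documentation, not clinical correctness: a probe cannot
#' tell an undiagnosed patient from an undocumented one.
#'
#' Probe id `dq13` is reserved and not implemented.
#'
#' @param ds A `clinic_dataset`.
#' @param probe_id One of `"dq1"` ... `"dq12"`.
#' @param ref_date Reference date (study end), supplied explicitly.
#' @param codesets Named list of [codeset]s; the defaults supply the
#'   diabetes/COPD/hypothyroidism/gout and drug sets that probes
#'   dq9-dq12 need.
#' @return One-row data frame: `probe_id`, `clinic_id`, `numerator`,
#'   `denominator`, `percentage` (`NA` when the denominator is zero),
#'   `description`.
#' @export
run_probe <- function(ds, probe_id, ref_date, codesets = default_codesets()) {
  if (!probe_id %in% names(dq_probe_descriptions)) {
    stop("unknown probe_id '", probe_id, "'; valid ids: ",
         paste(names(dq_probe_descriptions), collapse = ", "), call. = FALSE)
  }
  ref_date <- parse_iso_date(ref_date)
  active_ids <- calculated_active(ds, ref_date)
  pts <- ds$patients
  act <- pts[pts$patient_id %in% active_ids, , drop = FALSE]
  age <- age_at(act$birth_date, ref_date)
  ge12 <- act$patient_id[!is.na(age) & age >= 12]
  nd <- switch(probe_id,
    dq1 = {
      flagged <- pts$patient_id[pts$active_flag %in% TRUE]
      c(num = sum(flagged %in% active_ids), den = length(flagged))
    },
    dq2 = c(num = sum(is.na(act$gender)), den = nrow(act)),
    dq3 = c(num = sum(invalid_dob(act$birth_date, ref_date)), den = nrow(act)),
    dq4 = c(num = sum(is.na(act$birth_date) | !nzchar(trimws(act$birth_date))),
            den = nrow(act)),
    dq5 = {
      meds <- current_meds(ds, ref_date, active_ids)
      c(num = sum(!is.na(meds$drug_code)), den = nrow(meds))
    },
    dq6 = {
      meds <- current_meds(ds, ref_date, active_ids)
      c(num = sum(!active_ids %in% meds$patient_id), den = length(active_ids))
    },
    dq7 = {
      probs <- recent_problems(ds, ref_date, active_ids)
      c(num = sum(!is.na(probs$problem_code)), den = nrow(probs))
    },
    dq8 = {
      probs <- recent_problems(ds, ref_date, ge12)
      c(num = sum(ge12 %in% probs$patient_id), den = length(ge12))
    },
    dq9 = {
      probs <- ds$problems[ds$problems$patient_id %in% ge12 &
                             !is.na(ds$problems$documented_date) &
                             ds$problems$documented_date <= ref_date, , drop = FALSE]
      dm <- unique(probs$patient_id[code_matches(probs$problem_code,
                                                 codesets[["diabetes"]])])
      c(num = length(dm), den = length(ge12))
    },
    dq10 = concordance_probe(ds, ref_date, active_ids, "tiotropium", "copd", codesets),
    dq11 = concordance_probe(ds, ref_date, active_ids, "levothyroxine",
                             "hypothyroidism", codesets),
    dq12 = concordance_probe(ds, ref_date, active_ids, "anti_gout", "gout", codesets))
  data.frame(probe_id = probe_id,
             clinic_id = ds$clinic_id,
             numerator = unname(nd["num"]),
             denominator = unname(nd["den"]),
             percentage = if (nd["den"] > 0) unname(100 * nd["num"] / nd["den"]) else NA_real_,
             description = unname(dq_probe_descriptions[probe_id]),
             stringsAsFactors = FALSE)
}

#' Run the full probe suite
#'
#' Runs dq1..dq12 and returns one row per probe, always all twelve.
#'
#' @inheritParams run_probe
#' @return A data frame of class `dq_report` (12 rows).
#' @export
run_all_probes <- function(ds, ref_date, codesets = default_codesets()) {
  out <- do.call(rbind, lapply(names(dq_probe_descriptions), run_probe,
                               ds = ds, ref_date = ref_date, codesets = codesets))
  class(out) <- c("dq_report", class(out))
  out
}

#' @export
print.dq_report <- function(x, ...) {
  cat(sprintf("Data-quality probes, clinic %s\n", x$clinic_id[1L]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s %5s  (%d/%d)  %s\n", x$probe_id[i],
                if (is.na(x$percentage[i])) "--" else sprintf("%.1f", x$percentage[i]),
                x$numerator[i], x$denominator[i], x$description[i]))
  }
  invisible(x)
}

#' Render a per-clinic probe summary as markdown
#'
#' The trial returned each clinic an individualized summary of its data
#' quality; this produces the same artifact for a probe report.
#'
#' @param report A `dq_report` from [run_all_probes()].
#' @return A single markdown string.
#' @export
format_dq_report <- function(report) {
  lines <- c(sprintf("## Data quality, clinic %s", report$clinic_id[1L]), "",
             "| probe | % | n/N | description |", "|---|---|---|---|",
             sprintf("| %s | %s | %d/%d | %s |", report$probe_id,
                     ifelse(is.na(report$percentage), "--",
                            sprintf("%.1f", report$percentage)),
                     report$numerator, report$denominator, report$description))
  paste(lines, collapse = "\n")
}
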