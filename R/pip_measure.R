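#' Define a measurement window
#'
#' Windows are closed on both ends.  The default span is 16 weeks
#' (112 days): the trial measured a 16-week baseline window immediately
#' preceding the study and a 16-week treatment window.
#'
#' @param start First day (ISO string or `Date`).
#' @param end Last day; defaults to `start + weeks*7 - 1`.
#' @param weeks Span in weeks when `end` is not given.
#' @param label `"baseline"` or `"treatment"`.
#' @return An object of class `measurement_window`.
#' @export
measurement_window <- function(start, end = NULL, weeks = 16,
                               label = c("baseline", "treatment")) {
  label <- match.arg(label)
  start <- parse_iso_date(start)
  stopifnot(!is.na(start))
  end <- if (is.null(end)) start + weeks * 7L - 1L else parse_iso_date(end)
  stopifnot(!is.na(end), end >= start)
  structure(list(start = start, end = end, label = label),
            class = "measurement_window")
}

#' The trial's paired 16-week windows
#'
#' Convenience constructor: a treatment window ending at `ref_date` and a
#' baseline window of equal length immediately before it.
#'
#' @param ref_date Last day of the treatment window (the study-end date).
#' @param weeks Window span in weeks (default 16).
#' @return Named list with `baseline` and `treatment` windows.
#' @export
study_windows <- function(ref_date, weeks = 16) {
  ref_date <- parse_iso_date(ref_date)
  span <- weeks * 7L
  list(
    baseline = measurement_window(ref_date - 2L * span + 1L,
                                  ref_date - span, label = "baseline"),
    treatment = measurement_window(ref_date - span + 1L, ref_date,
                                   label = "treatment"))
}

# Vectorized evaluation environment: for each codeset referenced by the
# library, a logical per-patient indicator for "on a matching coded
# medication active in the window" and "has a matching problem documented
# by window end"; plus age at window end and gender.
build_eval_env <- function(ds, lib, window) {
  pts <- ds$patients$patient_id
  idx <- function(ids) match(ids, pts)
  meds <- ds$medications
  act <- !is.na(meds$start_date) & meds$start_date <= window$end &
    (is.na(meds$end_date) | meds$end_date >= window$start) & !is.na(meds$drug_code)
  meds <- meds[act, , drop = FALSE]
  probs <- ds$problems
  probs <- probs[!is.na(probs$documented_date) & probs$documented_date <= window$end, ,
                 drop = FALSE]
  cs_names <- unique(unlist(lapply(lib$rules, function(r)
    c(pred_codesets(r$scope), pred_codesets(r$fire)))))
  on_med <- has_problem <- list()
  for (nm in cs_names) {
    cs <- lib$codesets[[nm]]
    v <- rep(FALSE, length(pts))
    hit <- idx(meds$patient_id[code_matches(meds$drug_code, cs)])
    v[hit] <- TRUE
    on_med[[nm]] <- v
    v <- rep(FALSE, length(pts))
    hit <- idx(probs$patient_id[code_matches(probs$problem_code, cs)])
    v[hit] <- TRUE
    has_problem[[nm]] <- v
  }
  list(n = length(pts), patient_id = pts,
       age = age_at(ds$patients$birth_date, window$end),
       gender = ds$patients$gender,
       on_med = on_med, has_problem = has_problem)
}

eval_pred_vec <- function(pred, env) {
  switch(pred$op,
    age_ge = !is.na(env$age) & env$age >= pred$years,
    age_lt = !is.na(env$age) & env$age < pred$years,
    gender_is = !is.na(env$gender) & env$gender == pred$value,
    on_med = env$on_med[[pred$codeset]],
    has_problem = env$has_problem[[pred$codeset]],
    all_of = Reduce(`&`, lapply(pred$args, eval_pred_vec, env = env),
                    rep(TRUE, env$n)),
    any_of = Reduce(`|`, lapply(pred$args, eval_pred_vec, env = env),
                    rep(FALSE, env$n)),
    not = !eval_pred_vec(pred$args[[1L]], env),
    stop("unknown predicate op '", pred$op, "'", call. = FALSE))
}

#' Measure PIPs for one clinic and window
#'
#' For each enabled rule and each patient with at least one encounter in
#' the window, the patient counts toward the rule's *eligible* tally iff
#' the scope predicate holds ("possible PIP": the opportunity condition —
#' age plus the anchor drug-or-disease condition, not merely age 65+),
#' and toward *fired* iff the full fire predicate holds.  A (patient,
#' rule) pair contributes at most once per window no matter how many
#' encounters or prescriptions occur: counting is patient-level, because
#' event-level denominators cannot be audited from aggregate answers.
#'
#' The overall denominator is the sum of eligible pairs across rules and
#' the numerator the sum of fired pairs; their ratio (as a percentage) is
#' the clinic's PIP rate for the window, the trial's primary outcome.
#'
#' @param ds A `clinic_dataset`.
#' @param lib A `rule_library`.
#' @param window A [measurement_window()].
#' @return An object of class `pip_counts`: per-rule eligible/fired
#'   counts, totals, `patients_seen` (distinct patients with an encounter
#'   in the window) and `patients_at_risk` (those in scope of >= 1 rule).
#' @export
measure_pips <- function(ds, lib, window) {
  stopifnot(inherits(ds, "clinic_dataset"), inherits(lib, "rule_library"),
            inherits(window, "measurement_window"))
  rules <- enabled_rules(lib)
  enc <- ds$encounters
  seen_ids <- unique(enc$patient_id[!is.na(enc$encounter_date) &
                                      enc$encounter_date >= window$start &
                                      enc$encounter_date <= window$end])
  env <- build_eval_env(ds, lib, window)
  seen <- env$patient_id %in% seen_ids
  at_risk <- rep(FALSE, env$n)
  per_rule <- data.frame(rule_id = vapply(rules, `[[`, "", "rule_id"),
                         eligible = 0L, fired = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    sc <- eval_pred_vec(rules[[i]]$scope, env) & seen
    fi <- eval_pred_vec(rules[[i]]$fire, env) & seen
    fi <- fi & sc  # guaranteed by load-time validation; kept as a belt
    per_rule$eligible[i] <- sum(sc)
    per_rule$fired[i] <- sum(fi)
    at_risk <- at_risk | sc
  }
  structure(list(clinic_id = ds$clinic_id,
                 window = window,
                 per_rule = per_rule,
                 totals = list(denominator = sum(per_rule$eligible),
                               numerator = sum(per_rule$fired)),
                 patients_seen = length(seen_ids),
                 patients_at_risk = sum(at_risk)),
            class = "pip_counts")
}

#' @export
print.pip_counts <- function(x, ...) {
  r <- pip_rate(x)
  cat(sprintf("<pip_counts> clinic %s, %s window %s..%s\n", x$clinic_id,
              x$window$label, format(x$window$start), format(x$window$end)))
  cat(sprintf("  PIPs %d / possible %d (%s) | patients seen %d, at risk %d\n",
              x$totals$numerator, x$totals$denominator,
              if (is.na(r)) "rate undefined" else sprintf("%.2f%%", r),
              x$patients_seen, x$patients_at_risk))
  invisible(x)
}

#' PIP rate as a percentage
#'
#' `100 * numerator / denominator`, kept at full precision; the value is
#' *missing* (not zero, not an error) when the denominator is zero —
#' a clinic with no eligible (patient, rule) pairs has no defined rate.
#'
#' @param x A `pip_counts` object, or a numerator when `denominator`
#'   is supplied directly.
#' @param denominator Optional denominator for the two-argument form.
#' @return Numeric percentage or `NA`.
#' @examples
#' pip_rate(138, 5308)     # 2.6 (to 1 d.p.): control baseline
#' pip_rate(768, 18668)    # 4.11 (to 2 d.p.): intervention treatment
#' @export
pip_rate <- function(x, denominator = NULL) {
  if (inherits(x, "pip_counts")) {
    num <- x$totals$numerator
    den <- x$totals$denominator
  } else {
    num <- x
    den <- denominator
  }
  ifelse(den > 0, 100 * num / den, NA_real_)
}
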