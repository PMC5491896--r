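#' @title The prescribing-rule predicate language
#' @description
#' Rules are written in a deliberately small predicate language over one
#' patient's coded records in a time window:
#'
#' * `AGE_GE(years)` / `AGE_LT(years)` — age at window end
#' * `ON_MED(codeset)` — a coded medication matching the set is active at
#'   some point in the window
#' * `HAS_PROBLEM(codeset)` — a problem-list entry matching the set is
#'   documented at any time up to window end (problem lists are status
#'   registers, not events, so problems are cumulative)
#' * `GENDER_IS(value)` — documented gender equals `value`
#' * `ALL_OF`, `ANY_OF`, `NOT` — boolean combination
#'
#' There is *no* dose-threshold and *no* duration predicate: criteria that
#' need cumulative prescription duration or dose arithmetic are
#' unrepresentable by construction, mirroring the subset of STOPP
#' criteria that simple EMR rule engines can carry.
#'
#' Atoms over absent data evaluate to `FALSE`, never to an error: a
#' patient whose only matching prescription is uncoded free text is
#' invisible to `ON_MED`.  This is the mechanism by which poor data
#' quality silently suppresses alerts, and the package keeps it explicit
#' and testable.
#' @name rule_dsl
NULL

pred_atom_ops <- c("age_ge", "age_lt", "on_med", "has_problem", "gender_is")
pred_comb_ops <- c("all_of", "any_of", "not")

#' Predicate constructors
#'
#' Build predicates programmatically; [load_rule_library()] builds the
#' same structures from YAML/JSON.
#'
#' @param years Age threshold in whole years.
#' @param codeset Name of a code set (resolved against the library's
#'   code-set collection at load/evaluation time).
#' @param value Gender value (`"M"`, `"F"`, `"other"`).
#' @param ... Component predicates.
#' @param pred A predicate to negate.
#' @return A predicate (a tagged list of class `stopp_predicate`).
#' @name predicates
NULL

new_pred <- function(op, ...) {
  structure(c(list(op = op), list(...)), class = "stopp_predicate")
}

#' @rdname predicates
#' @export
pred_age_ge <- function(years) new_pred("age_ge", years = as.integer(years))
#' @rdname predicates
#' @export
pred_age_lt <- function(years) new_pred("age_lt", years = as.integer(years))
#' @rdname predicates
#' @export
pred_on_med <- function(codeset) new_pred("on_med", codeset = as.character(codeset))
#' @rdname predicates
#' @export
pred_has_problem <- function(codeset) new_pred("has_problem", codeset = as.character(codeset))
#' @rdname predicates
#' @export
pred_gender_is <- function(value) new_pred("gender_is", value = as.character(value))
#' @rdname predicates
#' @export
pred_all_of <- function(...) new_pred("all_of", args = unname(list(...)))
#' @rdname predicates
#' @export
pred_any_of <- function(...) new_pred("any_of", args = unname(list(...)))
#' @rdname predicates
#' @export
pred_not <- function(pred) new_pred("not", args = list(pred))

# Parse the nested tagged-object form used in rule files, e.g.
#   {all_of: [{age_ge: 65}, {on_med: benzodiazepines}]}
parse_predicate <- function(x) {
  if (inherits(x, "stopp_predicate")) return(x)
  if (!is.list(x) || length(x) != 1L || is.null(names(x))) {
    stop("malformed predicate: expected a single tagged object", call. = FALSE)
  }
  op <- names(x)
  body <- x[[1L]]
  switch(op,
    age_ge = pred_age_ge(body),
    age_lt = pred_age_lt(body),
    on_med = pred_on_med(body),
    has_problem = pred_has_problem(body),
    gender_is = pred_gender_is(body),
    all_of = do.call(pred_all_of, lapply(body, parse_predicate)),
    any_of = do.call(pred_any_of, lapply(body, parse_predicate)),
    not = pred_not(parse_predicate(if (is.list(body) && is.null(names(body)) &&
                                       length(body) == 1L) body[[1L]] else body)),
    stop("unknown predicate operator '", op, "'", call. = FALSE))
}

# Canonical comparable form (drops classes/attribute noise).
pred_canonical <- function(p) {
  if (p$op %in% pred_atom_ops) return(unclass(p)[c("op", setdiff(names(p), c("op")))])
  list(op = p$op, args = lapply(p$args, pred_canonical))
}

pred_conjuncts <- function(p) {
  if (p$op == "all_of") p$args else list(p)
}

# TRUE iff every conjunct of `scope` appears (structurally) among the
# conjuncts of `fire` — i.e. fire is expressed as ALL_OF(scope, extra).
pred_contains_scope <- function(fire, scope) {
  fc <- lapply(pred_conjuncts(fire), pred_canonical)
  all(vapply(pred_conjuncts(scope), function(s) {
    sc <- pred_canonical(s)
    any(vapply(fc, identical, logical(1), sc))
  }, logical(1)))
}

pred_codesets <- function(p) {
  if (p$op %in% c("on_med", "has_problem")) return(p$codeset)
  if (p$op %in% pred_comb_ops) return(unique(unlist(lapply(p$args, pred_codesets))))
  character(0)
}

#' Load and validate a rule library
#'
#' A rule is a `rule_id`, an alert `title`, a `scope` predicate (the
#' opportunity condition: the patient *could* trigger this criterion) and
#' a `fire` predicate (the full condition: the prescription is
#' potentially inappropriate).  The same file drives both the per-patient
#' engine and the measurement queries, so alert logic and outcome
#' measurement cannot drift apart.
#'
#' Load-time validation enforces, for every rule, that `fire` is
#' structurally `ALL_OF(scope, extra)` — so firing always implies being
#' in scope — and that every referenced code-set name resolves.
#'
#' @param path Rule file (YAML or JSON).
#' @param codesets Named list of [codeset]s used to resolve references;
#'   defaults to the bundled fixture.
#' @return An object of class `rule_library`.
#' @seealso [default_rule_library()] for the shipped 40-rule default.
#' @export
load_rule_library <- function(path, codesets = default_codesets()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rules <- lapply(raw$rules, function(r) {
    stopifnot(!is.null(r$rule_id), !is.null(r$title))
    scope <- parse_predicate(r$scope)
    fire <- parse_predicate(r$fire)
    if (!pred_contains_scope(fire, scope)) {
      stop("rule '", r$rule_id,
           "': fire is not ALL_OF(scope, ...); every scope conjunct must ",
           "appear in fire", call. = FALSE)
    }
    for (cs in unique(c(pred_codesets(scope), pred_codesets(fire)))) {
      if (!cs %in% names(codesets)) {
        stop("rule '", r$rule_id, "': unknown codeset '", cs, "'", call. = FALSE)
      }
    }
    list(rule_id = r$rule_id, title = r$title, scope = scope, fire = fire,
         enabled = if (is.null(r$enabled)) TRUE else isTRUE(r$enabled))
  })
  ids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(rules = rules,
                 version = if (is.null(raw$version)) "unversioned" else raw$version,
                 codesets = codesets),
            class = "rule_library")
}

#' @export
print.rule_library <- function(x, ...) {
  en <- sum(vapply(x$rules, `[[`, TRUE, "enabled"))
  cat(sprintf("<rule_library> version %s: %d rules (%d enabled)\n",
              x$version, length(x$rules), en))
  invisible(x)
}

#' The shipped default rule library
#'
#' Loads the bundled library of 40 enabled prescribing rules.  The rules
#' are an implementer's reconstruction *in kind* of the STOPP v1/v2
#' subset expressible in the restricted DSL (drug-disease, drug-drug-class
#' and age-conditioned criteria; no dose or duration logic): each entry
#' notes the STOPP item it is modelled on, but the library is engine
#' fixture content, not clinical guidance, and the published trial did
#' not enumerate its exact 40 rules.
#'
#' @inheritParams load_rule_library
#' @return A `rule_library` with exactly 40 enabled rules.
#' @export
default_rule_library <- function(codesets = default_codesets()) {
  load_rule_library(system.file("extdata", "stopp40.yaml", package = "stoppcds",
                                mustWork = TRUE),
                    codesets = codesets)
}

enabled_rules <- function(lib) Filter(function(r) isTRUE(r$enabled), lib$rules)

#' One patient's evaluation context
#'
#' Restricts a clinic dataset to a single patient and time window, in the
#' form [evaluate_predicate()] consumes.  A medication is *active in the
#' window* iff `start_date <= window_end` and (`end_date` missing or
#' `end_date >= window_start`) — plain interval overlap, the standard
#' currency convention.  Problems count if documented on or before window
#' end.  Age is taken at window end.
#'
#' @param ds A `clinic_dataset`.
#' @param patient_id Patient identifier.
#' @param window A [measurement_window()] (or any list with `start`/`end`).
#' @param codesets Named list of [codeset]s.
#' @return A list with `age`, `gender`, `med_codes`, `problem_codes`,
#'   `codesets`.
#' @export
patient_context <- function(ds, patient_id, window,
                            codesets = default_codesets()) {
  p <- ds$patients[ds$patients$patient_id == patient_id, , drop = FALSE]
  if (nrow(p) == 0L) stop("unknown patient_id: ", patient_id, call. = FALSE)
  meds <- ds$medications[ds$medications$patient_id == patient_id, , drop = FALSE]
  act <- !is.na(meds$start_date) & meds$start_date <= window$end &
    (is.na(meds$end_date) | meds$end_date >= window$start)
  probs <- ds$problems[ds$problems$patient_id == patient_id, , drop = FALSE]
  doc <- !is.na(probs$documented_date) & probs$documented_date <= window$end
  list(age = age_at(p$birth_date[1L], window$end),
       gender = p$gender[1L],
       med_codes = meds$drug_code[act & !is.na(meds$drug_code)],
       problem_codes = probs$problem_code[doc],
       codesets = codesets)
}

#' Evaluate a predicate for one patient
#'
#' Pure boolean evaluation against a [patient_context()].  Atoms over
#' missing data are `FALSE` (see [rule_dsl]); consequently
#' `NOT(HAS_PROBLEM(x))` is `TRUE` for a patient with an empty problem
#' list — absence of evidence fires "without a documented history of"
#' criteria, exactly as a coded-data engine must behave.
#'
#' @param pred A predicate (see [predicates]).
#' @param ctx A [patient_context()].
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_predicate <- function(pred, ctx) {
  stopifnot(inherits(pred, "stopp_predicate"))
  switch(pred$op,
    age_ge = !is.na(ctx$age) && ctx$age >= pred$years,
    age_lt = !is.na(ctx$age) && ctx$age < pred$years,
    gender_is = !is.na(ctx$gender) && ctx$gender == pred$value,
    on_med = {
      cs <- ctx$codesets[[pred$codeset]]
      if (is.null(cs)) stop("unknown codeset '", pred$codeset, "'", call. = FALSE)
      any(code_matches(ctx$med_codes, cs))
    },
    has_problem = {
      cs <- ctx$codesets[[pred$codeset]]
      if (is.null(cs)) stop("unknown codeset '", pred$codeset, "'", call. = FALSE)
      any(code_matches(ctx$problem_codes, cs))
    },
    all_of = all(vapply(pred$args, evaluate_predicate, logical(1), ctx = ctx)),
    any_of = any(vapply(pred$args, evaluate_predicate, logical(1), ctx = ctx)),
    not = !evaluate_predicate(pred$args[[1L]], ctx),
    stop("unknown predicate op '", pred$op, "'", call. = FALSE))
}
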