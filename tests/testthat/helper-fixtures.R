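# Shared fixtures: tiny constructed clinics, a miniature rule library,
# a random-clinic builder, and an independent brute-force PIP evaluator
# (written from scratch here, on purpose: it is the oracle the engine is
# checked against and shares no code with it).

REF <- as.Date("2015-10-02")
WIN <- measurement_window("2015-06-13", weeks = 16, label = "treatment")

mini_lib <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    'version: "mini"',
    "rules:",
    "  - rule_id: M1",
    "    title: Benzodiazepine with a history of falls",
    "    scope: {all_of: [{age_ge: 65}, {on_med: benzodiazepines}]}",
    paste0("    fire:  {all_of: [{age_ge: 65}, {on_med: benzodiazepines},",
           " {has_problem: falls_history}]}")), path)
  load_rule_library(path)
}

# One 70-year-old on a coded benzodiazepine with a documented fall,
# seen once inside WIN: the constructed-certainty patient.
certain_clinic <- function(clinic_id = "c1") {
  clinic_dataset(
    clinic_id,
    patients = data.frame(patient_id = "p1", clinic_id = clinic_id,
                          birth_date = "1945-01-15", gender = "F",
                          active_flag = TRUE),
    encounters = data.frame(patient_id = "p1", encounter_date = "2015-07-01"),
    medications = data.frame(patient_id = "p1", drug_code = "N05BA01",
                             drug_name = "lorazepam", start_date = "2015-01-01",
                             end_date = NA),
    problems = data.frame(patient_id = "p1", problem_code = "E888",
                          code_system = "ICD9", documented_date = "2014-03-01"))
}

# Random clinic exercising the full DSL surface: codes drawn from the
# shipped rule code sets plus junk, uncoded meds, missing demographics,
# records straddling the window boundaries.
random_clinic <- function(seed, n = 200, clinic_id = "rc") {
  set.seed(seed)
  cs <- default_codesets()
  atc_pool <- c(vapply(cs[vapply(cs, function(x) x$system == "ATC", TRUE)],
                       stoppcds:::codeset_example_code, ""),
                "C10AA01", "A02BC01")
  icd_pool <- c(vapply(cs[vapply(cs, function(x) x$system != "ATC", TRUE)],
                       stoppcds:::codeset_example_code, ""),
                "V70.0", "724.2")
  pid <- sprintf("%s-p%03d", clinic_id, seq_len(n))
  age <- sample(40:95, n, replace = TRUE)
  bd <- format(REF - round(age * 365.25) - sample(0:300, n, TRUE), "%Y-%m-%d")
  bd[runif(n) < 0.05] <- NA
  gender <- sample(c("M", "F", NA), n, replace = TRUE, prob = c(.47, .47, .06))
  patients <- data.frame(patient_id = pid, clinic_id = clinic_id,
                         birth_date = bd, gender = gender, active_flag = TRUE)
  n_enc <- rpois(n, 1.2)
  encounters <- data.frame(
    patient_id = rep(pid, n_enc),
    encounter_date = format(REF - sample(0:400, sum(n_enc), TRUE), "%Y-%m-%d"))
  n_med <- rpois(n, 2.5)
  m <- sum(n_med)
  code <- sample(atc_pool, m, replace = TRUE)
  code[runif(m) < 0.2] <- NA
  start <- REF - sample(0:500, m, TRUE)
  end <- start + sample(30:400, m, TRUE)
  end[runif(m) < 0.5] <- NA
  medications <- data.frame(patient_id = rep(pid, n_med), drug_code = code,
                            drug_name = "x", start_date = format(start),
                            end_date = format(end))
  n_pr <- rpois(n, 1.0)
  k <- sum(n_pr)
  problems <- if (k) data.frame(
    patient_id = rep(pid, n_pr),
    problem_code = sample(icd_pool, k, replace = TRUE),
    code_system = "ICD9",
    documented_date = format(REF - sample(0:1200, k, TRUE))) else NULL
  clinic_dataset(clinic_id, patients, encounters, medications, problems)
}

# ---- independent brute-force evaluator ------------------------------

bf_match <- function(code, prefixes) {
  if (is.na(code)) return(FALSE)
  code <- toupper(trimws(code))
  for (p in prefixes) {
    if (nchar(code) >= nchar(p) && substr(code, 1, nchar(p)) == p) return(TRUE)
  }
  FALSE
}

bf_eval <- function(pred, age, gender, meds, probs, csets) {
  op <- pred$op
  if (op == "age_ge") return(!is.na(age) && age >= pred$years)
  if (op == "age_lt") return(!is.na(age) && age < pred$years)
  if (op == "gender_is") return(!is.na(gender) && gender == pred$value)
  if (op == "on_med") {
    pref <- csets[[pred$codeset]]$prefixes
    for (code in meds) if (bf_match(code, pref)) return(TRUE)
    return(FALSE)
  }
  if (op == "has_problem") {
    pref <- csets[[pred$codeset]]$prefixes
    for (code in probs) if (bf_match(code, pref)) return(TRUE)
    return(FALSE)
  }
  if (op == "all_of") {
    for (a in pred$args) if (!bf_eval(a, age, gender, meds, probs, csets)) return(FALSE)
    return(TRUE)
  }
  if (op == "any_of") {
    for (a in pred$args) if (bf_eval(a, age, gender, meds, probs, csets)) return(TRUE)
    return(FALSE)
  }
  if (op == "not") return(!bf_eval(pred$args[[1]], age, gender, meds, probs, csets))
  stop("bf_eval: unknown op ", op)
}

# Naive patients x rules loop over one clinic and window.
bf_measure <- function(ds, lib, window) {
  csets <- lib$codesets
  rules <- Filter(function(r) isTRUE(r$enabled), lib$rules)
  enc <- ds$encounters
  seen <- unique(enc$patient_id[!is.na(enc$encounter_date) &
                                  enc$encounter_date >= window$start &
                                  enc$encounter_date <= window$end])
  eligible <- fired <- setNames(integer(length(rules)),
                                vapply(rules, `[[`, "", "rule_id"))
  at_risk <- 0L
  for (pidv in seen) {
    p <- ds$patients[ds$patients$patient_id == pidv, ]
    age <- age_at(p$birth_date, window$end)
    meds <- ds$medications[ds$medications$patient_id == pidv, ]
    ok <- !is.na(meds$start_date) & meds$start_date <= window$end &
      (is.na(meds$end_date) | meds$end_date >= window$start)
    med_codes <- meds$drug_code[ok]
    pr <- ds$problems[ds$problems$patient_id == pidv, ]
    prob_codes <- pr$problem_code[!is.na(pr$documented_date) &
                                    pr$documented_date <= window$end]
    any_scope <- FALSE
    for (r in rules) {
      if (bf_eval(r$scope, age, p$gender, med_codes, prob_codes, csets)) {
        eligible[r$rule_id] <- eligible[r$rule_id] + 1L
        any_scope <- TRUE
        if (bf_eval(r$fire, age, p$gender, med_codes, prob_codes, csets)) {
          fired[r$rule_id] <- fired[r$rule_id] + 1L
        }
      }
    }
    if (any_scope) at_risk <- at_risk + 1L
  }
  list(eligible = eligible, fired = fired,
       denominator = sum(eligible), numerator = sum(fired),
       patients_seen = length(seen), patients_at_risk = at_risk)
}

arm_knob <- stoppcds:::arm_val
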