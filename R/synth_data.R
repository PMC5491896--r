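#' @title Synthetic EMR study populations
#' @description
#' A seeded generator of multi-clinic primary-care populations carrying
#' the statistical structure the trial analysis assumes *and* the
#' data-quality pathologies the probe suite measures.  Every knob in
#' [generator_config()] has a matching probe or measurement, so the
#' generator doubles as a calibration rig: generate at a known knob
#' value, measure, and the estimate must come back.
#'
#' PIP situations are planted abstractly per (patient, rule) through
#' scope and fire probabilities, then materialized as concrete coded
#' records; realistic longitudinal prescribing is out of scope because
#' the measurement consumes only scope/fire events.  Data-quality
#' corruption (uncoded medications, missing demographics) is applied to
#' the materialized records, so an uncoded anchor prescription destroys
#' a planted PIP's *detectability* without changing its truth — the
#' generator records both, which makes alert suppression by poor data
#' quality itself measurable.
#' @name synth_data
NULL

# Background code pools: deliberately disjoint from every code set the
# rules and probes reference, so background records never create or
# complete a planted PIP (asserted by test).
bg_atc_pool <- c("C10AA01", "A10BA02", "C09AA05", "R06AE07",
                 "J01CA04", "N02BE01", "B03BB01", "L04AX03")
bg_icd_pool <- c("V70.0", "460", "724.2", "477.9", "372.30", "682.9", "786.2")

arm_val <- function(x, arm) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && arm %in% names(x)) return(unname(x[[arm]]))
  stop("per-arm parameter must be a scalar or named for '", arm, "'",
       call. = FALSE)
}

#' Generator configuration
#'
#' Every proportion knob accepts either a scalar or a named vector
#' `c(control = ..., intervention = ...)`.  All randomness flows from
#' the single `seed`: identical configs produce byte-identical datasets.
#'
#' @param seed Integer RNG seed.
#' @param n_clinics_per_arm Clinics per arm.
#' @param physicians_per_clinic Integer vector recycled across the
#'   clinic roster; drives the small/large size stratum (< 4 physicians
#'   is small) used to stratify randomization.
#' @param patients_per_clinic Flagged-active patients per clinic.
#' @param ref_date Study-end date (ISO string); the treatment window is
#'   the 16 weeks ending here and baseline the 16 weeks before that.
#' @param frac_age_ge65 Proportion of patients aged 65+.
#' @param frac_child Proportion aged under 12 (probe dq8/dq9 exclusions).
#' @param ghost_active_frac Proportion flagged active with no encounter
#'   in 24 months (complement of probe dq1).
#' @param encounters_per_patient_per_window Poisson mean encounters per
#'   16-week window for calculated-active patients.
#' @param meds_per_elderly_patient,meds_per_adult_patient Mean current
#'   medication count for medicated patients.
#' @param coded_med_frac Probability a prescription is coded (dq5); the
#'   remainder are free-text "custom" medications invisible to rules.
#' @param no_current_meds_frac Proportion of calculated-active patients
#'   with no current medications (dq6).
#' @param problem_list_usage Proportion of calculated-active patients
#'   aged 12+ with a problem documented in the past 12 months (dq8).
#' @param diabetes_frac Proportion with diabetes on the problem list (dq9).
#' @param concordance Named vector/list `tiotropium`, `levothyroxine`,
#'   `anti_gout`: P(matching problem documented | on the drug)
#'   (dq10-dq12); each entry may itself be per-arm.
#' @param concordance_drug_prevalence P(on each concordance drug) among
#'   medicated calculated-active patients.
#' @param missing_gender_frac,missing_dob_frac,invalid_dob_frac
#'   Demographic corruption rates (dq2-dq4).
#' @param scope_prevalence Per anchor drug class: P(a medicated elderly
#'   patient is on it), i.e. P(in scope) per rule.  With 40 rules at the
#'   default 0.125 an at-risk patient is eligible for about 5 rules,
#'   matching the observed possible-PIPs-per-patient ratio.
#' @param pip_prevalence P(fire | in scope) per (patient, rule) pair.
#' @param treatment_effect Multiplicative change of `pip_prevalence` in
#'   the intervention arm's treatment window (1 = null).  Only
#'   drug-drug criteria can lose their fire status mid-study (a
#'   documented problem cannot be un-documented), so effects below
#'   `1 - share of drug-drug rules` are not realizable and rejected.
#' @return A validated `generator_config` (a list).
#' @export
generator_config <- function(seed = 1L,
                             n_clinics_per_arm = 4L,
                             physicians_per_clinic = c(2L, 4L, 3L, 5L),
                             patients_per_clinic = 1000L,
                             ref_date = "2015-10-02",
                             frac_age_ge65 = 0.12,
                             frac_child = 0.08,
                             ghost_active_frac = 0.3,
                             encounters_per_patient_per_window = 0.5,
                             meds_per_elderly_patient = 4,
                             meds_per_adult_patient = 2,
                             coded_med_frac = 0.8,
                             no_current_meds_frac = 0.5,
                             problem_list_usage = 0.2,
                             diabetes_frac = 0.05,
                             concordance = c(tiotropium = 0.5,
                                             levothyroxine = 0.25,
                                             anti_gout = 0.1),
                             concordance_drug_prevalence = 0.03,
                             missing_gender_frac = 0.005,
                             missing_dob_frac = 0,
                             invalid_dob_frac = 0,
                             scope_prevalence = 0.125,
                             pip_prevalence = 0.05,
                             treatment_effect = 1) {
  cfg <- list(seed = as.integer(seed),
              n_clinics_per_arm = as.integer(n_clinics_per_arm),
              physicians_per_clinic = as.integer(physicians_per_clinic),
              patients_per_clinic = as.integer(patients_per_clinic),
              ref_date = as.character(ref_date),
              frac_age_ge65 = frac_age_ge65, frac_child = frac_child,
              ghost_active_frac = ghost_active_frac,
              encounters_per_patient_per_window = encounters_per_patient_per_window,
              meds_per_elderly_patient = meds_per_elderly_patient,
              meds_per_adult_patient = meds_per_adult_patient,
              coded_med_frac = coded_med_frac,
              no_current_meds_frac = no_current_meds_frac,
              problem_list_usage = problem_list_usage,
              diabetes_frac = diabetes_frac,
              concordance = concordance,
              concordance_drug_prevalence = concordance_drug_prevalence,
              missing_gender_frac = missing_gender_frac,
              missing_dob_frac = missing_dob_frac,
              invalid_dob_frac = invalid_dob_frac,
              scope_prevalence = scope_prevalence,
              pip_prevalence = pip_prevalence,
              treatment_effect = treatment_effect)
  props <- c("frac_age_ge65", "frac_child", "ghost_active_frac",
             "coded_med_frac", "no_current_meds_frac", "problem_list_usage",
             "diabetes_frac", "concordance_drug_prevalence",
             "missing_gender_frac", "missing_dob_frac", "invalid_dob_frac",
             "scope_prevalence", "pip_prevalence")
  for (nm in props) {
    v <- unlist(cfg[[nm]])
    if (any(v < 0 | v > 1)) stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (any(unlist(cfg$concordance) < 0 | unlist(cfg$concordance) > 1)) {
    stop("'concordance' entries must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(parse_iso_date(cfg$ref_date))) stop("invalid ref_date", call. = FALSE)
  if (cfg$treatment_effect < 0 || cfg$treatment_effect > 1) {
    stop("treatment_effect must lie in [0, 1] (1 = no effect)", call. = FALSE)
  }
  for (arm in c("control", "intervention")) {
    if (arm_val(cfg$no_current_meds_frac, arm) >= 1 &&
        any(unlist(cfg$pip_prevalence) > 0) &&
        any(unlist(cfg$scope_prevalence) > 0)) {
      stop("impossible config: no_current_meds_frac = 1 leaves no patients ",
           "that planted PIPs (which require medications) can attach to",
           call. = FALSE)
    }
  }
  structure(cfg, class = "generator_config")
}

#' Paper-like generator configuration
#'
#' The bundled calibration: knobs set to the observed per-arm field
#' values of the trial the package models — medication coding 82.3% /
#' 79.0%, problem-list usage 12.3% / 3.5%, ghost-active complement of
#' 35.7% / 28.6%, elderly share 19% / 5%, PIP rates 4.0% / 2.6%
#' (intervention / control throughout) — with `treatment_effect = 1`,
#' i.e. a null study.  Clinic count and size strata follow the trial's
#' 8 practices; the per-clinic population defaults to a scaled-down
#' 2,000 flagged-active patients so a full study generates in seconds.
#'
#' @param patients_per_clinic Flagged-active patients per clinic.
#' @param seed RNG seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
paperlike_config <- function(patients_per_clinic = 2000L, seed = 1L, ...) {
  args <- list(
    seed = seed,
    n_clinics_per_arm = 4L,
    physicians_per_clinic = c(2L, 4L, 3L, 5L, 3L, 5L, 2L, 4L),
    patients_per_clinic = patients_per_clinic,
    frac_age_ge65 = c(control = 0.05, intervention = 0.19),
    ghost_active_frac = c(control = 1 - 0.286, intervention = 1 - 0.357),
    coded_med_frac = c(control = 0.790, intervention = 0.823),
    no_current_meds_frac = c(control = 0.846, intervention = 0.699),
    problem_list_usage = c(control = 0.035, intervention = 0.123),
    diabetes_frac = c(control = 0.035, intervention = 0.053),
    concordance = list(tiotropium = c(control = 0.727, intervention = 0.481),
                       levothyroxine = c(control = 0.243, intervention = 0.227),
                       anti_gout = c(control = 0.122, intervention = 0.084)),
    missing_gender_frac = c(control = 0.005, intervention = 0.003),
    missing_dob_frac = 0,
    invalid_dob_frac = 0,
    scope_prevalence = 0.125,
    pip_prevalence = c(control = 0.026, intervention = 0.040),
    treatment_effect = 1)
  user <- list(...)
  args[names(user)] <- user
  do.call(generator_config, args)
}

# Planting template extracted from a rule library: every enabled rule
# must be ALL_OF(AGE_GE(a), ON_MED(anchor)) firing with exactly one
# extra atom — HAS_PROBLEM, NOT(HAS_PROBLEM) or ON_MED.  The generator
# (not the engine) requires this shape; the DSL itself is richer.
rule_plant_info <- function(lib) {
  info <- lapply(enabled_rules(lib), function(r) {
    sc <- pred_conjuncts(r$scope)
    ops <- vapply(sc, `[[`, "", "op")
    if (!identical(sort(ops), c("age_ge", "on_med"))) {
      stop("generator requires scope = ALL_OF(AGE_GE, ON_MED(anchor)); ",
           "rule '", r$rule_id, "' does not fit", call. = FALSE)
    }
    anchor <- sc[[which(ops == "on_med")]]$codeset
    fc <- pred_conjuncts(r$fire)
    extra <- Filter(function(p) !any(vapply(lapply(sc, pred_canonical),
                                            identical, logical(1),
                                            pred_canonical(p))), fc)
    if (length(extra) != 1L) {
      stop("generator requires exactly one extra conjunct in fire; rule '",
           r$rule_id, "' has ", length(extra), call. = FALSE)
    }
    e <- extra[[1L]]
    etype <- switch(e$op,
                    has_problem = "problem",
                    on_med = "med",
                    not = {
                      if (e$args[[1L]]$op != "has_problem")
                        stop("rule '", r$rule_id, "': NOT only supported over ",
                             "HAS_PROBLEM in the generator", call. = FALSE)
                      "not_problem"
                    },
                    stop("rule '", r$rule_id, "': unsupported extra '", e$op, "'",
                         call. = FALSE))
    ecs <- if (etype == "not_problem") e$args[[1L]]$codeset else e$codeset
    list(rule_id = r$rule_id, anchor = anchor, extra_type = etype,
         extra_codeset = ecs, extra_key = paste(etype, ecs, sep = ":"))
  })
  info
}

rand_days <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# One synthetic clinic.  Returns the clinic_dataset plus the planted
# (pre-corruption) truth per rule and window.
gen_clinic <- function(cfg, clinic_id, arm, n_physicians, lib, plant,
                       codesets, ref_date) {
  n <- cfg$patients_per_clinic
  wins <- study_windows(ref_date)
  base_start <- wins$baseline$start
  base_end <- wins$baseline$end
  v <- function(nm) arm_val(cfg[[nm]], arm)

  pid <- paste0(clinic_id, "-", sprintf("%07x", sample.int(2^28 - 1, n)))
  ghost <- stats::runif(n) < v("ghost_active_frac")
  ucat <- stats::runif(n)
  is_eld <- ucat < v("frac_age_ge65")
  is_child <- !is_eld & ucat < v("frac_age_ge65") + cfg$frac_child
  age <- integer(n)
  age[is_eld] <- 64L + sample.int(30L, sum(is_eld), replace = TRUE)
  age[is_child] <- sample.int(11L, sum(is_child), replace = TRUE)
  adult <- !is_eld & !is_child
  age[adult] <- 11L + sample.int(53L, sum(adult), replace = TRUE)
  dob <- (base_end - 365L) - round(age * 365.25) - rand_days(n, 0, 299)
  birth_raw <- format(dob, "%Y-%m-%d")
  u <- stats::runif(n)
  birth_raw[u < cfg$missing_dob_frac] <- NA
  birth_raw[u >= cfg$missing_dob_frac &
              u < cfg$missing_dob_frac + cfg$invalid_dob_frac] <- "2199-12-31"
  gender <- sample(c("M", "F"), n, replace = TRUE)
  gender[stats::runif(n) < v("missing_gender_frac")] <- NA

  # Encounters: calculated-active patients are guaranteed an encounter
  # in the past 24 months; ghosts get at most an older one.
  lam <- cfg$encounters_per_patient_per_window
  nb <- ifelse(ghost, 0L, stats::rpois(n, lam))
  nt <- ifelse(ghost, 0L, stats::rpois(n, lam))
  nh <- ifelse(ghost, 0L, stats::rpois(n, lam * (730 - 224) / 112))
  none <- !ghost & nb + nt + nh == 0L
  nh[none] <- 1L
  old_enc <- ghost & stats::runif(n) < 0.5
  enc_pid <- c(rep(pid, nb), rep(pid, nt), rep(pid, nh), pid[old_enc])
  enc_date <- c(base_start + rand_days(sum(nb), 0, 111),
                wins$treatment$start + rand_days(sum(nt), 0, 111),
                ref_date - rand_days(sum(nh), 224, 730),
                ref_date - rand_days(sum(old_enc), 731, 1400))

  calc_active <- !ghost
  age_ref <- age_at(birth_raw, ref_date)           # observable age
  age_true_base <- age_at(format(dob, "%Y-%m-%d"), base_end)  # true age

  has_meds <- calc_active & stats::runif(n) < (1 - v("no_current_meds_frac"))

  med_pid <- character(0); med_code <- character(0); med_name <- character(0)
  med_start <- as.Date(character(0)); med_end <- as.Date(character(0))
  add_meds <- function(ids, codes, names_, starts, ends, coded) {
    codes[!coded] <- NA
    names_[!coded] <- "custom medication (free text)"
    med_pid <<- c(med_pid, ids); med_code <<- c(med_code, codes)
    med_name <<- c(med_name, names_)
    med_start <<- c(med_start, starts); med_end <<- c(med_end, ends)
  }
  prob_pid <- character(0); prob_code <- character(0)
  prob_date <- as.Date(character(0))
  add_problems <- function(ids, codes, dates) {
    prob_pid <<- c(prob_pid, ids); prob_code <<- c(prob_code, codes)
    prob_date <<- c(prob_date, dates)
  }

  # Background current medications (codes disjoint from rule/probe sets).
  midx <- which(has_meds)
  lam_m <- ifelse(age[midx] >= 65L, cfg$meds_per_elderly_patient,
                  cfg$meds_per_adult_patient)
  n_meds <- 1L + stats::rpois(length(midx), pmax(lam_m - 1, 0.1))
  ids <- rep(pid[midx], n_meds)
  tot <- length(ids)
  ends <- ref_date + rand_days(tot, 10, 200)
  ends[stats::runif(tot) < 0.7] <- NA
  add_meds(ids, sample(bg_atc_pool, tot, replace = TRUE),
           rep("background medication", tot),
           ref_date - rand_days(tot, 30, 700), ends,
           coded = stats::runif(tot) < v("coded_med_frac"))

  # Concordance drugs and their (possibly undocumented) diagnoses.
  conc_pairs <- list(tiotropium = "copd", levothyroxine = "hypothyroidism",
                     anti_gout = "gout")
  for (drug in names(conc_pairs)) {
    on <- has_meds & stats::runif(n) < cfg$concordance_drug_prevalence
    k <- sum(on)
    if (k) {
      add_meds(pid[on], rep(codeset_example_code(codesets[[drug]]), k),
               rep(drug, k), ref_date - rand_days(k, 60, 700),
               rep(as.Date(NA), k), coded = stats::runif(k) < v("coded_med_frac"))
      conc <- arm_val(cfg$concordance[[drug]], arm)
      dx <- on & stats::runif(n) < conc
      if (any(dx)) {
        add_problems(pid[dx],
                     rep(codeset_example_code(codesets[[conc_pairs[[drug]]]]), sum(dx)),
                     ref_date - rand_days(sum(dx), 400, 1500))
      }
    }
  }

  # Background problem-list usage (recent) and diabetes (any time).
  elig12 <- calc_active & !is.na(age_ref) & age_ref >= 12L
  recent <- elig12 & stats::runif(n) < v("problem_list_usage")
  k <- sum(recent)
  if (k) {
    npr <- 1L + stats::rpois(k, 0.4)
    add_problems(rep(pid[recent], npr),
                 sample(bg_icd_pool, sum(npr), replace = TRUE),
                 ref_date - rand_days(sum(npr), 0, 364))
  }
  dm <- elig12 & stats::runif(n) < v("diabetes_frac")
  if (any(dm)) {
    add_problems(pid[dm], rep("250.00", sum(dm)),
                 ref_date - rand_days(sum(dm), 400, 1500))
  }

  # ---- PIP planting -------------------------------------------------
  plantpop <- calc_active & has_meds & !is.na(age_true_base) & age_true_base >= 65L
  families <- unique(vapply(plant, `[[`, "", "anchor"))
  planted <- list()
  for (f in families) {
    sel <- plantpop & stats::runif(n) < arm_val(cfg$scope_prevalence, arm)
    planted[[f]] <- sel
    k <- sum(sel)
    if (k) {
      add_meds(pid[sel], rep(codeset_example_code(codesets[[f]]), k),
               rep(paste0(f, " (anchor)"), k),
               base_start - rand_days(k, 30, 400), rep(as.Date(NA), k),
               coded = stats::runif(k) < v("coded_med_frac"))
    }
  }

  p_fire <- arm_val(cfg$pip_prevalence, arm)
  extras <- unique(vapply(plant, `[[`, "", "extra_key"))
  med_share <- mean(vapply(plant, `[[`, "", "extra_type") == "med")
  eff <- cfg$treatment_effect
  apply_eff <- arm == "intervention" && eff < 1
  if (apply_eff) {
    if (med_share == 0 || eff < 1 - med_share) {
      stop("treatment_effect ", eff, " is not realizable: only drug-drug ",
           "criteria (share ", signif(med_share, 3), ") can stop firing ",
           "mid-study", call. = FALSE)
    }
  }
  e_adj <- if (apply_eff) 1 - (1 - eff) / med_share else 1
  fired_base <- fired_treat <- list()
  for (ek in extras) {
    spec <- plant[[which(vapply(plant, `[[`, "", "extra_key") == ek)[1L]]]
    fams <- unique(vapply(Filter(function(x) x$extra_key == ek, plant),
                          `[[`, "", "anchor"))
    needs <- Reduce(`|`, planted[fams], rep(FALSE, n))
    fb <- stats::runif(n) < p_fire
    ft <- if (apply_eff && spec$extra_type == "med") fb & (stats::runif(n) < e_adj) else fb
    fired_base[[ek]] <- fb
    fired_treat[[ek]] <- ft
    ecs <- codesets[[spec$extra_codeset]]
    if (spec$extra_type == "problem") {
      sel <- needs & fb
      if (any(sel)) add_problems(pid[sel], rep(codeset_example_code(ecs), sum(sel)),
                                 ref_date - rand_days(sum(sel), 400, 1500))
    } else if (spec$extra_type == "not_problem") {
      sel <- needs & !fb   # non-fired patients carry the documented history
      if (any(sel)) add_problems(pid[sel], rep(codeset_example_code(ecs), sum(sel)),
                                 ref_date - rand_days(sum(sel), 400, 1500))
    } else {  # med extra: the flagged co-prescription is kept coded so the
              # conditional fire rate equals the knob; anchors still corrupt
      both <- needs & fb & ft
      if (any(both)) add_meds(pid[both], rep(codeset_example_code(ecs), sum(both)),
                              rep(spec$extra_codeset, sum(both)),
                              base_start - rand_days(sum(both), 30, 400),
                              rep(as.Date(NA), sum(both)), coded = rep(TRUE, sum(both)))
      stopped <- needs & fb & !ft
      if (any(stopped)) add_meds(pid[stopped],
                                 rep(codeset_example_code(ecs), sum(stopped)),
                                 rep(spec$extra_codeset, sum(stopped)),
                                 base_start - rand_days(sum(stopped), 30, 400),
                                 base_end - rand_days(sum(stopped), 0, 50),
                                 coded = rep(TRUE, sum(stopped)))
    }
  }

  # ---- truth (planted, pre-corruption) ------------------------------
  in_base <- nb > 0L
  in_treat <- nt > 0L
  truth <- do.call(rbind, lapply(plant, function(r) {
    sel <- planted[[r$anchor]]
    fb <- fired_base[[r$extra_key]]
    ft <- fired_treat[[r$extra_key]]
    if (r$extra_type == "not_problem") { fb <- fb; ft <- ft }  # same semantics
    data.frame(clinic_id = clinic_id, rule_id = r$rule_id,
               window = c("baseline", "treatment"),
               true_eligible = c(sum(sel & in_base), sum(sel & in_treat)),
               true_fired = c(sum(sel & in_base & fb), sum(sel & in_treat & ft)),
               stringsAsFactors = FALSE)
  }))

  patients <- data.frame(patient_id = pid, clinic_id = clinic_id,
                         birth_date = birth_raw, gender = gender,
                         active_flag = TRUE, stringsAsFactors = FALSE)
  encounters <- data.frame(patient_id = enc_pid,
                           encounter_date = format(enc_date, "%Y-%m-%d"),
                           stringsAsFactors = FALSE)
  medications <- data.frame(patient_id = med_pid, drug_code = med_code,
                            drug_name = med_name,
                            start_date = format(med_start, "%Y-%m-%d"),
                            end_date = format(med_end, "%Y-%m-%d"),
                            stringsAsFactors = FALSE)
  problems <- data.frame(patient_id = prob_pid, problem_code = prob_code,
                         code_system = "ICD9",
                         documented_date = format(prob_date, "%Y-%m-%d"),
                         stringsAsFactors = FALSE)
  if (nrow(problems) == 0L) problems <- NULL
  if (nrow(medications) == 0L) medications <- NULL
  list(ds = clinic_dataset(clinic_id, patients, encounters, medications,
                           problems, arm = arm, n_physicians = n_physicians),
       truth = truth)
}

#' Generate a full synthetic study
#'
#' Builds the clinic roster, stratifies it into small and large clinics
#' by physician count, randomizes arms within strata, and generates each
#' clinic population per the configuration.  All randomness derives from
#' `cfg$seed`; the caller's RNG state is restored on exit.
#'
#' @param cfg A [generator_config()].
#' @param lib Rule library whose scope/fire situations are planted;
#'   defaults to the shipped 40-rule library.
#' @param codesets Code sets used for materializing records.
#' @return An object of class `study_dataset`: `clinics` (named list of
#'   `clinic_dataset`s), `windows`, `ref_date`, `truth` (planted
#'   pre-corruption counts per clinic, rule and window) and `config`.
#' @export
generate_study <- function(cfg, lib = default_rule_library(),
                           codesets = default_codesets()) {
  stopifnot(inherits(cfg, "generator_config"))
  plant <- rule_plant_info(lib)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  ref_date <- parse_iso_date(cfg$ref_date)
  n_cl <- 2L * cfg$n_clinics_per_arm
  phys <- rep_len(cfg$physicians_per_clinic, n_cl)
  roster <- data.frame(clinic_id = sprintf("CL%02d", seq_len(n_cl)),
                       n_physicians = phys,
                       stratum = ifelse(phys < 4L, "small", "large"),
                       arm = NA_character_, stringsAsFactors = FALSE)
  for (st in unique(roster$stratum)) {
    idx <- sample(which(roster$stratum == st))
    half <- ceiling(length(idx) / 2)
    roster$arm[idx[seq_len(half)]] <- "intervention"
    roster$arm[idx[-seq_len(half)]] <- "control"
  }
  # balance arms overall if strata sizes were odd
  n_int <- sum(roster$arm == "intervention")
  if (n_int != cfg$n_clinics_per_arm) {
    flip_from <- if (n_int > cfg$n_clinics_per_arm) "intervention" else "control"
    flip_to <- setdiff(c("intervention", "control"), flip_from)
    k <- abs(n_int - cfg$n_clinics_per_arm)
    roster$arm[sample(which(roster$arm == flip_from), k)] <- flip_to
  }
  clinics <- list()
  truth <- list()
  for (i in seq_len(n_cl)) {
    g <- gen_clinic(cfg, roster$clinic_id[i], roster$arm[i],
                    roster$n_physicians[i], lib, plant, codesets, ref_date)
    clinics[[roster$clinic_id[i]]] <- g$ds
    truth[[i]] <- g$truth
  }
  structure(list(clinics = clinics,
                 roster = roster,
                 windows = study_windows(ref_date),
                 ref_date = ref_date,
                 truth = do.call(rbind, truth),
                 config = cfg),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d clinics (%d per arm), ref date %s\n",
              length(x$clinics), x$config$n_clinics_per_arm,
              format(x$ref_date)))
  print(x$roster, row.names = FALSE)
  invisible(x)
}

#' Write a study to disk
#'
#' One sub-directory of CSVs per clinic, a `clinics.csv` roster,
#' `truth.json` (planted pre-corruption counts) and `config.json`.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$roster, file.path(dir, "clinics.csv"), row.names = FALSE)
  for (ds in study$clinics) {
    write_clinic_dataset(ds, file.path(dir, ds$clinic_id))
  }
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(unclass(study$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Study directory.
#' @return A `study_dataset` (without planted truth unless present).
#' @export
read_study <- function(dir) {
  roster <- utils::read.csv(file.path(dir, "clinics.csv"),
                            stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  clinics <- list()
  for (i in seq_len(nrow(roster))) {
    clinics[[roster$clinic_id[i]]] <-
      read_clinic_dataset(file.path(dir, roster$clinic_id[i]),
                          clinic_id = roster$clinic_id[i],
                          arm = roster$arm[i],
                          n_physicians = roster$n_physicians[i])
  }
  truth_path <- file.path(dir, "truth.json")
  structure(list(clinics = clinics, roster = roster,
                 windows = study_windows(cfg$ref_date),
                 ref_date = parse_iso_date(cfg$ref_date),
                 truth = if (file.exists(truth_path))
                   jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL,
                 config = cfg),
            class = "study_dataset")
}

#' Simulate clinic-level PIP counts directly
#'
#' The counts-level core of the generator: draws per-clinic eligible
#' (patient, rule) pair totals and binomially fired counts without
#' materializing patient records.  This is what calibration studies of
#' [gee_test()] run on — the test consumes exactly this clinic-by-window
#' aggregate, so record materialization adds nothing but time there.
#'
#' @param n_clinics_per_arm Clinics per arm.
#' @param eligible_per_clinic Scalar or per-arm named vector: Poisson
#'   mean of eligible pairs per clinic per window.
#' @param rate Scalar or per-arm named vector: P(fire | eligible).
#' @param treatment_effect Multiplier on the intervention arm's rate in
#'   the treatment window.
#' @return A counts data frame suitable for [gee_test()].
#' @export
simulate_trial_counts <- function(n_clinics_per_arm = 4L,
                                  eligible_per_clinic = c(control = 1327,
                                                          intervention = 4583),
                                  rate = c(control = 0.026,
                                           intervention = 0.040),
                                  treatment_effect = 1) {
  rows <- list()
  for (arm in c("control", "intervention")) {
    nn <- arm_val(eligible_per_clinic, arm)
    pp <- arm_val(rate, arm)
    for (k in seq_len(n_clinics_per_arm)) {
      for (w in c("baseline", "treatment")) {
        p <- pp * if (arm == "intervention" && w == "treatment") treatment_effect else 1
        ne <- stats::rpois(1L, nn)
        rows[[length(rows) + 1L]] <- data.frame(
          clinic_id = paste0(substr(arm, 1, 3), k), arm = arm, window = w,
          fired = stats::rbinom(1L, ne, p), eligible = ne,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
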