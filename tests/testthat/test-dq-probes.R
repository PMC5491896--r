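# A clinic with exactly controlled medication coding: n_coded of n_total
# current medications carry an ATC code.
coded_frac_clinic <- function(n_total, n_coded) {
  pid <- sprintf("m%04d", seq_len(n_total))
  clinic_dataset("dqc",
    patients = data.frame(patient_id = pid, clinic_id = "dqc",
                          birth_date = "1950-01-01", gender = "F",
                          active_flag = TRUE),
    encounters = data.frame(patient_id = pid, encounter_date = "2015-08-01"),
    medications = data.frame(
      patient_id = pid,
      drug_code = c(rep("C10AA01", n_coded), rep(NA, n_total - n_coded)),
      drug_name = "rx", start_date = "2015-01-01", end_date = NA),
    problems = data.frame(patient_id = pid[1], problem_code = "V70.0",
                          code_system = "ICD9", documented_date = "2015-06-01"))
}

test_that("calculated-active uses a closed 24-month lookback", {
  lo <- months_before(REF, 24)   # exactly 24 months before REF
  ds <- clinic_dataset("ca",
    patients = data.frame(patient_id = c("in", "out", "flagged"),
                          clinic_id = "ca", birth_date = "1950-01-01",
                          gender = "M", active_flag = TRUE),
    encounters = data.frame(patient_id = c("in", "out"),
                            encounter_date = format(c(lo, lo - 1))))
  act <- calculated_active(ds, REF)
  expect_identical(sort(act), "in")
  # the flagged-active patient with no recent encounter is dq1's complement
  r <- run_probe(ds, "dq1", REF)
  expect_equal(r$percentage, 100 / 3)
  # empty encounter table
  expect_length(calculated_active(clinic_dataset("e"), REF), 0L)
})

test_that("dq5 is exact on a clinic built with 823 coded of 1000 meds", {
  r <- run_probe(coded_frac_clinic(1000, 823), "dq5", REF)
  expect_identical(r$numerator, 823L)
  expect_identical(r$denominator, 1000L)
  expect_equal(round(r$percentage, 1), 82.3)
})

test_that("dq7 is 100% whenever any recent problems exist (codes are required)", {
  r <- run_probe(coded_frac_clinic(10, 5), "dq7", REF)
  expect_equal(r$percentage, 100)
  r2 <- run_probe(random_clinic(123, 100), "dq7", REF)
  expect_true(is.na(r2$percentage) || r2$percentage == 100)
})

test_that("concordance probes go missing, not zero, on an empty denominator", {
  r <- run_probe(coded_frac_clinic(10, 5), "dq10", REF)
  expect_identical(r$denominator, 0L)
  expect_true(is.na(r$percentage))
})

test_that("unknown probe ids name the valid ones", {
  expect_error(run_probe(coded_frac_clinic(2, 1), "dq13", REF), "dq12")
})

test_that("the suite always returns 12 probes with percentages in [0, 100]", {
  for (s in c(8, 9)) {
    rep <- run_all_probes(random_clinic(s, 150), REF)
    expect_identical(nrow(rep), 12L)
    expect_identical(rep$probe_id, paste0("dq", 1:12))
    ok <- is.na(rep$percentage) | (rep$percentage >= 0 & rep$percentage <= 100)
    expect_true(all(ok))
    expect_true(all(rep$numerator <= rep$denominator))
  }
})

test_that("invalid and absent dates of birth are disjoint probe populations", {
  ds <- clinic_dataset("dob",
    patients = data.frame(
      patient_id = c("a", "b", "c", "d"), clinic_id = "dob",
      birth_date = c(NA, "2199-01-01", "garbage", "1950-01-01"),
      gender = "F", active_flag = TRUE),
    encounters = data.frame(patient_id = c("a", "b", "c", "d"),
                            encounter_date = "2015-08-01"))
  inv <- run_probe(ds, "dq3", REF)
  mis <- run_probe(ds, "dq4", REF)
  expect_identical(inv$numerator, 2L)  # future date + unparsable
  expect_identical(mis$numerator, 1L)  # absent only
  expect_identical(inv$numerator + mis$numerator <= inv$denominator, TRUE)
})

test_that("every generator knob with a matching probe is recovered at n = 5000", {
  cfg <- generator_config(seed = 21, n_clinics_per_arm = 1L,
                          patients_per_clinic = 5000L,
                          ghost_active_frac = 0.35,
                          coded_med_frac = 0.8,
                          no_current_meds_frac = 0.55,
                          problem_list_usage = 0.15,
                          diabetes_frac = 0.06,
                          concordance = c(tiotropium = 0.5,
                                          levothyroxine = 0.25, anti_gout = 0.1),
                          concordance_drug_prevalence = 0.05,
                          missing_gender_frac = 0.01)
  st <- generate_study(cfg)
  ds <- st$clinics[[1]]
  rep <- run_all_probes(ds, st$ref_date)
  expect_recovered <- function(probe, knob_pct) {
    row <- rep[rep$probe_id == probe, ]
    se <- 100 * sqrt(knob_pct / 100 * (1 - knob_pct / 100) / row$denominator)
    expect_lt(abs(row$percentage - knob_pct), 3 * se + 1e-9,
              label = sprintf("%s=%.2f vs knob %.2f (3se=%.2f)", probe,
                              row$percentage, knob_pct, 3 * se))
  }
  expect_recovered("dq1", 100 * (1 - 0.35))
  expect_recovered("dq2", 1)
  expect_recovered("dq5", 80)
  expect_recovered("dq6", 55)
  expect_recovered("dq8", 15)
  expect_recovered("dq9", 6)
  expect_recovered("dq10", 50)
  expect_recovered("dq11", 25)
  expect_recovered("dq12", 10)
})
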