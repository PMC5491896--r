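test_that("age_at floors whole years and propagates missingness", {
  expect_identical(age_at("1950-06-01", as.Date("2015-06-01")), 65L)
  expect_identical(age_at("1950-06-02", as.Date("2015-06-01")), 64L)
  expect_identical(age_at(NA_character_, as.Date("2015-06-01")), NA_integer_)
  expect_identical(age_at("not-a-date", as.Date("2015-06-01")), NA_integer_)
  # monotone non-decreasing in ref_date for fixed birth date
  set.seed(7)
  for (i in 1:20) {
    bd <- format(REF - sample(1000:30000, 1))
    refs <- sort(REF + sample(-2000:2000, 10))
    ages <- age_at(bd, refs)
    expect_true(all(diff(ages) >= 0))
  }
})

test_that("strict ISO parsing rejects impossible and malformed dates", {
  expect_identical(parse_iso_date(c("2015-02-30", "2015/01/01", "2015-1-1")),
                   rep(as.Date(NA), 3))
  expect_identical(parse_iso_date("2016-02-29"), as.Date("2016-02-29"))
})

test_that("round-trip through CSV and JSON-lines is field-for-field identity", {
  ds <- random_clinic(42, n = 60, clinic_id = "rt")
  for (fmt in c("csv", "jsonl")) {
    dir <- file.path(tempfile(), fmt)
    write_clinic_dataset(ds, dir, format = fmt)
    back <- read_clinic_dataset(dir, clinic_id = "rt", format = fmt)
    for (tab in c("patients", "encounters", "medications", "problems")) {
      expect_equal(back[[tab]], ds[[tab]], info = paste(fmt, tab))
    }
  }
  # missing gender survives as missing, not as an empty-string category
  expect_true(anyNA(ds$patients$gender))
})

test_that("multi-clinic study round-trips with identical per-table row counts", {
  st <- generate_study(paperlike_config(patients_per_clinic = 80, seed = 3,
                                        n_clinics_per_arm = 2L))
  dir <- tempfile()
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(names(back$clinics), names(st$clinics))
  for (cid in names(st$clinics)) {
    for (tab in c("patients", "encounters", "medications", "problems")) {
      expect_identical(nrow(back$clinics[[cid]][[tab]]),
                       nrow(st$clinics[[cid]][[tab]]))
    }
  }
})

test_that("empty and minimal inputs load and yield zero counts downstream", {
  ds <- clinic_dataset("empty")
  expect_identical(nrow(ds$patients), 0L)
  pc <- measure_pips(ds, mini_lib(), WIN)
  expect_identical(pc$totals$denominator, 0L)
  ds1 <- clinic_dataset("one",
    patients = data.frame(patient_id = "p", clinic_id = "one",
                          birth_date = "1990-01-01", gender = "M",
                          active_flag = TRUE),
    encounters = data.frame(patient_id = "p", encounter_date = "2015-07-01"))
  pc1 <- measure_pips(ds1, mini_lib(), WIN)
  expect_identical(pc1$totals$denominator, 0L)
  expect_identical(pc1$patients_seen, 1L)
})

test_that("a blank drug_code loads as missing (uncoded), counted by probe dq5", {
  ds <- clinic_dataset("u",
    patients = data.frame(patient_id = "p", clinic_id = "u",
                          birth_date = "1950-01-01", gender = "F",
                          active_flag = TRUE),
    encounters = data.frame(patient_id = "p", encounter_date = "2015-09-01"),
    medications = data.frame(patient_id = c("p", "p"),
                             drug_code = c("", "N05BA01"),
                             drug_name = c("custom rx", "lorazepam"),
                             start_date = "2015-01-01", end_date = NA))
  expect_identical(ds$medications$drug_code, c(NA, "N05BA01"))
  r <- run_probe(ds, "dq5", REF)
  expect_equal(r$percentage, 50)
})

test_that("invalid rows are rejected with a per-row report, not silently", {
  expect_warning(
    ds <- clinic_dataset("v",
      patients = data.frame(patient_id = c("a", "a", "b"), clinic_id = "v",
                            birth_date = "1950-01-01", gender = "F",
                            active_flag = TRUE),
      medications = data.frame(patient_id = "b", drug_code = "NOT-ATC",
                               drug_name = "x", start_date = "2015-01-01",
                               end_date = "2014-01-01")),
    "rejected")
  rej <- attr(ds, "rejected")
  expect_identical(rej$patients$reason, "duplicate patient_id")
  expect_identical(nrow(ds$patients), 2L)
  expect_identical(nrow(ds$medications), 0L)
  expect_match(rej$medications$reason, "ATC")
})

test_that("schema and referential failures are hard errors", {
  expect_error(
    clinic_dataset("s", patients = data.frame(patient_id = "p")),
    "schema error")
  expect_error(
    clinic_dataset("r",
      patients = data.frame(patient_id = "p", clinic_id = "r",
                            birth_date = NA, gender = NA, active_flag = TRUE),
      encounters = data.frame(patient_id = "ghost",
                              encounter_date = "2015-01-01")),
    "referential error.*ghost")
})
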