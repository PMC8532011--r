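make_tiny_ds <- function() {
  ehr_dataset(
    patients = data.frame(
      patient_id = c("P1", "P2", "Pé3"),
      birth_date = as.Date(c("1970-05-01", "2001-06-01", "1940-01-01")),
      sex = c("male", "female", "unknown"),
      race_black = c(FALSE, TRUE, FALSE),
      death_date = as.Date(c(NA, NA, "2018-07-01")),
      home_lat = c(47.66, 47.60, NA), home_lon = c(-122.31, -122.35, NA)),
    visits = rbind(
      hrow_visit("V1", "outpatient", "2018-03-01", fac = "C1", pid = "P1"),
      hrow_visit("V2", "inpatient", "2018-04-01", fac = "H1", pid = "P2",
                 end = "2018-04-05"),
      hrow_visit("V3", "outpatient", "2018-02-01", fac = "C1", pid = "Pé3"),
      hrow_visit("V4", "outpatient", "2017-11-01", fac = "C1", pid = "P1")),
    diagnoses = hrow_dx("J45.909", "icd10", "2018-03-01", visit_id = "V1"),
    labs = hrow_lab("urine_protein_dipstick", 2, "2018-03-01"),
    medications = hrow_med("metformin", "2018-03-01"),
    pcp = data.frame(patient_id = c("P1", "P2"),
                     has_in_system_pcp = c(TRUE, FALSE),
                     as_of_date = as.Date("2019-01-01")),
    pregnancies = data.frame(patient_id = "P2",
                             start_date = as.Date("2017-01-01"),
                             end_date = as.Date("2017-09-20")),
    facilities = h_facilities(),
    registry = data.frame(patient_id = c("P1", "P1"),
                          date = as.Date(c("2019-02-01", "2019-08-01")),
                          visit_type = c("emergency", "inpatient"),
                          facility_id = c("H1", "X1")))
}

test_that("write -> load round-trips bit-exactly, including non-ASCII", {
  ds <- make_tiny_ds()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- load_dataset(dir)
  for (nm in names(ds)) {
    expect_equal(as.data.frame(ds2[[nm]]), as.data.frame(ds[[nm]]),
                 label = nm)
  }
  expect_true("Pé3" %in% ds2$patients$patient_id)
})

test_that("round-trip identity holds on generated datasets", {
  for (seed in c(2, 9)) {
    ds <- generate_ehr(generator_config(n_patients = 30, seed = seed))
    dir <- withr::local_tempdir()
    write_dataset(ds, dir)
    ds2 <- load_dataset(dir)
    for (nm in names(ds)) {
      expect_equal(as.data.frame(ds2[[nm]]), as.data.frame(ds[[nm]]))
    }
  }
})

test_that("an empty dataset writes headers only and loads back", {
  ds <- ehr_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_equal(length(readLines(file.path(dir, "patients.csv"))), 1L)
  ds2 <- load_dataset(dir)
  expect_equal(nrow(ds2$patients), 0L)
})

test_that("loader failures are specific: missing file, bad row, orphan id", {
  ds <- make_tiny_ds()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  file.remove(file.path(dir, "labs.csv"))
  expect_error(load_dataset(dir), "labs.csv", class = "carefrag_io_error")
  expect_error(load_dataset(tempfile()), class = "carefrag_io_error")
})

test_that("each invariant violation raises its own condition class", {
  ds <- make_tiny_ds()
  # orphan patient id, named in the message
  bad <- ds
  bad$diagnoses <- rbind(bad$diagnoses,
                         hrow_dx("E11.9", "icd10", "2018-01-01", pid = "P999"))
  expect_error(validate_dataset(bad), "P999", class = "carefrag_integrity_error")
  # dipstick grade outside 0..4
  bad <- ds
  bad$labs <- rbind(bad$labs, hrow_lab("urine_protein_dipstick", 5, "2018-01-01"))
  expect_error(validate_dataset(bad), class = "carefrag_range_error")
  # enum violation
  bad <- ds
  bad$visits$visit_type[1] <- "telehealth"
  expect_error(validate_dataset(bad), class = "carefrag_enum_error")
  # end before start
  bad <- ds
  bad$visits$end_date[1] <- bad$visits$start_date[1] - 1
  expect_error(validate_dataset(bad), class = "carefrag_range_error")
  # duplicate patient
  bad <- ds
  bad$patients <- rbind(bad$patients, bad$patients[1, ])
  expect_error(validate_dataset(bad), class = "carefrag_unique_error")
  # overlapping pregnancies
  bad <- ds
  bad$pregnancies <- rbind(bad$pregnancies,
                           data.frame(patient_id = "P2",
                                      start_date = as.Date("2017-05-01"),
                                      end_date = as.Date("2018-01-01")))
  expect_error(validate_dataset(bad), class = "carefrag_overlap_error")
  # unknown facility
  bad <- ds
  bad$registry$facility_id[1] <- "NOPE"
  expect_error(validate_dataset(bad), "NOPE", class = "carefrag_integrity_error")
  # qualitative analyte without a flag
  bad <- ds
  bad$labs <- rbind(bad$labs, hrow_lab("c_peptide", 0.2, "2018-01-01"))
  expect_error(validate_dataset(bad), class = "carefrag_enum_error")
})

test_that("filter_cohort applies visit-year, age and death rules", {
  ds <- make_tiny_ds()
  # P1: adult, 2018 visit, alive -> in.  P2: 17 at 2019-01-01 -> out.
  # Pé3: died 2018 -> out.
  expect_equal(filter_cohort(ds, 2018), "P1")
  # age reference date is configurable: at mid-2019 P2 has turned 18,
  # but 18 must be reached by the reference date, not the visit date
  expect_equal(filter_cohort(ds, 2018, age_reference_date = as.Date("2019-07-01")),
               c("P1", "P2"))
  # visits only in 2017 do not qualify
  ds2 <- make_tiny_ds()
  ds2$visits <- ds2$visits[ds2$visits$visit_id == "V4"]
  expect_equal(filter_cohort(ds2, 2018), character(0))
})

test_that("filter_cohort is monotone under adding a qualifying visit", {
  ds <- make_tiny_ds()
  before <- filter_cohort(ds, 2018)
  ds$visits <- rbind(ds$visits,
                     hrow_visit("V9", "outpatient", "2018-09-09", fac = "C1",
                                pid = "P1"))
  after <- filter_cohort(ds, 2018)
  expect_true(all(before %in% after))
  # out-of-system-only visitors stay out
  ds$visits <- rbind(ds$visits,
                     hrow_visit("V10", "emergency", "2018-05-05", fac = "X1",
                                pid = "Pé3"))
  expect_false("Pé3" %in% filter_cohort(ds, 2018))
})
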