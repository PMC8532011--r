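# Expected eGFR values below were fixed by independent arithmetic evaluation
# of the MDRD formula (175 * age^-0.203 * scr^-1.154 * 0.742[f] * 1.212[b])
# before the implementation was written.
test_that("MDRD eGFR evaluates the printed formula exactly", {
  expect_equal(egfr_mdrd(1.0, 50, "female", FALSE), 58.69, tolerance = 1e-4)
  expect_equal(egfr_mdrd(1.0, 50, "male", TRUE), 95.86, tolerance = 1e-4)
  # categorical factors are exactly multiplicative
  expect_equal(egfr_mdrd(1.3, 64, "female", FALSE) / egfr_mdrd(1.3, 64, "male", FALSE),
               0.742)
  expect_equal(egfr_mdrd(0.9, 33, "male", TRUE) / egfr_mdrd(0.9, 33, "male", FALSE),
               1.212)
  expect_error(egfr_mdrd(0, 50, "male", FALSE), class = "carefrag_domain_error")
  expect_error(egfr_mdrd(1, 17, "male", FALSE), class = "carefrag_domain_error")
})

test_that("asthma: one code in the year; nothing outside year or set", {
  rec <- make_record(diagnoses = hrow_dx("J45.909", "icd10", "2018-03-02"))
  expect_true(detect_asthma(rec, 2018)$flag)
  rec <- make_record(diagnoses = hrow_dx("J45.909", "icd10", "2017-12-31"))
  expect_false(detect_asthma(rec, 2018)$flag)
  # 493.20 is COPD-range, not in the asthma set
  rec <- make_record(diagnoses = hrow_dx("493.20", "icd9", "2018-03-02"))
  expect_false(detect_asthma(rec, 2018)$flag)
  expect_true(detect_asthma(
    make_record(diagnoses = hrow_dx("493.01", "icd9", "2018-06-01")), 2018)$flag)
})

test_that("CKD: two qualifying measurements >= 3 calendar months apart", {
  low_egfr <- function(d) hrow_lab("serum_creatinine", 2.0, d)
  expect_true(detect_ckd(make_record(labs = rbind(low_egfr("2018-01-10"),
                                                  low_egfr("2018-04-11"))))$flag)
  expect_false(detect_ckd(make_record(labs = rbind(low_egfr("2018-01-10"),
                                                   low_egfr("2018-03-01"))))$flag)
  # exactly 3 calendar months: inclusive boundary
  expect_true(detect_ckd(make_record(labs = rbind(low_egfr("2018-01-10"),
                                                  low_egfr("2018-04-10"))))$flag)
  # mixed pair, both orderings
  expect_true(detect_ckd(make_record(labs = rbind(
    hrow_lab("urine_protein_dipstick", 1, "2018-02-01"),
    low_egfr("2018-06-01"))))$flag)
  expect_true(detect_ckd(make_record(labs = rbind(
    low_egfr("2018-02-01"),
    hrow_lab("urine_protein_dipstick", 1, "2018-06-01"))))$flag)
  # strict same-type mode rejects the mixed pair
  cfg <- phenotype_config(ckd_mixed_pairs = FALSE)
  expect_false(detect_ckd(make_record(labs = rbind(
    hrow_lab("urine_protein_dipstick", 1, "2018-02-01"),
    low_egfr("2018-06-01"))), config = cfg)$flag)
  # eGFR >= 60 does not qualify: creatinine 1.0 at age 55 male ~ 77
  expect_false(detect_ckd(make_record(labs = rbind(
    hrow_lab("serum_creatinine", 1.0, "2018-01-10"),
    hrow_lab("serum_creatinine", 1.0, "2018-06-10"))))$flag)
})

test_that("COPD: age gate and the four conditions", {
  dx_lama <- list(diagnoses = hrow_dx("J44.9", "icd10", "2018-02-01"),
                  medications = hrow_med("lama", "2018-05-01", "tiotropium"))
  rec <- do.call(make_record, dx_lama)
  r <- detect_copd(rec, age_at_index = 45)
  expect_true(r$flag); expect_equal(r$evidence, "condition1")
  expect_false(detect_copd(rec, age_at_index = 39)$flag)
  # LAMA after 6 months misses condition 1 (and 1 outpatient dx misses 2)
  rec <- make_record(diagnoses = hrow_dx("J44.9", "icd10", "2018-02-01"),
                     medications = hrow_med("lama", "2018-09-02", "tiotropium"))
  expect_false(detect_copd(rec, age_at_index = 45)$flag)
  # boundary: prescription exactly at dx + 6 months counts
  rec <- make_record(diagnoses = hrow_dx("J44.9", "icd10", "2018-02-01"),
                     medications = hrow_med("lama", "2018-08-01", "tiotropium"))
  expect_equal(detect_copd(rec, age_at_index = 45)$evidence, "condition1")
  # condition 2: one ED dx suffices; one outpatient does not, two do
  v <- hrow_visit("V1", "emergency", "2018-03-01")
  rec <- make_record(visits = v,
                     diagnoses = hrow_dx("496", "icd9", "2018-03-01", visit_id = "V1"))
  expect_equal(detect_copd(rec, age_at_index = 60)$evidence, "condition2")
  rec <- make_record(diagnoses = hrow_dx("J43.9", "icd10", "2018-03-01"))
  expect_false(detect_copd(rec, age_at_index = 60)$flag)
  rec <- make_record(diagnoses = rbind(hrow_dx("J43.9", "icd10", "2018-03-01"),
                                       hrow_dx("496", "icd9", "2018-05-01")))
  expect_equal(detect_copd(rec, age_at_index = 60)$evidence, "condition2")
  # condition 3: inpatient principal dx
  v <- hrow_visit("V1", "inpatient", "2018-03-01", end = "2018-03-04")
  rec <- make_record(visits = v,
                     diagnoses = hrow_dx("491.21", "icd9", "2018-03-01",
                                         rank = "principal", visit_id = "V1"))
  expect_equal(detect_copd(rec, age_at_index = 60)$evidence, "condition3")
  # condition 4: principal respiratory failure + secondary exacerbation
  rec <- make_record(visits = v, diagnoses = rbind(
    hrow_dx("518.81", "icd9", "2018-03-01", rank = "principal", visit_id = "V1"),
    hrow_dx("491.21", "icd9", "2018-03-01", rank = "secondary", visit_id = "V1")))
  expect_equal(detect_copd(rec, age_at_index = 60)$evidence, "condition4")
  # without the secondary exacerbation code it fails
  rec <- make_record(visits = v, diagnoses = hrow_dx(
    "518.81", "icd9", "2018-03-01", rank = "principal", visit_id = "V1"))
  expect_false(detect_copd(rec, age_at_index = 60)$flag)
})

test_that("diabetes events: per-day dedup and pregnancy exclusion", {
  rec <- make_record(labs = rbind(hrow_lab("hba1c", 7.0, "2015-01-10"),
                                  hrow_lab("hba1c", 7.0, "2015-01-11"),
                                  hrow_lab("hba1c", 7.0, "2015-01-11")))
  ev <- enumerate_diabetes_events(rec)
  expect_equal(nrow(ev), 2L)
  expect_true(all(diff(ev$date) >= 0))     # chronological
  rec <- make_record(
    sex = "female", birth_date = "1988-01-01",
    medications = hrow_med("insulin", "2015-05-01"),
    pregnancies = data.frame(patient_id = "P1",
                             start_date = as.Date("2015-02-01"),
                             end_date = as.Date("2015-10-30")))
  expect_equal(nrow(enumerate_diabetes_events(rec)), 0L)
})

test_that("diabetes: inpatient route, 2-year pairing, metformin guard", {
  v <- hrow_visit("V1", "inpatient", "2016-03-01", end = "2016-03-03")
  rec <- make_record(visits = v,
                     diagnoses = hrow_dx("E11.9", "icd10", "2016-03-01",
                                         rank = "secondary", visit_id = "V1"))
  r <- detect_diabetes(rec)
  expect_true(r$flag); expect_equal(r$evidence, "inpatient_dx")
  # two metformin prescriptions alone never qualify
  rec <- make_record(medications = rbind(hrow_med("metformin", "2015-03-01"),
                                         hrow_med("metformin", "2015-09-01")))
  expect_false(detect_diabetes(rec)$flag)
  # ... but with another manifestation they do
  rec <- make_record(medications = rbind(hrow_med("metformin", "2015-03-01"),
                                         hrow_med("metformin", "2015-09-01")),
                     labs = hrow_lab("hba1c", 6.8, "2015-06-01"))
  expect_true(detect_diabetes(rec)$flag)
  # lab + outpatient dx within 2 years
  rec <- make_record(labs = hrow_lab("hba1c", 6.8, "2015-01-10"),
                     diagnoses = hrow_dx("250.00", "icd9", "2016-06-01"))
  expect_true(detect_diabetes(rec)$flag)
  # exactly 2 calendar years: inclusive
  rec <- make_record(labs = hrow_lab("hba1c", 6.8, "2015-01-10"),
                     diagnoses = hrow_dx("250.00", "icd9", "2017-01-10"))
  expect_true(detect_diabetes(rec)$flag)
  # beyond 2 years fails
  rec <- make_record(labs = hrow_lab("hba1c", 6.8, "2015-01-10"),
                     diagnoses = hrow_dx("250.00", "icd9", "2017-06-01"))
  expect_false(detect_diabetes(rec)$flag)
})

test_that("Klompas type classification follows the four conditions", {
  base_dx <- function(codes, dates) {
    do.call(rbind, Map(function(cd, dt) hrow_dx(cd, "icd10", dt), codes, dates))
  }
  # condition 1: more T1D codes + glucagon (oral agent blocks condition 2)
  rec <- make_record(
    diagnoses = base_dx(c("E10.9", "E10.9", "E10.9", "E11.9"),
                        c("2015-01-01", "2015-03-01", "2015-05-01", "2015-07-01")),
    medications = rbind(hrow_med("glucagon", "2015-02-01"),
                        hrow_med("sulfonylurea", "2015-02-15")))
  r <- classify_diabetes_type(rec)
  expect_equal(r$type, "t1d"); expect_equal(r$evidence, "klompas1")
  # tie in counts fails 1-2, but a negative C-peptide rescues via 3
  rec <- make_record(
    diagnoses = base_dx(c("E10.9", "E11.9"), c("2015-01-01", "2015-03-01")),
    labs = hrow_lab("c_peptide", 0.1, "2015-05-01", flag = "negative"))
  r <- classify_diabetes_type(rec)
  expect_equal(r$type, "t1d"); expect_equal(r$evidence, "klompas3")
  # pure T2D record
  rec <- make_record(diagnoses = base_dx(rep("E11.9", 4),
                                         c("2015-01-01", "2015-02-01",
                                           "2015-03-01", "2015-04-01")))
  expect_equal(classify_diabetes_type(rec)$type, "t2d")
  # condition 2 blocked by an oral agent other than metformin
  rec <- make_record(
    diagnoses = base_dx(c("E10.9", "E10.9", "E11.9"),
                        c("2015-01-01", "2015-03-01", "2015-05-01")),
    medications = hrow_med("sulfonylurea", "2015-02-01"))
  expect_equal(classify_diabetes_type(rec)$type, "t2d")
  # positive autoantibody: condition 4
  rec <- make_record(
    diagnoses = base_dx(c("E11.9", "E11.9"), c("2015-01-01", "2015-03-01")),
    labs = hrow_lab("diabetes_autoantibody", 1, "2015-02-01", flag = "positive"))
  expect_equal(classify_diabetes_type(rec)$evidence, "klompas4")
  # calling on a non-diabetic record errors
  expect_error(classify_diabetes_type(make_record()),
               class = "carefrag_domain_error")
})

test_that("labels satisfy exclusivity/implication and row-order invariance", {
  fx <- fixture_suite()
  lab <- label_all(fx$dataset)
  expect_false(any(lab$t1d & lab$t2d))
  expect_true(all(lab$diabetes[lab$t1d | lab$t2d]))
  expect_true(all((lab$t1d | lab$t2d) == lab$diabetes))
  # evidence is nonempty wherever a flag is true
  for (f in c("asthma", "ckd", "copd", "diabetes")) {
    ev <- lab[[paste0(f, "_evidence")]][lab[[f]]]
    expect_true(all(!is.na(ev) & nzchar(ev)), label = f)
  }
  # permuting table rows leaves every label unchanged
  ds <- fx$dataset
  set.seed(5)
  for (nm in c("diagnoses", "labs", "medications", "visits")) {
    ds[[nm]] <- ds[[nm]][sample(nrow(ds[[nm]]))]
  }
  lab2 <- label_all(ds)
  data.table::setkey(lab, patient_id); data.table::setkey(lab2, patient_id)
  expect_equal(lab, lab2)
})

test_that("adding a qualifying dx row never un-flags asthma or COPD 2-3", {
  rec_dx <- rbind(hrow_dx("J45.909", "icd10", "2018-03-02"),
                  hrow_dx("496", "icd9", "2018-02-01"),
                  hrow_dx("J42", "icd10", "2018-04-01"))
  rec <- make_record(diagnoses = rec_dx)
  expect_true(detect_asthma(rec, 2018)$flag)
  expect_true(detect_copd(rec, age_at_index = 60)$flag)
  rec2 <- make_record(diagnoses = rbind(rec_dx,
                                        hrow_dx("J45.1", "icd10", "2018-06-01"),
                                        hrow_dx("J44.9", "icd10", "2018-07-01")))
  expect_true(detect_asthma(rec2, 2018)$flag)
  expect_true(detect_copd(rec2, age_at_index = 60)$flag)
})

test_that("label_all on an empty dataset returns an empty table", {
  lab <- label_all(ehr_dataset())
  expect_equal(nrow(lab), 0L)
  expect_true(all(c("patient_id", "asthma", "t2d") %in% names(lab)))
})
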