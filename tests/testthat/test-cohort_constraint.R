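# small population helper: k patients at controlled distances from H1,
# with configurable PCP flags and registry visits
make_population <- function(dists_km, pcp, registry = NULL) {
  n <- length(dists_km)
  fac <- h_facilities()
  home <- vincenty_direct(fac$lat[1], fac$lon[1], 80, dists_km * 1000)
  pid <- sprintf("P%02d", seq_len(n))
  ehr_dataset(
    patients = data.frame(patient_id = pid, birth_date = as.Date("1970-01-01"),
                          sex = "female", race_black = FALSE,
                          death_date = as.Date(NA),
                          home_lat = home$lat, home_lon = home$lon),
    visits = do.call(rbind, lapply(seq_len(n), function(i)
      hrow_visit(paste0("V", i), "outpatient", "2018-06-01", fac = "C1",
                 pid = pid[i]))),
    pcp = data.frame(patient_id = pid, has_in_system_pcp = pcp,
                     as_of_date = as.Date("2019-01-01")),
    facilities = fac,
    registry = if (is.null(registry)) empty_table("registry") else registry)
}

test_that("fulfills_constraint: conjunction, inclusive boundary, missing data", {
  ds <- make_population(c(7.9, 0.5, 8.0), pcp = c(TRUE, FALSE, TRUE))
  p8 <- constraint_params(8)
  expect_true(fulfills_constraint("P01", ds, p8))
  expect_false(fulfills_constraint("P02", ds, p8))   # close but no PCP
  # the distance placement is geodesically exact, so 8.0 km sits on the
  # boundary: "within d km" is inclusive
  expect_true(fulfills_constraint("P03", ds, p8))
  # missing home coordinates -> FALSE with a warning
  ds$patients$home_lat[1] <- NA
  expect_warning(r <- fulfills_constraint("P01", ds, p8), "home")
  expect_false(r)
  expect_error(constraint_params(-1), class = "carefrag_domain_error")
})

test_that("select_subcohort returns the n0/m0 fraction", {
  ds <- make_population(c(rep(2, 3), rep(20, 7)), pcp = rep(TRUE, 10))
  sel <- select_subcohort(ds$patients$patient_id, ds, constraint_params(8))
  expect_equal(sel$patient_ids, sprintf("P%02d", 1:3))
  expect_equal(sel$fraction$percentage, 30)
  # unbounded d with universal PCP selects everyone
  sel <- select_subcohort(ds$patients$patient_id, ds, constraint_params(Inf))
  expect_equal(sel$fraction$percentage, 100)
  # empty candidate set: undefined, flagged
  sel <- select_subcohort(character(0), ds, constraint_params(8))
  expect_true(sel$fraction$undefined)
})

test_that("frag_fraction reproduces printed-ratio arithmetic and flags 0/0", {
  expect_equal(frag_fraction(797, 1194)$percentage, 66.75)
  expect_equal(frag_fraction(1997, 2975)$percentage, 67.13)
  expect_equal(frag_fraction(3194, 14644)$percentage, 21.81)
  f <- frag_fraction(0, 0)
  expect_true(f$undefined); expect_true(is.na(f$percentage))
  expect_error(frag_fraction(5, 3), class = "carefrag_domain_error")
})

test_that("fragmentation counts in-system visits in a closed window", {
  reg <- data.frame(
    patient_id = c("P01", "P01", "P01", "P02", "P01", "P01"),
    date = as.Date(c("2019-01-01", "2019-06-30", "2019-07-01", "2019-02-01",
                     "2019-03-03", "2019-03-03")),
    visit_type = c("emergency", "inpatient", "emergency", "emergency",
                   "emergency", "emergency"),
    facility_id = c("H1", "H2", "H1", "X1", "H3", "H3"))
  ds <- make_population(c(2, 2), pcp = c(TRUE, TRUE), registry = reg)
  w6 <- default_windows()$`6m`
  # window endpoints count; the duplicated H3 row collapses to one visit
  fr <- fragmentation(ds$registry, c("P01", "P02"), w6, ds$facilities)
  expect_equal(fr$numerator, 3L)   # H1@Jan1, H2@Jun30, H3@Mar3
  expect_equal(fr$denominator, 4L) # + X1
  # same-day ED + inpatient at the same facility are two distinct visits
  reg2 <- rbind(reg, data.frame(patient_id = "P01", date = as.Date("2019-03-03"),
                                visit_type = "inpatient", facility_id = "H3"))
  ds2 <- make_population(c(2, 2), pcp = c(TRUE, TRUE), registry = reg2)
  fr2 <- fragmentation(ds2$registry, c("P01", "P02"), w6, ds2$facilities)
  expect_equal(fr2$numerator, 4L)
  # empty subset -> undefined
  expect_true(fragmentation(ds$registry, character(0), w6, ds$facilities)$undefined)
  # facility filter gives the per-hospital numerator over the same denominator
  fr3 <- fragmentation(ds$registry, c("P01", "P02"), w6, ds$facilities,
                       facility_filter = "H1")
  expect_equal(fr3$numerator, 1L); expect_equal(fr3$denominator, 4L)
})

test_that("per-hospital numerators add up to the system numerator", {
  set.seed(31)
  ds <- generate_ehr(generator_config(n_patients = 300, seed = 31))
  cohort <- filter_cohort(ds, 2018)
  sel <- select_subcohort(cohort, ds, constraint_params(8))
  windows <- default_windows()
  ph <- per_hospital_report(ds$registry, sel$patient_ids, windows, ds$facilities)
  for (w in c("6m", "12m")) {
    sys <- fragmentation(ds$registry, sel$patient_ids, windows[[w]], ds$facilities)
    expect_equal(sum(ph$numerator[ph$window == w]), sys$numerator)
    expect_true(all(ph$denominator[ph$window == w] == sys$denominator))
  }
  # single-hospital system: per-hospital equals system percentage
  ds1 <- ds
  ds1$facilities <- ds1$facilities[!(facility_id %in% c("H_HMC", "H_NWH"))]
  ds1$registry <- ds1$registry[!(facility_id %in% c("H_HMC", "H_NWH"))]
  sys1 <- fragmentation(ds1$registry, sel$patient_ids, windows$`6m`, ds1$facilities)
  ph1 <- per_hospital_report(ds1$registry, sel$patient_ids, windows["6m"],
                             ds1$facilities)
  expect_equal(ph1$numerator, sys1$numerator)
  expect_equal(ph1$percentage, sys1$percentage)
})

test_that("sweep: nesting, monotone fulfilling %, unbounded endpoint", {
  ds <- make_population(c(0.5, 3, 9, 15, 40), pcp = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  ids <- ds$patients$patient_id
  sw <- sweep_constraint(c(0, 1, 5, 10, 30, Inf), ids, ds)
  expect_equal(sw$n0, c(0L, 1L, 2L, 3L, 3L, 4L))
  expect_true(all(diff(sw$fulfilling_pct) >= 0))
  # d = 0 with nobody at distance 0 selects nobody
  expect_equal(sw$fulfilling_pct[1], 0)
  # unbounded endpoint = all PCP holders
  sel_inf <- select_subcohort(ids, ds, constraint_params(Inf))
  expect_equal(sw$n0[6], length(sel_inf$patient_ids))
  # nesting of the selected sets
  s5 <- select_subcohort(ids, ds, constraint_params(5))$patient_ids
  s10 <- select_subcohort(ids, ds, constraint_params(10))$patient_ids
  expect_true(all(s5 %in% s10))
  expect_error(sweep_constraint(c(5, 5, 6), ids, ds),
               class = "carefrag_domain_error")
})

test_that("all fractions match the naive-loop recount on small datasets", {
  for (seed in c(1, 7, 23)) {
    ds <- generate_ehr(generator_config(n_patients = 40, seed = seed))
    cohort <- filter_cohort(ds, 2018)
    params <- constraint_params(8)
    sel <- select_subcohort(cohort, ds, params)
    bf <- bf_fulfilling(ds, cohort, 8, params$pcp_as_of_date)
    expect_setequal(sel$patient_ids, bf)
    for (w in default_windows()) {
      fr <- fragmentation(ds$registry, sel$patient_ids, w, ds$facilities)
      cnt <- bf_fragmentation(ds, sel$patient_ids, w$start_date, w$end_date)
      expect_equal(fr$numerator, unname(cnt["num"]))
      expect_equal(fr$denominator, unname(cnt["den"]))
    }
  }
})

test_that("subgroup_report undefined cells stay NA, never 0", {
  ds <- make_population(c(2, 3), pcp = c(FALSE, FALSE))
  labels <- data.table::data.table(patient_id = ds$patients$patient_id,
                                   asthma = c(TRUE, TRUE), ckd = FALSE,
                                   copd = FALSE, diabetes = FALSE,
                                   t1d = FALSE, t2d = FALSE)
  rep <- subgroup_report(ds, labels)
  expect_equal(rep$n0[1], 0L)
  expect_true(is.na(rep$pct_ful_6m[1]))    # no fulfilling patients
  expect_true(is.na(rep$pct_all_6m[1]))    # no registry visits at all
})
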