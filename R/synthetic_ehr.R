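# Synthetic EHR + all-payer registry generator.
#
# Produces datasets with the statistical structure the analysis assumes, so
# every stage is testable offline: disease prevalences mirroring the study
# population, a configurable share of patients with an in-system PCP, home
# locations at controlled geodesic distances from 3 in-system hospitals
# (distance sampled from a near-urban/far-tail log-normal mixture, bearing
# uniform, coordinates by a direct-geodesic step), and registry hospital
# visits whose probability of occurring in-system follows
#     p_in = logistic(b0 + b_pcp * has_pcp + b_dist * distance_km).
# The logistic model is the generator's own stand-in for the observed
# direction (in-system share falls with distance, rises with an in-system
# PCP); its defaults put the fulfilling subset at d = 8 km around 65-75%
# in-system.  Same seed + config => byte-identical output.

#' Generator configuration
#'
#' @param n_patients number of patients
#' @param seed integer RNG seed; same seed + config reproduce bytewise
#' @param cohort_year study year (visits that define the cohort)
#' @param span_start first year of the look-back span
#' @param disease_prevalences named probabilities for
#'   `asthma, ckd, copd, t2d, t1d`; defaults are the study population's
#'   printed prevalences (4.26%, 7.38%, 2.21%, 16.45%, 0.84%)
#' @param pcp_probability probability a patient has an in-system PCP
#' @param home_distance mixture parameters for home-to-nearest-hospital
#'   distance (km): `w_near` weight of the near-urban log-normal and the
#'   two (meanlog, sdlog) pairs
#' @param n_out_of_system number of out-of-system hospitals
#' @param visit_rate mean registry hospital visits per patient-year:
#'   `base` for disease-negative, `disease` for disease-positive patients
#' @param ed_fraction share of registry visits that are ED (rest inpatient)
#' @param in_system_model coefficients `b0`, `b_pcp`, `b_dist` of the
#'   logistic in-system assignment
#' @param pregnancy_rate probability of one pregnancy episode for a female
#'   patient aged 18-45
#' @param death_rate probability of a death date in the cohort year
#' @param minor_fraction share of patients under 18 (exercise the age gate)
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_patients = 2000L, seed = 1L,
                             cohort_year = 2018L, span_start = 2011L,
                             disease_prevalences = c(asthma = 0.0426,
                                                     ckd = 0.0738,
                                                     copd = 0.0221,
                                                     t2d = 0.1645,
                                                     t1d = 0.0084),
                             pcp_probability = 0.35,
                             home_distance = list(w_near = 0.75,
                                                  meanlog_near = log(6),
                                                  sdlog_near = 0.9,
                                                  meanlog_far = log(40),
                                                  sdlog_far = 0.6),
                             n_out_of_system = 6L,
                             visit_rate = c(base = 0.25, disease = 1.0),
                             ed_fraction = 0.6,
                             in_system_model = c(b0 = 0.2, b_pcp = 1.0,
                                                 b_dist = -0.06),
                             pregnancy_rate = 0.08,
                             death_rate = 0.005,
                             minor_fraction = 0.02) {
  if (any(disease_prevalences < 0) || any(disease_prevalences > 1) ||
      pcp_probability < 0 || pcp_probability > 1 ||
      ed_fraction < 0 || ed_fraction > 1 || any(visit_rate < 0) ||
      n_patients < 1) {
    cf_stop("invalid generator config: probabilities must lie in [0,1], rates >= 0",
            "carefrag_domain_error")
  }
  need <- c("asthma", "ckd", "copd", "t2d", "t1d")
  if (!all(need %in% names(disease_prevalences))) {
    cf_stop("disease_prevalences must name asthma, ckd, copd, t2d, t1d",
            "carefrag_domain_error")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 cohort_year = as.integer(cohort_year),
                 span_start = as.integer(span_start),
                 index_date = as.Date(sprintf("%d-01-01", cohort_year + 1)),
                 disease_prevalences = disease_prevalences,
                 pcp_probability = pcp_probability,
                 home_distance = home_distance,
                 n_out_of_system = as.integer(n_out_of_system),
                 visit_rate = visit_rate, ed_fraction = ed_fraction,
                 in_system_model = in_system_model,
                 pregnancy_rate = pregnancy_rate, death_rate = death_rate,
                 minor_fraction = minor_fraction),
            class = "generator_config")
}

# three in-system hospitals (urban Seattle-like coordinates) + clinic
base_facilities <- function(n_out = 6L) {
  hosp <- data.table::data.table(
    facility_id = c("H_UWMC", "H_HMC", "H_NWH"),
    name = c("University Medical Center", "Harbor Medical Center",
             "Northwest Hospital"),
    in_system = TRUE,
    lat = c(47.6496, 47.6040, 47.7128),
    lon = c(-122.3080, -122.3233, -122.3405),
    is_hospital = TRUE)
  clinic <- data.table::data.table(
    facility_id = "C_CLINIC", name = "In-System Primary Care Clinic",
    in_system = TRUE, lat = 47.62, lon = -122.32, is_hospital = FALSE)
  out <- data.table::data.table(facility_id = character(0), name = character(0),
                                in_system = logical(0), lat = numeric(0),
                                lon = numeric(0), is_hospital = logical(0))
  if (n_out > 0L) {
    dist_km <- c(1.2, 3, 8, 20, 60, 150)[((seq_len(n_out) - 1L) %% 6L) + 1L]
    bearing <- (seq_len(n_out) * 57) %% 360
    pt <- vincenty_direct(47.61, -122.33, bearing, dist_km * 1000)
    out <- data.table::data.table(
      facility_id = sprintf("X%03d", seq_len(n_out)),
      name = sprintf("Outside Hospital %d", seq_len(n_out)),
      in_system = FALSE, lat = pt$lat, lon = pt$lon, is_hospital = TRUE)
  }
  rbind(hosp, clinic, out)
}

#' Enumerate implantable rule branches
#'
#' Every rule clause of the five phenotypes, as `disease:branch` pairs; each
#' supports a `positive` and a `near_miss` polarity (the near miss differs
#' from the positive by one minimal edit: a date shifted outside a window, a
#' count one below threshold, or a code/flag one set away).
#'
#' @return data.table with columns `disease`, `branch`
#' @export
implant_branches <- function() {
  data.table::data.table(
    disease = c("asthma", "asthma",
                "ckd", "ckd", "ckd",
                "copd", "copd", "copd", "copd", "copd", "copd",
                "diabetes", "diabetes", "diabetes", "diabetes", "diabetes",
                "t1d", "t1d", "t1d", "t1d",
                "t2d"),
    branch = c("dx_in_year", "icd9_dx",
               "egfr_pair", "dipstick_pair", "mixed_pair",
               "condition1", "condition2_ed", "condition2_outpatient",
               "condition3", "condition4", "age_gate",
               "inpatient_dx", "pair_hba1c_dx", "pair_rx_glucose",
               "metformin_pair", "pregnancy_excluded",
               "klompas1", "klompas2", "klompas3", "klompas4",
               "default_t2d"))
}

#' Implant specification
#'
#' @param disease,branch a row of [implant_branches()]
#' @param polarity `"positive"` (the detector must fire via exactly this
#'   branch) or `"near_miss"` (one minimal edit away; detector must not
#'   fire)
#' @return object of class `implant_spec`
#' @export
implant_spec <- function(disease, branch, polarity = c("positive", "near_miss")) {
  polarity <- match.arg(polarity)
  br <- implant_branches()
  if (!any(br$disease == disease & br$branch == branch)) {
    cf_stop(sprintf("unknown implant branch %s:%s", disease, branch),
            "carefrag_domain_error")
  }
  structure(list(disease = disease, branch = branch, polarity = polarity),
            class = "implant_spec")
}

#' Implant disease evidence rows for one patient
#'
#' Deterministic minimal row sets exercising one rule branch.  For
#' `positive` polarity the corresponding detector returns `TRUE` via the
#' requested branch; for `near_miss` it returns `FALSE` (or, for the
#' type-1 branches, classifies as type 2).
#'
#' @param patient_id patient id the rows belong to
#' @param spec an [implant_spec()]
#' @param anchor `Date` around which evidence dates are placed (kept inside
#'   the look-back span)
#' @return list of row data.frames (`visits`, `diagnoses`, `labs`,
#'   `medications`, `pregnancies`; absent tables omitted) plus
#'   `required_age` / `required_sex` hints for the host patient
#' @export
implant <- function(patient_id, spec, anchor = as.Date("2018-03-15")) {
  stopifnot(inherits(spec, "implant_spec"))
  pos <- spec$polarity == "positive"
  pid <- patient_id
  D <- function(s) as.Date(s)
  vid <- function(i) sprintf("V_%s_%02d", pid, i)
  dx <- function(code, system, date, rank = "unranked", visit_id = NA_character_) {
    data.frame(patient_id = pid, visit_id = visit_id, code = code,
               code_system = system, rank = rank, date = as.Date(date))
  }
  lab <- function(analyte, value, date, flag = "none") {
    data.frame(patient_id = pid, date = as.Date(date), analyte = analyte,
               value = value, qualitative_flag = flag)
  }
  med <- function(class, name, date) {
    data.frame(patient_id = pid, date = as.Date(date), drug_class = class,
               drug_name = name)
  }
  inpatient_visit <- function(i, date, fac = "H_UWMC") {
    data.frame(visit_id = vid(i), patient_id = pid, visit_type = "inpatient",
               start_date = as.Date(date), end_date = as.Date(date) + 3,
               facility_id = fac)
  }
  ed_visit <- function(i, date, fac = "H_HMC") {
    data.frame(visit_id = vid(i), patient_id = pid, visit_type = "emergency",
               start_date = as.Date(date), end_date = as.Date(date),
               facility_id = fac)
  }
  out <- list(required_age = 55L, required_sex = NA_character_)
  key <- paste(spec$disease, spec$branch, sep = ":")
  yr <- as.integer(format(anchor, "%Y"))

  switch(key,
    "asthma:dx_in_year" = {
      # near miss: same code dated in the prior year
      out$diagnoses <- dx("J45.909", "icd10", if (pos) anchor else anchor - 370)
    },
    "asthma:icd9_dx" = {
      # near miss: 493.20 sits in the COPD range, one set away from asthma
      out$diagnoses <- dx(if (pos) "493.02" else "493.20", "icd9", anchor)
    },
    "ckd:egfr_pair" = {
      # creatinine 2.0 at age 55 -> eGFR ~ 33; near miss: 2-month gap
      gap <- if (pos) add_months(anchor, 4L) else add_months(anchor, 2L)
      out$labs <- rbind(lab("serum_creatinine", 2.0, anchor),
                        lab("serum_creatinine", 2.0, gap))
    },
    "ckd:dipstick_pair" = {
      out$labs <- if (pos) {
        rbind(lab("urine_protein_dipstick", 2, anchor),
              lab("urine_protein_dipstick", 1, add_months(anchor, 5L)))
      } else lab("urine_protein_dipstick", 2, anchor)     # single measurement
    },
    "ckd:mixed_pair" = {
      # one dipstick + one low eGFR >= 3 months later; near miss: grade 0
      out$labs <- rbind(lab("urine_protein_dipstick", if (pos) 1 else 0, anchor),
                        lab("serum_creatinine", 2.2, add_months(anchor, 4L)))
    },
    "copd:condition1" = {
      # outpatient dx then LAMA; near miss: prescription at 7 months
      rx <- if (pos) add_months(anchor, 3L) else add_months(anchor, 7L)
      out$diagnoses <- dx("J44.9", "icd10", anchor)
      out$medications <- med("lama", "tiotropium", rx)
    },
    "copd:condition2_ed" = {
      # near miss: J41.0 is one digit off the set's J41.8 and in no set
      v <- ed_visit(1L, anchor)
      out$visits <- v
      out$diagnoses <- dx(if (pos) "J44.1" else "J41.0", "icd10", anchor,
                          visit_id = v$visit_id)
    },
    "copd:condition2_outpatient" = {
      out$diagnoses <- if (pos) {
        rbind(dx("496", "icd9", anchor), dx("J42", "icd10", anchor + 40))
      } else dx("496", "icd9", anchor)                    # one below threshold
    },
    "copd:condition3" = {
      v <- inpatient_visit(1L, anchor)
      out$visits <- v
      out$diagnoses <- dx("J43.9", "icd10", anchor,
                          rank = if (pos) "principal" else "secondary",
                          visit_id = v$visit_id)
    },
    "copd:condition4" = {
      v <- inpatient_visit(1L, anchor)
      out$visits <- v
      rows <- dx("518.81", "icd9", anchor, rank = "principal", visit_id = v$visit_id)
      if (pos) rows <- rbind(rows, dx("491.21", "icd9", anchor,
                                      rank = "secondary", visit_id = v$visit_id))
      out$diagnoses <- rows
    },
    "copd:age_gate" = {
      # identical qualifying records; polarity toggles the age gate
      out$required_age <- if (pos) 45L else 39L
      out$diagnoses <- rbind(dx("J44.9", "icd10", anchor),
                             dx("J44.9", "icd10", anchor + 30))
    },
    "diabetes:inpatient_dx" = {
      v <- inpatient_visit(1L, anchor)
      if (pos) {
        out$visits <- v
        out$diagnoses <- dx("E11.9", "icd10", anchor, rank = "secondary",
                            visit_id = v$visit_id)
      } else {
        # same single code as an outpatient dx: one event, no pair
        out$diagnoses <- dx("E11.9", "icd10", anchor)
      }
    },
    "diabetes:pair_hba1c_dx" = {
      # near miss: second event at 25 months
      second <- if (pos) add_months(anchor, 18L) else add_months(anchor, 25L)
      out$labs <- lab("hba1c", 7.1, anchor)
      out$diagnoses <- dx("250.00", "icd9", second)
    },
    "diabetes:pair_rx_glucose" = {
      # near miss: glucose below the 200 mg/dL threshold leaves one event
      out$medications <- med("insulin", "insulin glargine", anchor)
      out$labs <- lab("random_glucose", if (pos) 210 else 199,
                      add_months(anchor, 6L))
    },
    "diabetes:metformin_pair" = {
      # two metformin prescriptions alone never qualify; adding any other
      # manifestation (here an HbA1c event) makes the record positive
      out$medications <- rbind(med("metformin", "metformin", anchor),
                               med("metformin", "metformin", add_months(anchor, 6L)))
      if (pos) out$labs <- lab("hba1c", 6.9, add_months(anchor, 3L))
    },
    "diabetes:pregnancy_excluded" = {
      # identical event pair; polarity moves it inside a pregnancy episode
      out$required_sex <- "female"
      out$required_age <- 30L
      out$labs <- rbind(lab("hba1c", 7.0, anchor),
                        lab("random_glucose", 230, anchor + 100))
      if (!pos) {
        out$pregnancies <- data.frame(patient_id = pid,
                                      start_date = anchor - 30,
                                      end_date = anchor + 240)
      }
    },
    "t1d:klompas1" = {
      # T1D count > T2D count + glucagon; oral agent blocks condition 2 so
      # the classification rests on condition 1.  Near miss: tie.
      n10 <- if (pos) 2L else 1L
      out$diagnoses <- rbind(
        do.call(rbind, lapply(seq_len(n10), function(i)
          dx("E10.9", "icd10", anchor + 20 * i))),
        dx("E11.9", "icd10", anchor + 100))
      out$medications <- rbind(med("glucagon", "glucagon kit", anchor + 10),
                               med("sulfonylurea", "glipizide", anchor + 15))
    },
    "t1d:klompas2" = {
      # T1D count > T2D count and no oral agent beyond metformin;
      # near miss: a sulfonylurea prescription blocks the condition
      out$diagnoses <- rbind(dx("E10.9", "icd10", anchor),
                             dx("E10.9", "icd10", anchor + 30),
                             dx("E11.9", "icd10", anchor + 60))
      if (!pos) out$medications <- med("sulfonylurea", "glipizide", anchor + 5)
    },
    "t1d:klompas3" = {
      # counts favour T2D; a negative C-peptide still classifies type 1
      out$diagnoses <- rbind(dx("E11.9", "icd10", anchor),
                             dx("E11.9", "icd10", anchor + 30))
      out$labs <- lab("c_peptide", 0.1, anchor + 10,
                      flag = if (pos) "negative" else "positive")
    },
    "t1d:klompas4" = {
      out$diagnoses <- rbind(dx("E11.9", "icd10", anchor),
                             dx("E11.9", "icd10", anchor + 30))
      out$labs <- lab("diabetes_autoantibody", 1, anchor + 10,
                      flag = if (pos) "positive" else "negative")
    },
    "t2d:default_t2d" = {
      # plain type-2 record; near miss: flips to type 1 via condition 2
      if (pos) {
        out$diagnoses <- rbind(dx("E11.9", "icd10", anchor),
                               dx("E11.9", "icd10", anchor + 40),
                               dx("E11.9", "icd10", anchor + 80))
        out$medications <- med("sulfonylurea", "glipizide", anchor + 5)
      } else {
        out$diagnoses <- rbind(dx("E10.9", "icd10", anchor),
                               dx("E10.9", "icd10", anchor + 40))
      }
    },
    cf_stop(sprintf("unknown implant branch %s", key), "carefrag_domain_error")
  )
  out
}

# expected label row for a fixture patient given its implant spec
expected_flags <- function(spec) {
  f <- c(asthma = FALSE, ckd = FALSE, copd = FALSE, diabetes = FALSE,
         t1d = FALSE, t2d = FALSE)
  pos <- spec$polarity == "positive"
  if (spec$disease %in% c("asthma", "ckd", "copd")) {
    f[spec$disease] <- pos
  } else if (spec$disease == "diabetes") {
    f["diabetes"] <- pos
    # none of the diabetes-branch row sets satisfies a type-1 condition
    # (T1D code count never exceeds T2D count, no C-peptide/autoantibody),
    # so every positive classifies as type 2
    if (pos) f["t2d"] <- TRUE
  } else if (spec$disease %in% c("t1d", "t2d")) {
    f["diabetes"] <- TRUE
    if (spec$disease == "t1d") {
      f["t1d"] <- pos; f["t2d"] <- !pos
    } else {
      f["t2d"] <- pos; f["t1d"] <- !pos
    }
  }
  f
}

#' Deterministic branch-coverage fixture dataset
#'
#' A miniature dataset with one patient per (rule branch, polarity) — every
#' clause of every phenotype gets a minimal positive and a near-miss
#' negative — plus a manifest of hand-derivable expected labels.  All
#' patients carry an in-system PCP, a home ~3 km from a hospital, and one
#' in-system visit in the cohort year, so the whole suite survives
#' [filter_cohort()].
#'
#' @param cohort_year study year for the fixtures
#' @return list with `dataset` (an `ehr_dataset`) and `manifest` (a
#'   data.table: patient_id, disease, branch, polarity + six expected
#'   flags)
#' @export
fixture_suite <- function(cohort_year = 2018L) {
  br <- implant_branches()
  specs <- list()
  for (i in seq_len(nrow(br))) {
    for (pol in c("positive", "near_miss")) {
      specs[[length(specs) + 1L]] <- implant_spec(br$disease[i], br$branch[i], pol)
    }
  }
  anchor <- as.Date(sprintf("%d-03-15", cohort_year))
  index <- as.Date(sprintf("%d-01-01", cohort_year + 1))
  fac <- base_facilities(2L)
  home <- vincenty_direct(fac$lat[1], fac$lon[1], 135, 3000)

  pats <- list(); visits <- list(); dxs <- list(); labs <- list()
  meds <- list(); pregs <- list(); pcps <- list(); manifest <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    pid <- sprintf("FIX%03d", k)
    # the diabetes-family branches exercise 2-year windows; anchor them
    # deep enough in the look-back span that a +25-month near miss still
    # falls inside it (otherwise the span filter, not the window rule,
    # would produce the negative)
    anch <- if (sp$disease %in% c("diabetes", "t1d", "t2d")) anchor - 900L else anchor
    rows <- implant(pid, sp, anch)
    sex <- if (!is.na(rows$required_sex)) rows$required_sex
           else if (k %% 2L) "female" else "male"
    birth <- add_months(index, -12L * rows$required_age) - 15L
    pats[[k]] <- data.frame(patient_id = pid, birth_date = birth, sex = sex,
                            race_black = (k %% 7L) == 0L,
                            death_date = as.Date(NA),
                            home_lat = home$lat, home_lon = home$lon)
    bg <- data.frame(visit_id = sprintf("V_%s_BG", pid), patient_id = pid,
                     visit_type = "outpatient",
                     start_date = anchor - 10, end_date = anchor - 10,
                     facility_id = "C_CLINIC")
    visits[[k]] <- rbind(bg, rows$visits)
    dxs[[k]] <- rows$diagnoses
    labs[[k]] <- rows$labs
    meds[[k]] <- rows$medications
    pregs[[k]] <- rows$pregnancies
    pcps[[k]] <- data.frame(patient_id = pid, has_in_system_pcp = TRUE,
                            as_of_date = index)
    manifest[[k]] <- data.table::data.table(
      patient_id = pid, disease = sp$disease, branch = sp$branch,
      polarity = sp$polarity, t(expected_flags(sp)))
  }
  ds <- ehr_dataset(
    patients = data.table::rbindlist(pats),
    visits = data.table::rbindlist(visits, fill = TRUE),
    diagnoses = data.table::rbindlist(dxs[!vapply(dxs, is.null, TRUE)]),
    labs = data.table::rbindlist(labs[!vapply(labs, is.null, TRUE)]),
    medications = data.table::rbindlist(meds[!vapply(meds, is.null, TRUE)]),
    pcp = data.table::rbindlist(pcps),
    pregnancies = data.table::rbindlist(pregs[!vapply(pregs, is.null, TRUE)]),
    facilities = fac)
  list(dataset = ds, manifest = data.table::rbindlist(manifest))
}

#' Generate a synthetic EHR dataset + registry
#'
#' See the module comment for the generative model.  The returned dataset
#' passes [validate_dataset()]; empirical disease prevalences track the
#' configured ones; registry visits are assigned in-system with the
#' logistic probability; output is bytewise reproducible under a fixed
#' seed (the caller's RNG state is left untouched).
#'
#' @param config a [generator_config()]
#' @return an `ehr_dataset` (registry included)
#' @export
generate_ehr <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  index <- config$index_date
  year0 <- as.Date(sprintf("%d-01-01", config$cohort_year))
  fac <- base_facilities(config$n_out_of_system)
  hosp <- fac[fac$in_system & fac$is_hospital]
  out_hosp <- fac[!fac$in_system]

  pid <- sprintf("P%06d", seq_len(n))
  # ages: a small minor share, adults per the study population's buckets
  bucket <- sample(c("minor", "a", "b", "c"), n, replace = TRUE,
                   prob = c(config$minor_fraction,
                            (1 - config$minor_fraction) * c(0.3504, 0.4348, 0.2149) / 1.0001))
  age <- integer(n)
  age[bucket == "minor"] <- sample(12:17, sum(bucket == "minor"), replace = TRUE)
  age[bucket == "a"] <- sample(18:39, sum(bucket == "a"), replace = TRUE)
  age[bucket == "b"] <- sample(40:65, sum(bucket == "b"), replace = TRUE)
  age[bucket == "c"] <- sample(66:95, sum(bucket == "c"), replace = TRUE)
  birth <- add_months(index, -12L * age) - sample(0:330, n, replace = TRUE)
  sex <- sample(c("female", "male", "unknown"), n, replace = TRUE,
                prob = c(0.5345, 0.4654, 0.0001))
  race_black <- stats::runif(n) < 0.0742
  death <- rep(as.Date(NA), n)
  died <- stats::runif(n) < config$death_rate
  death[died] <- year0 + sample(0:364, sum(died), replace = TRUE)

  # homes: distance mixture, uniform bearing, anchored at a random hospital
  hd <- config$home_distance
  near <- stats::runif(n) < hd$w_near
  dist_km <- ifelse(near,
                    stats::rlnorm(n, hd$meanlog_near, hd$sdlog_near),
                    stats::rlnorm(n, hd$meanlog_far, hd$sdlog_far))
  dist_km <- pmin(dist_km, 400)
  anchor_h <- sample(nrow(hosp), n, replace = TRUE)
  home <- vincenty_direct(hosp$lat[anchor_h], hosp$lon[anchor_h],
                          stats::runif(n, 0, 360), dist_km * 1000)

  patients <- data.table::data.table(
    patient_id = pid, birth_date = birth, sex = sex, race_black = race_black,
    death_date = death, home_lat = home$lat, home_lon = home$lon)

  has_pcp <- stats::runif(n) < config$pcp_probability
  pcp <- data.table::data.table(patient_id = pid, has_in_system_pcp = has_pcp,
                                as_of_date = index)

  # disease assignment (t1d/t2d exclusive; t2d wins the rare double draw).
  # Configured prevalences are population rates among cohort adults; the
  # COPD rule can only fire for patients >= 40 at index, so its draw is
  # confined to that stratum and upweighted to preserve the overall rate.
  pv <- config$disease_prevalences
  adult <- age >= 18L
  dis <- list()
  for (d in setdiff(names(pv), "copd")) dis[[d]] <- stats::runif(n) < pv[[d]]
  over40 <- adult & age >= 40L
  p_copd <- min(1, pv[["copd"]] * sum(adult) / max(1L, sum(over40)))
  dis$copd <- over40 & stats::runif(n) < p_copd
  dis$t1d <- dis$t1d & !dis$t2d

  # implant evidence rows for every drawn disease
  br <- implant_branches()
  positives <- list()
  for (d in names(pv)) {
    idx <- which(dis[[d]] & adult)
    if (!length(idx)) next
    branches <- br$branch[br$disease == d]
    # age-/pregnancy-sensitive branches are host-dependent; keep the bulk
    # generator to branches valid for any adult host
    branches <- setdiff(branches, c("age_gate", "pregnancy_excluded", "icd9_dx"))
    pick <- sample(branches, length(idx), replace = TRUE)
    # the adult MDRD equation needs age >= 18 at the (historical) lab date;
    # young CKD hosts get the age-free proteinuria branch instead
    if (d == "ckd") pick[age[idx] < 25L] <- "dipstick_pair"
    for (k in seq_along(idx)) {
      positives[[length(positives) + 1L]] <-
        list(i = idx[k], spec = implant_spec(d, pick[k], "positive"))
    }
  }
  visits <- list(); dxs <- list(); labs <- list(); meds <- list()
  for (p in positives) {
    # evidence sits 600-1500 days before the cohort year so every
    # follow-on date a branch generates (up to +18 months) stays inside
    # the look-back span; the asthma rule alone is year-bound
    anch <- if (p$spec$disease == "asthma") {
      year0 + sample(0:300, 1L)
    } else year0 - sample(600:1500, 1L)
    anch <- max(anch, as.Date(sprintf("%d-02-01", config$span_start)))
    rows <- implant(pid[p$i], p$spec, anchor = anch)
    if (!is.null(rows$visits)) visits[[length(visits) + 1L]] <- rows$visits
    if (!is.null(rows$diagnoses)) dxs[[length(dxs) + 1L]] <- rows$diagnoses
    if (!is.null(rows$labs)) labs[[length(labs) + 1L]] <- rows$labs
    if (!is.null(rows$medications)) meds[[length(meds) + 1L]] <- rows$medications
  }

  # background cohort-qualifying outpatient visit for every patient alive
  # at their visit date (clamped before death)
  bg_date <- year0 + sample(0:364, n, replace = TRUE)
  bg_date[died] <- pmin(bg_date[died], death[died])
  visits[[length(visits) + 1L]] <- data.table::data.table(
    visit_id = sprintf("VBG%06d", seq_len(n)), patient_id = pid,
    visit_type = "outpatient", start_date = bg_date, end_date = bg_date,
    facility_id = "C_CLINIC")

  # pregnancy episodes for some females 18-45 (kept clear of implanted
  # diabetes events, which all predate the cohort year tail)
  preg_ok <- which(sex == "female" & age >= 18L & age <= 45L &
                   stats::runif(n) < config$pregnancy_rate & !dis$t1d &
                   !dis$t2d)
  pregnancies <- if (length(preg_ok)) {
    st <- as.Date(sprintf("%d-01-01", config$span_start)) +
      sample(0:600, length(preg_ok), replace = TRUE)
    data.table::data.table(patient_id = pid[preg_ok], start_date = st,
                           end_date = st + 266L)
  } else empty_table("pregnancies")

  # registry hospital visits over the 12 months after index
  any_disease <- Reduce(`|`, dis)
  rate <- ifelse(any_disease, config$visit_rate[["disease"]],
                 config$visit_rate[["base"]])
  nvis <- stats::rpois(n, rate)
  nvis[died] <- 0L
  src <- rep(seq_len(n), nvis)
  m <- length(src)
  registry <- if (m) {
    cf <- config$in_system_model
    p_in <- stats::plogis(cf[["b0"]] + cf[["b_pcp"]] * has_pcp[src] +
                          cf[["b_dist"]] * dist_km[src])
    is_in <- stats::runif(m) < p_in
    facility <- character(m)
    facility[is_in] <- sample(hosp$facility_id, sum(is_in), replace = TRUE,
                              prob = c(0.45, 0.35, 0.20))
    if (any(!is_in)) {
      facility[!is_in] <- sample(out_hosp$facility_id, sum(!is_in),
                                 replace = TRUE)
    }
    data.table::data.table(
      patient_id = pid[src],
      date = index + sample(0:364, m, replace = TRUE),
      visit_type = ifelse(stats::runif(m) < config$ed_fraction,
                          "emergency", "inpatient"),
      facility_id = facility)
  } else empty_table("registry")

  ehr_dataset(
    patients = patients,
    visits = data.table::rbindlist(visits, fill = TRUE),
    diagnoses = if (length(dxs)) data.table::rbindlist(dxs) else empty_table("diagnoses"),
    labs = if (length(labs)) data.table::rbindlist(labs) else empty_table("labs"),
    medications = if (length(meds)) data.table::rbindlist(meds) else empty_table("medications"),
    pcp = pcp, pregnancies = pregnancies, facilities = fac,
    registry = registry)
}
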