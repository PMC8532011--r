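# Relational EHR data model: nine delimited-text tables and their invariants.
#
# The bundle mirrors a hospital enterprise data warehouse (patients, visits,
# diagnoses, labs, medications, primary-care-physician assignments,
# pregnancy episodes, facilities) plus an all-payer hospital-visit registry
# (the stand-in for a commercial statewide feed).  On-disk format is fixed:
# comma-separated, UTF-8, ISO-8601 dates, header row required — a single
# unambiguous dialect so write -> load round-trips are bit-exact.

#' @import data.table
NULL

EHR_TABLES <- c("patients", "visits", "diagnoses", "labs", "medications",
                "pcp", "pregnancies", "facilities", "registry")

SEX_LEVELS        <- c("female", "male", "unknown")
VISIT_TYPES       <- c("outpatient", "emergency", "inpatient")
REGISTRY_TYPES    <- c("emergency", "inpatient")
CODE_SYSTEMS      <- c("icd9", "icd10")
DX_RANKS          <- c("principal", "secondary", "unranked")
LAB_ANALYTES      <- c("serum_creatinine", "hba1c", "random_glucose",
                       "fasting_glucose", "urine_protein_dipstick",
                       "c_peptide", "diabetes_autoantibody")
QUAL_FLAGS        <- c("positive", "negative", "none")

#' Default medication drug-class vocabulary
#'
#' Controlled tokens for `medications$drug_class`: the antihyperglycemic
#' classes used by the diabetes rules, the long-acting muscarinic
#' antagonists (LAMA) used by the COPD rule, glucagon, plus `other`.
#'
#' @return character vector of allowed tokens
#' @export
default_drug_classes <- function() {
  c("lama", "glucagon", "metformin", "thiazolidinedione", "insulin",
    "sulfonylurea", "meglitinide", "dpp4_inhibitor",
    "alpha_glucosidase_inhibitor", "amylin_analogue", "incretin_mimetic",
    "other")
}

# column name -> storage class; Date columns handled specially on IO
ehr_schema <- function() {
  list(
    patients = list(cols = c(patient_id = "character", birth_date = "Date",
                             sex = "character", race_black = "logical",
                             death_date = "Date", home_lat = "numeric",
                             home_lon = "numeric")),
    visits = list(cols = c(visit_id = "character", patient_id = "character",
                           visit_type = "character", start_date = "Date",
                           end_date = "Date", facility_id = "character")),
    diagnoses = list(cols = c(patient_id = "character", visit_id = "character",
                              code = "character", code_system = "character",
                              rank = "character", date = "Date")),
    labs = list(cols = c(patient_id = "character", date = "Date",
                         analyte = "character", value = "numeric",
                         qualitative_flag = "character")),
    medications = list(cols = c(patient_id = "character", date = "Date",
                                drug_class = "character",
                                drug_name = "character")),
    pcp = list(cols = c(patient_id = "character",
                        has_in_system_pcp = "logical", as_of_date = "Date")),
    pregnancies = list(cols = c(patient_id = "character", start_date = "Date",
                                end_date = "Date")),
    facilities = list(cols = c(facility_id = "character", name = "character",
                               in_system = "logical", lat = "numeric",
                               lon = "numeric", is_hospital = "logical")),
    registry = list(cols = c(patient_id = "character", date = "Date",
                             visit_type = "character",
                             facility_id = "character"))
  )
}

#' Empty table with the documented columns
#'
#' @param table one of the nine table names
#' @return a zero-row `data.table` with correctly typed columns
#' @export
empty_table <- function(table) {
  sch <- ehr_schema()[[table]]$cols
  out <- lapply(sch, function(cl) switch(cl,
    character = character(0), numeric = numeric(0), logical = logical(0),
    Date = as.Date(character(0))))
  data.table::as.data.table(out)
}

coerce_table <- function(df, table) {
  sch <- ehr_schema()[[table]]$cols
  df <- data.table::as.data.table(df)
  missing <- setdiff(names(sch), names(df))
  if (length(missing)) {
    cf_validation_stop(sprintf("table \"%s\": missing column(s) %s", table,
                               paste(missing, collapse = ", ")),
                       "carefrag_schema_error")
  }
  df <- df[, names(sch), with = FALSE]
  for (col in names(sch)) {
    v <- df[[col]]
    tgt <- sch[[col]]
    if (tgt == "Date") {
      data.table::set(df, j = col, value = as_date_strict(v, paste0(table, "$", col)))
    } else if (tgt == "numeric" && !is.numeric(v)) {
      if (table == "labs" && col == "value") v <- sub("\\+$", "", v)
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        cf_validation_stop(sprintf(
          "table \"%s\", column \"%s\": non-numeric value at row(s) %s",
          table, col, paste(utils::head(bad, 5), collapse = ", ")),
          "carefrag_schema_error")
      }
      data.table::set(df, j = col, value = num)
    } else if (tgt == "logical" && !is.logical(v)) {
      lg <- as.logical(toupper(as.character(v)))
      data.table::set(df, j = col, value = lg)
    } else if (tgt == "character" && !is.character(v)) {
      data.table::set(df, j = col, value = as.character(v))
    }
  }
  # empty strings mean NA for optional character fields
  for (col in c("facility_id", "visit_id")) {
    if (col %in% names(df) && is.character(df[[col]])) {
      v <- df[[col]]
      v[!is.na(v) & v == ""] <- NA_character_
      data.table::set(df, j = col, value = v)
    }
  }
  df[]
}

#' Assemble an EHR dataset bundle
#'
#' @param patients,visits,diagnoses,labs,medications,pcp,pregnancies,facilities,registry
#'   data.frames following the documented schemas; omitted tables default to
#'   empty
#' @param validate run [validate_dataset()] (default TRUE)
#' @param drug_classes allowed medication class tokens
#' @return object of class `ehr_dataset` (a named list of data.tables)
#' @export
ehr_dataset <- function(patients = empty_table("patients"),
                        visits = empty_table("visits"),
                        diagnoses = empty_table("diagnoses"),
                        labs = empty_table("labs"),
                        medications = empty_table("medications"),
                        pcp = empty_table("pcp"),
                        pregnancies = empty_table("pregnancies"),
                        facilities = empty_table("facilities"),
                        registry = empty_table("registry"),
                        validate = TRUE,
                        drug_classes = default_drug_classes()) {
  tabs <- list(patients = patients, visits = visits, diagnoses = diagnoses,
               labs = labs, medications = medications, pcp = pcp,
               pregnancies = pregnancies, facilities = facilities,
               registry = registry)
  tabs <- mapply(coerce_table, tabs, names(tabs), SIMPLIFY = FALSE)
  ds <- structure(tabs, class = "ehr_dataset")
  if (validate) validate_dataset(ds, drug_classes = drug_classes)
  ds
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  for (nm in EHR_TABLES) cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

enum_check <- function(v, levels, table, col, allow_na = FALSE) {
  bad <- which(!(v %in% levels) & !(allow_na & is.na(v)))
  if (length(bad)) {
    cf_validation_stop(sprintf(
      "table \"%s\", column \"%s\": value \"%s\" at row %d not in {%s}",
      table, col, v[bad[1]], bad[1], paste(levels, collapse = ", ")),
      "carefrag_enum_error")
  }
}

#' Validate an EHR dataset
#'
#' Enforces every documented table invariant: enumerations, coordinate and
#' dipstick-grade ranges, date ordering, uniqueness, non-overlap of
#' pregnancy episodes, and referential integrity (every `patient_id` and
#' `facility_id` must resolve).  Each violation class raises a distinct
#' condition class under `carefrag_validation_error`.
#'
#' @param ds an `ehr_dataset`
#' @param drug_classes allowed medication class tokens
#' @return `ds`, invisibly, if valid
#' @export
validate_dataset <- function(ds, drug_classes = default_drug_classes()) {
  stopifnot(inherits(ds, "ehr_dataset"))
  p <- ds$patients
  if (anyDuplicated(p$patient_id)) {
    cf_validation_stop(sprintf("patients: duplicated patient_id \"%s\"",
                               p$patient_id[duplicated(p$patient_id)][1]),
                       "carefrag_unique_error")
  }
  enum_check(p$sex, SEX_LEVELS, "patients", "sex")
  bad <- which(!is.na(p$home_lat) & (p$home_lat < -90 | p$home_lat > 90 |
               p$home_lon < -180 | p$home_lon > 180))
  if (length(bad)) {
    cf_validation_stop(sprintf("patients: coordinates out of range at row %d", bad[1]),
                       "carefrag_range_error")
  }

  v <- ds$visits
  enum_check(v$visit_type, VISIT_TYPES, "visits", "visit_type")
  bad <- which(v$end_date < v$start_date)
  if (length(bad)) {
    cf_validation_stop(sprintf("visits: end_date before start_date at row %d", bad[1]),
                       "carefrag_range_error")
  }
  bad <- which(v$visit_type %in% c("emergency", "inpatient") & is.na(v$facility_id))
  if (length(bad)) {
    cf_validation_stop(sprintf(
      "visits: facility_id required for emergency/inpatient visits (row %d)", bad[1]),
      "carefrag_missing_error")
  }

  dx <- ds$diagnoses
  bad <- which(is.na(dx$code) | dx$code == "")
  if (length(bad)) {
    cf_validation_stop(sprintf("diagnoses: empty code at row %d", bad[1]),
                       "carefrag_missing_error")
  }
  enum_check(dx$code_system, CODE_SYSTEMS, "diagnoses", "code_system")
  enum_check(dx$rank, DX_RANKS, "diagnoses", "rank")

  lb <- ds$labs
  enum_check(lb$analyte, LAB_ANALYTES, "labs", "analyte")
  enum_check(lb$qualitative_flag, QUAL_FLAGS, "labs", "qualitative_flag")
  dip <- which(lb$analyte == "urine_protein_dipstick")
  bad <- dip[is.na(lb$value[dip]) | lb$value[dip] < 0 | lb$value[dip] > 4 |
             lb$value[dip] != floor(lb$value[dip])]
  if (length(bad)) {
    cf_validation_stop(sprintf(
      "labs: dipstick grade must be an integer 0..4 (\"4+\" top grade); row %d has %s",
      bad[1], format(lb$value[bad[1]])), "carefrag_range_error")
  }
  ql <- which(lb$analyte %in% c("c_peptide", "diabetes_autoantibody"))
  bad <- ql[lb$qualitative_flag[ql] == "none"]
  if (length(bad)) {
    cf_validation_stop(sprintf(
      "labs: c_peptide/diabetes_autoantibody rows must carry a positive/negative flag (row %d)",
      bad[1]), "carefrag_enum_error")
  }

  enum_check(ds$medications$drug_class, drug_classes, "medications", "drug_class")

  pc <- ds$pcp
  if (nrow(pc) && anyDuplicated(pc[, c("patient_id", "as_of_date")])) {
    cf_validation_stop("pcp: more than one row per patient per as_of_date",
                       "carefrag_unique_error")
  }

  pr <- ds$pregnancies
  bad <- which(pr$end_date < pr$start_date)
  if (length(bad)) {
    cf_validation_stop(sprintf("pregnancies: end before start at row %d", bad[1]),
                       "carefrag_range_error")
  }
  if (nrow(pr) > 1L) {
    o <- pr[order(patient_id, start_date)]
    ov <- which(o$patient_id[-1] == o$patient_id[-nrow(o)] &
                o$start_date[-1] <= o$end_date[-nrow(o)])
    if (length(ov)) {
      cf_validation_stop(sprintf(
        "pregnancies: overlapping episodes for patient \"%s\"", o$patient_id[ov[1] + 1L]),
        "carefrag_overlap_error")
    }
  }

  fc <- ds$facilities
  if (anyDuplicated(fc$facility_id)) {
    cf_validation_stop("facilities: duplicated facility_id", "carefrag_unique_error")
  }
  bad <- which(fc$lat < -90 | fc$lat > 90 | fc$lon < -180 | fc$lon > 180)
  if (length(bad)) {
    cf_validation_stop(sprintf("facilities: coordinates out of range at row %d", bad[1]),
                       "carefrag_range_error")
  }

  rg <- ds$registry
  enum_check(rg$visit_type, REGISTRY_TYPES, "registry", "visit_type")

  # referential integrity
  ids <- p$patient_id
  for (nm in c("visits", "diagnoses", "labs", "medications", "pcp",
               "pregnancies", "registry")) {
    ref <- ds[[nm]]$patient_id
    orphan <- setdiff(unique(ref), ids)
    if (length(orphan)) {
      cf_validation_stop(sprintf(
        "table \"%s\": patient_id(s) %s not present in patients", nm,
        paste(sprintf("\"%s\"", utils::head(orphan, 5)), collapse = ", ")),
        "carefrag_integrity_error")
    }
  }
  fids <- fc$facility_id
  for (nm in c("visits", "registry")) {
    ref <- ds[[nm]]$facility_id
    orphan <- setdiff(unique(ref[!is.na(ref)]), fids)
    if (length(orphan)) {
      cf_validation_stop(sprintf(
        "table \"%s\": facility_id(s) %s not present in facilities", nm,
        paste(sprintf("\"%s\"", utils::head(orphan, 5)), collapse = ", ")),
        "carefrag_integrity_error")
    }
  }
  # birth precedes events
  if (nrow(ds$visits)) {
    first <- ds$visits[, .(d = min(start_date)), by = patient_id]
    m <- merge(first, p[, .(patient_id, birth_date)], by = "patient_id")
    bad <- which(m$d < m$birth_date)
    if (length(bad)) {
      cf_validation_stop(sprintf(
        "visits: event precedes birth_date for patient \"%s\"", m$patient_id[bad[1]]),
        "carefrag_chronology_error")
    }
  }
  invisible(ds)
}

#' Load an EHR dataset from a directory of CSV files
#'
#' Expects the nine files `patients.csv`, `visits.csv`, `diagnoses.csv`,
#' `labs.csv`, `medications.csv`, `pcp.csv`, `pregnancies.csv`,
#' `facilities.csv`, `registry.csv` with documented headers.  A missing file
#' is fatal; malformed rows and integrity breaches raise classed errors
#' naming the offending rows/ids.
#'
#' @param directory_path directory containing the CSV files
#' @param validate run validation after loading (default TRUE)
#' @return an `ehr_dataset`
#' @export
load_dataset <- function(directory_path, validate = TRUE) {
  if (!dir.exists(directory_path)) {
    cf_stop(sprintf("directory \"%s\" does not exist", directory_path),
            "carefrag_io_error")
  }
  tabs <- list()
  for (nm in EHR_TABLES) {
    f <- file.path(directory_path, paste0(nm, ".csv"))
    if (!file.exists(f)) {
      cf_stop(sprintf("missing table file \"%s\"", f), "carefrag_io_error")
    }
    raw <- data.table::fread(f, colClasses = "character", encoding = "UTF-8",
                             na.strings = NULL, keepLeadingZeros = TRUE)
    tabs[[nm]] <- raw
  }
  do.call(ehr_dataset, c(tabs, list(validate = validate)))
}

#' Write an EHR dataset to a directory of CSV files
#'
#' Inverse of [load_dataset()]: `load_dataset(write_dataset(ds, dir))`
#' reproduces `ds` field for field (UTF-8, ISO-8601 dates).
#'
#' @param ds an `ehr_dataset`
#' @param directory_path output directory (created if needed)
#' @return `directory_path`, invisibly
#' @export
write_dataset <- function(ds, directory_path) {
  stopifnot(inherits(ds, "ehr_dataset"))
  ok <- dir.exists(directory_path) || dir.create(directory_path, recursive = TRUE)
  if (!ok) cf_stop(sprintf("cannot create \"%s\"", directory_path), "carefrag_io_error")
  for (nm in EHR_TABLES) {
    out <- data.table::copy(ds[[nm]])
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) {
        data.table::set(out, j = col, value = format(out[[col]], "%Y-%m-%d"))
      }
    }
    data.table::fwrite(out, file.path(directory_path, paste0(nm, ".csv")),
                       bom = FALSE, na = "", quote = "auto")
  }
  invisible(directory_path)
}

#' Select the study cohort for a calendar year
#'
#' Cohort membership requires (1) at least one visit of any type in
#' `cohort_year` at an in-system facility (a visits-table row with a missing
#' `facility_id` counts as in-system: the warehouse analog only records
#' in-system encounters), (2) age >= 18 completed years at the age-reference
#' date (default: January 1 of the following year, the study index date),
#' and (3) no recorded death in `cohort_year` or earlier.
#'
#' @param ds an `ehr_dataset`
#' @param cohort_year integer calendar year
#' @param age_reference_date `Date`; default `cohort_year + 1`-01-01
#' @return character vector of qualifying patient ids (sorted)
#' @export
filter_cohort <- function(ds, cohort_year,
                          age_reference_date = as.Date(sprintf("%d-01-01", cohort_year + 1))) {
  stopifnot(inherits(ds, "ehr_dataset"))
  v <- ds$visits
  in_sys_fac <- ds$facilities$facility_id[ds$facilities$in_system]
  yr <- as.integer(format(v$start_date, "%Y"))
  vis_ok <- yr == cohort_year & (is.na(v$facility_id) | v$facility_id %in% in_sys_fac)
  ids_visited <- unique(v$patient_id[vis_ok])
  p <- ds$patients[patient_id %in% ids_visited]
  if (nrow(p) == 0L) return(character(0))
  age <- age_at(p$birth_date, age_reference_date)
  dead <- !is.na(p$death_date) &
    as.integer(format(p$death_date, "%Y")) <= cohort_year
  sort(p$patient_id[age >= 18L & !dead])
}

#' Assemble one patient's record across all tables
#'
#' @param ds an `ehr_dataset`
#' @param patient_id a single patient id present in `ds$patients`
#' @return object of class `patient_record`: the patient's rows from every
#'   table plus the `patient` demographics row
#' @export
patient_record <- function(ds, patient_id) {
  stopifnot(inherits(ds, "ehr_dataset"), length(patient_id) == 1L)
  if (!patient_id %in% ds$patients$patient_id) {
    cf_stop(sprintf("unknown patient \"%s\"", patient_id), "carefrag_integrity_error")
  }
  pid <- patient_id
  rec <- list(patient = ds$patients[patient_id == pid])
  for (nm in setdiff(EHR_TABLES, c("patients", "facilities"))) {
    rec[[nm]] <- ds[[nm]][patient_id == pid]
  }
  rec$facilities <- ds$facilities
  structure(rec, class = "patient_record")
}

# one-patient dataset from a record: lets single-record detectors delegate
# to the vectorized labelling core (single source of rule logic)
record_as_dataset <- function(record) {
  ehr_dataset(patients = record$patient, visits = record$visits,
              diagnoses = record$diagnoses, labs = record$labs,
              medications = record$medications, pcp = record$pcp,
              pregnancies = record$pregnancies, facilities = record$facilities,
              registry = record$registry, validate = FALSE)
}
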