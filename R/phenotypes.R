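# Computable phenotypes for the five chronic-disease subgroups.
#
# Each rule is a deterministic function of structured rows (diagnosis codes,
# labs, medications, pregnancy episodes):
#   * asthma  — >=1 asthma diagnosis code in the cohort year;
#   * CKD     — two CKD-range measurements (MDRD eGFR < 60 mL/min/1.73m2 or
#               urine-protein dipstick >= 1+) >= 3 calendar months apart;
#   * COPD    — age >= 40 at the index date and any of four conditions
#               (outpatient dx followed by a LAMA prescription within 6
#               months; >=1 ED dx or >=2 outpatient dx; inpatient principal
#               dx; inpatient principal respiratory-failure dx with a
#               secondary acute-exacerbation dx on the same stay);
#   * diabetes — Nichols: >=1 inpatient diabetes dx, or any 2 of 5 event
#               types within 2 years (pregnancy-dated events excluded; a
#               metformin/thiazolidinedione-only prescription pair does not
#               count when no other manifestation exists);
#   * type 1 vs type 2 — Klompas: four type-1 conditions over the full
#               2011-2018 span; diabetics failing all four are type 2.
#
# The single-record detectors (detect_*) delegate to the same vectorized
# core as label_all(), so there is exactly one implementation of each rule.

#' Phenotyping configuration
#'
#' @param cohort_year calendar year defining the cohort and the asthma rule
#' @param span_start,span_end first/last year of the observation span used
#'   by the chronic-disease rules (look-back analog of 2011-2018)
#' @param index_date study index date; defaults to Jan 1 after `cohort_year`
#' @param ckd_window `"full"` (default: whole span; chronicity needs a
#'   3-month separation that a 1-year window needlessly constrains) or
#'   `"cohort_year"`
#' @param ckd_mixed_pairs if `TRUE` (default) one eGFR measurement and one
#'   dipstick measurement >= 3 months apart qualify; `FALSE` requires the
#'   pair to share a measurement type
#' @param klompas_counting `"rows"` (default: count diagnosis rows) or
#'   `"days"` (count distinct dates)
#' @param oral_hypo_other_than_metformin drug-class tokens blocking Klompas
#'   condition 2
#' @param code_sets phenotyping vocabulary, see [default_code_sets()]
#' @return object of class `phenotype_config`
#' @export
phenotype_config <- function(cohort_year = 2018L,
                             span_start = 2011L, span_end = cohort_year,
                             index_date = as.Date(sprintf("%d-01-01", cohort_year + 1)),
                             ckd_window = c("full", "cohort_year"),
                             ckd_mixed_pairs = TRUE,
                             klompas_counting = c("rows", "days"),
                             oral_hypo_other_than_metformin =
                               c("sulfonylurea", "meglitinide", "dpp4_inhibitor",
                                 "alpha_glucosidase_inhibitor", "thiazolidinedione"),
                             code_sets = default_code_sets()) {
  structure(list(
    cohort_year = as.integer(cohort_year),
    span_start = as.integer(span_start), span_end = as.integer(span_end),
    index_date = as.Date(index_date),
    ckd_window = match.arg(ckd_window),
    ckd_mixed_pairs = isTRUE(ckd_mixed_pairs),
    klompas_counting = match.arg(klompas_counting),
    oral_hypo_other_than_metformin = oral_hypo_other_than_metformin,
    code_sets = code_sets), class = "phenotype_config")
}

ANTIHYPERGLYCEMIC_CLASSES <- c(
  "alpha_glucosidase_inhibitor", "amylin_analogue", "metformin",
  "dpp4_inhibitor", "incretin_mimetic", "insulin", "meglitinide",
  "sulfonylurea", "thiazolidinedione")

#' MDRD estimated glomerular filtration rate
#'
#' `eGFR = 175 * age^-0.203 * creatinine^-1.154 * 0.742[female] *
#' 1.212[Black]`, in mL/min/1.73m2.  Adult equation: `age` must be >= 18.
#'
#' @param serum_creatinine mg/dL, positive
#' @param age years, >= 18
#' @param sex `"female"`, `"male"` or `"unknown"` (the 0.742 factor applies
#'   only to `"female"`)
#' @param race_black logical: apply the 1.212 factor
#' @return eGFR vector
#' @export
#' @examples
#' egfr_mdrd(1.0, 50, "female", FALSE)  # ~58.69
egfr_mdrd <- function(serum_creatinine, age, sex, race_black) {
  if (any(!is.finite(serum_creatinine)) || any(serum_creatinine <= 0)) {
    cf_stop("serum creatinine must be positive", "carefrag_domain_error")
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    cf_stop("MDRD equation requires age >= 18", "carefrag_domain_error")
  }
  175 * age^-0.203 * serum_creatinine^-1.154 *
    ifelse(sex == "female", 0.742, 1) * ifelse(race_black, 1.212, 1)
}

# ---------------------------------------------------------------------------
# vectorized labelling core

# diagnosis rows augmented with visit type and span filter; rows without a
# visit link are treated as outpatient (ambulatory default)
dx_with_type <- function(ds, config) {
  dx <- data.table::copy(ds$diagnoses)
  if (nrow(dx) == 0L) {
    dx[, visit_type := character(0)]
    return(dx)
  }
  vt <- ds$visits[, .(visit_id, visit_type)]
  dx <- merge(dx, vt, by = "visit_id", all.x = TRUE, sort = FALSE)
  dx[is.na(visit_type), visit_type := "outpatient"]
  yr <- as.integer(format(dx$date, "%Y"))
  dx[yr >= config$span_start & yr <= config$span_end]
}

asthma_flags <- function(dx, ids, config) {
  hits <- any_match(dx, "asthma_dx",
                    date_range = as.Date(sprintf("%d-%s", config$cohort_year,
                                                 c("01-01", "12-31"))),
                    code_sets = config$code_sets)
  ev <- if (nrow(hits)) hits[, .(evidence = sprintf(
    "dx_in_year:%s@%s", code[1], format(date[1]))), by = patient_id]
  else data.table::data.table(patient_id = character(0), evidence = character(0))
  list(flag = ids %in% hits$patient_id,
       evidence = ev$evidence[match(ids, ev$patient_id)])
}

ckd_qualifying <- function(ds, ids, config) {
  lb <- ds$labs[patient_id %in% ids]
  if (config$ckd_window == "cohort_year") {
    yr <- as.integer(format(lb$date, "%Y"))
    lb <- lb[yr == config$cohort_year]
  } else {
    yr <- as.integer(format(lb$date, "%Y"))
    lb <- lb[yr >= config$span_start & yr <= config$span_end]
  }
  out <- data.table::data.table(patient_id = character(0),
                                date = as.Date(character(0)),
                                type = character(0), detail = character(0))
  cr <- lb[analyte == "serum_creatinine" & !is.na(value) & value > 0]
  if (nrow(cr)) {
    cr <- merge(cr, ds$patients[, .(patient_id, birth_date, sex, race_black)],
                by = "patient_id", sort = FALSE)
    age <- age_at(cr$birth_date, cr$date)
    cr <- cr[age >= 18L]           # adult MDRD equation only
    if (nrow(cr)) {
      age <- age_at(cr$birth_date, cr$date)
      g <- egfr_mdrd(cr$value, age, cr$sex, cr$race_black)
      keep <- g < 60
      if (any(keep)) {
        out <- rbind(out, data.table::data.table(
          patient_id = cr$patient_id[keep], date = cr$date[keep],
          type = "egfr_lt_60", detail = sprintf("egfr=%.1f", g[keep])))
      }
    }
  }
  dip <- lb[analyte == "urine_protein_dipstick" & !is.na(value) & value >= 1]
  if (nrow(dip)) {
    out <- rbind(out, data.table::data.table(
      patient_id = dip$patient_id, date = dip$date,
      type = "proteinuria", detail = sprintf("dipstick=%d+", as.integer(dip$value))))
  }
  out
}

# two qualifying measurements >= 3 calendar months apart (inclusive)
ckd_pair_ok <- function(dates) {
  if (length(dates) < 2L) return(FALSE)
  max(dates) >= add_months(min(dates), 3L)
}

ckd_flags <- function(ds, ids, config) {
  q <- ckd_qualifying(ds, ids, config)
  flag <- rep(FALSE, length(ids)); evid <- rep(NA_character_, length(ids))
  if (nrow(q)) {
    for (g in split(q, q$patient_id)) {
      ok <- if (config$ckd_mixed_pairs) ckd_pair_ok(g$date)
            else any(vapply(split(g$date, g$type), ckd_pair_ok, logical(1)))
      if (ok) {
        i <- match(g$patient_id[1], ids)
        o <- g[order(date)]
        flag[i] <- TRUE
        evid[i] <- sprintf("%s@%s+%s@%s", o$type[1], format(o$date[1]),
                           o$type[nrow(o)], format(o$date[nrow(o)]))
      }
    }
  }
  list(flag = flag, evidence = evid)
}

copd_flags <- function(ds, dx, ids, ages, config) {
  cs <- config$code_sets
  copd <- any_match(dx, "copd_dx", code_sets = cs)
  flag <- rep(FALSE, length(ids)); evid <- rep(NA_character_, length(ids))
  eligible <- ids[!is.na(ages) & ages >= 40L]

  # condition 1: outpatient dx followed by LAMA within 6 calendar months
  c1 <- character(0)
  op <- copd[visit_type == "outpatient" & patient_id %in% eligible]
  lama <- ds$medications[drug_class == "lama" & patient_id %in% eligible]
  if (nrow(op) && nrow(lama)) {
    j <- merge(op[, .(patient_id, dx_date = date)],
               lama[, .(patient_id, rx_date = date)],
               by = "patient_id", allow.cartesian = TRUE)
    j <- j[rx_date >= dx_date & rx_date <= add_months(dx_date, 6L)]
    c1 <- unique(j$patient_id)
  }
  # condition 2: >=1 ED dx OR >=2 outpatient dx
  cnt <- copd[patient_id %in% eligible,
              .(ed = sum(visit_type == "emergency"),
                op = sum(visit_type == "outpatient")), by = patient_id]
  c2 <- cnt[ed >= 1L | op >= 2L, patient_id]
  # condition 3: inpatient principal dx
  c3 <- unique(copd[visit_type == "inpatient" & rank == "principal" &
                    patient_id %in% eligible, patient_id])
  # condition 4: same inpatient stay, principal respiratory failure +
  # secondary acute exacerbation
  rf <- any_match(dx[visit_type == "inpatient" & rank == "principal" &
                     patient_id %in% eligible & !is.na(visit_id)],
                  "resp_failure_dx", code_sets = cs)
  ex <- any_match(dx[visit_type == "inpatient" & rank == "secondary" &
                     patient_id %in% eligible & !is.na(visit_id)],
                  "copd_exacerbation_dx", code_sets = cs)
  c4 <- unique(rf$patient_id[rf$visit_id %in% ex$visit_id &
                             paste(rf$patient_id, rf$visit_id) %in%
                               paste(ex$patient_id, ex$visit_id)])
  for (cond in list(list("condition1", c1), list("condition2", c2),
                    list("condition3", c3), list("condition4", c4))) {
    new <- match(setdiff(cond[[2]], ids[flag]), ids)
    new <- new[!is.na(new)]
    flag[new] <- TRUE
    evid[new] <- cond[[1]]          # evidence names the first condition met
  }
  list(flag = flag, evidence = evid)
}

#' Enumerate qualifying diabetes events for one patient
#'
#' The five event types: HbA1c >= 6.5%, random glucose >= 200 mg/dL,
#' fasting glucose >= 126 mg/dL, an outpatient diabetes diagnosis code, and
#' an antihyperglycemic prescription.  Events are deduplicated to one per
#' (type, day); events dated within a pregnancy episode are removed; the
#' result is sorted chronologically.  Prescription events whose day's drug
#' classes are all metformin/thiazolidinedione are marked `weak` (they
#' cannot pair up on their own).
#'
#' @param record a [patient_record()]
#' @param config a [phenotype_config()]
#' @return data.table with columns `event_type`, `date`, `weak`
#' @export
enumerate_diabetes_events <- function(record, config = phenotype_config()) {
  stopifnot(inherits(record, "patient_record"))
  ds <- record_as_dataset(record)
  diabetes_events(ds, dx_with_type(ds, config), record$patient$patient_id, config)
}

diabetes_events <- function(ds, dx, ids, config) {
  lb <- ds$labs[patient_id %in% ids]
  yr <- as.integer(format(lb$date, "%Y"))
  lb <- lb[yr >= config$span_start & yr <= config$span_end]
  ev <- list(
    lb[analyte == "hba1c" & value >= 6.5,
       .(patient_id, date, event_type = "hba1c_ge_6_5", weak = FALSE)],
    lb[analyte == "random_glucose" & value >= 200,
       .(patient_id, date, event_type = "random_glucose_ge_200", weak = FALSE)],
    lb[analyte == "fasting_glucose" & value >= 126,
       .(patient_id, date, event_type = "fasting_glucose_ge_126", weak = FALSE)])
  op <- any_match(dx[visit_type == "outpatient" & patient_id %in% ids],
                  "diabetes_dx", code_sets = config$code_sets)
  if (nrow(op)) {
    ev <- c(ev, list(op[, .(patient_id, date, event_type = "outpatient_dx",
                            weak = FALSE)]))
  }
  rx <- ds$medications[patient_id %in% ids &
                       drug_class %in% ANTIHYPERGLYCEMIC_CLASSES]
  yr <- as.integer(format(rx$date, "%Y"))
  rx <- rx[yr >= config$span_start & yr <= config$span_end]
  if (nrow(rx)) {
    rxe <- rx[, .(weak = all(drug_class %in% c("metformin", "thiazolidinedione"))),
              by = .(patient_id, date)]
    ev <- c(ev, list(rxe[, .(patient_id, date,
                             event_type = "antihyperglycemic_rx", weak)]))
  }
  ev <- data.table::rbindlist(ev, use.names = TRUE)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  date = as.Date(character(0)),
                                  event_type = character(0), weak = logical(0)))
  }
  ev <- unique(ev, by = c("patient_id", "event_type", "date"))
  # pregnancy exclusion (event-list rule only)
  pr <- ds$pregnancies[patient_id %in% ids]
  if (nrow(pr)) {
    drop <- rep(FALSE, nrow(ev))
    for (k in seq_len(nrow(pr))) {
      drop <- drop | (ev$patient_id == pr$patient_id[k] &
                      ev$date >= pr$start_date[k] & ev$date <= pr$end_date[k])
    }
    ev <- ev[!drop]
  }
  ev[order(patient_id, date, event_type)]
}

diabetes_flags <- function(ds, dx, ids, config) {
  cs <- config$code_sets
  inp <- any_match(dx[visit_type == "inpatient" & patient_id %in% ids],
                   "diabetes_dx", code_sets = cs)
  ev <- diabetes_events(ds, dx, ids, config)
  flag <- rep(FALSE, length(ids)); evid <- rep(NA_character_, length(ids))
  has_inp <- ids %in% inp$patient_id
  flag[has_inp] <- TRUE
  evid[has_inp] <- "inpatient_dx"
  if (nrow(ev)) {
    for (g in split(ev, ev$patient_id)) {
      i <- match(g$patient_id[1], ids)
      if (is.na(i) || flag[i]) next
      if (nrow(g) < 2L || all(g$weak)) next   # metformin/TZD-only never pairs
      gaps_ok <- g$date[-1] <= add_months(g$date[-nrow(g)], 24L)
      if (any(gaps_ok)) {
        k <- which(gaps_ok)[1]
        flag[i] <- TRUE
        evid[i] <- sprintf("event_pair:%s@%s+%s@%s",
                           g$event_type[k], format(g$date[k]),
                           g$event_type[k + 1L], format(g$date[k + 1L]))
      }
    }
  }
  list(flag = flag, evidence = evid)
}

klompas_flags <- function(ds, dx, ids, diabetic, config) {
  cs <- config$code_sets
  t1 <- any_match(dx[patient_id %in% ids], "t1d_dx", code_sets = cs)
  t2 <- any_match(dx[patient_id %in% ids], "t2d_dx", code_sets = cs)
  if (config$klompas_counting == "days") {
    t1 <- unique(t1, by = c("patient_id", "date"))
    t2 <- unique(t2, by = c("patient_id", "date"))
  }
  n1 <- table(factor(t1$patient_id, levels = ids))
  n2 <- table(factor(t2$patient_id, levels = ids))
  md <- ds$medications[patient_id %in% ids]
  yr <- as.integer(format(md$date, "%Y"))
  md <- md[yr >= config$span_start & yr <= config$span_end]
  glucagon <- ids %in% md[drug_class == "glucagon", patient_id]
  oral_other <- ids %in% md[drug_class %in% config$oral_hypo_other_than_metformin,
                            patient_id]
  lb <- ds$labs[patient_id %in% ids]
  yr <- as.integer(format(lb$date, "%Y"))
  lb <- lb[yr >= config$span_start & yr <= config$span_end]
  cpep_neg <- ids %in% lb[analyte == "c_peptide" & qualitative_flag == "negative",
                          patient_id]
  auto_pos <- ids %in% lb[analyte == "diabetes_autoantibody" &
                          qualitative_flag == "positive", patient_id]
  more_t1 <- as.integer(n1) > as.integer(n2)   # strict: ties fail 1-2
  conds <- cbind(k1 = more_t1 & glucagon,
                 k2 = more_t1 & !oral_other,
                 k3 = cpep_neg, k4 = auto_pos)
  t1d <- diabetic & (conds[, 1] | conds[, 2] | conds[, 3] | conds[, 4])
  branch <- apply(conds, 1L, function(z) if (any(z)) paste0("klompas", which(z)[1]) else NA_character_)
  t2d <- diabetic & !t1d
  list(t1d = t1d, t2d = t2d,
       evidence = ifelse(t1d, branch, ifelse(t2d, "not_type1", NA_character_)))
}

#' Label all cohort patients with the five disease flags
#'
#' Runs every detector over the dataset and returns one row per patient:
#' boolean flags `asthma`, `ckd`, `copd`, `diabetes`, `t1d`, `t2d` plus an
#' evidence column per flag naming the satisfied rule branch and its key
#' dates/codes.  `t1d` and `t2d` are mutually exclusive and each implies
#' `diabetes`.  Deterministic and invariant to input row order.
#'
#' @param ds an `ehr_dataset`
#' @param config a [phenotype_config()]
#' @param patient_ids patients to label; defaults to
#'   `filter_cohort(ds, config$cohort_year)`
#' @return a data.table of labels, one row per patient
#' @export
label_all <- function(ds, config = phenotype_config(),
                      patient_ids = filter_cohort(ds, config$cohort_year)) {
  stopifnot(inherits(ds, "ehr_dataset"), inherits(config, "phenotype_config"))
  ids <- patient_ids
  if (length(ids) == 0L) {
    return(data.table::data.table(
      patient_id = character(0), asthma = logical(0), ckd = logical(0),
      copd = logical(0), diabetes = logical(0), t1d = logical(0),
      t2d = logical(0), asthma_evidence = character(0),
      ckd_evidence = character(0), copd_evidence = character(0),
      diabetes_evidence = character(0), diabetes_type_evidence = character(0)))
  }
  dx <- dx_with_type(ds, config)
  dx <- dx[patient_id %in% ids]
  p <- ds$patients[match(ids, patient_id)]
  ages <- age_at(p$birth_date, config$index_date)

  a <- asthma_flags(dx, ids, config)
  k <- ckd_flags(ds, ids, config)
  c <- copd_flags(ds, dx, ids, ages, config)
  d <- diabetes_flags(ds, dx, ids, config)
  t <- klompas_flags(ds, dx, ids, d$flag, config)

  data.table::data.table(
    patient_id = ids, asthma = a$flag, ckd = k$flag, copd = c$flag,
    diabetes = d$flag, t1d = t$t1d, t2d = t$t2d,
    asthma_evidence = a$evidence, ckd_evidence = k$evidence,
    copd_evidence = c$evidence, diabetes_evidence = d$evidence,
    diabetes_type_evidence = t$evidence)
}

# -- single-record detectors -------------------------------------------------

record_labels <- function(record, config) {
  ds <- record_as_dataset(record)
  label_all(ds, config, patient_ids = record$patient$patient_id)
}

#' Detect asthma for one patient
#'
#' @param record a [patient_record()]
#' @param year cohort year for the ">=1 diagnosis code in the year" rule
#' @param config a [phenotype_config()] (its `cohort_year` is overridden by
#'   `year`)
#' @return list with `flag` (logical) and `evidence`
#' @export
detect_asthma <- function(record, year, config = phenotype_config()) {
  config$cohort_year <- as.integer(year)
  if (config$span_end < config$cohort_year) config$span_end <- config$cohort_year
  lab <- record_labels(record, config)
  list(flag = lab$asthma, evidence = lab$asthma_evidence)
}

#' Detect chronic kidney disease for one patient
#'
#' @param record a [patient_record()]
#' @param config a [phenotype_config()]; set `ckd_window` / `ckd_mixed_pairs`
#'   there
#' @return list with `flag` and `evidence`
#' @export
detect_ckd <- function(record, config = phenotype_config()) {
  lab <- record_labels(record, config)
  list(flag = lab$ckd, evidence = lab$ckd_evidence)
}

#' Detect chronic obstructive pulmonary disease for one patient
#'
#' @param record a [patient_record()]
#' @param age_at_index optional age override; defaults to the age at
#'   `config$index_date`
#' @param config a [phenotype_config()]
#' @return list with `flag` and `evidence` naming the first satisfied
#'   condition
#' @export
detect_copd <- function(record, age_at_index = NULL, config = phenotype_config()) {
  ds <- record_as_dataset(record)
  id <- record$patient$patient_id
  dx <- dx_with_type(ds, config)
  age <- if (is.null(age_at_index)) {
    age_at(record$patient$birth_date, config$index_date)
  } else as.integer(age_at_index)
  r <- copd_flags(ds, dx, id, age, config)
  list(flag = r$flag, evidence = r$evidence)
}

#' Detect diabetes (Nichols rule) for one patient
#'
#' @param record a [patient_record()]
#' @param config a [phenotype_config()]
#' @return list with `flag` and `evidence`
#' @export
detect_diabetes <- function(record, config = phenotype_config()) {
  lab <- record_labels(record, config)
  list(flag = lab$diabetes, evidence = lab$diabetes_evidence)
}

#' Classify a diabetic patient as type 1 or type 2 (Klompas rule)
#'
#' Errors if the record does not satisfy [detect_diabetes()].
#'
#' @param record a [patient_record()]
#' @param config a [phenotype_config()]
#' @return list with `type` (`"t1d"` or `"t2d"`) and `evidence`
#' @export
classify_diabetes_type <- function(record, config = phenotype_config()) {
  lab <- record_labels(record, config)
  if (!lab$diabetes) {
    cf_stop("classify_diabetes_type() requires a record satisfying detect_diabetes()",
            "carefrag_domain_error")
  }
  list(type = if (lab$t1d) "t1d" else "t2d",
       evidence = lab$diabetes_type_evidence)
}
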