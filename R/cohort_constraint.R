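# Constraint-based subcohort selection and care-fragmentation metrics.
#
# The selection rule is the parameterized primary-care-physician constraint:
# a patient fulfills it iff they have an in-system primary care physician
# AND reside within d km (geodesic, boundary inclusive) of at least one
# in-system hospital.  Fragmentation metrics are ratios of registry hospital
# visits (ED + inpatient): numerator in-system (or a single named hospital),
# denominator anywhere, over a closed follow-up window.

#' Constraint parameters
#'
#' @param d_km distance threshold in kilometres (>= 0), or `Inf` for the
#'   unbounded sentinel (distance ceases to matter; selection reduces to the
#'   PCP requirement)
#' @param pcp_as_of_date `Date` at which the PCP assignment is read (the
#'   most recent `pcp` row with `as_of_date` on or before it)
#' @return object of class `constraint_params`
#' @export
constraint_params <- function(d_km = 8, pcp_as_of_date = as.Date("2019-01-01")) {
  if (!is.numeric(d_km) || length(d_km) != 1L || is.na(d_km) || d_km < 0) {
    cf_stop("d_km must be a single nonnegative number (Inf = unbounded)",
            "carefrag_domain_error")
  }
  structure(list(d_km = d_km, pcp_as_of_date = as.Date(pcp_as_of_date)),
            class = "constraint_params")
}

#' Follow-up window
#'
#' Closed date interval; a registry visit dated on either endpoint counts.
#'
#' @param start_date,end_date `Date`s, `start_date <= end_date`
#' @param label window label, e.g. `"6m"`, `"12m"`
#' @return object of class `follow_up_window`
#' @export
follow_up_window <- function(start_date, end_date, label = "custom") {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) {
    cf_stop("window end precedes start", "carefrag_domain_error")
  }
  structure(list(start_date = start_date, end_date = end_date, label = label),
            class = "follow_up_window")
}

#' Standard follow-up windows from an index date
#'
#' The subsequent 6 months (index to index + 6 months - 1 day) and the
#' subsequent 12 months, mirroring Jan 1-Jun 30 and Jan 1-Dec 31 for a
#' Jan 1 index.
#'
#' @param index_date `Date`
#' @return named list of two [follow_up_window()]s, `"6m"` and `"12m"`
#' @export
default_windows <- function(index_date = as.Date("2019-01-01")) {
  index_date <- as.Date(index_date)
  list(`6m` = follow_up_window(index_date, add_months(index_date, 6L) - 1L, "6m"),
       `12m` = follow_up_window(index_date, add_months(index_date, 12L) - 1L, "12m"))
}

#' In-system hospitals of a facility table
#'
#' @param facilities facility table
#' @return rows with `in_system & is_hospital`
#' @export
in_system_hospitals <- function(facilities) {
  facilities[facilities$in_system & facilities$is_hospital, , drop = FALSE]
}

# per-patient constraint inputs: PCP flag at the as-of date and min distance
# to the in-system hospitals.  Missing home coordinates or a missing PCP row
# evaluate to "not fulfilling" (never silently dropped: counts returned).
constraint_inputs <- function(patient_ids, ds, params) {
  hosp <- in_system_hospitals(ds$facilities)
  if (nrow(hosp) == 0L) {
    cf_stop("facility table has no in-system hospitals", "carefrag_domain_error")
  }
  p <- ds$patients[match(patient_ids, patient_id)]
  pc <- ds$pcp[patient_id %in% patient_ids & as_of_date <= params$pcp_as_of_date]
  pc <- pc[order(patient_id, as_of_date)]
  pc <- pc[, .SD[.N], by = patient_id]
  has_pcp <- pc$has_in_system_pcp[match(patient_ids, pc$patient_id)]
  missing_pcp <- is.na(has_pcp)
  has_pcp[missing_pcp] <- FALSE
  missing_home <- is.na(p$home_lat) | is.na(p$home_lon)
  dist_km <- rep(NA_real_, length(patient_ids))
  if (any(!missing_home)) {
    dist_km[!missing_home] <- min_hospital_distance_km(
      p$home_lat[!missing_home], p$home_lon[!missing_home], hosp)
  }
  list(has_pcp = has_pcp, dist_km = dist_km,
       missing_pcp = missing_pcp, missing_home = missing_home)
}

#' Does a patient fulfill the PCP + distance constraint?
#'
#' `TRUE` iff the patient has an in-system primary care physician at the
#' as-of date and the minimum geodesic distance from home to an in-system
#' hospital is `<= d_km` (boundary inclusive; with `d_km = Inf` distance is
#' ignored).  Missing home coordinates or PCP row give `FALSE` with a
#' warning.
#'
#' @param patient_id single patient id
#' @param ds an `ehr_dataset`
#' @param params a [constraint_params()]
#' @return logical scalar
#' @export
fulfills_constraint <- function(patient_id, ds, params = constraint_params()) {
  ci <- constraint_inputs(patient_id, ds, params)
  if (ci$missing_home || ci$missing_pcp) {
    warning(sprintf("patient \"%s\": missing %s; constraint evaluates FALSE",
                    patient_id,
                    paste(c("home coordinates", "PCP row")[
                      c(ci$missing_home, ci$missing_pcp)], collapse = " and ")),
            call. = FALSE)
  }
  unname(ci$has_pcp & !is.na(ci$dist_km) & ci$dist_km <= params$d_km)
}

#' Fragmentation fraction
#'
#' @param numerator,denominator nonnegative counts, `numerator <=
#'   denominator`
#' @return object of class `frag_fraction` with fields `numerator`,
#'   `denominator`, `percentage` (half-up 2 decimals; `NA` with
#'   `undefined = TRUE` when the denominator is 0), and `raw_percentage`
#'   at full precision
#' @export
frag_fraction <- function(numerator, denominator) {
  if (numerator < 0 || denominator < 0 || numerator > denominator) {
    cf_stop("need 0 <= numerator <= denominator", "carefrag_domain_error")
  }
  undefined <- denominator == 0
  raw <- if (undefined) NA_real_ else numerator / denominator * 100
  structure(list(numerator = numerator, denominator = denominator,
                 raw_percentage = raw,
                 percentage = if (undefined) NA_real_ else round_half_up(raw, 2L),
                 undefined = undefined),
            class = "frag_fraction")
}

#' @export
print.frag_fraction <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<frag_fraction> %d/%d (undefined)\n", x$numerator, x$denominator))
  } else {
    cat(sprintf("<frag_fraction> %d/%d (%.2f%%)\n", x$numerator, x$denominator,
                x$percentage))
  }
  invisible(x)
}

#' Select the subcohort fulfilling the constraint
#'
#' @param patient_ids candidate patient ids (the m0 denominator)
#' @param ds an `ehr_dataset`
#' @param params a [constraint_params()]
#' @return list with `patient_ids` (the fulfilling subset), `fraction`
#'   (n0/m0 as a [frag_fraction()]) and `warnings` (counts of missing home
#'   coordinates / PCP rows among candidates)
#' @export
select_subcohort <- function(patient_ids, ds, params = constraint_params()) {
  stopifnot(all(patient_ids %in% ds$patients$patient_id))
  if (length(patient_ids) == 0L) {
    return(list(patient_ids = character(0), fraction = frag_fraction(0, 0),
                warnings = c(missing_home = 0L, missing_pcp = 0L)))
  }
  ci <- constraint_inputs(patient_ids, ds, params)
  # with the unbounded sentinel, selection reduces to the PCP requirement
  ok <- if (is.infinite(params$d_km)) ci$has_pcp else
    ci$has_pcp & !is.na(ci$dist_km) & ci$dist_km <= params$d_km
  list(patient_ids = patient_ids[ok],
       fraction = frag_fraction(sum(ok), length(patient_ids)),
       warnings = c(missing_home = sum(ci$missing_home),
                    missing_pcp = sum(ci$missing_pcp)))
}

# registry rows deduplicated and windowed; exact duplicates (same patient,
# date, type, facility) collapse to one — a same-day ED + inpatient pair
# stays two visits (distinct types)
registry_visits <- function(registry, patient_subset, window) {
  rg <- unique(registry[, c("patient_id", "date", "visit_type", "facility_id")])
  rg[rg$patient_id %in% patient_subset &
     rg$date >= window$start_date & rg$date <= window$end_date, , drop = FALSE]
}

#' Care-fragmentation fraction for a patient set and follow-up window
#'
#' Denominator: all registry hospital visits (ED + inpatient) by the subset
#' in the window.  Numerator: those at an in-system facility, or at the
#' single facility named by `facility_filter`.
#'
#' @param registry registry table
#' @param patient_subset character vector of patient ids
#' @param window a [follow_up_window()]
#' @param facilities facility table (for the in-system flag)
#' @param facility_filter optional single `facility_id`; restricts the
#'   numerator to that hospital (the per-hospital variant)
#' @return a [frag_fraction()]
#' @export
fragmentation <- function(registry, patient_subset, window, facilities,
                          facility_filter = NULL) {
  stopifnot(inherits(window, "follow_up_window"))
  rg <- registry_visits(registry, patient_subset, window)
  m <- nrow(rg)
  if (is.null(facility_filter)) {
    in_sys <- facilities$facility_id[facilities$in_system]
    n <- sum(rg$facility_id %in% in_sys)
  } else {
    stopifnot(length(facility_filter) == 1L)
    n <- sum(rg$facility_id == facility_filter, na.rm = TRUE)
  }
  frag_fraction(n, m)
}

#' Sweep the distance threshold d
#'
#' For each d in `d_grid`, the percentage of candidates fulfilling the
#' constraint and the in-system fragmentation percentage of the fulfilling
#' subset for each follow-up window.  The fulfilling percentage is
#' nondecreasing in d by construction (nested selection sets); this is
#' asserted.
#'
#' @param d_grid strictly increasing distance thresholds (km; `Inf` allowed
#'   as last point)
#' @param patient_ids candidate ids
#' @param ds an `ehr_dataset`
#' @param windows list of [follow_up_window()]s
#' @param params base [constraint_params()] (its `d_km` is swept)
#' @return a data.table of class `sweep_curve`: one row per d with columns
#'   `d_km`, `n0`, `m0`, `fulfilling_pct`, and per window
#'   `n_<label>`, `m_<label>`, `pct_<label>`
#' @export
sweep_constraint <- function(d_grid, patient_ids, ds,
                             windows = default_windows(),
                             params = constraint_params()) {
  if (any(diff(d_grid) <= 0)) {
    cf_stop("d_grid must be strictly increasing", "carefrag_domain_error")
  }
  ci <- constraint_inputs(patient_ids, ds, params)
  m0 <- length(patient_ids)
  rows <- lapply(d_grid, function(d) {
    ok <- if (is.infinite(d)) ci$has_pcp else
      ci$has_pcp & !is.na(ci$dist_km) & ci$dist_km <= d
    sub <- patient_ids[ok]
    row <- list(d_km = d, n0 = sum(ok), m0 = m0,
                fulfilling_pct = if (m0 == 0) NA_real_ else sum(ok) / m0 * 100)
    for (w in windows) {
      fr <- fragmentation(ds$registry, sub, w, ds$facilities)
      row[[paste0("n_", w$label)]] <- fr$numerator
      row[[paste0("m_", w$label)]] <- fr$denominator
      row[[paste0("pct_", w$label)]] <- fr$raw_percentage
    }
    row
  })
  out <- data.table::rbindlist(rows)
  stopifnot(!is.unsorted(out$fulfilling_pct, na.rm = TRUE))
  data.table::setattr(out, "class", c("sweep_curve", class(out)))
  out[]
}

#' Per-subgroup performance report (Table-2 analog)
#'
#' For the given distance threshold and each disease subgroup: the
#' fulfilling fraction n0/m0, the in-system fraction over *all* subgroup
#' patients per window, and the in-system fraction over the *fulfilling*
#' subset per window.  Cells with a zero denominator are flagged undefined
#' (`NA` percentage), never rendered as 0.
#'
#' @param ds an `ehr_dataset`
#' @param labels output of [label_all()]
#' @param params a [constraint_params()]
#' @param windows list of [follow_up_window()]s
#' @param diseases label columns to report
#' @return data.table, one row per subgroup; percentages half-up 2 decimals
#'   with raw numerator/denominator columns alongside
#' @export
subgroup_report <- function(ds, labels, params = constraint_params(),
                            windows = default_windows(),
                            diseases = c("asthma", "ckd", "copd", "t1d", "t2d")) {
  rows <- lapply(diseases, function(dis) {
    ids <- labels$patient_id[labels[[dis]]]
    sel <- select_subcohort(ids, ds, params)
    row <- list(subgroup = dis,
                n0 = sel$fraction$numerator, m0 = sel$fraction$denominator,
                fulfilling_pct = sel$fraction$percentage)
    for (w in windows) {
      all_fr <- fragmentation(ds$registry, ids, w, ds$facilities)
      ful_fr <- fragmentation(ds$registry, sel$patient_ids, w, ds$facilities)
      row[[paste0("n_all_", w$label)]] <- all_fr$numerator
      row[[paste0("m_all_", w$label)]] <- all_fr$denominator
      row[[paste0("pct_all_", w$label)]] <- all_fr$percentage
      row[[paste0("n_ful_", w$label)]] <- ful_fr$numerator
      row[[paste0("m_ful_", w$label)]] <- ful_fr$denominator
      row[[paste0("pct_ful_", w$label)]] <- ful_fr$percentage
    }
    row
  })
  data.table::rbindlist(rows)
}

#' Per-hospital fragmentation report
#'
#' One row per in-system hospital and window with the n3/m1 (6-month) or
#' n4/m2 (12-month) fraction.  For each window the per-hospital numerators
#' sum to the system numerator.
#'
#' @param registry registry table
#' @param patient_subset patient ids (typically the fulfilling subset)
#' @param windows list of [follow_up_window()]s
#' @param facilities facility table
#' @param hospital_ids in-system hospital ids; default: all in-system
#'   hospitals in `facilities`
#' @return data.table with columns `facility_id`, `window`, `numerator`,
#'   `denominator`, `percentage`
#' @export
per_hospital_report <- function(registry, patient_subset, windows, facilities,
                                hospital_ids = in_system_hospitals(facilities)$facility_id) {
  stopifnot(all(hospital_ids %in% facilities$facility_id[facilities$in_system]))
  rows <- list()
  for (w in windows) {
    for (h in hospital_ids) {
      fr <- fragmentation(registry, patient_subset, w, facilities,
                          facility_filter = h)
      rows[[length(rows) + 1L]] <- list(
        facility_id = h, window = w$label, numerator = fr$numerator,
        denominator = fr$denominator, percentage = fr$percentage)
    }
  }
  data.table::rbindlist(rows)
}
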