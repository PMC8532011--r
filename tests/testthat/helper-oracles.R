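# Independent oracles used by the tests.  These deliberately avoid the code
# paths they check: the geodesic oracle integrates the geodesic ODEs with
# RK4 and shoots on (azimuth, arc length); the fraction oracle recounts with
# naive loops and no data.table; the pattern oracle expands code strings
# character by character.

# --- geodesic ODE shooting oracle ------------------------------------------
# Integrates dphi/ds = cos(a)/M, dlambda/ds = sin(a)/(N cos phi),
# dalpha/ds = sin(a) tan(phi)/N on WGS-84 with fixed-step RK4, vectorized
# over pairs, and Newton-solves for the (azimuth, s) hitting the target.
# Accurate to well under 0.5 m for regional pairs (<= ~1000 km).
geodesic_oracle <- function(lat1, lon1, lat2, lon2, nsteps = 400L, iters = 8L) {
  a <- 6378137.0; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  p1 <- cbind(lat1, lon1) * pi / 180
  p2 <- cbind(lat2, lon2) * pi / 180

  derivs <- function(phi, alpha) {
    s2 <- sin(phi)^2
    W <- sqrt(1 - e2 * s2)
    M <- a * (1 - e2) / W^3
    N <- a / W
    cbind(cos(alpha) / M, sin(alpha) / (N * cos(phi)), sin(alpha) * tan(phi) / N)
  }
  integrate_to <- function(az, s) {
    h <- s / nsteps
    phi <- p1[, 1]; lam <- p1[, 2]; alp <- az
    for (k in seq_len(nsteps)) {
      k1 <- derivs(phi, alp)
      k2 <- derivs(phi + h / 2 * k1[, 1], alp + h / 2 * k1[, 3])
      k3 <- derivs(phi + h / 2 * k2[, 1], alp + h / 2 * k2[, 3])
      k4 <- derivs(phi + h * k3[, 1], alp + h * k3[, 3])
      phi <- phi + h / 6 * (k1[, 1] + 2 * k2[, 1] + 2 * k3[, 1] + k4[, 1])
      lam <- lam + h / 6 * (k1[, 2] + 2 * k2[, 2] + 2 * k3[, 2] + k4[, 2])
      alp <- alp + h / 6 * (k1[, 3] + 2 * k2[, 3] + 2 * k3[, 3] + k4[, 3])
    }
    cbind(phi, lam)
  }
  wrap <- function(x) atan2(sin(x), cos(x))
  residual <- function(az, s) {
    e <- integrate_to(az, s)
    cbind(e[, 1] - p2[, 1], wrap(e[, 2] - p2[, 2]))
  }
  # spherical initial guess (mean-radius great circle)
  R <- (2 * 6378137.0 + 6356752.3142) / 3
  dlon <- p2[, 2] - p1[, 2]
  cs <- pmin(1, pmax(-1, sin(p1[, 1]) * sin(p2[, 1]) +
                       cos(p1[, 1]) * cos(p2[, 1]) * cos(dlon)))
  s <- R * acos(cs)
  az <- atan2(sin(dlon) * cos(p2[, 1]),
              cos(p1[, 1]) * sin(p2[, 1]) - sin(p1[, 1]) * cos(p2[, 1]) * cos(dlon))
  s <- pmax(s, 1)               # avoid zero-length integration
  da <- 1e-7; dsx <- 10
  for (it in seq_len(iters)) {
    r0 <- residual(az, s)
    ra <- residual(az + da, s)
    rs <- residual(az, s + dsx)
    J11 <- (ra[, 1] - r0[, 1]) / da;  J12 <- (rs[, 1] - r0[, 1]) / dsx
    J21 <- (ra[, 2] - r0[, 2]) / da;  J22 <- (rs[, 2] - r0[, 2]) / dsx
    det <- J11 * J22 - J12 * J21
    az <- az - (r0[, 1] * J22 - r0[, 2] * J12) / det
    s <- s - (J11 * r0[, 2] - J21 * r0[, 1]) / det
  }
  s
}

# regional + global point pairs with distances frozen from an independent
# high-precision (Karney-algorithm) geodesic implementation
frozen_geodesic_pairs <- function() {
  data.frame(
    lat1 = c(0, 0, 47.6496, 47.6496, 47.0, 46.5, 47.6, 10.0, 35.0, 0.5),
    lon1 = c(0, 0, -122.3080, -122.3080, -122.0, -124.0, -122.3, 20.0, 135.0, 179.7),
    lat2 = c(0, 1, 47.6040, 47.7128, 48.5, 49.0, 47.6, -10.0, 36.0, -0.5),
    lon2 = c(1, 0, -122.3233, -122.3405, -120.5, -117.0, -122.2, -20.0, 136.0, -179.9),
    meters = c(111319.490793, 110574.388558, 5198.732242, 7438.490422,
               201152.821589, 593623.634186, 7520.038027, 4951449.037498,
               143321.578182, 119202.983843))
}

# --- naive-loop fraction oracles -------------------------------------------

bf_min_dist_km <- function(ds, pid) {
  p <- as.data.frame(ds$patients)
  f <- as.data.frame(ds$facilities)
  row <- p[p$patient_id == pid, ]
  if (is.na(row$home_lat) || is.na(row$home_lon)) return(NA_real_)
  best <- Inf
  for (i in seq_len(nrow(f))) {
    if (f$in_system[i] && f$is_hospital[i]) {
      d <- vincenty_inverse(row$home_lat, row$home_lon, f$lat[i], f$lon[i])$meters / 1000
      if (d < best) best <- d
    }
  }
  best
}

bf_fulfilling <- function(ds, ids, d_km, pcp_date) {
  pc <- as.data.frame(ds$pcp)
  out <- character(0)
  for (pid in ids) {
    rows <- pc[pc$patient_id == pid & pc$as_of_date <= pcp_date, ]
    has <- if (nrow(rows)) rows$has_in_system_pcp[which.max(as.numeric(rows$as_of_date))] else FALSE
    if (!isTRUE(has)) next
    dist <- bf_min_dist_km(ds, pid)
    if (is.infinite(d_km)) { out <- c(out, pid); next }
    if (!is.na(dist) && dist <= d_km) out <- c(out, pid)
  }
  out
}

bf_fragmentation <- function(ds, ids, win_start, win_end, facility = NULL) {
  rg <- unique(as.data.frame(ds$registry))
  fc <- as.data.frame(ds$facilities)
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(rg))) {
    if (!(rg$patient_id[i] %in% ids)) next
    if (rg$date[i] < win_start || rg$date[i] > win_end) next
    den <- den + 1L
    fid <- rg$facility_id[i]
    hit <- if (is.null(facility)) {
      isTRUE(fc$in_system[fc$facility_id == fid])
    } else identical(fid, facility)
    if (hit) num <- num + 1L
  }
  c(num = num, den = den)
}

# --- character-expansion pattern oracle ------------------------------------

oracle_normalize <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(toupper(chars[chars != "."]), collapse = "")
}

oracle_match <- function(code, pattern, code_system, pattern_system) {
  if (code_system != pattern_system) return(FALSE)
  p <- strsplit(oracle_normalize(pattern), "", fixed = TRUE)[[1]]
  c_ <- strsplit(oracle_normalize(code), "", fixed = TRUE)[[1]]
  np <- length(p)
  if (p[np] %in% c("X", "*")) {          # trailing wildcard: stem prefix
    stem <- p[-np]
    if (length(c_) < length(stem)) return(FALSE)
    for (i in seq_along(stem)) if (c_[i] != stem[i]) return(FALSE)
    return(TRUE)
  }
  if (length(c_) != np) return(FALSE)
  for (i in seq_len(np)) {
    if (p[i] == "X") next                 # interior single-char wildcard
    if (c_[i] != p[i]) return(FALSE)
  }
  TRUE
}

# --- small record builders --------------------------------------------------

hrow_dx <- function(code, system, date, rank = "unranked", visit_id = NA_character_,
                    pid = "P1") {
  data.frame(patient_id = pid, visit_id = visit_id, code = code,
             code_system = system, rank = rank, date = as.Date(date))
}

hrow_lab <- function(analyte, value, date, flag = "none", pid = "P1") {
  data.frame(patient_id = pid, date = as.Date(date), analyte = analyte,
             value = value, qualitative_flag = flag)
}

hrow_med <- function(class, date, name = class, pid = "P1") {
  data.frame(patient_id = pid, date = as.Date(date), drug_class = class,
             drug_name = name)
}

hrow_visit <- function(visit_id, type, date, fac = "H1", pid = "P1",
                       end = NULL) {
  data.frame(visit_id = visit_id, patient_id = pid, visit_type = type,
             start_date = as.Date(date),
             end_date = if (is.null(end)) as.Date(date) else as.Date(end),
             facility_id = fac)
}

h_facilities <- function() {
  data.frame(facility_id = c("H1", "H2", "H3", "C1", "X1"),
             name = c("Hosp 1", "Hosp 2", "Hosp 3", "Clinic", "Outside"),
             in_system = c(TRUE, TRUE, TRUE, TRUE, FALSE),
             lat = c(47.6496, 47.6040, 47.7128, 47.62, 47.58),
             lon = c(-122.3080, -122.3233, -122.3405, -122.32, -122.10),
             is_hospital = c(TRUE, TRUE, TRUE, FALSE, TRUE))
}

make_record <- function(diagnoses = NULL, labs = NULL, medications = NULL,
                        visits = NULL, pregnancies = NULL, registry = NULL,
                        pcp = NULL, birth_date = "1963-06-15", sex = "male",
                        race_black = FALSE, home = c(47.66, -122.31),
                        pid = "P1") {
  pat <- data.frame(patient_id = pid, birth_date = as.Date(birth_date),
                    sex = sex, race_black = race_black,
                    death_date = as.Date(NA),
                    home_lat = home[1], home_lon = home[2])
  ds <- ehr_dataset(
    patients = pat,
    visits = if (is.null(visits)) empty_table("visits") else visits,
    diagnoses = if (is.null(diagnoses)) empty_table("diagnoses") else diagnoses,
    labs = if (is.null(labs)) empty_table("labs") else labs,
    medications = if (is.null(medications)) empty_table("medications") else medications,
    pcp = if (is.null(pcp)) data.frame(patient_id = pid,
                                       has_in_system_pcp = TRUE,
                                       as_of_date = as.Date("2019-01-01")) else pcp,
    pregnancies = if (is.null(pregnancies)) empty_table("pregnancies") else pregnancies,
    facilities = h_facilities(),
    registry = if (is.null(registry)) empty_table("registry") else registry)
  patient_record(ds, pid)
}
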