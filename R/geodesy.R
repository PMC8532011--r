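# Geodesic distance on the WGS-84 reference ellipsoid.
#
# Cohort selection uses the ellipsoid great-circle ("geodesic") distance
# between a patient's home and each in-system hospital.  The inverse problem
# is solved with Vincenty's classical iteration (convergence tolerance 1e-12
# on the longitude-difference term, cap 200 iterations), which is accurate to
# well under a millimetre for non-antipodal pairs.  Vincenty's iteration is
# known to fail for nearly antipodal points; such pairs fall back to a 2-D
# Newton shooting solve built on the series-based direct solver and are
# flagged `converged = FALSE`.

WGS84_A <- 6378137.0
WGS84_F <- 1 / 298.257223563
WGS84_B <- WGS84_A * (1 - WGS84_F)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    cf_stop("coordinates must be finite, lat in [-90, 90], lon in [-180, 180]",
            "carefrag_coord_error")
  }
}

#' Vincenty inverse geodesic distance (WGS-84)
#'
#' Distance in metres between point pairs on the WGS-84 ellipsoid
#' (a = 6,378,137 m, f = 1/298.257223563), vectorized over pairs.
#' Exactly symmetric in its arguments.  Near-antipodal pairs where the
#' iteration fails are solved by a shooting fallback and flagged.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectors recycled to a common
#'   length)
#' @return data.frame with columns `meters` (>= 0; 0 iff the points
#'   coincide), `converged` (FALSE only for the fallback path) and
#'   `iterations`
#' @export
#' @examples
#' vincenty_inverse(0, 0, 0, 1)$meters  # 111319.49, the equatorial arc
vincenty_inverse <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  check_coords(lat1, lon1); check_coords(lat2, lon2)

  # canonical argument order makes d(a, b) bit-identical to d(b, a)
  swap <- (lat2 < lat1) | (lat2 == lat1 & lon2 < lon1)
  if (any(swap)) {
    tmp <- lat1[swap]; lat1[swap] <- lat2[swap]; lat2[swap] <- tmp
    tmp <- lon1[swap]; lon1[swap] <- lon2[swap]; lon2[swap] <- tmp
  }

  a <- WGS84_A; b <- WGS84_B; f <- WGS84_F
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  L <- deg2rad(lon2 - lon1)
  # wrap to (-pi, pi]
  L <- atan2(sin(L), cos(L))

  U1 <- atan((1 - f) * tan(phi1)); U2 <- atan((1 - f) * tan(phi2))
  sinU1 <- sin(U1); cosU1 <- cos(U1); sinU2 <- sin(U2); cosU2 <- cos(U2)

  same <- (lat1 == lat2) & (abs(L) < .Machine$double.eps)
  lambda <- L
  meters <- numeric(n); iters <- integer(n); converged <- rep(TRUE, n)
  active <- which(!same)
  sigma <- sinSigma <- cosSigma <- cos2Alpha <- cos2SigmaM <- numeric(n)
  it <- 0L
  while (length(active) && it < 200L) {
    it <- it + 1L
    i <- active
    sinL <- sin(lambda[i]); cosL <- cos(lambda[i])
    sinSig <- sqrt((cosU2[i] * sinL)^2 +
                   (cosU1[i] * sinU2[i] - sinU1[i] * cosU2[i] * cosL)^2)
    cosSig <- sinU1[i] * sinU2[i] + cosU1[i] * cosU2[i] * cosL
    sig <- atan2(sinSig, cosSig)
    sinAlpha <- ifelse(sinSig == 0, 0, cosU1[i] * cosU2[i] * sinL / sinSig)
    c2a <- 1 - sinAlpha^2
    c2sm <- ifelse(c2a == 0, 0, cosSig - 2 * sinU1[i] * sinU2[i] / c2a)
    C <- f / 16 * c2a * (4 + f * (4 - 3 * c2a))
    lamNew <- L[i] + (1 - C) * f * sinAlpha *
      (sig + C * sinSig * (c2sm + C * cosSig * (-1 + 2 * c2sm^2)))
    delta <- abs(lamNew - lambda[i])
    lambda[i] <- lamNew
    sigma[i] <- sig; sinSigma[i] <- sinSig; cosSigma[i] <- cosSig
    cos2Alpha[i] <- c2a; cos2SigmaM[i] <- c2sm
    iters[i] <- it
    done <- delta < 1e-12
    # diverging lambda (antipodal failure mode) also leaves the loop at cap
    active <- i[!done & abs(lamNew) <= pi]
    failed_now <- i[!done & abs(lamNew) > pi]
    if (length(failed_now)) converged[failed_now] <- FALSE
  }
  if (length(active)) converged[active] <- FALSE

  ok <- which(!same & converged)
  if (length(ok)) {
    u2 <- cos2Alpha[ok] * (a^2 - b^2) / b^2
    A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
    B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
    dSig <- B * sinSigma[ok] * (cos2SigmaM[ok] + B / 4 *
      (cosSigma[ok] * (-1 + 2 * cos2SigmaM[ok]^2) -
       B / 6 * cos2SigmaM[ok] * (-3 + 4 * sinSigma[ok]^2) *
         (-3 + 4 * cos2SigmaM[ok]^2)))
    meters[ok] <- b * A * (sigma[ok] - dSig)
  }
  bad <- which(!converged)
  for (i in bad) {
    meters[i] <- shoot_inverse(lat1[i], lon1[i], lat2[i], lon2[i])
    iters[i] <- 200L
  }
  data.frame(meters = meters, converged = converged, iterations = iters)
}

#' Vincenty direct geodesic problem (WGS-84)
#'
#' Destination point after travelling `s_m` metres from
#' (`lat`, `lon`) along initial azimuth `azimuth_deg` (clockwise from
#' north).  Vectorized; used by the synthetic generator to place homes at
#' controlled distances and by the near-antipodal fallback.
#'
#' @param lat,lon start coordinates, decimal degrees
#' @param azimuth_deg initial bearing, degrees clockwise from north
#' @param s_m distance in metres
#' @return data.frame with columns `lat`, `lon` (decimal degrees)
#' @export
vincenty_direct <- function(lat, lon, azimuth_deg, s_m) {
  n <- max(length(lat), length(lon), length(azimuth_deg), length(s_m))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  azimuth_deg <- rep_len(azimuth_deg, n); s_m <- rep_len(s_m, n)
  check_coords(lat, lon)
  if (any(s_m < 0)) cf_stop("distance must be nonnegative", "carefrag_coord_error")

  a <- WGS84_A; b <- WGS84_B; f <- WGS84_F
  alpha1 <- deg2rad(azimuth_deg)
  phi1 <- deg2rad(lat)
  U1 <- atan((1 - f) * tan(phi1))
  sigma1 <- atan2(tan(U1), cos(alpha1))
  sinAlpha <- cos(U1) * sin(alpha1)
  cos2Alpha <- 1 - sinAlpha^2
  u2 <- cos2Alpha * (a^2 - b^2) / b^2
  A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
  B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))

  sigma <- s_m / (b * A)
  for (k in 1:200) {
    cos2SigmaM <- cos(2 * sigma1 + sigma)
    dSig <- B * sin(sigma) * (cos2SigmaM + B / 4 *
      (cos(sigma) * (-1 + 2 * cos2SigmaM^2) -
       B / 6 * cos2SigmaM * (-3 + 4 * sin(sigma)^2) * (-3 + 4 * cos2SigmaM^2)))
    sigmaNew <- s_m / (b * A) + dSig
    if (max(abs(sigmaNew - sigma)) < 1e-13) { sigma <- sigmaNew; break }
    sigma <- sigmaNew
  }
  cos2SigmaM <- cos(2 * sigma1 + sigma)
  sinSigma <- sin(sigma); cosSigma <- cos(sigma)
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  phi2 <- atan2(sinU1 * cosSigma + cosU1 * sinSigma * cos(alpha1),
                (1 - f) * sqrt(sinAlpha^2 +
                  (sinU1 * sinSigma - cosU1 * cosSigma * cos(alpha1))^2))
  lambda <- atan2(sinSigma * sin(alpha1),
                  cosU1 * cosSigma - sinU1 * sinSigma * cos(alpha1))
  C <- f / 16 * cos2Alpha * (4 + f * (4 - 3 * cos2Alpha))
  Lofs <- lambda - (1 - C) * f * sinAlpha *
    (sigma + C * sinSigma * (cos2SigmaM + C * cosSigma * (-1 + 2 * cos2SigmaM^2)))
  lon2 <- deg2rad(lon) + Lofs
  lon2 <- atan2(sin(lon2), cos(lon2))
  data.frame(lat = rad2deg(phi2), lon = rad2deg(lon2))
}

# Fallback for near-antipodal pairs: solve the inverse problem by damped
# Gauss-Newton on (azimuth, arc length) through the direct solver.  The
# azimuth is ill-conditioned near the antipode, so several start azimuths
# are tried and the best-residual solution kept.
shoot_inverse <- function(lat1, lon1, lat2, lon2) {
  R <- (2 * WGS84_A + WGS84_B) / 3
  p1 <- deg2rad(c(lat1, lon1)); p2 <- deg2rad(c(lat2, lon2))
  dlon <- p2[2] - p1[2]
  cs <- sin(p1[1]) * sin(p2[1]) + cos(p1[1]) * cos(p2[1]) * cos(dlon)
  sig <- acos(max(-1, min(1, cs)))
  s0 <- max(R * sig, 1)
  az0 <- rad2deg(atan2(sin(dlon) * cos(p2[1]),
                       cos(p1[1]) * sin(p2[1]) -
                         sin(p1[1]) * cos(p2[1]) * cos(dlon)))
  resid <- function(x) {
    e <- vincenty_direct(lat1, lon1, x[1], max(x[2], 1))
    dl <- deg2rad(e$lon - lon2)
    c(deg2rad(e$lat - lat2), atan2(sin(dl), cos(dl)))
  }
  # near the antipode several geodesics connect the points; collect every
  # converged solution and keep the shortest
  best_x <- c(az0, s0); best_norm <- Inf; sols <- numeric(0)
  for (start in c(0, -20, 20, -45, 45, -90, 90, 135, 180)) {
    x <- c(az0 + start, s0)
    norm0 <- sqrt(sum(resid(x)^2))
    for (k in 1:60) {
      r0 <- resid(x)
      norm0 <- sqrt(sum(r0^2))
      if (norm0 * R < 1e-3) break
      h <- c(1e-6, 1e-1)
      J <- cbind((resid(x + c(h[1], 0)) - r0) / h[1],
                 (resid(x + c(0, h[2])) - r0) / h[2])
      step <- tryCatch(solve(J, r0), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      damp <- 1
      repeat {
        x_try <- x - damp * step
        norm_try <- sqrt(sum(resid(x_try)^2))
        if (norm_try < norm0 || damp < 1 / 64) break
        damp <- damp / 2
      }
      if (norm_try >= norm0) break
      x <- x_try
    }
    if (norm0 < best_norm) { best_norm <- norm0; best_x <- x }
    if (norm0 * R < 0.1) sols <- c(sols, max(x[2], 1))
  }
  if (length(sols)) min(sols) else max(best_x[2], 1)
}

#' Minimum geodesic distance from a home to a set of hospitals
#'
#' @param home_lat,home_lon home coordinates, decimal degrees
#' @param hospitals data.frame with columns `lat`, `lon` (typically the
#'   in-system hospital subset of the facility table)
#' @return distance in kilometres to the nearest hospital, full precision
#'   (no pre-rounding; threshold comparisons are made on this value)
#' @export
min_hospital_distance_km <- function(home_lat, home_lon, hospitals) {
  if (is.null(hospitals) || nrow(hospitals) == 0L) {
    cf_stop("hospital list must be nonempty", "carefrag_coord_error")
  }
  n <- max(length(home_lat), length(home_lon))
  home_lat <- rep_len(home_lat, n); home_lon <- rep_len(home_lon, n)
  d <- matrix(NA_real_, n, nrow(hospitals))
  for (j in seq_len(nrow(hospitals))) {
    d[, j] <- vincenty_inverse(home_lat, home_lon,
                               hospitals$lat[j], hospitals$lon[j])$meters
  }
  apply(d, 1L, min) / 1000
}
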