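# Transverse Mercator (UTM) projection on the WGS84 ellipsoid, implemented
# from the standard Krueger flattening series (accurate to well under a
# millimetre within a UTM zone). Internal geometry is always in projected
# metres; these routines convert API-facing longitude/latitude to and from
# that frame.

.wgs84 <- local({
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  list(
    a = a, f = f, n = n,
    A = a / (1 + n) * (1 + n^2 / 4 + n^4 / 64),
    alpha = c(n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16,
              13 * n^2 / 48 - 3 * n^3 / 5,
              61 * n^3 / 240),
    beta = c(n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96,
             n^2 / 48 + n^3 / 15,
             17 * n^3 / 480),
    delta = c(2 * n - 2 * n^2 / 3 - 2 * n^3,
              7 * n^2 / 3 - 8 * n^3 / 5,
              56 * n^3 / 15)
  )
})

#' Project longitude/latitude to UTM easting/northing
#'
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @param zone UTM zone number (1-60); `NULL` picks the zone of the mean
#'   longitude.
#' @param hemisphere `"N"` or `"S"`; `NULL` picks by mean latitude.
#' @return A list with matrix `xy` (easting/northing, metres), `zone` and
#'   `hemisphere`.
#' @export
utm_forward <- function(lon, lat, zone = NULL, hemisphere = NULL) {
  if (is.null(zone)) zone <- floor((mean(lon) + 180) / 6) + 1
  zone <- as.integer(zone)
  if (zone < 1 || zone > 60) stopf("UTM zone must be in 1..60, got %s", zone)
  if (is.null(hemisphere)) hemisphere <- if (mean(lat) >= 0) "N" else "S"
  lam0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lam0
  e <- .wgs84
  s2n <- 2 * sqrt(e$n) / (1 + e$n)
  t <- sinh(atanh(sin(phi)) - s2n * atanh(s2n * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- atanh(sin(lam) / sqrt(1 + t^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:3) {
    xi <- xi + e$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + e$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  k0 <- 0.9996
  E <- 500000 + k0 * e$A * eta
  N <- (if (hemisphere == "S") 1e7 else 0) + k0 * e$A * xi
  list(xy = cbind(x = E, y = N), zone = zone, hemisphere = hemisphere)
}

#' Inverse UTM projection to longitude/latitude
#'
#' @param x,y easting/northing in metres.
#' @param zone UTM zone number.
#' @param hemisphere `"N"` or `"S"`.
#' @return Matrix with columns `lon`, `lat` in degrees.
#' @export
utm_inverse <- function(x, y, zone, hemisphere = "N") {
  e <- .wgs84
  k0 <- 0.9996
  lam0 <- (as.integer(zone) * 6 - 183) * pi / 180
  xi <- (y - (if (hemisphere == "S") 1e7 else 0)) / (k0 * e$A)
  eta <- (x - 500000) / (k0 * e$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:3) {
    xi_p <- xi_p - e$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - e$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(sin(xi_p) / cosh(eta_p))
  phi <- chi
  for (j in 1:3) phi <- phi + e$delta[j] * sin(2 * j * chi)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  cbind(lon = (lam + lam0) * 180 / pi, lat = phi * 180 / pi)
}

# Parse a CRS identifier. Recognized forms:
#   "utm:18N" / "utm:18S"  - UTM zone in metres
#   "EPSG:326xx"/"EPSG:327xx" - UTM north/south via EPSG code
#   "EPSG:4326" / "WGS84"  - geographic degrees
#   "local:meters"         - already-projected local metric frame
parse_crs <- function(crs_id) {
  if (is.null(crs_id) || !nzchar(crs_id)) return(NULL)
  s <- toupper(gsub("\\s", "", crs_id))
  if (s %in% c("EPSG:4326", "WGS84", "CRS84", "OGC:CRS84",
               "URN:OGC:DEF:CRS:OGC:1.3:CRS84"))
    return(list(kind = "geographic", id = "EPSG:4326"))
  m <- regmatches(s, regexec("^UTM:([0-9]{1,2})([NS])$", s))[[1]]
  if (length(m) == 3)
    return(list(kind = "utm", zone = as.integer(m[2]), hemisphere = m[3],
                id = sprintf("utm:%s%s", m[2], m[3])))
  m <- regmatches(s, regexec("^EPSG:32([67])([0-9]{2})$", s))[[1]]
  if (length(m) == 3)
    return(list(kind = "utm", zone = as.integer(m[3]),
                hemisphere = if (m[2] == "6") "N" else "S", id = s))
  if (s %in% c("LOCAL:METERS", "LOCAL:METRES", "LOCAL"))
    return(list(kind = "local", id = "local:meters"))
  stopf("Unrecognized CRS identifier '%s' (use 'utm:<zone><N|S>', 'EPSG:326xx/327xx', 'EPSG:4326' or 'local:meters')", crs_id)
}

# Inverse-project x/y in the network CRS to lon/lat degrees. Local metric
# frames are mapped through an equirectangular chart at the equator so image
# requests stay well-formed for synthetic cities.
crs_to_lonlat <- function(x, y, crs_id) {
  crs <- parse_crs(crs_id)
  if (is.null(crs)) stopf("Cannot inverse-project without a CRS")
  switch(crs$kind,
    utm = utm_inverse(x, y, crs$zone, crs$hemisphere),
    local = cbind(lon = x / 111319.490793, lat = y / 111319.490793),
    geographic = cbind(lon = x, lat = y),
    stopf("Cannot inverse-project CRS '%s'", crs_id))
}
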