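# Mean Earth radius (IUGG mean radius R1), meters. Fixed so distances are
# reproducible across platforms; geosphere's default differs (6378137).
EARTH_RADIUS_M <- 6371008.8

#' Haversine distance in meters
#'
#' Great-circle distance on a sphere of mean radius 6 371 008.8 m.
#' Symmetric, and zero exactly for identical coordinates.  Vectorized over
#' both arguments with the usual recycling.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in meters.
#' @export
#' @examples
#' haversine_m(0, 0, 0, 1)   # ~111195 m: one degree of longitude at the equator
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE),
            all(abs(lat2) <= 90, na.rm = TRUE),
            all(abs(lon1) <= 180, na.rm = TRUE),
            all(abs(lon2) <= 180, na.rm = TRUE))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

# meters per degree of latitude / longitude at a given latitude, on the
# same sphere; used by the simulator to convert metric offsets to degrees.
meters_per_degree <- function(lat) {
  m_lat <- pi * EARTH_RADIUS_M / 180
  c(lat = m_lat, lon = m_lat * cos(lat * pi / 180))
}
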