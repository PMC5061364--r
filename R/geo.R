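# Site-table utilities: degree-minute coordinate parsing, great-circle
# inter-site distances, and the abundance-to-area extrapolation used to
# argue that vent fields hold very large local copepod populations.

#' Parse a degree-minute coordinate
#'
#' Accepts strings like `"26°07'N"`, `"44°49'W"` or `"104°18W"` (the prime
#' is optional); `S` and `W` yield negative decimal degrees.
#'
#' @param x Character vector of coordinate strings (or numeric, passed
#'   through).
#' @return Numeric decimal degrees.
#' @export
parse_coord <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(tok) {
    m <- regmatches(tok, regexec(
      "^\\s*(\\d+)\\s*[°d]\\s*(\\d+(?:\\.\\d+)?)\\s*'?\\s*([NSEW])\\s*$",
      tok))[[1]]
    if (length(m) != 4L) abort(paste0("cannot parse coordinate '", tok, "'"))
    deg <- as.numeric(m[2]) + as.numeric(m[3]) / 60
    if (m[4] %in% c("S", "W")) deg <- -deg
    deg
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a geographic point
#'
#' @param lat,lon Coordinates as degree-minute strings (see
#'   [parse_coord()]) or signed decimal degrees.
#' @return A `geo_point` (named list `lat`, `lon`).
#' @export
geo_point <- function(lat, lon) {
  lat <- parse_coord(lat); lon <- parse_coord(lon)
  if (abs(lat) > 90) abort("latitude out of range")
  if (abs(lon) > 180) abort("longitude out of range")
  structure(list(lat = lat, lon = lon), class = "geo_point")
}

#' Great-circle distance between two sites
#'
#' Haversine distance on a sphere of radius 6371.0 km; symmetric, zero for
#' identical points.
#'
#' @param a,b `geo_point`s (see [geo_point()]).
#' @return Distance in km.
#' @export
intersite_distance <- function(a, b) {
  geosphere::distHaversine(c(a$lon, a$lat), c(b$lon, b$lat),
                           r = 6371000) / 1000
}

#' Abundance extrapolation from sampler area to vent-field area
#'
#' Mean abundances are measured on 64 cm^2 settlement devices; scaled to a
#' square metre (factor 10000/64) and then to a vent-field area. Eight
#' individuals per 64 cm^2 correspond to 1250 per m^2, and a ~50 m^2 vent
#' field to more than 60000 individuals of a single species.
#'
#' @param mean_per_64cm2 Mean individuals per 64 cm^2 (> 0).
#' @param area_m2 Target area in m^2 (> 0, default 1).
#' @return Tibble with `per_m2` and `total`.
#' @export
density_extrapolation <- function(mean_per_64cm2, area_m2 = 1) {
  if (any(mean_per_64cm2 <= 0) || any(area_m2 <= 0)) {
    abort("inputs must be > 0")
  }
  per_m2 <- mean_per_64cm2 * 10000 / 64
  tibble(per_m2 = per_m2, area_m2 = area_m2, total = per_m2 * area_m2)
}
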