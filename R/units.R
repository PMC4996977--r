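#' @keywords internal
"_PACKAGE"

# Mean Earth radius used throughout (m); matches the value used for the
# metre <-> degree conversions in the advection scheme and for great-circle
# distances.
EARTH_RADIUS_M <- 6371000

# metres per degree of latitude (constant on the sphere)
m_per_deg_lat <- function() EARTH_RADIUS_M * pi / 180

# metres per degree of longitude at a given latitude
m_per_deg_lon <- function(lat) EARTH_RADIUS_M * cos(lat * pi / 180) * pi / 180

#' Arc length of an angular span along a parallel
#'
#' Length in kilometres of `deg` degrees of longitude at latitude `lat`
#' (degrees of latitude have the same length at any latitude). Useful for
#' translating grid resolutions into physical cell sizes: at the equator a
#' 1/6 degree habitat cell spans about 18.5 km per side and a 1/12 degree
#' forcing cell about 9 km.
#'
#' @param deg angular span in decimal degrees.
#' @param lat latitude in decimal degrees (default 0, the equator).
#' @return length in km.
#' @examples
#' arc_length_km(1 / 6)  # ~18.5 km
#' arc_length_km(1 / 12) # ~9 km
#' @export
arc_length_km <- function(deg, lat = 0) deg * m_per_deg_lon(lat) / 1000

# Graticule index of coordinate x on a global grid of the given resolution,
# half-open lower-inclusive intervals: cell k covers [k*res, (k+1)*res).
# The small tolerance keeps points computed as k*res (up to float noise)
# inside cell k.
grat_index <- function(x, res) as.integer(floor(x / res + 1e-9))

# first day of the month containing a Date
month_floor <- function(d) as.Date(format(d, "%Y-%m-01"))

stop_if_not_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}
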