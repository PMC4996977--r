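#' Gridded daily surface-velocity series
#'
#' Container for a daily sequence of surface ocean velocity fields on a
#' regular longitude--latitude grid, the physical forcing of the dispersal
#' model. Velocities are in m s^-1; `u` is the zonal (eastward positive) and
#' `v` the meridional (northward positive) component. Land cells are flagged
#' in a logical mask and carry `NA` velocities.
#'
#' @param lon,lat regular ascending grid-node coordinates (decimal degrees).
#' @param time vector of class `Date`, daily and contiguous; each field is the
#'   snapshot at 00Z of that day.
#' @param u,v numeric arrays of dimension `time x lat x lon` (m s^-1).
#' @param land logical `lat x lon` matrix, `TRUE` on land. Default: all ocean.
#' @return an object of class `velocity_series`.
#' @seealso [sample_velocity()], [read_velocity()], [generate_flow()]
#' @export
velocity_series <- function(lon, lat, time, u, v, land = NULL) {
  check_uniform <- function(x, name) {
    if (length(x) < 2) stop(sprintf("'%s' needs at least two nodes", name), call. = FALSE)
    d <- diff(x)
    if (any(d <= 0)) stop(sprintf("'%s' must be strictly ascending", name), call. = FALSE)
    if (diff(range(d)) > 1e-8 * mean(d))
      stop(sprintf("non-uniform grid spacing on '%s'", name), call. = FALSE)
    mean(d)
  }
  dlon <- check_uniform(lon, "lon")
  dlat <- check_uniform(lat, "lat")
  if (!inherits(time, "Date")) stop("'time' must be of class Date", call. = FALSE)
  if (length(time) > 1 && any(diff(as.integer(time)) != 1L))
    stop("'time' must be daily and contiguous", call. = FALSE)
  dims <- c(length(time), length(lat), length(lon))
  for (nm in c("u", "v")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), as.integer(dims)))
      stop(sprintf("'%s' must be an array of dim time x lat x lon = %s",
                   nm, paste(dims, collapse = " x ")), call. = FALSE)
  }
  if (is.null(land)) land <- matrix(FALSE, length(lat), length(lon))
  if (!is.matrix(land) || !identical(dim(land), as.integer(dims[2:3])) || !is.logical(land))
    stop("'land' must be a logical lat x lon matrix", call. = FALSE)
  ocean <- !land
  for (nm in c("u", "v")) {
    a <- get(nm)
    ok <- apply(a, 1L, function(s) all(is.finite(s[ocean])))
    if (!all(ok)) stop(sprintf("non-finite '%s' values on ocean cells", nm), call. = FALSE)
  }
  if (any(land)) {  # land carries no velocity
    land3 <- aperm(array(land, c(dim(land), length(time))), c(3, 1, 2))
    u[land3] <- NA_real_
    v[land3] <- NA_real_
  }
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat), time = time,
                 u = u, v = v, land = land, dlon = dlon, dlat = dlat),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("velocity_series: %d days (%s to %s), %d x %d grid (%.4g deg), %d land cells\n",
              length(x$time), format(x$time[1]), format(x$time[length(x$time)]),
              length(x$lat), length(x$lon), x$dlon, sum(x$land)))
  invisible(x)
}

# coerce a time argument (Date, POSIXct, or numeric days since the first
# snapshot) to fractional days since series$time[1]
as_series_days <- function(series, t) {
  if (inherits(t, "Date")) return(as.numeric(t - series$time[1]))
  if (inherits(t, "POSIXct"))
    return(as.numeric(difftime(t, as.POSIXct(paste(series$time[1], "00:00:00"), tz = "UTC"),
                               units = "days")))
  as.numeric(t)
}

# Vectorised space-time interpolation kernel. Returns list(u, v, ok); ok is
# FALSE where the query point or time is outside the grid hull (u, v NA
# there). Land-node velocities contribute zero with no re-weighting, so
# interpolated speeds taper toward coasts.
sample_uv <- function(series, lon, lat, tdays) {
  nlon <- length(series$lon); nlat <- length(series$lat); nt <- length(series$time)
  n <- max(length(lon), length(lat), length(tdays))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); tdays <- rep_len(tdays, n)

  ok <- lon >= series$lon[1] & lon <= series$lon[nlon] &
        lat >= series$lat[1] & lat <= series$lat[nlat] &
        tdays >= 0 & tdays <= (nt - 1) & is.finite(lon) & is.finite(lat)

  u <- rep(NA_real_, n); v <- rep(NA_real_, n)
  if (!any(ok)) return(list(u = u, v = v, ok = ok))

  lo <- lon[ok]; la <- lat[ok]; td <- tdays[ok]
  fx <- (lo - series$lon[1]) / series$dlon
  fy <- (la - series$lat[1]) / series$dlat
  i1 <- pmin(pmax(floor(fx), 0), nlon - 2); wx <- fx - i1
  j1 <- pmin(pmax(floor(fy), 0), nlat - 2); wy <- fy - j1
  k1 <- pmin(pmax(floor(td), 0), max(nt - 2, 0)); wt <- if (nt > 1) td - k1 else 0
  i1 <- i1 + 1L; j1 <- j1 + 1L; k1 <- k1 + 1L  # 1-based

  gather <- function(a, k, j, i) {
    val <- a[cbind(k, j, i)]
    val[is.na(val)] <- 0  # land contributes zero velocity
    val
  }
  interp <- function(a) {
    bil <- function(k) {
      gather(a, k, j1,      i1)      * (1 - wx) * (1 - wy) +
      gather(a, k, j1,      i1 + 1L) * wx       * (1 - wy) +
      gather(a, k, j1 + 1L, i1)      * (1 - wx) * wy +
      gather(a, k, j1 + 1L, i1 + 1L) * wx       * wy
    }
    if (nt == 1) bil(k1) else bil(k1) * (1 - wt) + bil(pmin(k1 + 1L, nt)) * wt
  }
  u[ok] <- interp(series$u)
  v[ok] <- interp(series$v)
  list(u = u, v = v, ok = ok)
}

#' Sample a velocity series at arbitrary points and times
#'
#' Bilinear interpolation in space of the two bracketing daily snapshots,
#' followed by linear interpolation in time. Velocities stored on land nodes
#' contribute zero to the interpolation (with no re-weighting), so sampled
#' currents taper smoothly toward coastlines.
#'
#' @param series a [velocity_series()].
#' @param lon,lat query coordinates (decimal degrees); vectorised.
#' @param t query time: a `Date`, `POSIXct`, or numeric fractional days since
#'   the first snapshot (00Z).
#' @return a list with numeric vectors `u` and `v` (m s^-1).
#' @export
sample_velocity <- function(series, lon, lat, t) {
  stopifnot(inherits(series, "velocity_series"))
  res <- sample_uv(series, lon, lat, as_series_days(series, t))
  if (!all(res$ok))
    stop("sample_velocity: query point or time outside the grid domain", call. = FALSE)
  list(u = res$u, v = res$v)
}

#' Test whether a point lies on a land cell
#'
#' Nearest-grid-cell lookup in the series' land mask.
#'
#' @inheritParams sample_velocity
#' @return logical vector, `TRUE` where the nearest cell is land.
#' @export
is_land <- function(series, lon, lat) {
  stopifnot(inherits(series, "velocity_series"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  if (any(lon < series$lon[1] | lon > series$lon[length(series$lon)] |
          lat < series$lat[1] | lat > series$lat[length(series$lat)], na.rm = FALSE))
    stop("is_land: point outside the grid domain", call. = FALSE)
  i <- pmin(pmax(round((lon - series$lon[1]) / series$dlon), 0), length(series$lon) - 1) + 1L
  j <- pmin(pmax(round((lat - series$lat[1]) / series$dlat), 0), length(series$lat) - 1) + 1L
  series$land[cbind(j, i)]
}

# internal land test that never errors (FALSE outside the hull)
on_land <- function(series, lon, lat) {
  nlon <- length(series$lon); nlat <- length(series$lat)
  inside <- lon >= series$lon[1] & lon <= series$lon[nlon] &
            lat >= series$lat[1] & lat <= series$lat[nlat]
  out <- rep(FALSE, length(lon))
  if (any(inside)) {
    i <- pmin(pmax(round((lon[inside] - series$lon[1]) / series$dlon), 0), nlon - 1) + 1L
    j <- pmin(pmax(round((lat[inside] - series$lat[1]) / series$dlat), 0), nlat - 1) + 1L
    out[inside] <- series$land[cbind(j, i)]
  }
  out
}

#' Write / read a velocity series
#'
#' Serialises the series to a single file in a fixed, validated layout
#' (named elements `lon`, `lat`, `time`, `u`, `v`, `land`; velocities in
#' m s^-1 with land stored as missing values). `read_velocity()` validates
#' the layout on the way in, naming any missing element, and re-checks grid
#' uniformity; `read_velocity(write_velocity(s))` reproduces grids, masks and
#' values exactly.
#'
#' @param series a [velocity_series()].
#' @param path file path.
#' @return `write_velocity()` returns `path` invisibly; `read_velocity()`
#'   returns a `velocity_series`.
#' @export
write_velocity <- function(series, path) {
  stopifnot(inherits(series, "velocity_series"))
  u <- series$u; v <- series$v
  land3 <- aperm(array(series$land, c(dim(series$land), length(series$time))), c(3, 1, 2))
  u[land3] <- NA_real_; v[land3] <- NA_real_
  saveRDS(list(format = "larvadrift-velocity-1", lon = series$lon, lat = series$lat,
               time = series$time, u = u, v = v, land = series$land,
               units = c(u = "m s-1", v = "m s-1")),
          path)
  invisible(path)
}

#' @rdname write_velocity
#' @export
read_velocity <- function(path) {
  raw <- readRDS(path)
  if (!is.list(raw)) stop("not a velocity file", call. = FALSE)
  for (nm in c("lon", "lat", "time", "u", "v", "land"))
    if (is.null(raw[[nm]]))
      stop(sprintf("velocity file is missing variable '%s'", nm), call. = FALSE)
  velocity_series(raw$lon, raw$lat, raw$time, raw$u, raw$v, land = raw$land)
}
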