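#' Parameters of the synthetic equatorial current system
#'
#' Describes a zonally banded surface current field: westward South and North
#' Equatorial Currents (SEC/NEC) and an eastward North Equatorial
#' Counter-Current (NECC), each a Gaussian jet in latitude, with an optional
#' seasonal cycle, ENSO coupling of the NECC (speed gain and a latitude
#' shift, negative = southward, the signature of eastern-Pacific El Nino
#' events), and non-divergent mesoscale eddies.
#'
#' @param lon_min,lon_max,lat_min,lat_max domain bounds, decimal degrees.
#' @param resolution grid spacing in degrees (default 1/12, mirroring
#'   eddy-resolving reanalysis forcing).
#' @param start first day (`Date`); daily snapshots are at 00Z.
#' @param n_days number of daily snapshots.
#' @param bands data frame with one row per current band and columns
#'   `name`, `center` (deg), `width` (Gaussian half-width, deg), `peak`
#'   (m s^-1, signed, westward negative), `seas_amp` (relative seasonal
#'   amplitude), `seas_peak_month` (month of maximum), `enso_gain`
#'   (relative speed gain per index unit) and `enso_lat_shift` (deg per
#'   index unit, negative = southward). See [default_bands()].
#' @param eddy_amp RMS eddy speed (m s^-1); 0 disables eddies.
#' @param eddy_scale eddy length scale (deg).
#' @param eddy_decorr_days temporal decorrelation of the eddy field (days).
#' @param seed integer RNG seed; fixes the output bit-exactly.
#' @return an object of class `flow_params`.
#' @export
flow_params <- function(lon_min = -150, lon_max = -80, lat_min = -12, lat_max = 12,
                        resolution = 1 / 12,
                        start = as.Date("1997-01-01"), n_days = 365,
                        bands = default_bands(),
                        eddy_amp = 0.05, eddy_scale = 2, eddy_decorr_days = 10,
                        seed = 1L) {
  stop_if_not_number(resolution, "resolution", min = 1e-6)
  stop_if_not_number(eddy_amp, "eddy_amp", min = 0)
  stop_if_not_number(eddy_scale, "eddy_scale", min = 1e-6)
  if (lon_max <= lon_min || lat_max <= lat_min) stop("empty domain", call. = FALSE)
  need <- c("name", "center", "width", "peak", "seas_amp", "seas_peak_month",
            "enso_gain", "enso_lat_shift")
  if (!is.data.frame(bands) || !all(need %in% names(bands)))
    stop("'bands' must be a data frame with columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(bands$width <= 0)) stop("band half-widths must be > 0", call. = FALSE)
  if (any(abs(bands$peak) > 2))
    stop("band peak speeds exceed the 2 m s-1 plausibility bound", call. = FALSE)
  structure(list(lon_min = lon_min, lon_max = lon_max, lat_min = lat_min,
                 lat_max = lat_max, resolution = resolution,
                 start = as.Date(start), n_days = as.integer(n_days),
                 bands = bands, eddy_amp = eddy_amp, eddy_scale = eddy_scale,
                 eddy_decorr_days = eddy_decorr_days, seed = as.integer(seed)),
            class = "flow_params")
}

#' Default equatorial current bands
#'
#' Westward SEC and NEC and an eastward NECC with a seasonal cycle peaking in
#' boreal autumn and ENSO coupling confined to the NECC: its speed scales by
#' `1 + 0.25 * index` and its axis shifts `-0.75` deg per positive index
#' unit (southward under El Nino). The ENSO coupling magnitudes are free
#' parameters of the generator, not calibrated against observations.
#'
#' @return data frame suitable for the `bands` argument of [flow_params()].
#' @export
default_bands <- function() {
  data.frame(
    name = c("SEC", "NEC", "NECC"),
    center = c(-4, 11, 6),
    width = c(3, 3, 2.5),
    peak = c(-0.35, -0.30, 0.35),
    seas_amp = c(0, 0, 0.35),
    seas_peak_month = c(1, 1, 10),
    enso_gain = c(0, 0, 0.25),
    enso_lat_shift = c(0, 0, -0.75)
  )
}

#' Monthly ENSO index series
#'
#' @param date monthly timestamps (`Date`, first of month), strictly increasing.
#' @param index dimensionless index values, positive during El Nino.
#' @param label optional event labels; if missing, labelled "El Nino" when
#'   `index >= 0.5`, "La Nina" when `index <= -0.5`, else "neutral".
#' @return data frame of class `enso_series` with columns date, index, label.
#' @export
enso_series <- function(date, index, label = NULL) {
  date <- as.Date(date)
  if (length(date) != length(index)) stop("date/index length mismatch", call. = FALSE)
  if (any(diff(as.numeric(date)) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (!all(is.finite(index))) stop("index values must be finite", call. = FALSE)
  if (is.null(label))
    label <- ifelse(index >= 0.5, "El Nino", ifelse(index <= -0.5, "La Nina", "neutral"))
  structure(data.frame(date = month_floor(date), index = as.numeric(index),
                       label = label, stringsAsFactors = FALSE),
            class = c("enso_series", "data.frame"))
}

#' Generate a synthetic monthly ENSO index
#'
#' First-order autoregressive surrogate for a bivariate ENSO index: smooth,
#' zero-mean, with events of both signs on the observed 2-7 year cadence when
#' run over multiple years.
#'
#' @param start first month (`Date`).
#' @param n_months series length.
#' @param rho lag-1 autocorrelation (monthly).
#' @param sd marginal standard deviation of the index.
#' @param seed integer RNG seed.
#' @return an [enso_series()].
#' @export
generate_enso <- function(start = as.Date("1997-01-01"), n_months = 24,
                          rho = 0.9, sd = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  innov <- stats::rnorm(n_months, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n_months)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n_months)[-1]) x[i] <- rho * x[i - 1] + innov[i]
  enso_series(seq(month_floor(as.Date(start)), by = "month", length.out = n_months), x)
}

# seasonal modulation factor, centred so that the monthly mean is maximal in
# the configured peak month (mid-month phase)
season_factor <- function(dates, amp, peak_month) {
  if (amp == 0) return(rep(1, length(dates)))
  m <- as.integer(format(dates, "%m"))
  mday <- as.integer(format(dates, "%d"))
  first <- month_floor(dates)
  ndays <- as.integer(month_floor(first + 32) - first)
  mm <- m + (mday - 0.5) / ndays - 0.5
  1 + amp * cos(2 * pi * (mm - peak_month) / 12)
}

# separable Gaussian smoothing of a matrix (rows then columns)
gauss_smooth <- function(mat, sigma_row, sigma_col = sigma_row) {
  kern <- function(n, s) {
    k <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * s^2))
    sweep(k, 1, rowSums(k), "/")
  }
  kern(nrow(mat), sigma_row) %*% mat %*% t(kern(ncol(mat), sigma_col))
}

#' Generate a synthetic daily surface-velocity series
#'
#' Builds daily (00Z) `u`/`v` fields on the configured grid. The zonal
#' component is the sum over current bands of
#' `peak * exp(-(lat - center(t))^2 / (2 w^2)) * season(t) * (1 + gain * enso(t))`,
#' with the band axis displaced by `enso_lat_shift * enso(t)` degrees. The
#' meridional component contains only the eddy contribution. Eddies are
#' derived from a Gaussian-smoothed random streamfunction by centred
#' differences (constant metric at the domain-centre latitude), which makes
#' the eddy field discretely divergence-free by construction; the eddy
#' streamfunction evolves as a daily AR(1) process.
#'
#' @param params a [flow_params()].
#' @param enso an [enso_series()] covering every month of the time span.
#' @param islands optional data frame (`lon`, `lat`, `radius` in degrees) of
#'   square land patches to mask, e.g. the `islands` element of a
#'   [generate_seascape()] result.
#' @return a [velocity_series()].
#' @export
generate_flow <- function(params, enso, islands = NULL) {
  stopifnot(inherits(params, "flow_params"), inherits(enso, "enso_series"))
  res <- params$resolution
  lon <- seq(params$lon_min, params$lon_max, by = res)
  lat <- seq(params$lat_min, params$lat_max, by = res)
  dates <- params$start + seq_len(params$n_days) - 1L

  if (any(params$bands$center < params$lat_min | params$bands$center > params$lat_max))
    stop("domain does not cover all band centre latitudes", call. = FALSE)

  months_needed <- unique(month_floor(dates))
  missing <- setdiff(format(months_needed, "%Y-%m"), format(enso$date, "%Y-%m"))
  if (length(missing))
    stop("ENSO series does not cover the time span; missing months: ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- enso$index[match(format(month_floor(dates), "%Y-%m"), format(enso$date, "%Y-%m"))]

  nt <- length(dates); nlat <- length(lat); nlon <- length(lon)
  u <- array(0, c(nt, nlat, nlon))
  v <- array(0, c(nt, nlat, nlon))

  for (b in seq_len(nrow(params$bands))) {
    bb <- params$bands[b, ]
    seas <- season_factor(dates, bb$seas_amp, bb$seas_peak_month)
    gain <- 1 + bb$enso_gain * idx
    center <- bb$center + bb$enso_lat_shift * idx
    dev <- outer(-center, lat, "+")  # nt x nlat: lat - center(t)
    prof <- bb$peak * exp(-dev^2 / (2 * bb$width^2)) * (seas * gain)
    u <- u + array(prof, c(nt, nlat, nlon))
  }

  if (params$eddy_amp > 0) {
    set.seed(params$seed)
    sig <- params$eddy_scale / res
    rho <- exp(-1 / params$eddy_decorr_days)
    dy <- res * m_per_deg_lat()
    dx <- res * m_per_deg_lon(mean(lat))
    psi <- gauss_smooth(matrix(stats::rnorm(nlat * nlon), nlat, nlon), sig)
    ssq <- 0; nsq <- 0
    ue <- array(0, c(nt, nlat, nlon)); ve <- array(0, c(nt, nlat, nlon))
    jint <- 2:(nlat - 1); iint <- 2:(nlon - 1)
    for (k in seq_len(nt)) {
      if (k > 1)
        psi <- rho * psi + sqrt(1 - rho^2) *
          gauss_smooth(matrix(stats::rnorm(nlat * nlon), nlat, nlon), sig)
      uk <- matrix(0, nlat, nlon); vk <- matrix(0, nlat, nlon)
      uk[jint, ] <- -(psi[jint + 1L, ] - psi[jint - 1L, ]) / (2 * dy)
      vk[, iint] <- (psi[, iint + 1L] - psi[, iint - 1L]) / (2 * dx)
      ue[k, , ] <- uk; ve[k, , ] <- vk
      ssq <- ssq + sum(uk[jint, iint]^2 + vk[jint, iint]^2)
      nsq <- nsq + 2 * length(jint) * length(iint)
    }
    scale <- params$eddy_amp / sqrt(ssq / nsq)
    u <- u + scale * ue
    v <- v + scale * ve
  }

  land <- matrix(FALSE, nlat, nlon)
  if (!is.null(islands) && nrow(islands)) {
    for (r in seq_len(nrow(islands))) {
      jj <- abs(lat - islands$lat[r]) <= islands$radius[r]
      ii <- abs(lon - islands$lon[r]) <= islands$radius[r]
      land[jj, ii] <- TRUE
    }
  }
  velocity_series(lon, lat, dates, u, v, land = land)
}

#' Synthetic seascape parameters
#'
#' Defines two biogeographic provinces separated by a reef-free open-ocean
#' gap (the dispersal barrier). Each province is a list of island clusters,
#' each cluster a region: reef points are scattered uniformly within a disc
#' around the cluster centre.
#'
#' @param provinces a named list with elements `west` and `east`, each a list
#'   of clusters; a cluster is a list with `region` (code), `lon`, `lat`
#'   (centre, deg), `radius` (deg) and `n_points` (reef point count), and
#'   optionally `island_radius` (deg of land to mask at the centre; 0 = none).
#' @param seed integer RNG seed.
#' @return an object of class `seascape_params`.
#' @export
seascape_params <- function(provinces = default_provinces(), seed = 1L) {
  if (!all(c("west", "east") %in% names(provinces)))
    stop("'provinces' must have elements 'west' and 'east'", call. = FALSE)
  regions <- unlist(lapply(provinces, vapply, function(cl) cl$region, ""))
  if (anyDuplicated(regions))
    stop("each region code must belong to exactly one cluster", call. = FALSE)
  ext <- function(side) {
    cls <- provinces[[side]]
    range(unlist(lapply(cls, function(cl) cl$lon + c(-1, 1) * cl$radius)))
  }
  w <- ext("west"); e <- ext("east")
  if (w[2] >= e[1] && e[2] >= w[1])
    stop("provinces overlap in longitude; no barrier gap", call. = FALSE)
  structure(list(provinces = provinces, seed = as.integer(seed),
                 barrier_gap = max(e[1] - w[2], w[1] - e[2])),
            class = "seascape_params")
}

#' Default two-province study seascape
#'
#' An eastern province of two reef clusters (an offshore archipelago on the
#' axis of the westward SEC and a lower-latitude coastal cluster) and a
#' western province of two archipelago clusters roughly 25 degrees of
#' longitude away, leaving a reef-free gap of about 2,800 km between
#' provinces -- wide enough that only sustained band flow, not diffusion,
#' can bridge it within a larval lifetime.
#'
#' @return province list for [seascape_params()].
#' @export
default_provinces <- function() {
  list(
    west = list(
      list(region = "WMA", lon = -114.5, lat = -4.0, radius = 0.8, n_points = 40),
      list(region = "WTU", lon = -113.0, lat = -5.5, radius = 0.8, n_points = 30)
    ),
    east = list(
      list(region = "EGA", lon = -86.0, lat = -4.0, radius = 0.6, n_points = 40),
      list(region = "ECO", lon = -85.0, lat = -1.5, radius = 0.6, n_points = 30)
    )
  )
}

#' Generate a synthetic reef seascape
#'
#' Scatters reef points within each cluster disc and assembles the region
#' scheme (every region flagged with its side of the barrier, west regions
#' first so the barrier is a fixed index in connectivity matrices).
#'
#' @param params a [seascape_params()].
#' @return list of class `seascape` with elements `points` (data frame
#'   `lon`, `lat`, `region`), `scheme` (a [region_scheme()]), `islands`
#'   (data frame of land patches, possibly empty) and `barrier_gap`
#'   (degrees of reef-free longitude).
#' @export
generate_seascape <- function(params) {
  stopifnot(inherits(params, "seascape_params"))
  set.seed(params$seed)
  pts <- list(); isl <- list()
  scheme_rows <- list()
  for (side in c("west", "east")) {
    for (cl in params$provinces[[side]]) {
      n <- cl$n_points
      if (n > 0) {
        r <- cl$radius * sqrt(stats::runif(n))
        th <- stats::runif(n, 0, 2 * pi)
        pts[[length(pts) + 1L]] <- data.frame(
          lon = cl$lon + r * cos(th), lat = cl$lat + r * sin(th),
          region = cl$region, stringsAsFactors = FALSE)
      }
      ir <- if (is.null(cl$island_radius)) 0 else cl$island_radius
      if (ir > 0)
        isl[[length(isl) + 1L]] <- data.frame(lon = cl$lon, lat = cl$lat, radius = ir)
      scheme_rows[[length(scheme_rows) + 1L]] <-
        data.frame(region = cl$region, side = side, stringsAsFactors = FALSE)
    }
  }
  scheme_df <- do.call(rbind, scheme_rows)
  scheme_df <- scheme_df[order(scheme_df$side != "west"), ]  # west block first
  structure(list(
    points = if (length(pts)) do.call(rbind, pts) else
      data.frame(lon = numeric(), lat = numeric(), region = character()),
    scheme = region_scheme(scheme_df$region, scheme_df$side),
    islands = if (length(isl)) do.call(rbind, isl) else
      data.frame(lon = numeric(), lat = numeric(), radius = numeric()),
    barrier_gap = params$barrier_gap
  ), class = "seascape")
}

#' Synthetic genetic-differentiation parameters
#'
#' Controls the coupling between modelled dispersal probability and pairwise
#' genetic differentiation (F'ST): differentiation decreases linearly with
#' the log10 of dispersal probability, plus Gaussian noise, clamped to [0, 1].
#'
#' @param intercept baseline F'ST at dispersal probability 1.
#' @param slope increase in F'ST per decade decrease in dispersal probability.
#' @param noise_sd standard deviation of added Gaussian noise.
#' @param floor probability floor `eps` applied to zero (or smaller)
#'   probabilities before taking logs; default `NULL` means half the smallest
#'   nonzero probability in the input.
#' @param seed integer RNG seed.
#' @return object of class `fst_params`.
#' @export
fst_params <- function(intercept = 0.05, slope = 0.08, noise_sd = 0.02,
                       floor = NULL, seed = 1L) {
  stop_if_not_number(slope, "slope", min = -10, max = 10)
  stop_if_not_number(noise_sd, "noise_sd", min = 0)
  structure(list(intercept = intercept, slope = slope, noise_sd = noise_sd,
                 floor = floor, seed = as.integer(seed)),
            class = "fst_params")
}

#' Generate a synthetic F'ST half-matrix from dispersal probabilities
#'
#' Ground-truth surrogate for empirical population-genetic differentiation:
#' `F'ST_ij = clamp(a + slope * (-log10(max(p_ij, eps))) + noise, 0, 1)`,
#' symmetric and reproducible under the seed. `eps` floors only zero (or
#' sub-floor) probabilities, so distinct nonzero probabilities map to
#' log-linearly spaced differentiation values.
#'
#' @param p pairwise dispersal probabilities: a [stats::dist] object or a
#'   symmetric matrix (diagonal ignored); values in [0, 1].
#' @param params an [fst_params()].
#' @return a [stats::dist] object of F'ST values with the labels of `p`.
#' @export
generate_fst <- function(p, params = fst_params()) {
  stopifnot(inherits(params, "fst_params"))
  d <- as_half_matrix(p, "p")
  pv <- as.vector(d)
  if (any(pv < 0)) stop("negative dispersal probabilities", call. = FALSE)
  if (any(pv > 1)) stop("dispersal probabilities exceed 1", call. = FALSE)
  eps <- params$floor
  if (is.null(eps)) {
    nz <- pv[pv > 0]
    if (!length(nz)) stop("all probabilities are zero; no floor definable", call. = FALSE)
    eps <- min(nz) / 2
  }
  s <- -log10(pmax(pv, eps))
  set.seed(params$seed)
  f <- params$intercept + params$slope * s +
    if (params$noise_sd > 0) stats::rnorm(length(s), 0, params$noise_sd) else 0
  f <- pmin(pmax(f, 0), 1)
  out <- d
  out[] <- f
  out
}

# coerce dist or symmetric matrix to dist, checking symmetry
as_half_matrix <- function(x, name = "x") {
  if (inherits(x, "dist")) return(x)
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x) || !isTRUE(all.equal(x, t(x), tolerance = 1e-12,
                                                check.attributes = FALSE)))
      stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
    return(stats::as.dist(x))
  }
  stop(sprintf("'%s' must be a dist object or symmetric matrix", name), call. = FALSE)
}

#' Read / write reef points and ENSO series as CSV
#'
#' Plain-CSV interchange for the two small tabular inputs: reef points
#' (`lon`, `lat`, `region`) and monthly ENSO index series (`date`, `index`,
#' optional `label`).
#'
#' @param points data frame with columns `lon`, `lat`, `region`.
#' @param enso an [enso_series()].
#' @param path file path.
#' @return readers return the parsed object; writers return `path` invisibly.
#' @name seascape_io
NULL

#' @rdname seascape_io
#' @export
write_reef_points <- function(points, path) {
  utils::write.csv(points[, c("lon", "lat", "region")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname seascape_io
#' @export
read_reef_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("lon", "lat", "region"))
    if (is.null(df[[nm]])) stop(sprintf("reef point file is missing column '%s'", nm),
                                call. = FALSE)
  df
}

#' @rdname seascape_io
#' @export
write_enso <- function(enso, path) {
  utils::write.csv(as.data.frame(enso), path, row.names = FALSE)
  invisible(path)
}

#' @rdname seascape_io
#' @export
read_enso <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  enso_series(as.Date(df$date), df$index, df$label)
}
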