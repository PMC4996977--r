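# Shared fixtures, built in code. The metre/degree conversions here are
# written out independently of the package internals so they can serve as
# oracles for the advection arithmetic.

R_EARTH <- 6371000
deg_m_lat <- R_EARTH * pi / 180
deg_m_lon <- function(lat) R_EARTH * cos(lat * pi / 180) * pi / 180

# velocity series with constant (or function-valued) components
make_series <- function(u = 0, v = 0, nd = 3,
                        lon = seq(0, 2, by = 0.5), lat = seq(0, 2, by = 0.5),
                        land = NULL, start = as.Date("2000-01-01")) {
  dims <- c(nd, length(lat), length(lon))
  fill <- function(x) {
    if (is.function(x)) {
      a <- array(0, dims)
      for (k in seq_len(nd)) for (j in seq_along(lat))
        a[k, j, ] <- x(k - 1, lat[j], lon)
      a
    } else array(x, dims)
  }
  velocity_series(lon, lat, start + 0:(nd - 1), fill(u), fill(v), land = land)
}

# neutral (all-zero) monthly ENSO series covering n_months from start
neutral_enso <- function(start = as.Date("2000-01-01"), n_months = 12)
  enso_series(seq(as.Date(start), by = "month", length.out = n_months),
              rep(0, n_months))

# a one-band westward-jet flow parameterisation on a narrow domain
sec_only_params <- function(peak = -0.35, resolution = 1 / 2, n_days = 200,
                            eddy_amp = 0.02, seed = 3) {
  bands <- default_bands()[1, ]
  bands$peak <- peak
  flow_params(lon_min = -120, lon_max = -80, lat_min = -10, lat_max = 2,
              resolution = resolution, start = as.Date("2000-01-01"),
              n_days = n_days, bands = bands, eddy_amp = eddy_amp, seed = seed)
}

# the two-province barrier experiment at test scale: daily cohorts from every
# habitat cell, with eastern-province releases riding the westward SEC across
# a ~25 degree reef-free gap
run_barrier_campaign <- function(peak = -0.35, n_larvae = 20, seed = 11) {
  sea <- generate_seascape(seascape_params(seed = 7))
  cells <- regrid_reefs(sea$points)
  flow <- generate_flow(sec_only_params(peak = peak, seed = seed + 1),
                        neutral_enso())
  bio <- bio_params(n_larvae = n_larvae)
  camp <- run_campaign(flow, cells, bio,
                       release_dates = as.Date("2000-01-05") + c(0, 10, 20),
                       seed = seed)
  list(camp = camp, cells = cells, scheme = sea$scheme)
}

# two habitat regions A (east side) and B (west side), 500 km apart on the
# same latitude line; returns cells, scheme, and the two cell ids
make_pair_cells <- function(sep_km = 500) {
  lat0 <- 1 / 12  # centre of the iy = 0 row
  dlon <- sep_km * 1000 / deg_m_lon(lat0)
  lon_a <- 10 + 1 / 12   # centre of a 1/6 cell
  lon_b <- lon_a - dlon
  pts <- data.frame(lon = c(lon_a, lon_b), lat = lat0,
                    region = c("A", "B"))
  cells <- regrid_reefs(pts)
  list(cells = cells, scheme = region_scheme(c("B", "A"), c("west", "east")),
       cell_a = cells$cell[cells$region == "A"],
       cells_b = cells$cell[cells$region == "B"])
}

# minimal settlement event table
make_events <- function(src, dst, release, settle = release + 30,
                        age = as.integer(settle - release)) {
  data.frame(source_cell = src, dest_cell = dst,
             release_date = as.Date(release), settle_date = as.Date(settle),
             age = age)
}
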