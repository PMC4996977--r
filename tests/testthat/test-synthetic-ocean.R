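flat_enso <- neutral_enso(n_months = 14)

test_that("zero forcing parameters give an identically zero field", {
  bands <- default_bands()
  bands$peak <- 0
  p <- flow_params(lon_min = -100, lon_max = -95, lat_min = -12, lat_max = 12,
                   resolution = 1 / 2, n_days = 10, start = as.Date("2000-01-01"),
                   bands = bands, eddy_amp = 0)
  s <- generate_flow(p, flat_enso)
  expect_true(all(s$u == 0))
  expect_true(all(s$v == 0))
})

test_that("a band jet peaks at its centre latitude with the configured speed", {
  bands <- default_bands()[3, ]  # NECC
  bands$peak <- 0.4; bands$seas_amp <- 0; bands$enso_gain <- 0; bands$enso_lat_shift <- 0
  p <- flow_params(lon_min = -100, lon_max = -95, lat_min = -12, lat_max = 12,
                   resolution = 1 / 4, n_days = 5, start = as.Date("2000-01-01"),
                   bands = bands, eddy_amp = 0)
  s <- generate_flow(p, flat_enso)
  j <- which(s$lat == 6)
  expect_equal(s$u[1, j, 1], 0.4)
  expect_true(all(abs(s$u[, j, ]) >= abs(s$u[, j + 8, ])))  # decays off-axis
  expect_true(all(s$v == 0))
})

test_that("the eddy field is discretely divergence-free", {
  bands <- default_bands()
  bands$peak <- 0
  p <- flow_params(lon_min = -100, lon_max = -90, lat_min = -12, lat_max = 12,
                   resolution = 1 / 4, n_days = 4, start = as.Date("2000-01-01"),
                   bands = bands, eddy_amp = 0.05, seed = 9)
  s <- generate_flow(p, flat_enso)
  dy <- (1 / 4) * deg_m_lat
  dx <- (1 / 4) * deg_m_lon(mean(s$lat))
  nlat <- length(s$lat); nlon <- length(s$lon)
  jj <- 3:(nlat - 2); ii <- 3:(nlon - 2)
  for (k in 1:4) {
    u <- s$u[k, , ]; v <- s$v[k, , ]
    div <- (u[jj, ii + 1] - u[jj, ii - 1]) / (2 * dx) +
           (v[jj + 1, ii] - v[jj - 1, ii]) / (2 * dy)
    scale <- max(abs(c(u, v))) / dx
    expect_lt(max(abs(div)), 1e-10 * scale)
  }
  expect_gt(max(abs(s$v)), 0)  # eddies do populate the meridional component
})

test_that("identical parameters and seed reproduce the field bit-exactly", {
  p <- sec_only_params(n_days = 20)
  s1 <- generate_flow(p, flat_enso)
  s2 <- generate_flow(p, flat_enso)
  expect_identical(s1$u, s2$u)
  expect_identical(s1$v, s2$v)
})

test_that("ENSO index perturbs the NECC speed by exactly gain * delta at its axis", {
  bands <- default_bands()[3, ]
  bands$peak <- 0.4; bands$seas_amp <- 0; bands$enso_gain <- 0.25; bands$enso_lat_shift <- 0
  p <- flow_params(lon_min = -100, lon_max = -98, lat_min = 0, lat_max = 12,
                   resolution = 1 / 4, n_days = 90, start = as.Date("2000-01-01"),
                   bands = bands, eddy_amp = 0)
  months <- seq(as.Date("2000-01-01"), by = "month", length.out = 4)
  e0 <- enso_series(months, c(0, 0, 0, 0))
  e2 <- enso_series(months, c(0, 2, 0, 0))  # +2 in February only
  s0 <- generate_flow(p, e0)
  s2 <- generate_flow(p, e2)
  j <- which(s0$lat == 6)
  feb <- format(s0$time, "%m") == "02"
  diff_feb <- s2$u[feb, j, 1] - s0$u[feb, j, 1]
  expect_equal(diff_feb, rep(2 * 0.25 * 0.4, sum(feb)))
  expect_equal(s2$u[!feb, j, 1], s0$u[!feb, j, 1])
})

test_that("a positive index shifts the NECC axis southward when so configured", {
  bands <- default_bands()[3, ]
  bands$seas_amp <- 0; bands$enso_gain <- 0; bands$enso_lat_shift <- -0.75
  p <- flow_params(lon_min = -100, lon_max = -98, lat_min = 0, lat_max = 12,
                   resolution = 1 / 4, n_days = 20, start = as.Date("2000-01-01"),
                   bands = bands, eddy_amp = 0)
  e_hi <- enso_series(as.Date("2000-01-01"), 2)
  s <- generate_flow(p, e_hi)
  peak_lat <- s$lat[which.max(s$u[1, , 1])]
  expect_equal(peak_lat, 6 - 0.75 * 2, tolerance = 1 / 4)
})

test_that("monthly-mean NECC speed is maximal in the configured peak month", {
  bands <- default_bands()[3, ]
  bands$seas_amp <- 0.35; bands$seas_peak_month <- 10
  bands$enso_gain <- 0; bands$enso_lat_shift <- 0
  p <- flow_params(lon_min = -100, lon_max = -99, lat_min = 0, lat_max = 12,
                   resolution = 1 / 2, n_days = 365, start = as.Date("2000-01-01"),
                   bands = bands, eddy_amp = 0)
  s <- generate_flow(p, flat_enso)
  j <- which(s$lat == 6)
  monthly <- tapply(s$u[, j, 1], format(s$time, "%m"), mean)
  expect_identical(names(which.max(monthly)), "10")
})

test_that("the generator refuses a time span the ENSO series does not cover", {
  p <- sec_only_params(n_days = 400)
  expect_error(generate_flow(p, neutral_enso(n_months = 3)), "missing months")
})

test_that("seascapes respect the barrier gap, densities, and the seed", {
  prov <- list(
    west = list(list(region = "W", lon = -130.5, lat = 0, radius = 0.5, n_points = 25)),
    east = list(list(region = "E", lon = -84.5, lat = 0, radius = 0.5, n_points = 25)))
  sea <- generate_seascape(seascape_params(prov, seed = 4))
  w <- sea$points[sea$points$region == "W", ]
  e <- sea$points[sea$points$region == "E", ]
  expect_gte(min(outer(e$lon, w$lon, "-")), 45)
  expect_equal(sea$barrier_gap, 45)

  prov$west[[1]]$n_points <- 0
  sea0 <- generate_seascape(seascape_params(prov, seed = 4))
  expect_false(any(sea0$points$region == "W"))

  sea_a <- generate_seascape(seascape_params(seed = 12))
  sea_b <- generate_seascape(seascape_params(seed = 12))
  expect_identical(sea_a$points, sea_b$points)

  overlapping <- list(
    west = list(list(region = "W", lon = -100, lat = 0, radius = 2, n_points = 5)),
    east = list(list(region = "E", lon = -99, lat = 0, radius = 2, n_points = 5)))
  expect_error(seascape_params(overlapping), "overlap")
})

test_that("synthetic F'ST is log-linear in dispersal probability", {
  p <- as.dist(matrix(c(0, 1e-2, 1e-4,
                        1e-2, 0, 1e-3,
                        1e-4, 1e-3, 0), 3, 3))
  f <- generate_fst(p, fst_params(intercept = 0.1, slope = 0.08, noise_sd = 0))
  fv <- as.vector(f)  # pairs (2,1)=1e-2, (3,1)=1e-4, (3,2)=1e-3
  expect_equal(fv[2] - fv[1], 2 * 0.08)
  expect_equal(fv[3] - fv[1], 1 * 0.08)

  f0 <- generate_fst(p, fst_params(intercept = 0.3, slope = 0, noise_sd = 0))
  expect_true(all(as.vector(f0) == 0.3))

  expect_error(generate_fst(as.dist(matrix(c(0, -1, -1, 0), 2, 2)), fst_params()),
               "negative")

  # clamped to [0, 1] and symmetric under noise
  fn <- generate_fst(p, fst_params(intercept = 0.9, slope = 0.3, noise_sd = 0.5, seed = 2))
  expect_true(all(as.vector(fn) >= 0 & as.vector(fn) <= 1))
  m <- as.matrix(fn)
  expect_identical(m, t(m))
})
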