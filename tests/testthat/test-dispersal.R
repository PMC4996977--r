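test_that("RK4 advection matches the closed form in uniform flow", {
  s <- make_series(u = 0.5, v = 0, lon = seq(-1, 1, 0.25), lat = seq(-1, 1, 0.25))
  step <- advect_step(s, 0, 0, 0, 14400)
  # 0.5 m/s for 4 h = 7,200 m eastward at the equator
  expect_equal(step$lon, 7200 / deg_m_lon(0), tolerance = 1e-12)
  expect_equal(step$lat, 0)
  expect_false(step$exited)

  z <- make_series(u = 0, v = 0)
  still <- advect_step(z, 1, 1, 0.5, 14400)
  expect_identical(c(still$lon, still$lat), c(1, 1))

  # leaving the domain flags the particle instead of extrapolating
  out <- advect_step(s, 0.999, 0, 0, 86400 * 3)
  expect_true(out$exited)
  expect_equal(out$lon, 0.999)
})

test_that("RK4 orbits a solid-body rotation with tiny radius drift", {
  omega <- 2 * pi / (30 * 86400)  # one revolution in 30 days
  rot <- function(lon, lat, t)
    list(u = -omega * lat * deg_m_lon(lat), v = omega * lon * deg_m_lat)
  pos <- c(lon = 1, lat = 0)
  dt <- 14400
  for (k in seq_len(30 * 86400 / dt)) {
    st <- advect_step(rot, pos[1], pos[2], (k - 1) * dt / 86400, dt)
    pos <- c(st$lon, st$lat)
  }
  radius <- sqrt(sum(pos^2))
  expect_lt(abs(radius - 1), 1e-6)
  expect_lt(sqrt((pos[1] - 1)^2 + pos[2]^2), 1e-4)  # phase error also tiny
})

test_that("random-walk displacements have the prescribed scale and recover D", {
  same <- diffusion_step(c(1, 2, 3), c(1, 2, 3), 0, 14400)
  expect_identical(same$lon, c(1, 2, 3))

  set.seed(42)
  n <- 2e5
  d1 <- diffusion_step(rep(0, n), rep(0, n), 7, 14400)
  sd_m <- sd(d1$lon * deg_m_lon(0))
  expect_equal(sd_m, sqrt(2 * 7 * 14400), tolerance = 0.01)  # 449.0 m

  # 1 day of six 4-h steps: MSD/(4t) estimates D = 7 within 3%
  set.seed(43)
  lon <- rep(0, 1e5); lat <- rep(0, 1e5)
  for (k in 1:6) {
    st <- diffusion_step(lon, lat, 7, 14400)
    lon <- st$lon; lat <- st$lat
  }
  msd <- mean((lon * deg_m_lon(0))^2 + (lat * deg_m_lat)^2)
  expect_equal(msd / (4 * 86400), 7, tolerance = 0.03)
})

test_that("daily biology reproduces the exponential survival curve", {
  bio <- bio_params(mortality = 0.02)
  n <- 1e5
  state <- data.frame(status = rep("drifting", n), age = 0)
  set.seed(7)
  for (d in 1:35) state <- daily_biology(state, bio)
  frac <- mean(state$status == "drifting")
  expect_equal(frac, 0.98^35, tolerance = 0.01)  # 0.4930

  immortal <- data.frame(status = rep("drifting", 1000), age = 0)
  for (d in 1:50) immortal <- daily_biology(immortal, bio_params(mortality = 0))
  expect_true(all(immortal$status == "drifting"))

  # expiry closes the pelagic window
  old <- data.frame(status = "drifting", age = 119)
  expect_equal(daily_biology(old, bio_params(mortality = 0))$status, "expired")
})

test_that("settlement requires active competency and presence in a cell", {
  pts <- data.frame(lon = 10.05, lat = 0.05, region = "A")
  cells <- regrid_reefs(pts)
  at_cell <- data.frame(status = "drifting", age = 6, onset = 5,
                        lon = cells$center_lon, lat = cells$center_lat)
  chk <- settle_check(at_cell, cells)
  expect_true(chk$settled)
  expect_equal(chk$destination, cells$cell)

  pre <- at_cell; pre$age <- 3
  expect_false(settle_check(pre, cells)$settled)

  away <- at_cell; away$lon <- 50
  expect_false(settle_check(away, cells)$settled)
})

test_that("ballistic transport settles all survivors downstream and none upstream", {
  pc <- make_pair_cells(sep_km = 500)
  lon_b <- pc$cells$center_lon[pc$cells$region == "B"]
  s <- make_series(u = -0.3, v = 0, nd = 40,
                   lon = seq(lon_b - 2, 12, by = 0.25), lat = seq(-1, 1, by = 0.25))
  bio <- bio_params(n_larvae = 50, mortality = 0, diffusivity = 0.5,
                    max_duration = 30)
  camp <- run_campaign(s, pc$cells, bio, release_dates = as.Date("2000-01-01"),
                       release_cells = pc$cell_a, seed = 5)
  expect_equal(nrow(camp$events), 50L)  # every larva settles...
  expect_true(all(camp$events$dest_cell == pc$cells_b))  # ...in the western target
  # transit time consistent with 500 km at 0.3 m/s (~19.3 days)
  expect_true(all(abs(camp$events$age - 500e3 / 0.3 / 86400) <= 1.5))
})

test_that("with no flow and no turbulence every larva self-seeds on its onset day", {
  pts <- data.frame(lon = 0.05, lat = 0.05, region = "A")
  cells <- regrid_reefs(pts)
  s <- make_series(u = 0, v = 0, nd = 130, lon = seq(-1, 1, 0.5), lat = seq(-1, 1, 0.5))
  bio <- bio_params(n_larvae = 300, mortality = 0, diffusivity = 0)
  camp <- run_campaign(s, cells, bio, release_dates = as.Date("2000-01-01"), seed = 2)
  expect_equal(nrow(camp$events), 300L)
  expect_true(all(camp$events$dest_cell == camp$events$source_cell))
  expect_equal(sort(unique(camp$events$age)), 1:10)  # settle on the onset day

  # certain mortality empties the event table
  lethal <- bio_params(n_larvae = 100, mortality = 1, diffusivity = 0)
  camp0 <- run_campaign(s, cells, lethal, release_dates = as.Date("2000-01-01"), seed = 2)
  expect_equal(nrow(camp0$events), 0L)
  expect_equal(unname(camp0$counts["dead"]), 100)
})

test_that("competency onset days cover the ramp uniformly", {
  pts <- data.frame(lon = 0.05, lat = 0.05, region = "A")
  cells <- regrid_reefs(pts)
  s <- make_series(u = 0, v = 0, nd = 130, lon = seq(-1, 1, 0.5), lat = seq(-1, 1, 0.5))
  bio <- bio_params(n_larvae = 20000, mortality = 0, diffusivity = 0)
  camp <- run_campaign(s, cells, bio, release_dates = as.Date("2000-01-01"), seed = 9)
  freq <- table(factor(camp$events$age, levels = 1:10)) / 20000
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("campaigns conserve particles and are deterministic under the seed", {
  res <- run_barrier_campaign(n_larvae = 5, seed = 31)
  counts <- res$camp$counts
  expect_identical(unname(counts["released"]),
                   unname(sum(counts[c("settled", "dead", "expired", "exited")])))
  res2 <- run_barrier_campaign(n_larvae = 5, seed = 31)
  expect_identical(res$camp$events, res2$camp$events)
})

test_that("insufficient forcing is refused with the last usable release date", {
  pts <- data.frame(lon = 0.05, lat = 0.05, region = "A")
  cells <- regrid_reefs(pts)
  s <- make_series(nd = 60, lon = seq(-1, 1, 0.5), lat = seq(-1, 1, 0.5))
  bio <- bio_params(n_larvae = 1)
  expect_error(run_campaign(s, cells, bio, release_dates = as.Date("2000-01-20")),
               "last usable release date is 1999-11-01")
})

test_that("the advection-only mode disables settlement and mortality", {
  pts <- data.frame(lon = 0.05, lat = 0.05, region = "A")
  cells <- regrid_reefs(pts)
  s <- make_series(u = 0, v = 0, nd = 40, lon = seq(-1, 1, 0.5), lat = seq(-1, 1, 0.5))
  bio <- bio_params(n_larvae = 30, mortality = 0.5, diffusivity = 0, max_duration = 20)
  camp <- run_campaign(s, cells, bio, release_dates = as.Date("2000-01-01"),
                       biology = FALSE, record_trajectories = TRUE, seed = 3)
  expect_equal(nrow(camp$events), 0L)
  expect_equal(unname(camp$counts["expired"]), 30)
  expect_true(!is.null(camp$trajectories))
  expect_setequal(unique(camp$trajectories$particle), 1:30)
})
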