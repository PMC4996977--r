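#' Larval biology and integration parameters
#'
#' Defaults follow the high-dispersal-potential parameterisation of a generic
#' broadcast-spawning coral: 1,600 larvae per daily release per habitat cell,
#' competency onset spread uniformly over days 1-10 (10% of each cohort per
#' day), a constant daily mortality probability of 0.02 (half-life about 35
#' days), a maximum pelagic duration of 120 days, a horizontal diffusion
#' coefficient of 7 m^2 s^-1 for sub-grid turbulence, and a 4-hour
#' integration step.
#'
#' @param n_larvae larvae per release event per cell.
#' @param onset_days integer days over which competency onset is spread;
#'   each larva draws its onset day uniformly from this set.
#' @param mortality daily mortality probability (applied at each 00Z).
#' @param max_duration maximum pelagic duration in days; drifting larvae are
#'   terminated (status `expired`) when their age reaches it.
#' @param diffusivity horizontal diffusion coefficient D (m^2 s^-1).
#' @param dt_hours integration step in hours; must divide 24 evenly.
#' @return object of class `bio_params`.
#' @export
bio_params <- function(n_larvae = 1600, onset_days = 1:10, mortality = 0.02,
                       max_duration = 120, diffusivity = 7, dt_hours = 4) {
  stop_if_not_number(mortality, "mortality", min = 0, max = 1)
  stop_if_not_number(diffusivity, "diffusivity", min = 0)
  if (24 %% dt_hours != 0) stop("dt_hours must divide 24 evenly", call. = FALSE)
  onset_days <- as.integer(onset_days)
  if (!length(onset_days) || any(onset_days < 0))
    stop("onset_days must be non-negative integers", call. = FALSE)
  if (max_duration < max(onset_days))
    stop("max_duration must cover the competency onset window", call. = FALSE)
  structure(list(n_larvae = as.integer(n_larvae), onset_days = onset_days,
                 mortality = mortality, max_duration = as.integer(max_duration),
                 diffusivity = diffusivity, dt_hours = dt_hours),
            class = "bio_params")
}

#' Pelagic half-life implied by a daily mortality probability
#'
#' @param p daily mortality probability.
#' @param type `"rate"` treats `p` as a continuous instantaneous rate
#'   (half-life `ln 2 / p`); `"discrete"` uses the daily Bernoulli survival
#'   `(1 - p)^t` (half-life `log 0.5 / log(1 - p)`). For `p = 0.02` both
#'   round to 35 days.
#' @return half-life in days.
#' @export
half_life <- function(p, type = c("rate", "discrete")) {
  type <- match.arg(type)
  stop_if_not_number(p, "p", min = 1e-12, max = 1 - 1e-12)
  switch(type, rate = log(2) / p, discrete = log(0.5) / log(1 - p))
}

# velocity sampler abstraction: a velocity_series, or a function
# (lon, lat, tdays) -> list(u, v) for analytic fields
make_sampler <- function(flow) {
  if (inherits(flow, "velocity_series")) {
    function(lon, lat, t) sample_uv(flow, lon, lat, t)
  } else if (is.function(flow)) {
    function(lon, lat, t) {
      s <- flow(lon, lat, t)
      list(u = s$u, v = s$v, ok = rep(TRUE, length(s$u)))
    }
  } else stop("'flow' must be a velocity_series or a function(lon, lat, t)",
              call. = FALSE)
}

#' One deterministic advection step (4th-order Runge-Kutta)
#'
#' Advances positions through the sampled flow over `dt` seconds with
#' classical RK4 in (lon, lat). Sampled velocities (m s^-1) are converted to
#' angular rates with `1/(R cos(lat) pi/180)` zonally and `1/(R pi/180)`
#' meridionally, R = 6,371,000 m. If any RK sub-sample falls outside the
#' flow domain the particle is flagged `exited` and its position left
#' unchanged (the caller decides its fate).
#'
#' @param flow a [velocity_series()] or an analytic velocity function
#'   `function(lon, lat, t)` returning `list(u, v)` in m s^-1.
#' @param lon,lat positions (decimal degrees); vectorised.
#' @param t time as fractional days since the first snapshot (or a
#'   `Date`/`POSIXct` for a `velocity_series`).
#' @param dt step length in seconds.
#' @return list with `lon`, `lat`, and logical `exited`.
#' @export
advect_step <- function(flow, lon, lat, t, dt) {
  sampler <- make_sampler(flow)
  if (inherits(flow, "velocity_series")) t <- as_series_days(flow, t)
  n <- length(lon)
  bad <- rep(FALSE, n)
  rate <- function(lo, la, td) {
    s <- sampler(lo, la, td)
    bad <<- bad | !s$ok
    u <- s$u; v <- s$v
    u[!s$ok] <- 0; v[!s$ok] <- 0
    list(dlon = u / m_per_deg_lon(la), dlat = v / m_per_deg_lat())
  }
  dtd <- dt / 86400
  k1 <- rate(lon, lat, t)
  k2 <- rate(lon + 0.5 * dt * k1$dlon, lat + 0.5 * dt * k1$dlat, t + dtd / 2)
  k3 <- rate(lon + 0.5 * dt * k2$dlon, lat + 0.5 * dt * k2$dlat, t + dtd / 2)
  k4 <- rate(lon + dt * k3$dlon, lat + dt * k3$dlat, t + dtd)
  nlon <- lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  nlat <- lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  nlon[bad] <- lon[bad]; nlat[bad] <- lat[bad]
  list(lon = nlon, lat = nlat, exited = bad)
}

#' One stochastic random-walk (turbulent diffusion) step
#'
#' Independent Gaussian displacements per horizontal axis with standard
#' deviation `sqrt(2 D dt)` metres (so the ensemble mean squared
#' displacement grows as 4 D t in 2-D), converted to degrees at the
#' particle's latitude. Uses the current RNG stream; seed the session (or
#' campaign) for reproducibility.
#'
#' @param lon,lat positions (decimal degrees); vectorised.
#' @param D horizontal diffusion coefficient (m^2 s^-1).
#' @param dt step length in seconds.
#' @return list with displaced `lon` and `lat`.
#' @export
diffusion_step <- function(lon, lat, D, dt) {
  stopifnot(D >= 0)
  if (D == 0) return(list(lon = lon, lat = lat))
  n <- length(lon)
  sd_m <- sqrt(2 * D * dt)
  list(lon = lon + stats::rnorm(n, 0, sd_m) / m_per_deg_lon(lat),
       lat = lat + stats::rnorm(n, 0, sd_m) / m_per_deg_lat())
}

#' Daily biology update
#'
#' Applied once per simulated day at the 00Z boundary, before that day's
#' integration steps: drifting larvae age by one day, are terminated
#' (`expired`) when their age reaches the maximum pelagic duration, and
#' otherwise die with the daily mortality probability. Competency is not a
#' stored state: a larva is competent whenever `age >= onset`.
#'
#' @param state data frame with at least columns `status` (one of
#'   `"drifting"`, `"settled"`, `"dead"`, `"expired"`, `"exited"`) and `age`
#'   (days).
#' @param bio a [bio_params()].
#' @param mortality logical; `FALSE` disables the mortality draw (the
#'   biology-off mode used for oceanographic-range runs).
#' @return the updated state data frame.
#' @export
daily_biology <- function(state, bio, mortality = TRUE) {
  stopifnot(inherits(bio, "bio_params"))
  drift <- state$status == "drifting"
  state$age[drift] <- state$age[drift] + 1
  expire <- drift & state$age >= bio$max_duration
  state$status[expire] <- "expired"
  live <- drift & !expire
  if (mortality && bio$mortality > 0 && any(live)) {
    dies <- stats::runif(sum(live)) < bio$mortality
    state$status[which(live)[dies]] <- "dead"
  }
  state
}

#' Settlement test
#'
#' A drifting larva settles if its competency is active (`age >= onset`) and
#' its position lies within a habitat cell -- including its natal cell
#' (self-seeding is legal). Checked at every integration step; a path that
#' crosses a cell entirely between checks is not settled (the checks are
#' discrete).
#'
#' @param state data frame with columns `status`, `age`, `onset`, `lon`, `lat`.
#' @param cells a [regrid_reefs()] result.
#' @return list with logical `settled` and integer `destination` (cell id,
#'   `NA` for unsettled rows).
#' @export
settle_check <- function(state, cells) {
  eligible <- state$status == "drifting" & state$age >= state$onset
  dest <- rep(NA_integer_, nrow(state))
  if (any(eligible))
    dest[eligible] <- locate_cells(cells, state$lon[eligible], state$lat[eligible])
  list(settled = eligible & !is.na(dest), destination = dest)
}

#' Run a release campaign
#'
#' The full stochastic Lagrangian individual-based simulation: for each
#' release date and release cell, `bio$n_larvae` larvae start at the cell
#' centre at 00Z. Each day, the daily biology update runs at the 00Z
#' boundary (ageing, expiry at the maximum duration, mortality), followed by
#' `24 / dt_hours` integration steps of advect (RK4), diffuse (random walk)
#' and settlement check. A displacement that would land a particle on a land
#' cell is cancelled (the particle holds position for that sub-step);
#' a particle leaving the flow domain is terminated with status `exited`.
#' With `biology = FALSE`, mortality and settlement are disabled and
#' particles are simply advected (with turbulence) to the maximum duration,
#' the mode used to map oceanographic range.
#'
#' @param flow a [velocity_series()] covering every release date plus the
#'   maximum pelagic duration.
#' @param cells habitat cells from [regrid_reefs()]; settlement targets.
#' @param bio a [bio_params()].
#' @param release_dates `Date` vector of release days (00Z).
#' @param release_cells cell ids to release from; default all cells.
#' @param biology logical; `FALSE` runs the advection-only mode.
#' @param record_trajectories logical; if `TRUE`, per-step positions of all
#'   live particles are returned (memory scales with particles x steps; meant
#'   for small runs).
#' @param seed integer seed fixing releases, mortality, onset draws and
#'   turbulence; identical inputs and seed give identical event tables.
#' @return object of class `dispersal_campaign`: list with `events` (the
#'   settlement event table: `source_cell`, `dest_cell`, `release_date`,
#'   `settle_date`, `age`), `releases` (per date/cell release counts),
#'   `counts` (released / settled / dead / expired / exited totals) and
#'   `trajectories` (`NULL` unless recorded: `particle`, `t` in days since
#'   the first flow snapshot, `lon`, `lat`).
#' @export
run_campaign <- function(flow, cells, bio, release_dates,
                         release_cells = NULL, biology = TRUE,
                         record_trajectories = FALSE, seed = 1L) {
  stopifnot(inherits(flow, "velocity_series"), inherits(cells, "reef_cells"),
            inherits(bio, "bio_params"))
  release_dates <- sort(unique(as.Date(release_dates)))
  if (is.null(release_cells)) release_cells <- cells$cell
  if (!all(release_cells %in% cells$cell)) stop("unknown release cell id", call. = FALSE)
  release_cells <- sort(unique(release_cells))

  t_first <- flow$time[1]; t_last <- flow$time[length(flow$time)]
  last_usable <- t_last - bio$max_duration
  if (any(release_dates < t_first) || any(release_dates > last_usable))
    stop(sprintf("forcing too short for requested releases: last usable release date is %s",
                 format(last_usable)), call. = FALSE)

  set.seed(as.integer(seed))
  steps_per_day <- as.integer(24 / bio$dt_hours)
  dt <- bio$dt_hours * 3600
  n_per <- bio$n_larvae
  n_rel_cells <- length(release_cells)
  N <- length(release_dates) * n_rel_cells * n_per

  # particle state (integer status codes: 0 drifting, 1 settled, 2 dead,
  # 3 expired, 4 exited; -1 pending release)
  p_lon <- rep(NA_real_, N); p_lat <- rep(NA_real_, N)
  p_src <- rep(NA_integer_, N); p_rel <- rep(NA_integer_, N)  # rel = day index
  p_onset <- rep(NA_integer_, N)
  p_status <- rep(-1L, N)

  day0 <- release_dates[1]
  rel_day_idx <- as.integer(release_dates - day0)
  end_day_idx <- as.integer(max(release_dates) - day0) + bio$max_duration
  t0_series <- as.numeric(day0 - t_first)  # series days at campaign day 0

  centers_lon <- cells$center_lon[match(release_cells, cells$cell)]
  centers_lat <- cells$center_lat[match(release_cells, cells$cell)]
  block <- 0L

  ev_src <- integer(0); ev_dst <- integer(0); ev_rel <- integer(0)
  ev_set <- integer(0); ev_age <- integer(0)
  traj <- if (record_trajectories) vector("list", 0) else NULL

  active <- integer(0)  # indices of drifting particles
  for (d in 0:end_day_idx) {
    # --- 00Z boundary: ageing, expiry, mortality (pre-existing particles)
    if (length(active)) {
      age <- d - p_rel[active]
      expire <- age >= bio$max_duration
      p_status[active[expire]] <- 3L
      active <- active[!expire]
      if (biology && bio$mortality > 0 && length(active)) {
        dies <- stats::runif(length(active)) < bio$mortality
        p_status[active[dies]] <- 2L
        active <- active[!dies]
      }
    }
    # --- releases scheduled today
    if (d %in% rel_day_idx) {
      idx <- block + seq_len(n_rel_cells * n_per)
      block <- block + n_rel_cells * n_per
      p_lon[idx] <- rep(centers_lon, each = n_per)
      p_lat[idx] <- rep(centers_lat, each = n_per)
      p_src[idx] <- rep(release_cells, each = n_per)
      p_rel[idx] <- d
      p_onset[idx] <- sample(bio$onset_days, length(idx), replace = TRUE)
      p_status[idx] <- 0L
      active <- c(active, idx)
    }
    if (!length(active)) next
    age_today <- d - p_rel[active]

    # --- sub-daily integration
    for (k in seq_len(steps_per_day)) {
      if (!length(active)) break
      tday <- t0_series + d + (k - 1) / steps_per_day
      lo <- p_lon[active]; la <- p_lat[active]

      adv <- advect_step(flow, lo, la, tday, dt)
      # domain exit terminates the particle
      if (any(adv$exited)) {
        p_status[active[adv$exited]] <- 4L
        keep <- !adv$exited
        active <- active[keep]; age_today <- age_today[keep]
        lo <- lo[keep]; la <- la[keep]
        adv <- list(lon = adv$lon[keep], lat = adv$lat[keep])
        if (!length(active)) break
      }
      # cancel displacements that would beach the particle
      beach <- on_land(flow, adv$lon, adv$lat)
      adv$lon[beach] <- lo[beach]; adv$lat[beach] <- la[beach]

      if (bio$diffusivity > 0) {
        dif <- diffusion_step(adv$lon, adv$lat, bio$diffusivity, dt)
        out <- dif$lon < flow$lon[1] | dif$lon > flow$lon[length(flow$lon)] |
               dif$lat < flow$lat[1] | dif$lat > flow$lat[length(flow$lat)]
        if (any(out)) {
          p_status[active[out]] <- 4L
          keep <- !out
          active <- active[keep]; age_today <- age_today[keep]
          adv <- list(lon = adv$lon[keep], lat = adv$lat[keep])
          dif <- list(lon = dif$lon[keep], lat = dif$lat[keep])
          if (!length(active)) break
        }
        beach <- on_land(flow, dif$lon, dif$lat)
        dif$lon[beach] <- adv$lon[beach]; dif$lat[beach] <- adv$lat[beach]
        p_lon[active] <- dif$lon; p_lat[active] <- dif$lat
      } else {
        p_lon[active] <- adv$lon; p_lat[active] <- adv$lat
      }

      # settlement: competent larvae inside any habitat cell settle there
      if (biology) {
        comp <- age_today >= p_onset[active]
        if (any(comp)) {
          ci <- active[comp]
          dest <- locate_cells(cells, p_lon[ci], p_lat[ci])
          hit <- !is.na(dest)
          if (any(hit)) {
            hi <- ci[hit]
            p_status[hi] <- 1L
            ev_src <- c(ev_src, p_src[hi]); ev_dst <- c(ev_dst, dest[hit])
            ev_rel <- c(ev_rel, p_rel[hi]); ev_set <- c(ev_set, rep(d, length(hi)))
            ev_age <- c(ev_age, d - p_rel[hi])
            keep <- rep(TRUE, length(active))
            keep[which(comp)[hit]] <- FALSE
            active <- active[keep]; age_today <- age_today[keep]
          }
        }
      }
      if (record_trajectories && length(active))
        traj[[length(traj) + 1L]] <- data.frame(
          particle = active, t = tday + 1 / steps_per_day,
          lon = p_lon[active], lat = p_lat[active])
    }
  }

  events <- data.frame(
    source_cell = ev_src, dest_cell = ev_dst,
    release_date = day0 + ev_rel, settle_date = day0 + ev_set,
    age = ev_age)
  releases <- expand.grid(cell = release_cells, date = release_dates,
                          KEEP.OUT.ATTRS = FALSE)
  releases$n <- n_per
  counts <- c(released = N,
              settled = sum(p_status == 1L), dead = sum(p_status == 2L),
              expired = sum(p_status == 3L), exited = sum(p_status == 4L),
              drifting = sum(p_status == 0L))
  structure(list(events = events, releases = releases, counts = counts,
                 trajectories = if (record_trajectories && length(traj))
                   do.call(rbind, traj) else NULL),
            class = "dispersal_campaign")
}

#' @export
print.dispersal_campaign <- function(x, ...) {
  cat("dispersal_campaign:\n")
  print(x$counts)
  invisible(x)
}
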