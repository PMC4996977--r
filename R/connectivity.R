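#' Build a regional connectivity matrix from settlement events
#'
#' Sums settlement events over the habitat cells of each ecoregion:
#' `counts[src, dst]` is the number of larvae released in region `src` that
#' settled in region `dst` (the diagonal is within-region self-recruitment).
#' Region order follows the scheme (west-of-barrier block first), so the
#' barrier is a fixed index in the matrix.
#'
#' @param events settlement event table (the `events` element of a
#'   [run_campaign()] result).
#' @param cells habitat cells ([regrid_reefs()]).
#' @param scheme a [region_scheme()] covering every cell region.
#' @param dates optional `Date` vector (e.g. from [annual_subset()] logic):
#'   only events whose release date falls in it are counted.
#' @param releases optional release table (`cell`, `date`, `n`); if given,
#'   per-region release totals (restricted to `dates`) are attached.
#' @return object of class `connectivity_matrix`: list with `counts`
#'   (region x region matrix), `regions`, `scheme`, `releases` (named vector
#'   or `NULL`) and `date_range`.
#' @export
build_matrix <- function(events, cells, scheme, dates = NULL, releases = NULL) {
  stopifnot(inherits(cells, "reef_cells"), inherits(scheme, "region_scheme"))
  if (!all(scheme$region %in% scheme$region)) stop("bad scheme", call. = FALSE)
  bad <- setdiff(unique(c(events$source_cell, events$dest_cell)), cells$cell)
  if (length(bad))
    stop("unknown cell id in event table: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(cells$region %in% scheme$region))
    stop("cell regions missing from the region scheme", call. = FALSE)
  keep <- if (is.null(dates)) rep(TRUE, nrow(events)) else events$release_date %in% dates
  ev <- events[keep, , drop = FALSE]
  regs <- scheme$region
  src <- factor(cells$region[match(ev$source_cell, cells$cell)], levels = regs)
  dst <- factor(cells$region[match(ev$dest_cell, cells$cell)], levels = regs)
  counts <- table(src, dst)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = list(source = regs, dest = regs))
  rel <- NULL
  if (!is.null(releases)) {
    rkeep <- if (is.null(dates)) rep(TRUE, nrow(releases)) else releases$date %in% dates
    rr <- releases[rkeep, , drop = FALSE]
    rreg <- factor(cells$region[match(rr$cell, cells$cell)], levels = regs)
    rel <- tapply(rr$n, rreg, sum, default = 0)
    rel <- stats::setNames(as.numeric(rel), regs)
  }
  structure(list(counts = counts, regions = regs, scheme = scheme,
                 releases = rel,
                 date_range = if (nrow(ev)) range(ev$release_date) else NULL),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d regions, %d settlers, %d directed connections\n",
              length(x$regions), sum(x$counts),
              sum(x$counts > 0) - sum(diag(x$counts) > 0)))
  print(x$counts)
  invisible(x)
}

#' Annual release window (June through May)
#'
#' Keeps events released between 1 June of `start_year` and 31 May of the
#' following year, the annual window centred on the boreal-winter peak of
#' El Nino / La Nina events.
#'
#' @param events settlement event table.
#' @param start_year calendar year whose 1 June opens the window.
#' @return the filtered event table.
#' @export
annual_subset <- function(events, start_year) {
  from <- as.Date(sprintf("%d-06-01", start_year))
  to <- as.Date(sprintf("%d-05-31", start_year + 1))
  events[events$release_date >= from & events$release_date <= to, , drop = FALSE]
}

#' Monthly cross-barrier connection series
#'
#' Counts settlement events that cross the dispersal barrier in the given
#' direction (westward: source on the east side, destination on the west
#' side; eastward: the reverse), binned by month of release and grouped by
#' source region.
#'
#' @param events settlement event table.
#' @param cells habitat cells.
#' @param scheme a [region_scheme()] with barrier sides.
#' @param direction `"westward"` or `"eastward"`.
#' @return data frame (`month`, `source_region`, `count`); zero rows if no
#'   crossing occurred.
#' @export
cross_barrier_series <- function(events, cells, scheme,
                                 direction = c("westward", "eastward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(scheme, "region_scheme"))
  side <- stats::setNames(scheme$side, scheme$region)
  src_reg <- cells$region[match(events$source_cell, cells$cell)]
  dst_reg <- cells$region[match(events$dest_cell, cells$cell)]
  cross <- if (direction == "westward")
    side[src_reg] == "east" & side[dst_reg] == "west"
  else
    side[src_reg] == "west" & side[dst_reg] == "east"
  cross[is.na(cross)] <- FALSE
  if (!any(cross))
    return(data.frame(month = as.Date(character()), source_region = character(),
                      count = integer(), stringsAsFactors = FALSE))
  ev <- events[cross, , drop = FALSE]
  agg <- stats::aggregate(list(count = rep(1L, nrow(ev))),
                          by = list(month = month_floor(ev$release_date),
                                    source_region = src_reg[cross]),
                          FUN = sum)
  agg[order(agg$month, agg$source_region), , drop = FALSE]
}

# directed off-diagonal region pairs with at least one settler
connection_set <- function(events, cells, scheme) {
  src <- cells$region[match(events$source_cell, cells$cell)]
  dst <- cells$region[match(events$dest_cell, cells$cell)]
  inter <- src != dst
  unique(paste(src[inter], dst[inter], sep = "->"))
}

#' Larval-number saturation analysis
#'
#' Given event tables from runs identical except for the number of larvae
#' per release (possibly formed by summing the output of smaller runs),
#' counts the inter-regional connections (directed off-diagonal region pairs
#' with any settler) obtained at each larval number, and the specific
#' connections gained and lost between consecutive runs. A levelling-off of
#' the totals indicates the system is saturated with respect to connection
#' detection at that scale.
#'
#' @param event_tables named list of event tables; names are the per-release
#'   larval numbers N (coercible to numeric), in increasing order.
#' @param cells habitat cells shared by all runs.
#' @param scheme the shared [region_scheme()].
#' @return list of class `saturation_analysis`: `totals` (data frame `n`,
#'   `connections`) and `differences` (per consecutive pair: character
#'   vectors `gained` and `lost` of `"SRC->DST"` connection labels).
#' @export
saturation_analysis <- function(event_tables, cells, scheme) {
  stopifnot(is.list(event_tables), length(event_tables) >= 1)
  n_vals <- as.numeric(names(event_tables))
  if (any(is.na(n_vals))) stop("event_tables must be named by larval number",
                               call. = FALSE)
  for (ev in event_tables)
    if (!all(cells$region[match(ev$source_cell, cells$cell)] %in% scheme$region))
      stop("mismatched region scheme across runs", call. = FALSE)
  sets <- lapply(event_tables, connection_set, cells = cells, scheme = scheme)
  totals <- data.frame(n = n_vals, connections = vapply(sets, length, 0L),
                       row.names = NULL)
  differences <- list()
  if (length(sets) > 1) {
    for (i in seq_len(length(sets) - 1)) {
      differences[[paste(n_vals[i], n_vals[i + 1], sep = "->")]] <- list(
        gained = sort(setdiff(sets[[i + 1]], sets[[i]])),
        lost = sort(setdiff(sets[[i]], sets[[i + 1]])))
    }
  }
  structure(list(totals = totals, differences = differences),
            class = "saturation_analysis")
}

#' Trajectory density grid
#'
#' Counts, on a graticule of the given resolution, the number of distinct
#' particles whose recorded track enters each cell; re-entries of the same
#' particle are not double-counted. This is the "oceanographic range"
#' visualisation of advection-only runs.
#'
#' @param trajectories data frame with columns `particle`, `lon`, `lat`
#'   (the `trajectories` element of a [run_campaign()] result).
#' @param resolution grid resolution in degrees (default 1/6).
#' @return data frame of class `trajectory_density` with columns `ix`, `iy`,
#'   `center_lon`, `center_lat`, `count`.
#' @export
density_grid <- function(trajectories, resolution = 1 / 6) {
  stopifnot(is.data.frame(trajectories),
            all(c("particle", "lon", "lat") %in% names(trajectories)))
  ix <- grat_index(trajectories$lon, resolution)
  iy <- grat_index(trajectories$lat, resolution)
  visits <- unique(data.frame(particle = trajectories$particle, ix = ix, iy = iy))
  agg <- stats::aggregate(list(count = rep(1L, nrow(visits))),
                          by = list(ix = visits$ix, iy = visits$iy), FUN = sum)
  agg$center_lon <- (agg$ix + 0.5) * resolution
  agg$center_lat <- (agg$iy + 0.5) * resolution
  agg <- agg[order(agg$ix, agg$iy), c("ix", "iy", "center_lon", "center_lat", "count")]
  structure(agg, resolution = resolution,
            class = c("trajectory_density", "data.frame"))
}

#' Write a connectivity matrix to CSV with a JSON metadata sidecar
#'
#' The matrix is written with source regions as rows; metadata (region
#' order, sides, per-region release totals, release date range) goes to
#' `<path>.json`.
#'
#' @param x a [build_matrix()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(x, path) {
  stopifnot(inherits(x, "connectivity_matrix"))
  utils::write.csv(as.data.frame(x$counts), path, row.names = TRUE)
  meta <- list(regions = x$regions, side = as.list(stats::setNames(x$scheme$side,
                                                                   x$scheme$region)),
               releases = if (is.null(x$releases)) NULL else as.list(x$releases),
               date_range = if (is.null(x$date_range)) NULL else
                 format(x$date_range))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
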