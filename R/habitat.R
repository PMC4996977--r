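#' Ecoregion scheme
#'
#' Ordered set of region codes with their side of the dispersal barrier.
#' Region order is preserved as given (by convention west-of-barrier regions
#' first), so the barrier sits at a fixed index in connectivity matrices.
#'
#' @param region character vector of unique region codes.
#' @param side character vector, one of `"west"`/`"east"` per region.
#' @return data frame of class `region_scheme`.
#' @export
region_scheme <- function(region, side) {
  region <- as.character(region); side <- as.character(side)
  if (length(region) != length(side)) stop("region/side length mismatch", call. = FALSE)
  if (anyDuplicated(region)) stop("region codes must be unique", call. = FALSE)
  if (!all(side %in% c("west", "east")))
    stop("side must be 'west' or 'east'", call. = FALSE)
  structure(data.frame(region = region, side = side, stringsAsFactors = FALSE),
            class = c("region_scheme", "data.frame"))
}

#' The 20 tropical Pacific coral ecoregions
#'
#' Ready-made [region_scheme()] for the multispecies coral ecoregions used
#' in basin-scale Pacific connectivity work: ten central Pacific regions
#' (west of the East Pacific Barrier) and ten eastern tropical Pacific
#' regions (east of it).
#'
#' @return a [region_scheme()] with 20 regions, central Pacific block first.
#' @export
pacific_ecoregions <- function() {
  central <- c("EAS", "EHW", "JOH", "MAR", "NHW", "NLI", "PIT", "SLI", "SOC", "TUA")
  eastern <- c("CAM", "CLI", "COC", "COL", "CRP", "GAL", "GOC", "MAL", "MEX", "REV")
  region_scheme(c(central, eastern),
                c(rep("west", length(central)), rep("east", length(eastern))))
}

#' Re-grid reef points onto a habitat-cell graticule
#'
#' Collapses reef point data onto the cells of a global graticule (default
#' 1/6 degree, about 18.5 km at the equator): one habitat cell per occupied
#' graticule square. Cell intervals are half-open and lower-inclusive; the
#' cell region is the majority region of the contained points, ties broken
#' toward the lexicographically smallest code (reported via `message()`).
#' Cell centres are the graticule square centroids and serve as larval
#' release points.
#'
#' @param points data frame with columns `lon`, `lat`, `region`.
#' @param resolution cell size in degrees; must divide 1 degree evenly.
#' @return data frame of class `reef_cells` with columns `cell`, `ix`, `iy`
#'   (graticule indices), `lon_min`, `lon_max`, `lat_min`, `lat_max`,
#'   `center_lon`, `center_lat`, `region`; the resolution is kept as an
#'   attribute.
#' @export
regrid_reefs <- function(points, resolution = 1 / 6) {
  if (!is.data.frame(points) || !nrow(points))
    stop("empty reef point input", call. = FALSE)
  if (abs(1 / resolution - round(1 / resolution)) > 1e-9)
    stop("resolution must divide 1 degree evenly", call. = FALSE)
  ix <- grat_index(points$lon, resolution)
  iy <- grat_index(points$lat, resolution)
  key <- paste(ix, iy)
  groups <- split(as.character(points$region), key)
  pick_region <- function(regions) {
    tab <- sort(table(regions), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    if (length(winners) > 1)
      message("mixed-region cell: tie broken toward '", min(winners), "'")
    min(winners)
  }
  region <- vapply(groups, pick_region, "")
  uk <- names(groups)
  uxy <- do.call(rbind, strsplit(uk, " "))
  ix <- as.integer(uxy[, 1]); iy <- as.integer(uxy[, 2])
  ord <- order(ix, iy)
  ix <- ix[ord]; iy <- iy[ord]; region <- region[ord]
  cells <- data.frame(
    cell = seq_along(ix), ix = ix, iy = iy,
    lon_min = ix * resolution, lon_max = (ix + 1) * resolution,
    lat_min = iy * resolution, lat_max = (iy + 1) * resolution,
    center_lon = (ix + 0.5) * resolution, center_lat = (iy + 0.5) * resolution,
    region = region, stringsAsFactors = FALSE, row.names = NULL)
  structure(cells, resolution = resolution, class = c("reef_cells", "data.frame"))
}

#' Locate points in the habitat-cell set
#'
#' Exact spatial-hash lookup on graticule indices (not nearest-cell): a point
#' belongs to the unique cell whose half-open, lower-inclusive bounds contain
#' it, or to no cell. This is the settlement test geometry: a larva anywhere
#' within the cell square counts as within reach of the reef.
#'
#' @param cells a [regrid_reefs()] result.
#' @param lon,lat point coordinates (vectorised).
#' @return integer vector of cell ids, `NA` where the point falls in no cell.
#' @export
locate_cells <- function(cells, lon, lat) {
  stopifnot(inherits(cells, "reef_cells"))
  res <- attr(cells, "resolution")
  key <- paste(grat_index(lon, res), grat_index(lat, res))
  cells$cell[match(key, paste(cells$ix, cells$iy))]
}

#' @rdname seascape_io
#' @param cells a [regrid_reefs()] result (for `write_cells`).
#' @param scheme optional [region_scheme()]; if supplied, a `side` column is
#'   included.
#' @export
write_cells <- function(cells, path, scheme = NULL) {
  df <- as.data.frame(cells)
  if (!is.null(scheme)) df$side <- scheme$side[match(df$region, scheme$region)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname seascape_io
#' @param resolution cell size in degrees (for `read_cells`).
#' @export
read_cells <- function(path, resolution = 1 / 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell", "ix", "iy", "lon_min", "lon_max", "lat_min", "lat_max",
            "center_lon", "center_lat", "region")
  for (nm in need)
    if (is.null(df[[nm]])) stop(sprintf("cell file is missing column '%s'", nm),
                                call. = FALSE)
  structure(df[, need], resolution = resolution,
            class = c("reef_cells", "data.frame"))
}
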