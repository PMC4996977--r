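#' Collapse a connectivity matrix to a directionless half-matrix
#'
#' Genetic differentiation integrates over exchange in both directions, so
#' the directed region-by-region settler counts are folded along the
#' diagonal: `h_ij = c_ij + c_ji` for `i < j`. The diagonal (within-region
#' self-seeding), absent from pairwise genetic data, is dropped.
#'
#' @param x a [build_matrix()] result or a square counts matrix.
#' @return a [stats::dist] object of exchanged-particle counts.
#' @export
to_half_matrix <- function(x) {
  m <- if (inherits(x, "connectivity_matrix")) x$counts else x
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square matrix", call. = FALSE)
  stats::as.dist(m + t(m))
}

#' Pairwise dispersal probability
#'
#' Normalises exchanged-particle counts by the larvae released from the two
#' regions of each pair, `p_ij = h_ij / (releases_i + releases_j)`, turning
#' counts into a (relative) probability of successful dispersal.
#'
#' @param half a half-matrix of exchanged counts ([to_half_matrix()]).
#' @param releases named numeric vector of larvae released per region
#'   (e.g. the `releases` element of a [build_matrix()] result).
#' @return a [stats::dist] object of probabilities.
#' @export
dispersal_probability <- function(half, releases) {
  half <- as_half_matrix(half, "half")
  labs <- attr(half, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(attr(half, "Size")))
  rel <- releases[labs]
  if (any(is.na(rel)) || any(rel <= 0))
    stop("positive release totals required for every region", call. = FALSE)
  m <- as.matrix(half) / outer(rel, rel, "+")
  stats::as.dist(m)
}

#' Transform dispersal probabilities into a distance half-matrix
#'
#' Converts dispersal probabilities into a dissimilarity directly comparable
#' with pairwise genetic differentiation (F'ST), where 0 means maximal
#' connectivity. In `linear` mode the probabilities are inverted by the
#' order-reversing rescale `(p_max - p)` mapped onto [0, 1] (not the
#' reciprocal, which explodes on rare connections and is undefined at zero).
#' In `log10` mode the distance is an increasing rescale of
#' `-log10(max(p, eps))` onto [0, 1], the transformation that highlights
#' rare long-distance connections; `eps` (half the smallest nonzero
#' probability unless supplied) floors only zero probabilities.
#'
#' @param p dispersal probability half-matrix ([dispersal_probability()]),
#'   or a symmetric matrix.
#' @param mode `"linear"` or `"log10"`.
#' @param eps probability floor for `log10` mode; default half the smallest
#'   nonzero probability.
#' @return a [stats::dist] object of distances in [0, 1].
#' @export
to_dispersal_distance <- function(p, mode = c("linear", "log10"), eps = NULL) {
  mode <- match.arg(mode)
  d <- as_half_matrix(p, "p")
  v <- as.vector(d)
  if (any(v < 0)) stop("negative probabilities", call. = FALSE)
  if (all(v == 0)) stop("all-zero half matrix carries no information", call. = FALSE)
  if (mode == "linear") {
    s <- max(v) - v
  } else {
    if (is.null(eps)) {
      nz <- v[v > 0]
      eps <- min(nz) / 2
    }
    s <- -log10(pmax(v, eps))
  }
  rng <- range(s)
  out <- d
  out[] <- if (diff(rng) == 0) rep(0, length(s)) else (s - rng[1]) / diff(rng)
  out
}

#' Great-circle distance half-matrix
#'
#' Haversine great-circle distances (mean Earth radius 6,371 km) between
#' site groups; at basin scale this, rather than the chord, is the intended
#' meaning of geographic distance between reefs.
#'
#' @param coords data frame with columns `lon`, `lat` and optionally `label`
#'   (used as matrix labels).
#' @return a [stats::dist] object of distances in km.
#' @export
geo_distance <- function(coords) {
  stopifnot(is.data.frame(coords), all(c("lon", "lat") %in% names(coords)))
  n <- nrow(coords)
  m <- matrix(0, n, n)
  xy <- as.matrix(coords[, c("lon", "lat")])
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    m[j, i] <- geosphere::distHaversine(xy[i, , drop = FALSE], xy[j, , drop = FALSE],
                                        r = EARTH_RADIUS_M) / 1000
  }
  m <- m + t(m)
  if (!is.null(coords$label)) dimnames(m) <- list(coords$label, coords$label)
  stats::as.dist(m)
}

#' Mantel test between two distance half-matrices
#'
#' Pearson correlation of the vectorised upper triangles, with significance
#' from random row/column co-permutations of the second matrix. The p-value
#' includes the observed statistic, `p = (1 + #{perm r >= r_obs}) / (1 +
#' n_perm)`, one-sided for positive association. Variance explained is
#' reported as `100 r^2` (per cent).
#'
#' @param d1,d2 [stats::dist] objects (or symmetric matrices) with matching
#'   size and, if labelled, matching labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed for the permutations.
#' @return list of class `mantel_result`: `r`, `r2_pct`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  d1 <- as_half_matrix(d1, "d1"); d2 <- as_half_matrix(d2, "d2")
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("matrices differ in size", call. = FALSE)
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("matrix labels do not match", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  v1 <- as.vector(d1); v2 <- as.vector(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant matrix: correlation undefined", call. = FALSE)
  r_obs <- stats::cor(v1, v2)
  n <- attr(d2, "Size")
  m2 <- as.matrix(d2)
  ut <- lower.tri(m2)  # same pair ordering as as.vector(dist)
  # centre/scale v1 once; correlation with each permuted v2 by dot product
  z1 <- (v1 - mean(v1)) / stats::sd(v1)
  set.seed(as.integer(seed))
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    vp <- m2[p, p][ut]
    sum(z1 * (vp - mean(vp))) / ((length(vp) - 1) * stats::sd(vp))
  }, 0)
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, r2_pct = 100 * r_obs^2, p = p_val,
                 n_perm = as.integer(n_perm)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (%.1f%% of variance), p = %.4g (%d permutations)\n",
              x$r, x$r2_pct, x$p, x$n_perm))
  invisible(x)
}

#' Read / write a pairwise F'ST half-matrix as CSV
#'
#' The CSV carries a full symmetric matrix with labels in the header and
#' first column; only the lower triangle is used on reading.
#'
#' @param fst a [stats::dist] object of F'ST values.
#' @param path file path.
#' @return `read_fst_matrix()` returns a [stats::dist]; the writer returns
#'   `path` invisibly.
#' @export
write_fst_matrix <- function(fst, path) {
  m <- as.matrix(fst)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_fst_matrix
#' @export
read_fst_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("F'ST file is not a square matrix", call. = FALSE)
  v <- m[lower.tri(m)]
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("F'ST values outside [0, 1]", call. = FALSE)
  stats::as.dist(m)
}
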