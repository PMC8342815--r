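#' 3D intensity volume
#'
#' Container for a 3D grayscale image stack. Intensities are non-negative
#' integers bounded by the bit depth (0-255 for 8-bit, 0-4095 for 12-bit
#' data); the array layout is `dim = c(nz, ny, nx)` so `data[z, y, x]` is the
#' voxel at 1-based coordinate `(z, y, x)`.
#'
#' @param data 3D numeric array of non-negative integer intensities.
#' @param bit_depth 8 or 12. If `NULL`, inferred from the data range
#'   (values above 255 imply 12-bit).
#' @param spacing physical voxel size per axis `(z, y, x)` in micrometers;
#'   used only when reporting lengths in physical units.
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, bit_depth = NULL, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "integer"
  if (anyNA(data) || min(data) < 0L)
    stop("intensities must be non-negative integers")
  if (is.null(bit_depth))
    bit_depth <- if (max(data) > 255L) 12L else 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L))
    stop("`bit_depth` must be 8 or 12")
  if (max(data) > 2L^bit_depth - 1L)
    stop("intensities exceed the stated bit depth")
  structure(
    list(data = data, bit_depth = bit_depth, spacing = as.numeric(spacing)),
    class = "volume_image"
  )
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d (z,y,x), %d-bit, max intensity %d\n",
              d[1], d[2], d[3], x$bit_depth, max(x$data)))
  invisible(x)
}

#' Set of voxels within a volume
#'
#' A voxel set stores member voxel coordinates of one originating volume,
#' together with the neighborhood definition (6- or 26-connectivity) used by
#' all connectivity-dependent operations on it.
#'
#' @param coords integer matrix with one `(z, y, x)` row per voxel, or an
#'   integer vector of linear indices if `index = TRUE`.
#' @param dims dimensions `(nz, ny, nx)` of the originating volume.
#' @param connectivity 6 or 26 (default 26: thin fibers break under
#'   6-connectivity).
#' @param index interpret `coords` as linear indices.
#' @return A `voxel_set` object.
#' @export
voxel_set <- function(coords, dims, connectivity = 26L, index = FALSE) {
  dims <- as.integer(dims)
  idx <- if (index) as.integer(coords) else vx_index(coords, dims)
  idx <- sort(unique(idx))
  if (length(idx) && (idx[1L] < 1L || idx[length(idx)] > prod(dims)))
    stop("voxel coordinates outside the volume")
  if (!connectivity %in% c(6L, 26L))
    stop("`connectivity` must be 6 or 26")
  structure(
    list(index = idx, dims = dims, connectivity = as.integer(connectivity)),
    class = "voxel_set"
  )
}

#' @export
length.voxel_set <- function(x) length(x$index)

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> %d voxels in %s volume, %d-connectivity\n",
              length(x$index), paste(x$dims, collapse = "x"),
              x$connectivity))
  invisible(x)
}

#' Coordinates of a voxel set
#'
#' @param x a `voxel_set`.
#' @return Integer matrix with one `(z, y, x)` row per member voxel.
#' @export
voxel_coords <- function(x) vx_coords(x$index, x$dims)

#' Global intensity threshold
#'
#' Returns the set of voxels whose intensity is at least `t` (and positive, so
#' `t = 0` and `t = 1` both keep exactly the nonzero voxels). The result is
#' monotone in `t`: raising the threshold never adds a voxel.
#'
#' @param volume a [volume_image()].
#' @param t intensity threshold, `0 <= t <= 2^bit_depth - 1`.
#' @param connectivity connectivity carried by the returned set.
#' @return A [voxel_set()] of the surviving voxels.
#' @export
threshold_volume <- function(volume, t, connectivity = 26L) {
  stopifnot(inherits(volume, "volume_image"))
  if (t < 0 || t > 2^volume$bit_depth - 1)
    stop(sprintf("threshold %s outside the %d-bit intensity range",
                 format(t), volume$bit_depth))
  idx <- which(volume$data >= max(t, 1L))
  voxel_set(idx, dim(volume$data), connectivity = connectivity, index = TRUE)
}

#' Connected components of a voxel set
#'
#' Partitions a voxel set into maximal connected subsets under its
#' connectivity. Components are ordered by size (descending), ties broken by
#' the smallest member coordinate in `(z, y, x)` lexicographic order, so the
#' partition is deterministic.
#'
#' @param voxels a [voxel_set()].
#' @return List of `voxel_set` components (empty list for an empty set).
#' @export
connected_components <- function(voxels) {
  stopifnot(inherits(voxels, "voxel_set"))
  if (length(voxels) == 0L) return(list())
  lab <- cpp_label_components(voxels$dims, voxels$index - 1L,
                              voxels$connectivity)
  groups <- split(voxels$index, lab)
  sizes <- lengths(groups)
  # tie-break equal-size components by their (z, y, x)-lexicographically
  # smallest member
  cc <- vx_coords(voxels$index, voxels$dims)
  d <- voxels$dims
  zkey <- (cc[, 1L] - 1) * as.double(d[2L]) * d[3L] +
    (cc[, 2L] - 1) * as.double(d[3L]) + cc[, 3L]
  minkey <- vapply(split(zkey, lab), min, numeric(1))
  ord <- order(-sizes, minkey)
  lapply(groups[ord], function(ix)
    voxel_set(ix, voxels$dims, voxels$connectivity, index = TRUE))
}

#' Geodesic source field
#'
#' Breadth-first path distance (in voxels) from a seed plus 1: the seed has
#' value 1, each of its neighbors 2, and so on. Voxels unreachable from the
#' seed carry no value. This field is the scaffold on which the codelet
#' tracer advances.
#'
#' @param voxels a [voxel_set()].
#' @param seed `(z, y, x)` coordinate of the starting voxel (typically the
#'   soma); must be a member of `voxels`.
#' @return A `source_field`: list with `index`, `value` (parallel vectors,
#'   reachable voxels only), `seed`, and `dims`.
#' @export
compute_source_field <- function(voxels, seed) {
  stopifnot(inherits(voxels, "voxel_set"))
  seed_idx <- vx_index(matrix(seed, ncol = 3L), voxels$dims)
  if (!seed_idx %in% voxels$index)
    stop("`seed` is not a member of the voxel set")
  val <- cpp_source_field(voxels$dims, voxels$index - 1L, seed_idx - 1L,
                          voxels$connectivity)
  keep <- val > 0L
  structure(
    list(index = voxels$index[keep], value = val[keep],
         seed = as.integer(seed), dims = voxels$dims,
         connectivity = voxels$connectivity),
    class = "source_field"
  )
}

#' Automatic soma detection
#'
#' Finds candidate soma positions as the largest ellipsoid-like bright
#' clusters: the volume is thresholded at a high intensity percentile,
#' connected components above a minimum volume are scored by
#' `volume x sphericity` (sphericity = ratio of the smallest to the largest
#' principal axis length of the component's inertia ellipsoid), and the
#' component centroids are returned ranked by score. A user-supplied seed
#' always overrides this heuristic downstream.
#'
#' @param volume a [volume_image()].
#' @param percentile intensity percentile defining "bright" (default 0.99,
#'   over nonzero voxels).
#' @param min_volume minimum component size in voxels (default 250).
#' @param connectivity neighborhood used for the components.
#' @return Integer matrix of candidate `(z, y, x)` centroids, best first;
#'   zero rows when no component qualifies.
#' @export
detect_soma <- function(volume, percentile = 0.99, min_volume = 250L,
                        connectivity = 26L) {
  stopifnot(inherits(volume, "volume_image"))
  nz <- volume$data[volume$data > 0L]
  empty <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("z", "y", "x")))
  if (length(nz) == 0L) return(empty)
  thr <- as.numeric(quantile(nz, percentile, type = 1))
  comps <- connected_components(
    threshold_volume(volume, thr, connectivity = connectivity))
  comps <- Filter(function(cc) length(cc) >= min_volume, comps)
  if (length(comps) == 0L) return(empty)
  score_one <- function(cc) {
    xyz <- voxel_coords(cc)
    cv <- stats::cov(xyz)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    sph <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
    c(score = length(cc) * sph, blob_core(cc))
  }
  sc <- t(vapply(comps, score_one, numeric(4)))
  ord <- order(-sc[, "score"])
  out <- matrix(as.integer(sc[ord, 2:4, drop = FALSE]), ncol = 3L)
  colnames(out) <- c("z", "y", "x")
  out
}

# Center of the densest ball-like core of a component: the soma is a solid
# blob while neurites are thin tubes, so the voxels whose radius-3
# neighborhood is fullest mark the soma body; their centroid is the
# candidate position.
blob_core <- function(cc, radius = 3) {
  xyz <- voxel_coords(cc)
  mask <- array(FALSE, cc$dims)
  mask[cc$index] <- TRUE
  offs <- as.matrix(expand.grid(z = -radius:radius, y = -radius:radius,
                                x = -radius:radius))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  dens <- integer(nrow(xyz))
  for (k in seq_len(nrow(offs))) {
    sh <- cbind(xyz[, 1] + offs[k, 1], xyz[, 2] + offs[k, 2],
                xyz[, 3] + offs[k, 3])
    ok <- sh[, 1] >= 1 & sh[, 1] <= cc$dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= cc$dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= cc$dims[3]
    dens[ok] <- dens[ok] + mask[vx_index(sh[ok, , drop = FALSE], cc$dims)]
  }
  core <- dens >= 0.95 * max(dens)
  round(colMeans(xyz[core, , drop = FALSE]))
}

# Nearest member of a voxel set within `radius` (Euclidean) of `coord`;
# NULL when none. Ties broken by distance, then (z,y,x) order.
nearest_member <- function(voxels, coord, radius = 3) {
  dims <- voxels$dims
  r <- ceiling(radius)
  zr <- max(1L, coord[1] - r):min(dims[1], coord[1] + r)
  yr <- max(1L, coord[2] - r):min(dims[2], coord[2] + r)
  xr <- max(1L, coord[3] - r):min(dims[3], coord[3] + r)
  cand <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
  d2 <- (cand[, 1] - coord[1])^2 + (cand[, 2] - coord[2])^2 +
    (cand[, 3] - coord[3])^2
  keep <- d2 <= radius^2
  cand <- cand[keep, , drop = FALSE]
  d2 <- d2[keep]
  idx <- vx_index(cand, dims)
  inset <- idx %in% voxels$index
  if (!any(inset)) return(NULL)
  cand <- cand[inset, , drop = FALSE]
  d2 <- d2[inset]
  ord <- order(d2, cand[, 1], cand[, 2], cand[, 3])
  as.integer(cand[ord[1L], ])
}
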