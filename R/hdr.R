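#' Build the HDR thresholding mask
#'
#' The high-dynamic-range mask is the set of voxels whose branch robustness
#' score reaches the cutoff `m`; voxels with a BRS below `m` are treated as
#' noise and discarded. Because the BRS combines structural importance with
#' the number of thresholds a voxel survives, the mask acts like a
#' position-dependent intensity threshold. Smaller `m` keeps more fine
#' detail; masks are nested in `m`. The published default is `m = 40`
#' (tuned down, e.g. to 10, when fine distal structure matters); note the
#' appropriate scale of `m` tracks the size of the traced trees, since BS
#' magnitudes grow with branch counts and depths.
#'
#' @param brs a `brs_field` from [accumulate_brs()].
#' @param m BRS cutoff (>= 0). Voxels with `BRS >= max(m, 1)` are kept, so
#'   `m = 0` yields exactly the BRS support.
#' @param strict keep `BRS > m` instead of `BRS >= m` (the boundary
#'   convention is otherwise "keep at `m` exactly").
#' @return An `hdr_mask` (a [voxel_set()] carrying `m`).
#' @export
build_hdr_mask <- function(brs, m = 40L, strict = FALSE) {
  stopifnot(inherits(brs, "brs_field"), m >= 0)
  idx <- if (strict) which(brs$values > max(m, 0L))
         else which(brs$values >= max(m, 1L))
  if (length(idx) == 0L) {
    h <- table(brs$values[brs$values > 0L])
    stop(sprintf(
      "HDR mask is empty at m = %s; BRS histogram (value:count): %s",
      format(m), paste(names(h), h, sep = ":", collapse = " ")))
  }
  vs <- voxel_set(idx, dim(brs$values), connectivity = brs$connectivity,
                  index = TRUE)
  vs$m <- m
  class(vs) <- c("hdr_mask", class(vs))
  vs
}

#' Segment the target neuron
#'
#' Intersects the HDR mask with the nonzero voxels of the raw image and
#' keeps the connected component containing the soma, carrying the original
#' raw intensities. The result is itself a valid tracing substrate, so the
#' tracer can be run on it again for the final reconstruction.
#'
#' @param volume the raw [volume_image()].
#' @param mask an `hdr_mask` (or any [voxel_set()]).
#' @param soma `(z, y, x)` soma coordinate; if it is not in the mask the
#'   nearest mask voxel within 3 voxels is substituted.
#' @param all_components keep every mask component instead of only the
#'   soma's (off by default: the goal is the single target neuron).
#' @return A `segmented_neuron`: list with `voxels` (a [voxel_set()]),
#'   `intensity` (raw values, parallel to the voxel indices), `soma`, and
#'   provenance (`m` when the mask carries one).
#' @export
segment_neuron <- function(volume, mask, soma, all_components = FALSE) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "voxel_set"))
  keep <- mask$index[volume$data[mask$index] > 0L]
  vs <- voxel_set(keep, dim(volume$data), connectivity = mask$connectivity,
                  index = TRUE)
  soma <- as.integer(soma)
  seed <- soma_seed_for(vs, soma)
  if (is.null(seed))
    stop("soma is not within 3 voxels of the masked image")
  if (!all_components) {
    comps <- connected_components(vs)
    seed_idx <- vx_index(matrix(seed, ncol = 3L), vs$dims)
    hit <- which(vapply(comps, function(cc) seed_idx %in% cc$index,
                        logical(1)))
    vs <- comps[[hit[1L]]]
  }
  structure(
    list(voxels = vs, intensity = volume$data[vs$index], soma = seed,
         m = mask$m, bit_depth = volume$bit_depth),
    class = "segmented_neuron"
  )
}

#' @export
print.segmented_neuron <- function(x, ...) {
  cat(sprintf("<segmented_neuron> %d voxels, soma (%s)%s\n",
              length(x$voxels), paste(x$soma, collapse = ","),
              if (!is.null(x$m)) sprintf(", m = %s", format(x$m)) else ""))
  invisible(x)
}

#' Segmented neuron as a volume
#'
#' @param x a `segmented_neuron`.
#' @return A [volume_image()] with the original intensities inside the
#'   segmentation and zero elsewhere.
#' @export
segmented_volume <- function(x) {
  stopifnot(inherits(x, "segmented_neuron"))
  a <- array(0L, x$voxels$dims)
  a[x$voxels$index] <- x$intensity
  volume_image(a, bit_depth = x$bit_depth)
}

#' Write a segmented neuron as a voxel list
#'
#' Plain-text interchange: one `x y z intensity` line per voxel (0-based
#' coordinates).
#'
#' @param x a `segmented_neuron`.
#' @param path destination file.
#' @export
write_voxel_list <- function(x, path) {
  stopifnot(inherits(x, "segmented_neuron"))
  cc <- voxel_coords(x$voxels)
  writeLines(sprintf("%d %d %d %d", cc[, "x"] - 1L, cc[, "y"] - 1L,
                     cc[, "z"] - 1L, x$intensity), path)
  invisible(path)
}
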