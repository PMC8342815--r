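#' Specification of a synthetic neuron phantom
#'
#' Parameters of the deterministic phantom generator. The generator emulates
#' the image statistics the segmentation method assumes: a tree-like tubular
#' fluorescent structure whose intensity decays toward distal branches,
#' optional localized low-intensity "weak points" on fibers, background
#' noise that varies with imaging depth (z-slabs), sparse salt voxels, and
#' optionally several neurons in one scene.
#'
#' @param seed integer RNG seed; the seed fully determines the output.
#' @param shape volume dimensions `(nz, ny, nx)`.
#' @param bit_depth 8 or 12.
#' @param soma_radius soma ball radius in voxels.
#' @param depth number of branching generations below the primary neurite.
#' @param child_counts possible child counts at a junction.
#' @param child_prob sampling probabilities for `child_counts`.
#' @param segment_length `(min, max)` fiber segment length in voxels.
#' @param tube_radius fiber tube radius in voxels.
#' @param proximal_intensity intensity of the soma and primary neurite.
#' @param decay per-generation intensity decay factor.
#' @param n_weak_points number of weak points placed on fibers (at
#'   generation 2 or deeper).
#' @param weak_intensity intensity of the weak-point bridge voxels.
#' @param slab_height z-slab thickness of the background-noise model.
#' @param noise_mean per-slab background mean (recycled across slabs).
#' @param noise_sd background Gaussian standard deviation.
#' @param salt_density fraction of background voxels receiving a bright
#'   salt value.
#' @param salt_intensity `(min, max)` salt intensity range.
#' @param n_neurons number of neurons in the scene.
#' @param tangle_overlap target adjacency fraction between neurons in a
#'   tangled scene (see [generate_tangled_scene()]).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         shape = c(128L, 128L, 128L),
                         bit_depth = 8L,
                         soma_radius = 5,
                         depth = 5L,
                         child_counts = 2L,
                         child_prob = 1,
                         segment_length = c(30, 55),
                         tube_radius = 1.5,
                         proximal_intensity = 200L,
                         decay = 0.9,
                         n_weak_points = 0L,
                         weak_intensity = 3L,
                         slab_height = 32L,
                         noise_mean = c(0.2, 0.6, 1, 0.6),
                         noise_sd = 0.8,
                         salt_density = 5e-5,
                         salt_intensity = c(10L, 40L),
                         n_neurons = 1L,
                         tangle_overlap = 0) {
  spec <- as.list(environment())
  stopifnot(bit_depth %in% c(8L, 12L),
            proximal_intensity <= 2^bit_depth - 1,
            weak_intensity >= 1,
            length(segment_length) == 2L,
            n_neurons >= 1L)
  structure(spec, class = "phantom_spec")
}

# unit vector
unitv <- function(v) v / sqrt(sum(v^2))

# random unit vector orthogonal to d
rand_ortho <- function(d) {
  repeat {
    w <- rnorm(3)
    w <- w - sum(w * d) * d
    n <- sqrt(sum(w^2))
    if (n > 1e-6) return(w / n)
  }
}

# Grow a random tree skeleton from `soma`. Returns a list of segments
# (id, parent, gen, points), where points are (z,y,x) positions stepped at
# ~0.75 voxels. Segments avoid existing fibers and stay inside a margin.
grow_skeleton <- function(spec, soma, dims) {
  step <- 0.75
  margin <- spec$tube_radius + 2
  center <- dims / 2
  segments <- list()
  occupied <- matrix(numeric(0), ncol = 3L)  # all accepted points
  grow_one <- function(start, dir, gen, parent) {
    len <- runif(1, spec$segment_length[1], spec$segment_length[2])
    nsteps <- max(2L, ceiling(len / step))
    pts <- matrix(0, nsteps, 3L)
    pos <- start
    soft <- margin + 10
    for (s in seq_len(nsteps)) {
      dir <- unitv(dir + rnorm(3, sd = 0.05))
      # anticipatory inward steering near the faces of the volume
      push <- pmax(0, (soft - pos) / soft) -
        pmax(0, (pos - (dims - soft + 1)) / soft)
      if (any(push != 0)) dir <- unitv(dir + 1.5 * push)
      pos <- pmin(pmax(pos + step * dir, margin), dims - margin + 1)
      pts[s, ] <- pos
    }
    list(points = pts, dir = dir)
  }
  # returns TRUE if pts collide with previously grown fibers
  collides <- function(pts, clearance) {
    if (nrow(occupied) == 0L) return(FALSE)
    check <- pts[-seq_len(min(8L, nrow(pts))), , drop = FALSE]
    if (nrow(check) == 0L) return(FALSE)
    for (k in seq_len(nrow(check))) {
      d2 <- (occupied[, 1] - check[k, 1])^2 +
        (occupied[, 2] - check[k, 2])^2 +
        (occupied[, 3] - check[k, 3])^2
      if (any(d2 < clearance^2)) return(TRUE)
    }
    FALSE
  }
  queue <- list(list(start = soma, dir = unitv(rnorm(3)), gen = 0L,
                     parent = 0L))
  # keep an air gap of at least ~2 voxels between tube surfaces so fibers
  # of different lineages are never 26-adjacent
  clearance <- 2 * spec$tube_radius + 3
  while (length(queue)) {
    task <- queue[[1L]]
    queue <- queue[-1L]
    seg <- NULL
    for (try in 1:20) {
      cand <- grow_one(task$start, task$dir, task$gen, task$parent)
      if (!collides(cand$points, clearance)) {
        seg <- cand
        break
      }
      task$dir <- unitv(task$dir + rnorm(3, sd = 0.8))
    }
    if (is.null(seg)) next  # crowded: terminate this lineage early
    id <- length(segments) + 1L
    segments[[id]] <- list(id = id, parent = task$parent, gen = task$gen,
                           points = seg$points)
    occupied <- rbind(occupied, seg$points)
    if (task$gen < spec$depth) {
      k <- sample(rep(spec$child_counts, 2L), 1L,
                  prob = rep(spec$child_prob, 2L))
      if (k > 0L) {
        w <- rand_ortho(seg$dir)
        ang <- runif(1, 0.6, 0.9)  # ~35-50 degrees half-angle
        end <- seg$points[nrow(seg$points), ]
        for (ci in seq_len(k)) {
          sgn <- if (ci %% 2L == 1L) 1 else -1
          wobble <- if (ci > 2L) rand_ortho(seg$dir) else w
          cdir <- unitv(cos(ang) * seg$dir + sgn * sin(ang) * wobble)
          queue[[length(queue) + 1L]] <-
            list(start = end, dir = cdir, gen = task$gen + 1L, parent = id)
        }
      }
    }
  }
  segments
}

# voxel offsets of a ball of given radius
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# rasterize polyline points as a tube; returns unique linear indices
rasterize_tube <- function(points, radius, dims) {
  offs <- ball_offsets(radius)
  ctr <- round(points)
  all <- ctr[rep(seq_len(nrow(ctr)), each = nrow(offs)), , drop = FALSE] +
    offs[rep(seq_len(nrow(offs)), times = nrow(ctr)), , drop = FALSE]
  ok <- all[, 1] >= 1 & all[, 1] <= dims[1] &
    all[, 2] >= 1 & all[, 2] <= dims[2] &
    all[, 3] >= 1 & all[, 3] <= dims[3]
  unique(vx_index(all[ok, , drop = FALSE], dims))
}

# Render one neuron (tree + soma) into per-voxel intensity and ownership.
# Returns list(segments, voxidx per segment, intensity per segment, soma).
render_neuron <- function(spec, soma, dims) {
  segments <- grow_skeleton(spec, soma, dims)
  seg_vox <- lapply(segments, function(s)
    rasterize_tube(s$points, spec$tube_radius, dims))
  soma_vox <- rasterize_tube(matrix(soma, ncol = 3L), spec$soma_radius, dims)
  seg_int <- vapply(segments, function(s)
    as.integer(round(spec$proximal_intensity * spec$decay^s$gen)),
    integer(1))
  list(segments = segments, seg_vox = seg_vox, seg_int = seg_int,
       soma_vox = soma_vox)
}

# carve weak points into the rendered neuron: the tube cross-section around
# a mid-fiber point is erased except for a thin thread of skeleton voxels at
# the weak intensity, so thresholds above that intensity sever the fiber
carve_weak_points <- function(spec, neuron, dims) {
  weak <- list()
  if (spec$n_weak_points < 1L) return(list(neuron = neuron, weak = weak))
  gens <- vapply(neuron$segments, `[[`, integer(1), "gen")
  eligible <- which(gens >= 2L)
  if (length(eligible) == 0L) eligible <- which(gens >= 1L)
  picks <- head(unique(sample(rep(eligible, 2L))),
                min(spec$n_weak_points, length(eligible)))
  for (si in picks) {
    pts <- neuron$segments[[si]]$points
    mid <- pts[round(nrow(pts) / 2), ]
    hole <- rasterize_tube(matrix(mid, ncol = 3L),
                           spec$tube_radius + 0.6, dims)
    near <- which(rowSums(sweep(pts, 2L, mid)^2) <=
                    (spec$tube_radius + 0.6)^2)
    thread <- unique(vx_index(round(pts[near, , drop = FALSE]), dims))
    weak[[length(weak) + 1L]] <-
      list(segment = si, center = round(mid), hole = setdiff(hole, thread),
           thread = thread)
  }
  list(neuron = neuron, weak = weak)
}

#' Generate a synthetic neuron phantom
#'
#' Grows a random tree skeleton from the soma, rasterizes it as tubes of
#' per-generation decaying intensity, carves the requested weak points,
#' and adds depth-varying background noise plus sparse salt voxels. Output
#' is bit-identical for identical specs (including the seed).
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_result`: list with `volume` (a [volume_image()]),
#'   `labels` (list of ground-truth [voxel_set()]s, one per neuron),
#'   `skeletons` (list of ground-truth `skeleton_tree`s), `somata`
#'   (matrix of `(z, y, x)` centers), `weak_points`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- as.integer(spec$shape)
  somata <- phantom_soma_positions(spec, dims)
  vol <- array(0L, dims)
  labels <- vector("list", spec$n_neurons)
  skeletons <- vector("list", spec$n_neurons)
  weak_all <- list()
  for (ni in seq_len(spec$n_neurons)) {
    neuron <- render_neuron(spec, somata[ni, ], dims)
    cw <- carve_weak_points(spec, neuron, dims)
    weak_all <- c(weak_all, cw$weak)
    paint <- paint_neuron(vol, cw, spec, dims)
    vol <- paint$vol
    labels[[ni]] <- voxel_set(paint$label_idx, dims, index = TRUE)
    skeletons[[ni]] <- skeleton_from_segments(neuron, somata[ni, ], dims)
  }
  # carved weak-point rings stay dark: they are part of the neuron's
  # footprint, not background
  holes <- unlist(lapply(weak_all, `[[`, "hole"))
  vol <- add_background(vol, spec, dims,
                        protected = c(unlist(lapply(labels, `[[`, "index")),
                                      holes))
  structure(
    list(volume = volume_image(vol, bit_depth = spec$bit_depth),
         labels = labels, skeletons = skeletons, somata = somata,
         weak_points = weak_all, spec = spec),
    class = "phantom_result"
  )
}

phantom_soma_positions <- function(spec, dims) {
  ctr <- round(dims / 2)
  if (spec$n_neurons == 1L) {
    m <- matrix(as.integer(ctr), 1L)
  } else {
    off <- round(dims[3] * 0.22)
    xs <- round(seq(ctr[3] - off, ctr[3] + off,
                    length.out = spec$n_neurons))
    m <- cbind(ctr[1], ctr[2], as.integer(xs))
  }
  colnames(m) <- c("z", "y", "x")
  m
}

# write one carved neuron into the scene volume (max-composited)
paint_neuron <- function(vol, cw, spec, dims) {
  neuron <- cw$neuron
  hole <- unlist(lapply(cw$weak, `[[`, "hole"))
  thread <- unlist(lapply(cw$weak, `[[`, "thread"))
  # distal-first so proximal (brighter) segments win overlaps
  ord <- order(vapply(neuron$segments, `[[`, integer(1), "gen"),
               decreasing = TRUE)
  for (si in ord)
    vol[neuron$seg_vox[[si]]] <- pmax(vol[neuron$seg_vox[[si]]],
                                      neuron$seg_int[si])
  vol[neuron$soma_vox] <- spec$proximal_intensity
  if (length(hole)) vol[hole] <- 0L
  if (length(thread)) vol[thread] <- as.integer(spec$weak_intensity)
  label_idx <- sort(unique(c(unlist(neuron$seg_vox), neuron$soma_vox)))
  label_idx <- setdiff(label_idx, hole)
  list(vol = vol, label_idx = label_idx)
}

add_background <- function(vol, spec, dims, protected) {
  bg <- setdiff(seq_len(prod(dims)), protected)
  if (length(bg) == 0L) return(vol)
  maxint <- 2L^spec$bit_depth - 1L
  zc <- vx_coords(bg, dims)[, 1L]
  slab <- (zc - 1L) %/% spec$slab_height + 1L
  mu <- rep(spec$noise_mean, length.out = max(slab))[slab]
  noise <- as.integer(pmin(pmax(round(rnorm(length(bg), mu,
                                            spec$noise_sd)), 0), maxint))
  vol[bg] <- noise
  if (spec$salt_density > 0) {
    nsalt <- rbinom(1L, length(bg), spec$salt_density)
    if (nsalt > 0L) {
      at <- sample(bg, nsalt)
      vol[at] <- as.integer(round(runif(nsalt, spec$salt_intensity[1],
                                        spec$salt_intensity[2])))
    }
  }
  vol
}

# ground-truth skeleton_tree from grown segments; single-child chains
# (left behind when one child of a junction could not be grown) are merged,
# since they are invisible to any morphological tracer
skeleton_from_segments <- function(neuron, soma, dims) {
  segs <- neuron$segments
  repeat {
    nchild <- tabulate(vapply(segs, `[[`, integer(1), "parent"),
                       nbins = length(segs))
    chain <- which(nchild == 1L)
    if (length(chain) == 0L) break
    p <- chain[1L]
    ch <- which(vapply(segs, `[[`, integer(1), "parent") == p)
    segs[[p]]$points <- rbind(segs[[p]]$points, segs[[ch]]$points)
    for (k in seq_along(segs))
      if (segs[[k]]$parent == ch) segs[[k]]$parent <- p
    segs <- segs[-ch]
    # reindex ids/parents
    old_ids <- vapply(segs, `[[`, integer(1), "id")
    map <- integer(max(old_ids)); map[old_ids] <- seq_along(segs)
    neuron$seg_vox[[p]] <- c(neuron$seg_vox[[p]], neuron$seg_vox[[ch]])
    neuron$seg_vox <- neuron$seg_vox[-ch]
    for (k in seq_along(segs)) {
      segs[[k]]$id <- map[segs[[k]]$id]
      if (segs[[k]]$parent > 0L) segs[[k]]$parent <- map[segs[[k]]$parent]
    }
  }
  n <- length(segs)
  branches <- vector("list", n)
  claimed <- integer(0)
  for (i in seq_len(n)) {
    cp <- segs[[i]]$points
    colnames(cp) <- c("z", "y", "x")
    vox <- setdiff(neuron$seg_vox[[i]], claimed)
    claimed <- c(claimed, vox)
    branches[[i]] <- list(
      id = i, parent = segs[[i]]$parent, central_points = cp,
      start_point = cp[1L, ], branch_point = NULL, end_point = NULL,
      voxel_index = sort(vox), children = integer(0))
  }
  for (i in seq_len(n)) {
    p <- branches[[i]]$parent
    if (p > 0L) branches[[p]]$children <- c(branches[[p]]$children, i)
  }
  for (i in seq_len(n)) {
    cp <- branches[[i]]$central_points
    if (length(branches[[i]]$children))
      branches[[i]]$branch_point <- cp[nrow(cp), ]
    else
      branches[[i]]$end_point <- cp[nrow(cp), ]
  }
  branches[[1L]]$voxel_index <-
    sort(unique(c(branches[[1L]]$voxel_index, neuron$soma_vox)))
  structure(
    list(branches = branches, root = 1L, soma = as.integer(soma),
         dims = dims, connectivity = 26L, threshold = NA_integer_,
         aborted = FALSE, n_branches = n, measured = FALSE),
    class = "skeleton_tree"
  )
}

#' Adjacency fraction between two voxel sets
#'
#' Fraction of the voxels of `b` lying within one voxel (Chebyshev
#' distance, i.e. in the 26-neighborhood or coincident) of a voxel of `a`.
#' This is the tangling measure used to calibrate multi-neuron scenes.
#'
#' @param a,b [voxel_set()]s over the same volume.
#' @return Numeric fraction in `[0, 1]`.
#' @export
adjacency_fraction <- function(a, b) {
  stopifnot(identical(a$dims, b$dims))
  dil <- array(FALSE, a$dims)
  ca <- voxel_coords(a)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    sh <- cbind(ca[, 1] + dz, ca[, 2] + dy, ca[, 3] + dx)
    ok <- sh[, 1] >= 1 & sh[, 1] <= a$dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= a$dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= a$dims[3]
    dil[vx_index(sh[ok, , drop = FALSE], a$dims)] <- TRUE
  }
  mean(dil[b$index])
}

#' Generate a tangled multi-neuron scene
#'
#' Generates `n_neurons >= 2` phantoms in one volume and translates the
#' second neuron along the x axis until the measured adjacency fraction of
#' its fiber voxels to the first neuron's (see [adjacency_fraction()]) is as
#' close as possible to `spec$tangle_overlap`. With a target of 0 the
#' neurons are placed so that even their 1-voxel dilations are disjoint.
#'
#' @param spec a [phantom_spec()] with `n_neurons >= 2`.
#' @param tolerance admissible deviation of the achieved adjacency fraction
#'   from the target (default 0.05); beyond it a generation error is
#'   raised.
#' @return A `phantom_result` (see [generate_phantom()]); `somata` reflects
#'   the final placement.
#' @export
generate_tangled_scene <- function(spec, tolerance = 0.05) {
  stopifnot(inherits(spec, "phantom_spec"), spec$n_neurons >= 2L)
  set.seed(spec$seed)
  dims <- as.integer(spec$shape)
  somata <- phantom_soma_positions(spec, dims)
  rendered <- vector("list", spec$n_neurons)
  for (ni in seq_len(spec$n_neurons))
    rendered[[ni]] <- render_neuron(spec, somata[ni, ], dims)
  lab1 <- voxel_set(unique(c(unlist(rendered[[1L]]$seg_vox),
                             rendered[[1L]]$soma_vox)), dims, index = TRUE)
  # candidate x-translations of neuron 2 (and beyond)
  vox2 <- vx_coords(unique(c(unlist(rendered[[2L]]$seg_vox),
                             rendered[[2L]]$soma_vox)), dims)
  shift_ok <- function(dx) {
    x <- vox2[, 3] + dx
    all(x >= 1 & x <= dims[3])
  }
  frac_at <- function(dx) {
    sh <- cbind(vox2[, 1:2, drop = FALSE], vox2[, 3] + dx)
    adjacency_fraction(lab1, voxel_set(sh, dims, index = FALSE))
  }
  dxs <- Filter(shift_ok, as.list(seq(10L, -round(dims[3] * 0.44), by = -1L)))
  dxs <- unlist(dxs)
  fr <- vapply(dxs, frac_at, numeric(1))
  if (spec$tangle_overlap == 0) {
    ok <- which(fr == 0)
    if (length(ok) == 0L)
      stop("cannot place neurons with disjoint dilations in this volume")
    best <- ok[which.min(abs(dxs[ok]))]  # least displacement
  } else {
    best <- which.min(abs(fr - spec$tangle_overlap))
    if (abs(fr[best] - spec$tangle_overlap) > tolerance)
      stop(sprintf(
        "target overlap %.3f unreachable (closest achievable %.3f)",
        spec$tangle_overlap, fr[best]))
  }
  dx <- dxs[best]
  # apply the shift to neuron 2 and assemble the scene
  shift_idx <- function(idx) {
    cc <- vx_coords(idx, dims)
    vx_index(cbind(cc[, 1:2, drop = FALSE], cc[, 3] + dx), dims)
  }
  rendered[[2L]]$seg_vox <- lapply(rendered[[2L]]$seg_vox, shift_idx)
  rendered[[2L]]$soma_vox <- shift_idx(rendered[[2L]]$soma_vox)
  for (si in seq_along(rendered[[2L]]$segments))
    rendered[[2L]]$segments[[si]]$points[, 3] <-
      rendered[[2L]]$segments[[si]]$points[, 3] + dx
  somata[2L, 3] <- somata[2L, 3] + dx
  vol <- array(0L, dims)
  labels <- vector("list", spec$n_neurons)
  skeletons <- vector("list", spec$n_neurons)
  for (ni in seq_len(spec$n_neurons)) {
    paint <- paint_neuron(vol, list(neuron = rendered[[ni]], weak = list()),
                          spec, dims)
    vol <- paint$vol
    labels[[ni]] <- voxel_set(paint$label_idx, dims, index = TRUE)
    skeletons[[ni]] <- skeleton_from_segments(rendered[[ni]], somata[ni, ],
                                              dims)
  }
  vol <- add_background(vol, spec, dims,
                        protected = unlist(lapply(labels, `[[`, "index")))
  structure(
    list(volume = volume_image(vol, bit_depth = spec$bit_depth),
         labels = labels, skeletons = skeletons, somata = somata,
         weak_points = list(), spec = spec, shift = dx),
    class = "phantom_result"
  )
}
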