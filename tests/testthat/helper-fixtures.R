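# Shared fixture builders. Everything is generated in code; geometry is in
# (z, y, x) with 1-based coordinates.

# solid tube along x, 3x3 cross-section
tube_volume <- function(len = 34L, intensity = 100L) {
  a <- array(0L, c(9L, 9L, len + 6L))
  a[4:6, 4:6, 3:(2L + len)] <- intensity
  volume_image(a)
}

# symmetric Y: stem along x, two arms diverging in y
y_volume <- function(intensity = 80L) {
  a <- array(0L, c(30L, 40L, 40L))
  a[14:16, 19:21, 2:20] <- intensity
  for (s in 0:14) {
    a[14:16, (19 + s):(21 + s), (20 + s):(22 + s)] <- intensity
    a[14:16, (17 - s):(19 - s), (20 + s):(22 + s)] <- intensity
  }
  volume_image(a)
}
y_soma <- c(15L, 20L, 2L)
y_junction <- c(15L, 20L, 21L)

# random sparse voxel set in a small grid
random_voxels <- function(n, dims = c(12L, 12L, 12L), connectivity = 26L) {
  idx <- sample.int(prod(dims), n)
  voxel_set(idx, dims, connectivity = connectivity, index = TRUE)
}

# random branch topology as a parent vector (branch 1 is the root)
random_parent_vector <- function(n) {
  if (n == 1L) return(0L)
  c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
}

# independent recursive recomputation of branch measurements from a parent
# vector and lengths: G, N and the longest offspring length
oracle_measurements <- function(parent, len) {
  n <- length(parent)
  children <- lapply(seq_len(n), function(i) which(parent == i))
  G <- N <- moL <- rep(NA_real_, n)
  rec <- function(i) {
    ch <- children[[i]]
    if (length(ch) == 0L) {
      G[i] <<- 0; N[i] <<- 0; moL[i] <<- 0
    } else {
      for (c_ in ch) rec(c_)
      G[i] <<- max(G[ch]) + 1
      N[i] <<- sum(N[ch] + 1)
      moL[i] <<- max(len[ch], moL[ch])
    }
  }
  rec(which(parent == 0L))
  list(G = G, N = N, moL = moL)
}

# direct evaluation of the per-branch score formula from oracle measurements
oracle_branch_scores <- function(parent, len, g0, n0, l0) {
  mm <- oracle_measurements(parent, len)
  n <- length(parent)
  has_child <- vapply(seq_len(n), function(i) any(parent == i), logical(1))
  vapply(seq_len(n), function(i) {
    lam <- if (mm$G[i] < g0 && mm$N[i] < n0 && has_child[i])
      floor(mm$moL[i] / l0) else 0
    max(mm$G[i] - g0, 0) + floor(mm$N[i] / n0) + floor(len[i] / l0) + lam
  }, numeric(1))
}

# a tree whose root has descendant-generation counts 1 and 5 under it and
# 14 descendants in total (the canonical worked-example shape), with a
# 3-point root
worked_example_tree <- function() {
  # root(1); X(2)->terminal(3); Y(4)->5->6->7->8->terminal(9);
  # six extra terminals under Y to reach 14 descendants
  parent <- c(0L, 1L, 2L, 1L, 4L, 5L, 6L, 7L, 8L, rep(4L, 6L))
  len <- c(3L, rep(1L, 14L))
  skeleton_from_parents(parent, len)
}

# segmentation-free run of the scoring sweep + mask + segmentation
nr_segment <- function(volume, soma, m, l0 = 10L, b_max = 10000L) {
  sched <- build_threshold_schedule(volume, soma, b_max = b_max)
  brs <- accumulate_brs(volume, soma, sched, l0 = l0)
  segment_neuron(volume, build_hdr_mask(brs, m), soma)
}

# direct reimplementation of the mass/inertia/overlap formulas used as the
# comparison oracle: plain loops, no shared code with the package internals
oracle_report <- function(ref_xyz, test_xyz, ref_idx, test_idx) {
  props <- function(xyz) {
    n <- nrow(xyz)
    ctr <- colSums(xyz) / n
    it <- matrix(0, 3, 3)
    r2sum <- 0
    for (i in seq_len(n)) {
      r <- xyz[i, ] - ctr
      r2 <- sum(r^2)
      r2sum <- r2sum + r2
      it <- it + r2 * diag(3) - outer(r, r)
    }
    eg <- eigen(it, symmetric = TRUE)
    ord <- order(eg$values, decreasing = TRUE)
    list(ctr = ctr, rg = sqrt(r2sum / n), mom = eg$values[ord],
         axes = eg$vectors[, ord])
  }
  H <- props(ref_xyz); Tt <- props(test_xyz)
  d_cm <- min(1, sqrt(sum((Tt$ctr - H$ctr)^2)) / H$rg)
  d_rg <- min(1, abs(Tt$rg - H$rg) / H$rg)
  iH <- c(1, H$mom[2] / H$mom[1], H$mom[3] / H$mom[1])
  iT <- c(1, Tt$mom[2] / Tt$mom[1], Tt$mom[3] / Tt$mom[1])
  d_i <- min(1, sqrt(sum((iH - iT)^2)))
  d_pa <- 1 - sum(abs(colSums(H$axes * Tt$axes))) / 3
  inter <- length(intersect(ref_idx, test_idx))
  r <- inter / length(ref_idx)
  p <- inter / length(test_idx)
  s <- ((1 - d_rg) + (1 - d_cm) + (1 - d_i) + (1 - d_pa) + r) / 5
  list(D_CM = d_cm, D_RG = d_rg, D_I = d_i, D_PA = d_pa,
       recall = r, precision = p, S_Global = s)
}

# 26-neighborhood adjacency matrix of a coordinate list
chebyshev_adjacency <- function(xyz) {
  dz <- abs(outer(xyz[, 1], xyz[, 1], "-"))
  dy <- abs(outer(xyz[, 2], xyz[, 2], "-"))
  dx <- abs(outer(xyz[, 3], xyz[, 3], "-"))
  ad <- dz <= 1 & dy <= 1 & dx <= 1
  diag(ad) <- FALSE
  ad
}

# independent geodesic oracle: igraph BFS distances from the first voxel
bfs_oracle_distances <- function(vs) {
  xyz <- voxel_coords(vs)
  g <- igraph::graph_from_adjacency_matrix(chebyshev_adjacency(xyz),
                                           mode = "undirected")
  as.integer(igraph::distances(g, v = 1)[1, ])
}

# single-global-threshold baseline: soma-connected component of {I >= t}
threshold_baseline <- function(volume, soma, t) {
  vs <- threshold_volume(volume, t)
  seed <- neuroretriever:::soma_seed_for(vs, soma)
  if (is.null(seed)) return(integer(0))
  compute_source_field(vs, seed)$index
}
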