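test_that("threshold keeps voxels at or above t, never below", {
  a <- array(0L, c(3, 3, 1))
  a[, , 1] <- matrix(1:9, 3, 3)
  v <- volume_image(a)
  expect_equal(length(threshold_volume(v, 4)), 6L)
  expect_equal(length(threshold_volume(v, 0)), 9L)   # all nonzero
  expect_equal(length(threshold_volume(v, 1)), 9L)
  # monotone nesting over random volumes
  set.seed(11)
  for (k in 1:5) {
    b <- array(sample(0:30, 8^3, replace = TRUE), c(8, 8, 8))
    vb <- volume_image(b)
    t1 <- sample(0:10, 1); t2 <- t1 + sample(1:10, 1)
    s1 <- threshold_volume(vb, t1)$index
    s2 <- threshold_volume(vb, t2)$index
    expect_true(all(s2 %in% s1))
  }
  expect_error(threshold_volume(v, 300), "range")
})

test_that("weak-point voxels drop out above their intensity", {
  spec <- phantom_spec(seed = 4, shape = c(64, 64, 64), depth = 3,
                       n_weak_points = 1, weak_intensity = 3L,
                       noise_mean = 0, noise_sd = 0, salt_density = 0)
  ph <- generate_phantom(spec)
  thread <- ph$weak_points[[1]]$thread
  expect_true(all(thread %in% threshold_volume(ph$volume, 3)$index))
  expect_false(any(thread %in% threshold_volume(ph$volume, 4)$index))
})

test_that("connected components respect connectivity and partition the set", {
  dims <- c(5L, 5L, 5L)
  face <- voxel_set(rbind(c(1, 1, 1), c(1, 1, 2)), dims, connectivity = 6)
  expect_length(connected_components(face), 1L)
  corner <- rbind(c(1, 1, 1), c(2, 2, 2))
  expect_length(connected_components(voxel_set(corner, dims, 6)), 2L)
  expect_length(connected_components(voxel_set(corner, dims, 26)), 1L)
})

test_that("components match a union-find oracle on random sparse sets", {
  uf_components <- function(vs) {
    cc <- voxel_coords(vs)
    n <- nrow(cc)
    par <- seq_len(n)
    find <- function(i) { while (par[i] != i) i <- par[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && max(abs(cc[i, ] - cc[j, ])) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) par[ri] <- rj
      }
    }
    par <- vapply(seq_len(n), find, integer(1))
    unname(split(vs$index, par))
  }
  set.seed(7)
  for (k in 1:4) {
    vs <- random_voxels(100)
    got <- lapply(connected_components(vs), `[[`, "index")
    want <- uf_components(vs)
    norm <- function(l) unname(sort(vapply(l, function(x)
      paste(x, collapse = ","), character(1))))
    expect_equal(norm(got), norm(want))
    # partition: disjoint union equals input
    expect_equal(sort(unlist(got, use.names = FALSE)), vs$index)
    # deterministic ordering: sizes non-increasing
    expect_true(all(diff(lengths(got)) <= 0))
  }
})

test_that("source field equals BFS distance + 1 and obeys its invariants", {
  dims <- c(4L, 4L, 12L)
  # single voxel
  one <- voxel_set(rbind(c(1, 1, 1)), dims)
  sf1 <- compute_source_field(one, c(1, 1, 1))
  expect_equal(sf1$value, 1L)
  # straight 10-voxel line
  line <- voxel_set(cbind(1, 1, 1:10), dims)
  sfl <- compute_source_field(line, c(1, 1, 1))
  expect_equal(sfl$value[order(sfl$index)], 1:10)
  expect_error(compute_source_field(line, c(4, 4, 4)), "member")

  skip_if_not_installed("igraph")
  set.seed(21)
  for (k in 1:5) {
    vs <- random_voxels(200, dims = c(10L, 10L, 10L))
    cc <- connected_components(vs)[[1L]]
    seed <- voxel_coords(cc)[1L, ]
    sf <- compute_source_field(cc, seed)
    d <- bfs_oracle_distances(cc)
    expect_equal(sf$value[match(cc$index, sf$index)], d + 1L)
    # invariants: seed = 1; neighbor difference <= 1; predecessor exists
    xyz <- voxel_coords(cc)
    ad <- chebyshev_adjacency(xyz)
    vals <- d + 1L
    expect_equal(vals[1L], 1L)
    for (i in seq_len(nrow(xyz))) {
      nb <- which(ad[i, ])
      if (length(nb)) expect_true(all(abs(vals[nb] - vals[i]) <= 1L))
      if (vals[i] > 1L) expect_true(any(vals[nb] == vals[i] - 1L))
    }
  }
})

test_that("soma detection finds bright ellipsoidal blobs", {
  # solid ball on empty background
  a <- array(0L, c(32, 32, 32))
  ctr <- c(16, 16, 16)
  for (z in 11:21) for (y in 11:21) for (x in 11:21)
    if (sum((c(z, y, x) - ctr)^2) <= 25) a[z, y, x] <- 200L
  cand <- detect_soma(volume_image(a))
  expect_gte(nrow(cand), 1L)
  expect_lte(sqrt(sum((cand[1, ] - ctr)^2)), 1)
  # phantom: top candidate within 2 voxels of the generator's soma
  ph <- generate_phantom(phantom_spec(seed = 6, shape = c(96, 96, 96),
                                      depth = 4))
  cand <- detect_soma(ph$volume)
  expect_lte(sqrt(sum((cand[1, ] - ph$somata[1, ])^2)), 2)
  # all-zero volume
  expect_equal(nrow(detect_soma(volume_image(array(0L, c(5, 5, 5))))), 0L)
})
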