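test_that("a straight tube traces to a single branch of geodesic length", {
  v <- tube_volume(len = 34L)
  vs <- threshold_volume(v, 1)
  tr <- trace_skeleton(vs, c(5, 5, 3))
  expect_equal(tr$n_branches, 1L)
  b <- tr$branches[[1L]]
  expect_null(b$branch_point)
  expect_false(is.null(b$end_point))
  # L = number of codelet steps: positions 2 .. max source field
  sf <- compute_source_field(vs, c(5, 5, 3))
  expect_equal(nrow(b$central_points), max(sf$value) - 1L)
  # end point near the far end of the tube (z, y, x order)
  expect_lt(abs(b$end_point[3] - 36), 2.5)
})

test_that("the initial codelet covers source-field values 1, 2 and 3", {
  v <- tube_volume()
  vs <- threshold_volume(v, 1)
  tr <- trace_skeleton(vs, c(5, 5, 3))
  sf <- compute_source_field(vs, c(5, 5, 3))
  init <- sf$index[sf$value <= 3L]
  expect_equal(sort(unique(sf$value[sf$value <= 3L])), 1:3)
  com <- colMeans(voxel_coords(voxel_set(init, vs$dims, index = TRUE)))
  expect_equal(unname(tr$branches[[1L]]$central_points[1L, ]), unname(com),
               tolerance = 1e-8)
})

test_that("a Y-shaped tube yields 3 branches with the junction located", {
  tr <- trace_skeleton(threshold_volume(y_volume(), 1), y_soma)
  expect_equal(tr$n_branches, 3L)
  root <- tr$branches[[1L]]
  expect_equal(length(root$children), 2L)
  expect_lte(sqrt(sum((root$branch_point - y_junction)^2)), 3)
  n_end <- sum(vapply(tr$branches, function(b) !is.null(b$end_point),
                      logical(1)))
  expect_equal(n_end, 2L)
})

test_that("branch measurements follow the recursive definitions", {
  # the canonical example: children with G 1 and 5 give the parent G 6
  tr <- measure_branches(worked_example_tree())
  root <- tr$branches[[tr$root]]
  expect_equal(root$G, 6L)
  expect_equal(root$N, 14L)
  expect_equal(root$L, 3L)
  # single branch: terminal by definition
  single <- measure_branches(skeleton_from_parents(0L, 5L))
  expect_equal(single$branches[[1L]]$G, 0L)
  expect_equal(single$branches[[1L]]$N, 0L)
  expect_equal(branch_descendants(single, 1L), integer(0))
  # random topologies vs independent recursion
  set.seed(31)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    parent <- random_parent_vector(n)
    len <- sample(1:30, n, replace = TRUE)
    tree <- measure_branches(skeleton_from_parents(parent, len))
    mm <- oracle_measurements(parent, len)
    expect_equal(vapply(tree$branches, `[[`, integer(1), "G"), as.integer(mm$G))
    expect_equal(vapply(tree$branches, `[[`, integer(1), "N"), as.integer(mm$N))
    expect_equal(vapply(tree$branches, `[[`, integer(1), "max_offspring_L"),
                 as.integer(mm$moL))
    # offspring sets agree with N
    expect_equal(length(branch_descendants(tree, 1L)),
                 tree$branches[[1L]]$N)
  }
})

test_that("traced trees satisfy the structural invariants deterministically", {
  ph <- generate_phantom(phantom_spec(seed = 9, shape = c(64, 64, 64),
                                      depth = 3, noise_mean = 0,
                                      noise_sd = 0, salt_density = 0))
  vs <- threshold_volume(ph$volume, 1)
  tr1 <- measure_branches(trace_skeleton(vs, ph$somata[1, ]))
  tr2 <- measure_branches(trace_skeleton(vs, ph$somata[1, ]))
  expect_identical(tr1, tr2)       # bit-identical re-trace
  # no voxel claimed twice; sum of L equals total central points
  vox <- unlist(lapply(tr1$branches, `[[`, "voxel_index"))
  expect_equal(anyDuplicated(vox), 0L)
  expect_equal(sum(vapply(tr1$branches, `[[`, integer(1), "L")),
               sum(vapply(tr1$branches,
                          function(b) nrow(b$central_points), integer(1))))
  # N recursion against brute force on the traced tree
  parent <- vapply(tr1$branches, `[[`, integer(1), "parent")
  len <- vapply(tr1$branches, `[[`, integer(1), "L")
  mm <- oracle_measurements(parent, len)
  expect_equal(vapply(tr1$branches, `[[`, integer(1), "N"), as.integer(mm$N))
  # tree property: branches = 1 + sum over branch points of (children - 1)
  nch <- lengths(lapply(tr1$branches, `[[`, "children"))
  expect_equal(tr1$n_branches, 1L + sum(nch[nch > 0] - 1L) + sum(nch > 0))
})

test_that("spur pruning removes short terminals and merges chains", {
  # root with a long child, a 2-point spur, and grandchildren
  parent <- c(0L, 1L, 1L, 2L, 2L)
  len <- c(8L, 20L, 2L, 15L, 15L)
  pr <- prune_spurs(skeleton_from_parents(parent, len), min_length = 5L)
  # spur (branch 3) dropped; root then has a single child which is merged
  expect_equal(pr$n_branches, 3L)
  pr <- measure_branches(pr)
  expect_equal(pr$branches[[pr$root]]$L, 28L)  # 8 + 20 merged
  expect_equal(length(pr$branches[[pr$root]]$children), 2L)
})

test_that("SWC round-trips preserve topology and record structure", {
  # single 5-point branch: parents -1, 1, 2, 3, 4
  single <- skeleton_from_parents(0L, 5L)
  f <- tempfile(fileext = ".swc")
  write_swc(single, f)
  recs <- read.table(f, comment.char = "#")
  expect_equal(recs$V7, c(-1L, 1L, 2L, 3L, 4L))
  expect_equal(recs$V2[1L], 1L)   # soma record type

  # Y tree: each child's first record points at the retracted branch point
  tr <- trace_skeleton(threshold_volume(y_volume(), 1), y_soma)
  write_swc(tr, f)
  recs <- read.table(f, comment.char = "#")
  root_len <- nrow(tr$branches[[1L]]$central_points)
  kids_first_parent <- recs$V7[recs$V7 == root_len]
  expect_equal(length(kids_first_parent), 2L)
  bp <- tr$branches[[1L]]$branch_point
  expect_equal(unname(unlist(recs[root_len, c("V5", "V4", "V3")])) + 1,
               unname(bp), tolerance = 1e-4)

  # write-then-read topology for random phantoms
  for (s in 1:3) {
    ph <- generate_phantom(phantom_spec(seed = s, shape = c(64, 64, 64),
                                        depth = 3, noise_mean = 0,
                                        noise_sd = 0, salt_density = 0))
    tr <- prune_spurs(trace_skeleton(threshold_volume(ph$volume, 1),
                                     ph$somata[1, ]))
    write_swc(tr, f)
    rt <- read_swc(f)
    expect_equal(rt$n_branches, tr$n_branches)
    sig <- function(t_) sort(vapply(t_$branches, function(b)
      paste(nrow(b$central_points), length(b$children)), character(1)))
    expect_equal(sig(rt), sig(tr))
  }
})
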