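test_that("mass properties match closed forms and a brute-force tensor", {
  dims <- c(20L, 20L, 20L)
  # solid cube: isotropic inertia, center at the geometric center
  cube <- voxel_set(as.matrix(expand.grid(z = 3:7, y = 3:7, x = 3:7)), dims)
  mp <- mass_properties(cube)
  expect_equal(unname(mp$center), c(5, 5, 5))
  expect_equal(mp$inertia_vec, c(1, 1, 1), tolerance = 1e-10)
  # straight rod of 2k+1 voxels: rg = sqrt(k (k+1) / 3)
  k <- 7L
  rod <- voxel_set(cbind(10, 10, 10 + (-k:k)), dims)
  expect_equal(mass_properties(rod)$rg, sqrt(k * (k + 1) / 3))
  expect_error(mass_properties(matrix(numeric(0), ncol = 3)), "empty")
  # random clouds vs the brute-force inertia sum
  set.seed(61)
  vs <- random_voxels(500, dims = c(15L, 15L, 15L))
  mp <- mass_properties(vs)
  xyz <- voxel_coords(vs)
  it <- matrix(0, 3, 3)
  ctr <- colMeans(xyz)
  for (i in seq_len(nrow(xyz))) {
    r <- xyz[i, ] - ctr
    it <- it + sum(r^2) * diag(3) - outer(r, r)
  }
  expect_equal(sort(mp$moments, decreasing = TRUE),
               sort(eigen(it, symmetric = TRUE)$values, decreasing = TRUE),
               tolerance = 1e-9)
  expect_true(all(diff(mp$moments) <= 0))
  expect_equal(crossprod(mp$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("identical segmentations compare as a perfect match", {
  ph <- generate_phantom(phantom_spec(seed = 12, shape = c(64, 64, 64),
                                      depth = 3))
  a <- ph$labels[[1]]
  rep <- compare_segmentations(a, a)
  expect_equal(rep$S_Global, 1)
  expect_equal(rep$D_CM, 0); expect_equal(rep$D_RG, 0)
  expect_equal(rep$D_I, 0);  expect_equal(rep$D_PA, 0)
  expect_equal(rep$recall, 1); expect_equal(rep$precision, 1)
  expect_equal(rep$gs_class, "I")
})

test_that("distances clamp at 1 for far-translated copies", {
  dims <- c(60L, 20L, 20L)
  xyz <- as.matrix(expand.grid(z = 2:6, y = 2:6, x = 2:6))
  a <- voxel_set(xyz, dims)
  rg <- mass_properties(a)$rg
  shift <- ceiling(2 * rg) + 5
  b <- voxel_set(cbind(xyz[, 1] + shift, xyz[, 2], xyz[, 3]), dims)
  rep <- compare_segmentations(a, b)
  expect_equal(rep$D_CM, 1)
  expect_equal(rep$recall, 0)
})

test_that("reports agree with a direct formula oracle on random pairs", {
  set.seed(71)
  for (k in 1:100) {
    a <- random_voxels(sample(30:120, 1), dims = c(14L, 14L, 14L))
    b <- random_voxels(sample(30:120, 1), dims = c(14L, 14L, 14L))
    got <- compare_segmentations(a, b)
    want <- oracle_report(voxel_coords(a), voxel_coords(b),
                          a$index, b$index)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9)
    # every field within [0, 1]; S_Global is the stated mean
    expect_true(all(unlist(got[c("D_CM", "D_RG", "D_I", "D_PA",
                                 "recall", "precision", "S_Global")]) >= 0))
    expect_true(all(unlist(got[c("D_CM", "D_RG", "D_I", "D_PA",
                                 "recall", "precision", "S_Global")]) <= 1))
    expect_equal(got$S_Global,
                 ((1 - got$D_RG) + (1 - got$D_CM) + (1 - got$D_I) +
                    (1 - got$D_PA) + got$recall) / 5)
    # overlap identities
    expect_equal(got$recall * length(a), got$precision * length(b))
  }
})

test_that("axis comparison ignores sign flips and degenerate axes", {
  set.seed(81)
  vs <- random_voxels(200, dims = c(12L, 30L, 12L))
  mp <- mass_properties(vs)
  flipped <- mp
  for (j in 1:3) {
    flipped$axes <- mp$axes
    flipped$axes[, j] <- -flipped$axes[, j]
    expect_equal(neuroretriever:::axis_alignment_sum(mp, flipped),
                 neuroretriever:::axis_alignment_sum(mp, mp))
  }
  # symmetric object: degenerate moments, D_PA must still be 0 vs itself
  dims <- c(20L, 20L, 20L)
  cube <- voxel_set(as.matrix(expand.grid(z = 3:9, y = 3:9, x = 3:9)), dims)
  rep <- compare_segmentations(cube, cube)
  expect_equal(rep$D_PA, 0)
})

test_that("similarity classes follow the published boundaries", {
  expect_equal(classify_similarity(1), "I")
  expect_equal(classify_similarity(0.9), "I")
  expect_equal(classify_similarity(0.7), "II")
  expect_equal(classify_similarity(0.89), "II")
  expect_equal(classify_similarity(0.69), "III")
})

test_that("report export formats are consistent", {
  ph <- generate_phantom(phantom_spec(seed = 13, shape = c(48, 48, 48),
                                      depth = 2))
  rep <- compare_segmentations(ph$labels[[1]], ph$labels[[1]])
  f <- tempfile(fileext = ".tsv")
  write_similarity_tsv(list(rep), f, ids = "self")
  tab <- read.delim(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$S_Global, 1)
  expect_equal(tab$class, "I")
})
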