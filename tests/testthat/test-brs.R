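test_that("default schedules span the published threshold widths", {
  # clean 8-bit image: t1 = t_step = 2, width 98
  v8 <- tube_volume(intensity = 200L)
  s8 <- build_threshold_schedule(v8, c(5, 5, 3))
  expect_equal(s8$t[1L], 2L)
  expect_false(s8$t1_adjusted)
  expect_equal(s8$t[s8$n] - s8$t[1L], 98L)
  expect_equal(s8$n, 50L)
  # 12-bit: t_step = 10, width 490
  a <- tube_volume(intensity = 200L)$data
  a[a > 0L] <- 3000L
  v12 <- volume_image(a, bit_depth = 12L)
  s12 <- build_threshold_schedule(v12, c(5, 5, 3))
  expect_equal(s12$t[1L], 10L)
  expect_equal(s12$t[s12$n] - s12$t[1L], 490L)
})

test_that("t1 rises in whole steps when low thresholds explode the trace", {
  # noisy phantom: tracing at t = 2 picks up background fuzz branches
  ph <- generate_phantom(phantom_spec(seed = 3, shape = c(64, 64, 64),
                                      depth = 2, noise_mean = 0,
                                      noise_sd = 1.2, salt_density = 0))
  raw <- trace_skeleton(threshold_volume(ph$volume, 2), ph$somata[1, ])
  expect_gt(raw$n_branches, 10L)
  sched <- build_threshold_schedule(ph$volume, ph$somata[1, ], b_max = 10L)
  expect_true(sched$t1_adjusted)
  expect_gt(sched$t[1L], 2L)
  expect_equal(sched$t[1L] %% 2L, 0L)
  at_t1 <- trace_skeleton(threshold_volume(ph$volume, sched$t[1L]),
                          ph$somata[1, ])
  expect_lte(at_t1$n_branches, 10L)
})

test_that("score parameters follow the eligibility decay rules", {
  # at the top of the sweep G0 clamps to 1 and N0 stays 3 x G0
  p <- score_params(20L, t = seq(2, 100, by = 2))
  expect_equal(p$G0[50L], 1L)
  expect_equal(p$N0, 3L * p$G0)
  expect_true(all(diff(p$G0) <= 0))
  expect_true(all(p$G0 >= 1L))
  # worked-example parameterization: G0 = 2 gives N0 = 6
  p2 <- score_params(2L, t = 4L, t_max = 400L, l0 = 2L)
  expect_equal(p2$G0[1L], 2L)
  expect_equal(p2$N0[1L], 6L)

  # percentile convention: nearest rank, floored at 20
  set.seed(41)
  g_vals <- c(rep(0L, 10L), as.integer(round(seq(0, 40, length.out = 30))))
  parent <- c(0L, rep(1L, length(g_vals) - 1L))
  # build a tree whose branch G values are irrelevant; test the rank rule
  nearest_rank <- function(x, p) sort(x)[ceiling(p * length(x))]
  expect_equal(neuroretriever:::percentile_nearest_rank(g_vals, 0.75),
               nearest_rank(g_vals, 0.75))
  for (k in 1:20) {
    x <- sample.int(50, sample(3:40, 1), replace = TRUE)
    expect_equal(neuroretriever:::percentile_nearest_rank(x, 0.75),
                 nearest_rank(x, 0.75))
  }
  # full path through compute_score_params: G0(1) floored at 20
  tr <- measure_branches(skeleton_from_parents(c(0L, 1L, 1L),
                                               c(5L, 5L, 5L)))
  sch <- threshold_schedule(seq(2L, 100L, by = 2L))
  sp <- compute_score_params(tr, sch)
  expect_equal(sp$G0_1, 20L)   # tree G values are 1,0,0; 75th pct < 20
})

test_that("branch scores reproduce the worked example and the formula", {
  tr <- measure_branches(worked_example_tree())
  p <- score_params(2L, t = 4L, t_max = 400L, l0 = 2L)
  bs <- compute_branch_score(tr, p)
  # primary neurite: (6-2) + floor(14/6) + floor(3/2) + 0 = 7
  expect_equal(bs$branch_score[tr$root], 7L)
  # terminal with G = 0, N = 0, L < L0 scores 0
  term <- which(vapply(tr$branches, function(b) length(b$children) == 0L,
                       logical(1)))[1L]
  expect_equal(bs$branch_score[term], 0L)

  # random measured trees vs an independent recursion oracle
  set.seed(51)
  for (k in 1:50) {
    n <- sample(4:30, 1)
    parent <- random_parent_vector(n)
    len <- sample(1:60, n, replace = TRUE)
    tree <- measure_branches(skeleton_from_parents(parent, len))
    g0 <- sample(1:8, 1); l0 <- sample(c(2L, 5L, 10L, 20L), 1)
    p <- score_params(g0, t = 1L, t_max = 1000L, l0 = l0)
    got <- compute_branch_score(tree, p)$branch_score
    want <- oracle_branch_scores(parent, len, p$G0[1L], p$N0[1L], l0)
    expect_equal(got, as.integer(want))
  }
})

test_that("the lambda bonus applies only below both eligibility cuts", {
  # parent with one long terminal child
  tree <- measure_branches(skeleton_from_parents(c(0L, 1L), c(3L, 45L)))
  p_low <- score_params(5L, t = 1L, t_max = 1000L, l0 = 20L)  # G0=5, N0=15
  bs <- compute_branch_score(tree, p_low)
  # root: G=1<5, N=1<15, offspring length 45 -> lambda = 2
  expect_equal(bs$branch_score[1L], 2L)
  # with G0 = 1 the root has G >= G0: no lambda
  p_hi <- score_params(1L, t = 1L, t_max = 2L, l0 = 20L)  # G0 clamps to 1
  expect_equal(compute_branch_score(tree, p_hi)$branch_score[1L],
               0L + 0L + 0L + 0L)
})

test_that("BRS accumulates per-threshold scores over the sweep", {
  ph <- generate_phantom(phantom_spec(seed = 2, shape = c(48, 48, 48),
                                      depth = 2, noise_mean = 0,
                                      noise_sd = 0, salt_density = 0))
  soma <- ph$somata[1, ]
  sch3 <- threshold_schedule(c(2L, 61L, 120L))
  brs <- accumulate_brs(ph$volume, soma, sch3, l0 = 10L)
  # summation oracle: add the three per-threshold fields by hand
  manual <- array(0L, dim(ph$volume$data))
  g0_1 <- NULL
  for (j in 1:3) {
    vs <- threshold_volume(ph$volume, sch3$t[j])
    seed <- neuroretriever:::soma_seed_for(vs, soma)
    if (is.null(seed)) next
    tree <- measure_branches(prune_spurs(trace_skeleton(vs, seed)))
    if (j == 1L) g0_1 <- max(neuroretriever:::percentile_nearest_rank(
      vapply(tree$branches, `[[`, integer(1), "G"), 0.75), 20L)
    p <- score_params(g0_1, sch3$t, l0 = 10L)
    bv <- branch_score_voxels(compute_branch_score(tree, p, j))
    manual[bv$index] <- manual[bv$index] + bv$score
  }
  expect_equal(brs$values, manual)
  # voxels below t1 never score
  expect_true(all(brs$values[ph$volume$data < 2L] == 0L))
  # dropping an interior threshold (same sweep top, so identical
  # eligibility parameters) never increases BRS anywhere
  brs2 <- accumulate_brs(ph$volume, soma, threshold_schedule(c(2L, 120L)),
                         l0 = 10L)
  expect_true(all(brs2$values <= brs$values))
})

test_that("brighter voxels on a branch never score below dimmer ones", {
  ph <- generate_phantom(phantom_spec(seed = 8, shape = c(64, 64, 64),
                                      depth = 3, noise_mean = 0,
                                      noise_sd = 0, salt_density = 0))
  soma <- ph$somata[1, ]
  sched <- build_threshold_schedule(ph$volume, soma)
  brs <- accumulate_brs(ph$volume, soma, sched, l0 = 10L)
  # pick voxel pairs from one ground-truth branch with known intensities
  set.seed(1)
  gt <- ph$skeletons[[1]]
  checked <- 0L
  for (b in gt$branches) {
    if (length(b$voxel_index) < 2L) next
    ints <- ph$volume$data[b$voxel_index]
    hi <- b$voxel_index[which.max(ints)]
    lo <- b$voxel_index[which.min(ints)]
    if (ints[which.max(ints)] == ints[which.min(ints)]) next
    expect_gte(brs$values[hi], brs$values[lo])
    checked <- checked + 1L
  }
  expect_gte(checked, 1L)
})
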