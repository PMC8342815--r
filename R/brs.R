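#' Build the intensity-threshold schedule
#'
#' Constructs the ascending sweep of global intensity thresholds
#' `t_1 < t_2 < ... < t_n` with constant increment `t_step`. Defaults follow
#' the method's published parameterization: `n = 50` thresholds,
#' `t_step = 2` for 8-bit and 10 for 12-bit images (so the sweep widths
#' `t_n - t_1` are 98 and 490), and `t_1 = t_step`. For images with high
#' background the lowest thresholds connect nearly everything into one huge
#' component and tracing produces an unusable number of branches; in that
#' case `t_1` is raised by whole `t_step`s to the smallest value whose
#' branch count does not exceed `b_max` (default 10,000).
#'
#' @param volume a [volume_image()].
#' @param soma `(z, y, x)` seed used for the guard traces.
#' @param t_step threshold increment; default 2 (8-bit) or 10 (12-bit).
#' @param n number of thresholds (default 50).
#' @param b_max branch-count cap used to adjust `t_1` (default 10,000).
#' @param connectivity voxel connectivity for the guard traces.
#' @return A `threshold_schedule`: list with `t` (length `n`), `t_step`,
#'   `n`, `bit_depth`, `b_max` and `t1_adjusted`.
#' @export
build_threshold_schedule <- function(volume, soma, t_step = NULL, n = 50L,
                                     b_max = 10000L, connectivity = 26L) {
  stopifnot(inherits(volume, "volume_image"))
  if (is.null(t_step))
    t_step <- if (volume$bit_depth == 8L) 2L else 10L
  t_step <- as.integer(t_step); n <- as.integer(n)
  stopifnot(t_step >= 1L, n >= 2L)
  tmax_allowed <- 2L^volume$bit_depth - 1L
  t1 <- t_step
  adjusted <- FALSE
  repeat {
    if (t1 > tmax_allowed)
      stop("no threshold within the intensity range satisfies the b_max cap")
    vs <- threshold_volume(volume, t1, connectivity = connectivity)
    seed <- soma_seed_for(vs, soma)
    if (!is.null(seed)) {
      tr <- trace_skeleton(vs, seed, b_max = b_max)
      if (!tr$aborted && tr$n_branches <= b_max) break
    } else {
      break  # soma gone: nothing to trace, cap trivially satisfied
    }
    t1 <- t1 + t_step
    adjusted <- TRUE
  }
  structure(
    list(t = t1 + (seq_len(n) - 1L) * t_step, t_step = t_step, n = n,
         bit_depth = volume$bit_depth, b_max = b_max,
         t1_adjusted = adjusted),
    class = "threshold_schedule"
  )
}

#' Construct a threshold schedule from explicit values
#'
#' Low-level constructor for a sweep with given threshold values (must be
#' evenly spaced ascending); [build_threshold_schedule()] is the usual
#' entry point.
#'
#' @param t ascending, evenly spaced threshold values.
#' @param bit_depth 8 or 12.
#' @param b_max branch cap recorded with the schedule.
#' @return A `threshold_schedule`.
#' @export
threshold_schedule <- function(t, bit_depth = 8L, b_max = 10000L) {
  t <- as.integer(t)
  n <- length(t)
  stopifnot(n >= 1L)
  step <- if (n > 1L) unique(diff(t)) else 1L
  if (length(step) != 1L || step < 1L)
    stop("`t` must be evenly spaced ascending")
  structure(
    list(t = t, t_step = as.integer(step), n = n,
         bit_depth = as.integer(bit_depth), b_max = b_max,
         t1_adjusted = FALSE),
    class = "threshold_schedule"
  )
}

#' @export
print.threshold_schedule <- function(x, ...) {
  cat(sprintf(
    "<threshold_schedule> n=%d, t_step=%d, t in [%d, %d] (width %d)%s\n",
    x$n, x$t_step, x$t[1], x$t[x$n], x$t[x$n] - x$t[1],
    if (isTRUE(x$t1_adjusted)) " [t1 raised by b_max guard]" else ""))
  invisible(x)
}

# Seed coordinate for tracing a thresholded set: the soma voxel if it
# survived, else the nearest survivor within 3 voxels, else NULL.
soma_seed_for <- function(voxels, soma) {
  idx <- vx_index(matrix(as.integer(soma), ncol = 3L), voxels$dims)
  if (idx %in% voxels$index) return(as.integer(soma))
  nearest_member(voxels, as.integer(soma), radius = 3)
}

#' Eligibility parameters for branch scoring
#'
#' Computes the per-threshold score parameters from the tree traced at the
#' lowest threshold. `G0(1)` is the 75th percentile (nearest-rank) of the
#' descendant-generation counts of all branches at `t_1`, floored at 20. As
#' the threshold rises branches are eliminated and every branch's generation
#' count shrinks, so the requirement decays linearly to 1 at the top of the
#' sweep:
#' `G0(j) = max(ceiling(G0(1) * (1 - t_j / t_max)), 1)`, with `t_max` the
#' schedule's top threshold, and `N0(j) = 3 * G0(j)`.
#'
#' @param tree_at_t1 measured `skeleton_tree` traced at the lowest threshold.
#' @param schedule a `threshold_schedule`.
#' @param l0 length requirement `L_0` in voxels (default 20).
#' @return A `score_params`: list with vectors `G0`, `N0` (length `n`),
#'   scalar `L0` and `G0_1`.
#' @export
compute_score_params <- function(tree_at_t1, schedule, l0 = 20L) {
  stopifnot(inherits(tree_at_t1, "skeleton_tree"),
            inherits(schedule, "threshold_schedule"))
  if (!isTRUE(tree_at_t1$measured))
    stop("tree must be measured (see measure_branches)")
  if (length(tree_at_t1$branches) == 0L) stop("empty tree")
  g <- vapply(tree_at_t1$branches, `[[`, integer(1), "G")
  g0_1 <- max(percentile_nearest_rank(g, 0.75), 20L)
  score_params(g0_1, schedule$t, l0 = l0)
}

# nearest-rank percentile: smallest value with cumulative fraction >= p
percentile_nearest_rank <- function(x, p) {
  sort(x)[ceiling(p * length(x))]
}

#' Construct score parameters directly
#'
#' Low-level constructor for the per-threshold eligibility parameters, given
#' a `G0(1)` value and the threshold values; `compute_score_params()` is the
#' usual entry point. Supplying a single threshold with `t_max` gives the
#' parameters for one sweep position.
#'
#' @param g0_1 the `G0` value at the lowest threshold.
#' @param t vector of threshold values.
#' @param t_max top of the sweep (default `max(t)`).
#' @param l0 length requirement in voxels.
#' @return A `score_params` object.
#' @export
score_params <- function(g0_1, t, t_max = max(t), l0 = 20L) {
  g0 <- pmax(as.integer(ceiling(g0_1 * (1 - t / t_max))), 1L)
  structure(
    list(G0 = g0, N0 = 3L * g0, L0 = as.integer(l0),
         G0_1 = as.integer(g0_1), t = t, t_max = t_max),
    class = "score_params"
  )
}

#' Per-voxel branch score at one threshold
#'
#' Scores every branch of a measured tree at sweep position `j`. All voxels
#' of branch `i` share the branch score
#' `BS = max(G_i - G0(j), 0) + floor(N_i / N0(j)) + floor(L_i / L0) +
#' lambda_i`, where the longest-offspring bonus
#' `lambda_i = max over offspring p of floor(L_p / L0)` applies only when
#' `G_i < G0(j)` and `N_i < N0(j)` and the branch has offspring (so a
#' short upstream branch still inherits credit for carrying a long
#' downstream fiber).
#'
#' @param tree measured `skeleton_tree`.
#' @param params a `score_params`.
#' @param j sweep position (index into `params$G0`), default 1.
#' @return A `branch_score_field`: list with `branch_score` (integer per
#'   branch), `j`, the parameters used, and the tree's voxel membership for
#'   expansion to voxels.
#' @export
compute_branch_score <- function(tree, params, j = 1L) {
  stopifnot(inherits(tree, "skeleton_tree"), inherits(params, "score_params"))
  if (!isTRUE(tree$measured))
    stop("tree must be measured (see measure_branches)")
  g0 <- params$G0[j]; n0 <- params$N0[j]; l0 <- params$L0
  bs <- vapply(tree$branches, function(b) {
    lambda <- 0L
    if (b$G < g0 && b$N < n0 && length(b$children) > 0L)
      lambda <- as.integer(b$max_offspring_L %/% l0)
    as.integer(max(b$G - g0, 0L) + b$N %/% n0 + b$L %/% l0 + lambda)
  }, integer(1))
  structure(
    list(branch_score = bs, j = j, G0 = g0, N0 = n0, L0 = l0, tree = tree),
    class = "branch_score_field"
  )
}

#' Per-voxel values of a branch score field
#'
#' @param field a `branch_score_field`.
#' @return List with parallel vectors `index` (linear voxel indices into the
#'   traced volume) and `score`.
#' @export
branch_score_voxels <- function(field) {
  stopifnot(inherits(field, "branch_score_field"))
  idx <- lapply(field$tree$branches, `[[`, "voxel_index")
  n <- lengths(idx)
  list(index = unlist(idx, use.names = FALSE),
       score = rep(field$branch_score, n))
}

#' Accumulate the branch robustness score field
#'
#' Runs the full sweep: for each threshold `t_j` the volume is thresholded,
#' the soma component is traced and measured, every branch is scored, and
#' the per-voxel scores are summed over all thresholds into the branch
#' robustness score `BRS(k) = sum_j BS_k(j)`. High BRS marks voxels that are
#' structurally important and/or bright enough to survive many thresholds;
#' voxels never reached by any trace score 0. The eligibility parameters
#' are computed once from the tree at `t_1`.
#'
#' @param volume a [volume_image()].
#' @param soma `(z, y, x)` soma coordinate. At high thresholds where the
#'   soma voxel itself is eliminated, the nearest surviving voxel within 3
#'   voxels seeds the trace; if none survives that threshold contributes
#'   zeros (with a warning).
#' @param schedule a `threshold_schedule`.
#' @param l0 length requirement `L_0` in voxels (default 20).
#' @param connectivity voxel connectivity (default 26).
#' @param prune_length spur cutoff passed to [prune_spurs()] before each
#'   per-threshold tree is measured (default 10; 0 disables pruning).
#'   Pruning merges noise-fragmented fiber chains back into branches of
#'   their true length, which matters at the lowest thresholds where
#'   attached background fuzz makes the codelet split spuriously.
#' @return A `brs_field`: list with `values` (integer array over the
#'   volume), `schedule`, `params`, and per-threshold diagnostics
#'   (`branch_counts`).
#' @export
accumulate_brs <- function(volume, soma, schedule, l0 = 20L,
                           connectivity = 26L, prune_length = 10L) {
  stopifnot(inherits(volume, "volume_image"),
            inherits(schedule, "threshold_schedule"))
  dims <- dim(volume$data)
  brs <- array(0L, dims)
  params <- NULL
  counts <- integer(schedule$n)
  for (j in seq_len(schedule$n)) {
    tj <- schedule$t[j]
    if (tj > 2^volume$bit_depth - 1) break
    vs <- threshold_volume(volume, tj, connectivity = connectivity)
    if (length(vs) == 0L) break
    seed <- soma_seed_for(vs, soma)
    if (is.null(seed)) {
      if (j == 1L)
        stop("soma does not survive the lowest threshold")
      warning(sprintf("threshold %d: no surviving voxel near the soma; %s",
                      tj, "this threshold contributes zero scores"))
      next
    }
    tree <- trace_skeleton(vs, seed)
    if (prune_length > 0L) tree <- prune_spurs(tree, prune_length)
    tree <- measure_branches(tree)
    counts[j] <- tree$n_branches
    if (j == 1L)
      params <- compute_score_params(tree, schedule, l0 = l0)
    bsf <- compute_branch_score(tree, params, j)
    bv <- branch_score_voxels(bsf)
    nz <- bv$score > 0L
    if (any(nz))
      brs[bv$index[nz]] <- brs[bv$index[nz]] + bv$score[nz]
  }
  structure(
    list(values = brs, schedule = schedule, params = params, soma = soma,
         connectivity = connectivity, branch_counts = counts),
    class = "brs_field"
  )
}

#' @export
print.brs_field <- function(x, ...) {
  cat(sprintf("<brs_field> %s volume, max BRS %d, %d voxels scored\n",
              paste(dim(x$values), collapse = "x"), max(x$values),
              sum(x$values > 0L)))
  invisible(x)
}
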