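#' FAST skeleton tracing
#'
#' Traces the tree structure of the connected voxel component containing the
#' soma with a moving "codelet". All voxels are first coded by the geodesic
#' source field (path distance from the soma plus 1); the codelet at position
#' `i` is the connected set of voxels with source-field values in
#' `{i-1, i, i+1}`, launched at `i = 2` so that it initially covers values 1,
#' 2 and 3. The trajectory of the codelet's center of mass defines the
#' branch's central points. When the codelet splits into two or more
#' connected components the branch ends: the recorded branch point is
#' retracted two codelet steps back along the central-point trajectory, the
#' gap to each child's start point is filled with interpolated central points
#' ("local tracing"), and each component seeds a child branch. A branch ends
#' at an end point when its codelet can no longer advance. Voxels claimed by
#' an earlier branch are never re-entered, which breaks loops
#' deterministically at the meeting front.
#'
#' @param voxels a [voxel_set()] (typically from [threshold_volume()]).
#' @param soma `(z, y, x)` coordinate of the starting voxel. If it is not a
#'   member of `voxels`, the nearest member within 3 voxels is substituted
#'   (with a message); otherwise an error is raised.
#' @param b_max abort tracing once the branch count exceeds this cap (the
#'   guard used when scheduling thresholds); default unlimited.
#' @param retract branch-point retraction in codelet steps (default 2).
#' @param min_component codelet components smaller than this do not spawn a
#'   branch (suppresses single-voxel spurs); default 2.
#' @return A `skeleton_tree`: list of branches (each with `id`, `parent`,
#'   `children`, `central_points`, `start_point`, `branch_point`,
#'   `end_point`, `voxel_index`), plus `soma`, `dims`, `threshold`,
#'   `aborted` and `n_branches`. When tracing aborted at `b_max` the branch
#'   list is partial and `aborted` is `TRUE`.
#' @export
trace_skeleton <- function(voxels, soma, b_max = Inf, retract = 2L,
                           min_component = 2L) {
  stopifnot(inherits(voxels, "voxel_set"))
  if (length(voxels) == 0L) stop("cannot trace an empty voxel set")
  soma <- as.integer(soma)
  soma_idx <- vx_index(matrix(soma, ncol = 3L), voxels$dims)
  if (!soma_idx %in% voxels$index) {
    near <- nearest_member(voxels, soma, radius = 3)
    if (is.null(near))
      stop("soma is not in the voxel set and no member lies within 3 voxels")
    message(sprintf("soma (%s) not in set; using nearest member (%s)",
                    paste(soma, collapse = ","),
                    paste(near, collapse = ",")))
    soma <- near
    soma_idx <- vx_index(matrix(soma, ncol = 3L), voxels$dims)
  }
  res <- cpp_fast_trace(voxels$dims, voxels$index - 1L, soma_idx - 1L,
                        voxels$connectivity, as.double(b_max),
                        as.integer(retract), as.integer(min_component))
  branches <- lapply(res$branches, function(b) {
    colnames(b$central_points) <- c("z", "y", "x")
    b$voxel_index <- b$voxel_index + 1L
    b$children <- integer(0)
    b
  })
  for (b in branches) {
    if (b$parent > 0L)
      branches[[b$parent]]$children <-
        c(branches[[b$parent]]$children, b$id)
  }
  structure(
    list(branches = branches, root = 1L, soma = soma, dims = voxels$dims,
         connectivity = voxels$connectivity, threshold = NA_integer_,
         aborted = res$aborted, n_branches = res$n_branches,
         measured = FALSE),
    class = "skeleton_tree"
  )
}

#' @export
print.skeleton_tree <- function(x, ...) {
  nbp <- sum(vapply(x$branches, function(b) length(b$children) > 0,
                    logical(1)))
  cat(sprintf(
    "<skeleton_tree> %d branches (%d branch points), soma (%s)%s\n",
    length(x$branches), nbp, paste(x$soma, collapse = ","),
    if (isTRUE(x$aborted)) " [aborted at b_max]" else ""))
  invisible(x)
}

#' Assemble a skeleton tree from a parent table
#'
#' Builds a structurally valid `skeleton_tree` directly from branch parent
#' links and lengths, without tracing an image. Useful for constructing
#' reference hierarchies (e.g. to exercise the branch-measurement recursion
#' on a known topology).
#'
#' @param parent integer vector, `parent[i]` = id of branch `i`'s parent
#'   (0 for the root; exactly one root required).
#' @param length_ central-point count per branch (default 1 each). Central
#'   points are laid out on arbitrary straight lines; only the topology and
#'   lengths are meaningful.
#' @return A `skeleton_tree`.
#' @export
skeleton_from_parents <- function(parent, length_ = rep(1L, length(parent))) {
  parent <- as.integer(parent)
  n <- length(parent)
  stopifnot(sum(parent == 0L) == 1L, length(length_) == n, all(length_ >= 1L))
  branches <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- cbind(z = as.numeric(i), y = seq_len(length_[i]), x = 1)
    colnames(cp) <- c("z", "y", "x")
    branches[[i]] <- list(
      id = i, parent = parent[i], central_points = cp,
      start_point = cp[1L, ], branch_point = NULL,
      end_point = NULL, voxel_index = integer(0), children = integer(0))
  }
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) branches[[p]]$children <- c(branches[[p]]$children, i)
  }
  for (i in seq_len(n)) {
    if (length(branches[[i]]$children))
      branches[[i]]$branch_point <- branches[[i]]$central_points[length_[i], ]
    else
      branches[[i]]$end_point <- branches[[i]]$central_points[length_[i], ]
  }
  structure(
    list(branches = branches, root = which(parent == 0L),
         soma = c(1L, 1L, 1L), dims = c(n, max(length_), 1L) + 1L,
         connectivity = 26L, threshold = NA_integer_, aborted = FALSE,
         n_branches = n, measured = FALSE),
    class = "skeleton_tree"
  )
}

#' Branch measurements
#'
#' Populates, for every branch `i` of a traced tree, the quantities the
#' branch-score formula consumes:
#' * `G` - descendant generations: 0 for terminal branches, otherwise
#'   `max(G over children) + 1`;
#' * `N` - total number of descendant branches (the size of the offspring
#'   set);
#' * `L` - branch length as its central-point count (codelet steps, voxel
#'   units);
#' * `max_offspring_L` - the largest `L` among all offspring (0 when there
#'   are none), the ingredient of the longest-offspring bonus.
#'
#' @param tree a `skeleton_tree`.
#' @return The tree with measurement fields set and `measured = TRUE`.
#' @export
measure_branches <- function(tree) {
  stopifnot(inherits(tree, "skeleton_tree"))
  n <- length(tree$branches)
  # process children before parents: order branches by depth, deepest first
  depth <- integer(n)
  ord <- integer(n)
  k <- 0L
  stack <- tree$root
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- i
    ch <- tree$branches[[i]]$children
    if (length(ch)) {
      depth[ch] <- depth[i] + 1L
      stack <- c(stack, ch)
    }
  }
  ord <- ord[seq_len(k)]
  G <- integer(n); N <- integer(n); L <- integer(n); moL <- integer(n)
  for (i in rev(ord)) {
    b <- tree$branches[[i]]
    L[i] <- nrow(b$central_points)
    ch <- b$children
    if (length(ch) == 0L) {
      G[i] <- 0L; N[i] <- 0L; moL[i] <- 0L
    } else {
      G[i] <- max(G[ch]) + 1L
      N[i] <- sum(N[ch] + 1L)
      moL[i] <- max(L[ch], moL[ch])
    }
  }
  for (i in seq_len(n)) {
    tree$branches[[i]]$G <- G[i]
    tree$branches[[i]]$N <- N[i]
    tree$branches[[i]]$L <- L[i]
    tree$branches[[i]]$max_offspring_L <- moL[i]
  }
  tree$measured <- TRUE
  tree
}

#' Prune spurious short branches
#'
#' Codelet splitting on thick or bumpy fibers occasionally spawns short
#' terminal "spur" branches (junction pockets, surface lumps) that are not
#' part of the underlying tree topology. This removes terminal branches
#' shorter than `min_length` central points that have at least one sibling,
#' then merges any branch left with a single child into that child
#' (concatenating central points and voxel membership), repeating until
#' stable. The root is never removed. Measurements are invalidated; re-run
#' [measure_branches()] afterwards.
#'
#' @param tree a `skeleton_tree`.
#' @param min_length spur length cutoff in central points (default 10,
#'   half the default branch-length requirement of the scoring stage).
#' @return A pruned `skeleton_tree` with renumbered branch ids.
#' @export
prune_spurs <- function(tree, min_length = 10L) {
  stopifnot(inherits(tree, "skeleton_tree"))
  br <- tree$branches
  alive <- rep(TRUE, length(br))
  repeat {
    changed <- FALSE
    for (i in seq_along(br)) {
      if (!alive[i] || br[[i]]$parent == 0L) next
      if (length(br[[i]]$children) > 0L) next
      if (nrow(br[[i]]$central_points) >= min_length) next
      p <- br[[i]]$parent
      if (length(br[[p]]$children) < 2L) next   # only child: not a spur
      # drop the spur; its voxels are absorbed by the parent
      br[[p]]$voxel_index <- sort(c(br[[p]]$voxel_index,
                                    br[[i]]$voxel_index))
      br[[p]]$children <- setdiff(br[[p]]$children, i)
      alive[i] <- FALSE
      changed <- TRUE
    }
    for (i in seq_along(br)) {
      if (!alive[i] || length(br[[i]]$children) != 1L) next
      ch <- br[[i]]$children
      br[[i]]$central_points <- rbind(br[[i]]$central_points,
                                      br[[ch]]$central_points)
      br[[i]]$voxel_index <- sort(c(br[[i]]$voxel_index,
                                    br[[ch]]$voxel_index))
      br[[i]]$children <- br[[ch]]$children
      br[[i]]$branch_point <- br[[ch]]$branch_point
      br[[i]]$end_point <- br[[ch]]$end_point
      for (g in br[[ch]]$children) br[[g]]$parent <- i
      alive[ch] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  # renumber contiguously
  keep <- which(alive)
  newid <- integer(length(br))
  newid[keep] <- seq_along(keep)
  out <- lapply(keep, function(i) {
    b <- br[[i]]
    b$id <- newid[i]
    if (b$parent > 0L) b$parent <- newid[b$parent]
    b$children <- newid[b$children]
    b$G <- b$N <- b$L <- b$max_offspring_L <- NULL
    b
  })
  tree$branches <- out
  tree$root <- newid[tree$root]
  tree$n_branches <- length(out)
  tree$measured <- FALSE
  tree
}

#' Offspring set of a branch
#'
#' Ids of all descendant branches of branch `id` (its offspring set).
#'
#' @param tree a `skeleton_tree`.
#' @param id branch id.
#' @return Integer vector of descendant branch ids (empty for terminals).
#' @export
branch_descendants <- function(tree, id) {
  out <- integer(0)
  stack <- tree$branches[[id]]$children
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, tree$branches[[i]]$children)
  }
  sort(out)
}

#' Write a skeleton to SWC
#'
#' Emits one SWC record per central point, parents always before children.
#' The first record (the soma) has type 1, all others type 3 (dendrite-like
#' neurite); radius is 1.0 throughout since fiber radius is not estimated.
#' Coordinates are written as 0-based `x y z` scaled by the voxel spacing,
#' so files are readable by standard morphology tools. Each child branch's
#' first record points at its parent's last record, i.e. the retracted
#' branch point.
#'
#' @param tree a `skeleton_tree`.
#' @param path destination file path.
#' @param spacing voxel size `(z, y, x)`; defaults to isotropic 1.
#' @return Invisibly, the number of records written.
#' @export
write_swc <- function(tree, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(tree, "skeleton_tree"))
  recs <- list()
  nid <- 0L
  last_rec <- integer(length(tree$branches))  # id of branch's last record
  order_branches <- integer(0)
  stack <- tree$root
  while (length(stack)) {          # parent-before-child (DFS, deterministic)
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_branches <- c(order_branches, i)
    stack <- c(stack, rev(tree$branches[[i]]$children))
  }
  for (i in order_branches) {
    b <- tree$branches[[i]]
    cp <- b$central_points
    parent_rec <- if (b$parent == 0L) -1L else last_rec[b$parent]
    for (r in seq_len(nrow(cp))) {
      nid <- nid + 1L
      type <- if (b$parent == 0L && r == 1L) 1L else 3L
      recs[[nid]] <- c(nid, type,
                       (cp[r, "x"] - 1) * spacing[3],
                       (cp[r, "y"] - 1) * spacing[2],
                       (cp[r, "z"] - 1) * spacing[1],
                       1.0,
                       if (r == 1L) parent_rec else nid - 1L)
    }
    last_rec[i] <- nid
  }
  m <- do.call(rbind, recs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                     m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6], m[, 7]),
             con)
  invisible(nid)
}

#' Read an SWC file back into a skeleton tree
#'
#' Reconstructs the branch hierarchy from SWC records: branches are the
#' maximal unbranched record chains. The inverse of [write_swc()] up to tree
#' isomorphism (voxel membership is not stored in SWC).
#'
#' @param path SWC file path.
#' @param spacing voxel size used at write time.
#' @return A `skeleton_tree` with central points and topology only.
#' @export
read_swc <- function(path, spacing = c(1, 1, 1)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  ids <- as.integer(m[, 1]); parents <- as.integer(m[, 7])
  nchild <- tabulate(parents[parents > 0L], nbins = max(ids))
  # branch starts: root records and records whose parent has >= 2 children
  is_start <- parents == -1L | nchild[pmax(parents, 1L)] >= 2L & parents > 0L
  rec_branch <- integer(max(ids))
  branch_of_start <- which(is_start)
  nb <- length(branch_of_start)
  branches <- vector("list", nb)
  bparent <- integer(nb)
  for (bi in seq_len(nb)) {
    first <- branch_of_start[bi]
    chain <- first
    repeat {
      nxt <- ids[parents == chain[length(chain)] & !is_start]
      if (length(nxt) != 1L) break
      chain <- c(chain, nxt)
    }
    rec_branch[chain] <- bi
    cp <- cbind(z = m[chain, 5] / spacing[1] + 1,
                y = m[chain, 4] / spacing[2] + 1,
                x = m[chain, 3] / spacing[3] + 1)
    branches[[bi]] <- list(id = bi, parent = NA_integer_,
                           central_points = cp, start_point = cp[1L, ],
                           branch_point = NULL, end_point = NULL,
                           voxel_index = integer(0), children = integer(0))
    bparent[bi] <- parents[first]
  }
  for (bi in seq_len(nb)) {
    p <- bparent[bi]
    pb <- if (p == -1L) 0L else rec_branch[p]
    branches[[bi]]$parent <- pb
    if (pb > 0L) branches[[pb]]$children <- c(branches[[pb]]$children, bi)
  }
  for (bi in seq_len(nb)) {
    cp <- branches[[bi]]$central_points
    if (length(branches[[bi]]$children))
      branches[[bi]]$branch_point <- cp[nrow(cp), ]
    else
      branches[[bi]]$end_point <- cp[nrow(cp), ]
  }
  root <- which(bparent == -1L)
  soma <- round(branches[[root]]$central_points[1L, ])
  structure(
    list(branches = branches, root = root, soma = as.integer(soma),
         dims = NULL, connectivity = 26L, threshold = NA_integer_,
         aborted = FALSE, n_branches = nb, measured = FALSE),
    class = "skeleton_tree"
  )
}
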