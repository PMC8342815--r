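#' Mass-distribution properties of a voxel set
#'
#' Treats every member voxel as a unit point mass and computes the center of
#' mass, the radius of gyration (root-mean-square distance from the center),
#' and the inertia tensor's principal decomposition: principal moments
#' `I1 >= I2 >= I3` with matching orthonormal principal axes, and the
#' normalized inertia vector `(1, I2/I1, I3/I1)`. Intensities are ignored
#' throughout.
#'
#' @param voxels a [voxel_set()] or an integer matrix of `(z, y, x)` rows.
#' @return A `mass_distribution`: list with `center`, `rg`, `moments`,
#'   `inertia_vec`, `axes` (columns are the principal axes, ordered by
#'   descending moment) and `n`.
#' @export
mass_properties <- function(voxels) {
  xyz <- if (inherits(voxels, "voxel_set")) voxel_coords(voxels)
         else matrix(voxels, ncol = 3L)
  if (nrow(xyz) == 0L) stop("empty voxel set")
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ctr <- colMeans(xyz)
  d <- sweep(xyz, 2L, ctr)
  r2 <- rowSums(d^2)
  rg <- sqrt(mean(r2))
  # moment-of-inertia tensor, unit masses: I = sum(|r|^2 E - r r^T)
  it <- diag(3) * sum(r2) - crossprod(d)
  eg <- eigen(it, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  moments <- eg$values[ord]
  axes <- eg$vectors[, ord, drop = FALSE]
  iv <- if (moments[1] > 0) c(1, moments[2] / moments[1],
                              moments[3] / moments[1]) else c(1, 1, 1)
  structure(
    list(center = ctr, rg = rg, moments = moments, inertia_vec = iv,
         axes = axes, n = nrow(xyz)),
    class = "mass_distribution"
  )
}

# Sum over paired principal axes of |A_ref,i . A_test,i|, robust to
# degenerate (repeated) eigenvalues: within a degenerate block the axes are
# arbitrary up to rotation, so the block's contribution is the maximum over
# such rotations - the sum of singular values of the cross-projection of the
# paired subspaces (clipped at the block size).
axis_alignment_sum <- function(ref, test, tol = 1e-6) {
  groups <- list()
  i <- 1L
  scale_ref <- max(ref$moments[1], 1)
  scale_test <- max(test$moments[1], 1)
  while (i <= 3L) {
    j <- i
    while (j < 3L &&
           (abs(ref$moments[j] - ref$moments[j + 1]) / scale_ref < tol ||
            abs(test$moments[j] - test$moments[j + 1]) / scale_test < tol))
      j <- j + 1L
    groups[[length(groups) + 1L]] <- i:j
    i <- j + 1L
  }
  total <- 0
  for (g in groups) {
    if (length(g) == 1L) {
      total <- total + abs(sum(ref$axes[, g] * test$axes[, g]))
    } else {
      m <- crossprod(ref$axes[, g, drop = FALSE],
                     test$axes[, g, drop = FALSE])
      total <- total + sum(pmin(svd(m)$d, 1))
    }
  }
  total
}

#' Compare two segmentations
#'
#' Quantifies the agreement between a test segmentation and a reference
#' (e.g. automatic vs. human, or vs. ground truth) with four normalized
#' structural distances plus voxel overlap:
#' * `D_CM = min(1, |center_test - center_ref| / rg_ref)` - displacement of
#'   the center of mass, in units of the reference's radius of gyration;
#' * `D_RG = min(1, |rg_test - rg_ref| / rg_ref)` - size difference;
#' * `D_I  = min(1, |i_ref - i_test|)` - Euclidean distance of the
#'   normalized inertia vectors (rough-shape difference);
#' * `D_PA = 1 - sum_i |A_ref,i . A_test,i| / 3` - misalignment of the
#'   paired principal axes (sign-invariant; degenerate axes compared by
#'   subspace);
#' * recall `R = |test n ref| / |ref|` and precision
#'   `P = |test n ref| / |test|`.
#'
#' The global similarity averages the four agreements and recall:
#' `S_Global = ((1-D_RG) + (1-D_CM) + (1-D_I) + (1-D_PA) + R) / 5`.
#' Precision is deliberately excluded: an automatic segmentation keeps
#' genuinely labeled fine structure that a human rater trims, so thicker
#' fibers depress `P` without representing error; real contamination still
#' surfaces through the `D` terms.
#'
#' @param reference reference [voxel_set()] (non-empty).
#' @param test test [voxel_set()]; if empty, a report with `R = 0` and
#'   `P = NA` is returned.
#' @return A `similarity_report` with fields `D_CM`, `D_RG`, `D_I`, `D_PA`,
#'   `recall`, `precision`, `S_Global` and `gs_class`.
#' @export
compare_segmentations <- function(reference, test) {
  stopifnot(inherits(reference, "voxel_set"), inherits(test, "voxel_set"))
  if (length(reference) == 0L) stop("reference segmentation is empty")
  inter <- length(intersect(reference$index, test$index))
  recall <- inter / length(reference)
  if (length(test) == 0L) {
    rep <- structure(
      list(D_CM = 1, D_RG = 1, D_I = 1, D_PA = 1, recall = 0,
           precision = NA_real_, S_Global = 0, gs_class = "III"),
      class = "similarity_report")
    return(rep)
  }
  precision <- inter / length(test)
  mref <- mass_properties(reference)
  mtest <- mass_properties(test)
  d_cm <- min(1, sqrt(sum((mtest$center - mref$center)^2)) / mref$rg)
  d_rg <- min(1, abs(mtest$rg - mref$rg) / mref$rg)
  d_i <- min(1, sqrt(sum((mref$inertia_vec - mtest$inertia_vec)^2)))
  d_pa <- 1 - axis_alignment_sum(mref, mtest) / 3
  d_pa <- min(1, max(0, d_pa))
  s <- ((1 - d_rg) + (1 - d_cm) + (1 - d_i) + (1 - d_pa) + recall) / 5
  rep <- structure(
    list(D_CM = d_cm, D_RG = d_rg, D_I = d_i, D_PA = d_pa,
         recall = recall, precision = precision, S_Global = s,
         gs_class = NA_character_),
    class = "similarity_report")
  rep$gs_class <- classify_similarity(rep)
  rep
}

#' Global-similarity class
#'
#' Bins a comparison into the published quality classes: Class I for
#' `S_Global >= 0.9` (a perfect match, `S_Global = 1`, is Class I), Class II
#' for `0.7 <= S_Global < 0.9`, Class III below 0.7.
#'
#' @param report a `similarity_report` (or a bare `S_Global` number).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_similarity <- function(report) {
  s <- if (inherits(report, "similarity_report")) report$S_Global
       else as.numeric(report)
  if (s >= 0.9) "I" else if (s >= 0.7) "II" else "III"
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    paste0("<similarity_report> S_Global = %.4f (Class %s)\n",
           "  D_CM=%.4f D_RG=%.4f D_I=%.4f D_PA=%.4f ",
           "recall=%.4f precision=%s\n"),
    x$S_Global, x$gs_class, x$D_CM, x$D_RG, x$D_I, x$D_PA, x$recall,
    ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision))))
  invisible(x)
}

#' Similarity report as a table row
#'
#' @param report a `similarity_report`.
#' @param id identifier for the row.
#' @return One-row data frame with columns id, D_CM, D_RG, D_I, D_PA,
#'   recall, precision, S_Global, class.
#' @export
similarity_row <- function(report, id = "pair") {
  data.frame(id = id, D_CM = report$D_CM, D_RG = report$D_RG,
             D_I = report$D_I, D_PA = report$D_PA, recall = report$recall,
             precision = report$precision, S_Global = report$S_Global,
             class = report$gs_class, stringsAsFactors = FALSE)
}

#' Write similarity reports to a TSV summary
#'
#' @param reports list of `similarity_report`s (or a single one).
#' @param path destination file.
#' @param ids row identifiers.
#' @export
write_similarity_tsv <- function(reports, path, ids = NULL) {
  if (inherits(reports, "similarity_report")) reports <- list(reports)
  if (is.null(ids)) ids <- as.character(seq_along(reports))
  df <- do.call(rbind, Map(similarity_row, reports, ids))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
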