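# Wrappers around the compiled matrix builders. Each takes a
# discretized_lesion and returns the matrix family in the form the feature
# formulas consume.

.EPS <- 2.220446049250313e-16  # smallest relative spacing; keeps log2(0) finite

#' Grey-level co-occurrence matrices
#'
#' Counts ordered voxel pairs (both inside the mask) for each of the 13
#' unique 3-D direction offsets at Chebyshev distance `distance`, then
#' symmetrises (adds the transpose) and normalises each per-angle matrix to
#' sum 1. Features are evaluated per angle and averaged, so the angles are
#' kept separate here.
#'
#' @param d A [discretize()]d lesion.
#' @param distance Integer offset distance (default 1).
#' @return List with `counts` (Ng x Ng x 13 raw ordered counts) and
#'   `P` (list of normalised symmetric per-angle matrices; angles with no
#'   voxel pairs are `NULL`).
#' @export
compute_glcm <- function(d, distance = 1) {
  stopifnot(inherits(d, "discretized_lesion"))
  arr <- level_array(d)
  counts <- cpp_glcm_counts(arr, dim(arr), d$ng, as.integer(distance))
  P <- vector("list", 13L)
  for (a in seq_len(13L)) {
    C <- counts[, , a, drop = FALSE]
    dim(C) <- c(d$ng, d$ng)
    s <- sum(C)
    if (s > 0) {
      M <- C + t(C)
      P[[a]] <- M / sum(M)
    }
  }
  list(counts = counts, P = P)
}

#' Grey-level run-length matrices
#'
#' Maximal runs of equal level along mask-internal collinear voxel
#' sequences, one matrix per direction; out-of-mask voxels break runs.
#'
#' @param d A [discretize()]d lesion.
#' @return List with `counts` (Ng x maxlen x 13) and `n_voxels`.
#' @export
compute_glrlm <- function(d) {
  stopifnot(inherits(d, "discretized_lesion"))
  arr <- level_array(d)
  counts <- cpp_glrlm_counts(arr, dim(arr), d$ng)
  list(counts = counts, n_voxels = length(d$levels))
}

#' Grey-level size-zone matrix
#'
#' 26-connected components of iso-level voxels, counted by (level, zone
#' size); direction-free.
#'
#' @param d A [discretize()]d lesion.
#' @return List with `zones` (data.frame level, size, count) and `n_voxels`.
#' @export
compute_glszm <- function(d) {
  stopifnot(inherits(d, "discretized_lesion"))
  arr <- level_array(d)
  lab <- cpp_label26(arr, dim(arr), TRUE)
  ids <- lab[lab > 0L]
  lv <- arr[lab > 0L]
  sizes <- tabulate(ids)
  zlev <- vapply(split(lv, ids), function(v) v[[1]], 0L)
  tab <- table(level = zlev, size = sizes)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  list(zones = data.frame(level = as.integer(df$level),
                          size = as.integer(df$size),
                          count = as.numeric(df$Freq)),
       n_voxels = length(d$levels), ng = d$ng)
}

#' Grey-level dependence matrix
#'
#' For each voxel the dependence is the number of in-mask 26-neighbours
#' whose level differs by at most `alpha`; counts are indexed
#' (level, dependence + 1).
#'
#' @param d A [discretize()]d lesion.
#' @param alpha Level-difference tolerance (default 0).
#' @return List with `counts` (Ng x 27) and `n_voxels`.
#' @export
compute_gldm <- function(d, alpha = 0) {
  stopifnot(inherits(d, "discretized_lesion"))
  arr <- level_array(d)
  list(counts = cpp_gldm_counts(arr, dim(arr), d$ng, as.numeric(alpha)),
       n_voxels = length(d$levels))
}

#' Neighbouring grey-tone difference matrix
#'
#' For every voxel with at least one in-mask 26-neighbour, accumulates
#' `|level - mean neighbour level|` into its level's row. Returns per-level
#' triples (n_i, p_i, s_i).
#'
#' @param d A [discretize()]d lesion.
#' @return List with `n` (per-level voxel counts), `p` (n / sum(n)), `s`
#'   (summed absolute differences), `n_valid` (voxels with >= 1 neighbour).
#' @export
compute_ngtdm <- function(d) {
  stopifnot(inherits(d, "discretized_lesion"))
  arr <- level_array(d)
  m <- cpp_ngtdm_counts(arr, dim(arr), d$ng)
  nvec <- m[, 1]
  nv <- sum(nvec)
  list(n = nvec, p = if (nv > 0) nvec / nv else nvec, s = m[, 2],
       n_valid = nv)
}
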