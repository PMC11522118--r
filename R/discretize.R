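#' Discretize a lesion's intensities into grey levels
#'
#' Fixed-bin-width binning anchored at the lesion's minimum intensity: voxel
#' with intensity x gets level `floor((x - min) / bin_width) + 1`, so level i
#' covers the half-open interval `[min + (i-1) w, min + i w)` and the number
#' of levels is `Ng = floor((max - min) / bin_width) + 1`. No resampling or
#' normalisation is applied beforehand: CT Hounsfield units are already
#' calibrated.
#'
#' @param region A [lesion_region()].
#' @param bin_width Bin width in HU (> 0); default 25.
#' @return An object of class `discretized_lesion` with elements `levels`
#'   (per-voxel integer level), `ng`, `bin_width`, `bin_edges` (Ng x 2),
#'   `coords`.
#' @export
discretize <- function(region, bin_width = 25) {
  if (!inherits(region, "lesion_region"))
    stop("`region` must be a lesion_region")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single value > 0")
  x <- region$intensities
  lo <- min(x)
  levels <- as.integer(floor((x - lo) / bin_width)) + 1L
  ng <- as.integer(floor((max(x) - lo) / bin_width)) + 1L
  # guard against floating-point edge where max lands exactly on an edge
  ng <- max(ng, max(levels))
  edges <- cbind(lo + (seq_len(ng) - 1) * bin_width,
                 lo + seq_len(ng) * bin_width)
  colnames(edges) <- c("lo", "hi")
  structure(list(levels = levels, ng = ng, bin_width = bin_width,
                 bin_edges = edges, coords = region$coords),
            class = "discretized_lesion")
}

# Dense level grid over the lesion bounding box; 0 outside the mask.
level_array <- function(d) {
  stopifnot(inherits(d, "discretized_lesion"))
  lo <- apply(d$coords, 2L, min)
  rel <- sweep(d$coords, 2L, lo) + 1L
  dims <- apply(rel, 2L, max)
  arr <- array(0L, dims)
  arr[cbind(rel[, 1], rel[, 2], rel[, 3])] <- d$levels
  arr
}
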