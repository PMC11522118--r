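# Naive brute-force oracles, written independently of the package's
# compiled matrix builders: plain R loops over voxels, used to verify the
# texture matrices on small grids.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

NEIGH26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

grid_get <- function(grid, p) {
  d <- dim(grid)
  if (any(p < 1) || any(p > d)) return(0L)
  grid[p[1], p[2], p[3]]
}

# ordered co-occurrence counts for one direction
bf_glcm <- function(grid, ng, off) {
  counts <- matrix(0, ng, ng)
  d <- dim(grid)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- grid[x, y, z]
    if (li <= 0) next
    lj <- grid_get(grid, c(x, y, z) + off)
    if (lj > 0) counts[li, lj] <- counts[li, lj] + 1
  }
  counts
}

# maximal runs for one direction: matrix (level, length) counts
bf_glrlm <- function(grid, ng, off) {
  d <- dim(grid)
  counts <- matrix(0, ng, max(d))
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- grid[x, y, z]
    if (li <= 0) next
    if (grid_get(grid, c(x, y, z) - off) == li) next  # not a run start
    len <- 1
    p <- c(x, y, z) + off
    while (grid_get(grid, p) == li) {
      len <- len + 1
      p <- p + off
    }
    counts[li, len] <- counts[li, len] + 1
  }
  counts
}

# 26-connected iso-level zones via BFS: data.frame(level, size) one row/zone
bf_zones <- function(grid) {
  d <- dim(grid)
  seen <- array(FALSE, d)
  out <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (seen[x, y, z] || grid[x, y, z] <= 0) next
    li <- grid[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(NEIGH26))) {
        q <- p + NEIGH26[k, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && grid[q[1], q[2], q[3]] == li) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    out[[length(out) + 1]] <- data.frame(level = li, size = size)
  }
  if (!length(out)) return(data.frame(level = integer(), size = integer()))
  do.call(rbind, out)
}

bf_gldm <- function(grid, ng, alpha = 0) {
  d <- dim(grid)
  counts <- matrix(0, ng, 27)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- grid[x, y, z]
    if (li <= 0) next
    dep <- 0
    for (k in seq_len(nrow(NEIGH26))) {
      lj <- grid_get(grid, c(x, y, z) + NEIGH26[k, ])
      if (lj > 0 && abs(li - lj) <= alpha) dep <- dep + 1
    }
    counts[li, dep + 1] <- counts[li, dep + 1] + 1
  }
  counts
}

bf_ngtdm <- function(grid, ng) {
  d <- dim(grid)
  nvec <- numeric(ng); svec <- numeric(ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- grid[x, y, z]
    if (li <= 0) next
    nb <- c()
    for (k in seq_len(nrow(NEIGH26))) {
      lj <- grid_get(grid, c(x, y, z) + NEIGH26[k, ])
      if (lj > 0) nb <- c(nb, lj)
    }
    if (!length(nb)) next
    nvec[li] <- nvec[li] + 1
    svec[li] <- svec[li] + abs(li - mean(nb))
  }
  matrix(c(nvec, svec), ncol = 2)
}

# region whose discretized levels reproduce `grid` exactly (bin width 25)
region_from_grid <- function(grid, spacing = c(1, 1, 1), patient = "p") {
  idx <- which(grid > 0)
  stopifnot(length(idx) > 0)
  co <- arrayInd(idx, dim(grid)) - 1L
  lesion_region(1L, patient, (grid[idx] - min(grid[idx])) * 25,
                co, spacing)
}

# dense level grid reconstructed from a discretized lesion
grid_from_disc <- function(d) {
  lo <- apply(d$coords, 2, min)
  rel <- sweep(d$coords, 2, lo) + 1L
  arr <- array(0L, apply(rel, 2, max))
  arr[rel] <- d$levels
  arr
}

random_level_grid <- function(max_dim = 3, max_ng = 3) {
  repeat {
    dims <- sample.int(max_dim, 3, replace = TRUE)
    g <- array(sample(0:max_ng, prod(dims), replace = TRUE), dims)
    if (any(g > 0)) return(g)
  }
}

# independent Welch t recomputation
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all rank assignments
wilcox_exact_oracle <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combs <- combn(n, length(a))
  ws <- apply(combs, 2, function(ix) sum(r[ix])) -
    length(a) * (length(a) + 1) / 2
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# small helper: region filled with given intensities on a full box
box_region <- function(intensities, dims, spacing = c(1, 1, 1),
                       patient = "p", lesion = 1L) {
  co <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                              0:(dims[3] - 1)))
  # expand.grid varies the first factor fastest, matching R array order
  lesion_region(lesion, patient, intensities, co, spacing)
}
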