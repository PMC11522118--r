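test_that("discretization uses half-open fixed-width bins anchored at the minimum", {
  r <- box_region(c(0, 10, 24, 25), c(4, 1, 1))
  d <- discretize(r, 25)
  expect_equal(d$levels, c(1L, 1L, 1L, 2L))
  expect_equal(d$ng, 2L)

  rc <- box_region(rep(42, 8), c(2, 2, 2))
  dc <- discretize(rc, 25)
  expect_equal(dc$ng, 1L)
  expect_true(all(dc$levels == 1L))

  rn <- box_region(c(-10, 40), c(2, 1, 1))
  dn <- discretize(rn, 25)
  expect_equal(dn$levels, c(1L, 3L))
  expect_equal(dn$ng, 3L)

  expect_error(discretize(r, 0), "bin_width")
})

test_that("GLCM matches hand-enumerated pairs and is symmetric stochastic", {
  # 2x2x1 levels [[1,1],[1,2]], in-plane offset (0,1,0): two ordered pairs
  # (1,1) and (1,2); symmetrised and normalised -> [[.5,.25],[.25,0]]
  r <- box_region(c(0, 0, 0, 30), c(2, 2, 1))
  g <- compute_glcm(discretize(r, 25))
  expect_equal(g$P[[2]], matrix(c(.5, .25, .25, 0), 2), tolerance = 1e-12)

  rc <- box_region(rep(5, 27), c(3, 3, 3))
  gc <- compute_glcm(discretize(rc, 25))
  expect_equal(gc$P[[1]], matrix(1, 1, 1))
  f <- compute_features(rc)
  expect_equal(unname(f["original_glcm_JointEntropy"]), 0)
  expect_equal(unname(f["original_glcm_Correlation"]), 1)

  # per-angle matrices are exactly symmetric and sum to 1
  set.seed(3)
  rr <- box_region(rnorm(60, 0, 40), c(5, 4, 3))
  gg <- compute_glcm(discretize(rr, 25))
  for (P in gg$P) {
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
  }
})

test_that("level-permutation leaves level-symmetric GLCM features unchanged", {
  set.seed(4)
  lev <- sample(1:3, 36, TRUE)
  r1 <- box_region((lev - 1) * 25, c(4, 3, 3))
  perm <- c(3L, 1L, 2L)
  r2 <- box_region((perm[lev] - 1) * 25, c(4, 3, 3))
  f1 <- compute_features(r1)
  f2 <- compute_features(r2)
  expect_equal(f1["original_glcm_JointEntropy"],
               f2["original_glcm_JointEntropy"], tolerance = 1e-12)
  expect_equal(f1["original_glcm_JointEnergy"],
               f2["original_glcm_JointEnergy"], tolerance = 1e-12)
})

test_that("GLRLM counts maximal runs and RunPercentage behaves", {
  # 1x4x1 levels [1,1,2,2] along y
  r <- box_region(c(0, 0, 30, 30), c(1, 4, 1))
  rl <- compute_glrlm(discretize(r, 25))
  ang_y <- rl$counts[, , 2]  # direction (0,1,0)
  expect_equal(ang_y[1, 2], 1)  # level 1, run length 2
  expect_equal(ang_y[2, 2], 1)
  expect_equal(sum(ang_y), 2)

  rconst <- box_region(rep(7, 5), c(1, 5, 1))
  counts <- compute_glrlm(discretize(rconst, 25))$counts
  ang <- counts[, , 2]
  expect_equal(sum(ang), 1)        # one single run along y
  expect_equal(unname(ang[5]), 1)  # of length 5
  expect_equal(sum(ang) / 5, 1 / 5)  # run percentage 1/5

  ralt <- box_region(c(0, 30, 0, 30), c(1, 4, 1))
  counts_alt <- compute_glrlm(discretize(ralt, 25))$counts
  expect_equal(sum(counts_alt[, 1, 2]), 4)  # four runs of length 1
  expect_equal(sum(counts_alt[, , 2]), 4)   # RP = 4/4 = 1 along y
})

test_that("GLSZM zones follow 26-connectivity", {
  g <- array(0L, c(3, 3, 1))
  g[1, 1, 1] <- 1L
  g[2, 2, 1] <- 1L  # diagonal touch -> same zone
  z <- compute_glszm(discretize(region_from_grid(g), 25))
  expect_equal(z$zones$size, 2L)
  expect_equal(z$zones$count, 1)

  rconst <- box_region(rep(1, 24), c(4, 3, 2))
  zc <- compute_glszm(discretize(rconst, 25))
  expect_equal(zc$zones, data.frame(level = 1L, size = 24L, count = 1))

  # checkerboard 2x2x1: each level pair is diagonal, hence 26-connected
  chk <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  zk <- compute_glszm(discretize(region_from_grid(chk), 25))
  expect_equal(zk$zones$size, c(2L, 2L))
  expect_equal(sum(zk$zones$count), 2)
})

test_that("GLDM dependence counts neighbours within the level tolerance", {
  rone <- lesion_region(1, "p", 50, cbind(0, 0, 0), c(1, 1, 1))
  g1 <- compute_gldm(discretize(rone, 25))
  expect_equal(g1$counts[1, 1], 1)  # dependence 0 -> column 1
  expect_equal(sum(g1$counts), 1)

  rplane <- box_region(rep(10, 9), c(3, 3, 1))
  gp <- compute_gldm(discretize(rplane, 25))
  expect_equal(gp$counts[1, 9], 1)  # centre voxel: 8 dependent neighbours

  # alpha large enough: dependence = in-mask neighbour count for all voxels
  set.seed(5)
  r <- box_region(rnorm(27, 0, 50), c(3, 3, 3))
  d <- discretize(r, 25)
  ga <- compute_gldm(d, alpha = d$ng)
  gd_all <- colSums(ga$counts)
  # centre has 26 neighbours, corners 7
  expect_equal(gd_all[27], 1)
  expect_equal(gd_all[8], 8)
})

test_that("NGTDM accumulates |level - mean neighbour level|", {
  r <- box_region(c(0, 25, 0), c(1, 3, 1))  # levels 1,2,1
  nt <- compute_ngtdm(discretize(r, 25))
  expect_equal(nt$s[2], 1)        # centre: |2 - 1| = 1
  expect_equal(nt$s[1], 2)        # each end sees only the centre: |1 - 2|
  expect_equal(nt$n, c(2, 1))
  f <- compute_features(box_region(rep(3, 27), c(3, 3, 3)))
  expect_equal(unname(f["original_ngtdm_Contrast"]), 0)
  expect_equal(unname(f["original_ngtdm_Coarseness"]), 1e6)
})

test_that("all five matrices equal brute-force enumeration on random small grids", {
  set.seed(42)
  for (rep in 1:120) {
    g <- random_level_grid()
    d <- discretize(region_from_grid(g), 25)
    grid <- grid_from_disc(d)
    ng <- d$ng
    glcm <- compute_glcm(d)$counts
    rl <- compute_glrlm(d)$counts
    for (a in seq_len(13)) {
      expect_equal(matrix(glcm[, , a], ng), bf_glcm(grid, ng, DIRS13[a, ]))
      bf <- bf_glrlm(grid, ng, DIRS13[a, ])
      got <- matrix(rl[, , a], ng)
      expect_equal(got[, seq_len(ncol(bf)), drop = FALSE], bf)
      if (ncol(got) > ncol(bf))
        expect_true(all(got[, -seq_len(ncol(bf))] == 0))
    }
    zo <- compute_glszm(d)$zones
    bfz <- bf_zones(grid)
    got_tab <- zo[rep(seq_len(nrow(zo)), zo$count), c("level", "size")]
    expect_equal(
      got_tab[order(got_tab$level, got_tab$size), ],
      bfz[order(bfz$level, bfz$size), ], ignore_attr = TRUE)
    expect_equal(unname(compute_gldm(d)$counts), unname(bf_gldm(grid, ng)))
    nt <- compute_ngtdm(d)
    bfn <- bf_ngtdm(grid, ng)
    expect_equal(nt$n, bfn[, 1])
    expect_equal(nt$s, bfn[, 2])
  }
})

test_that("matrix mass is conserved", {
  set.seed(9)
  r <- box_region(rnorm(4 * 5 * 3, 0, 40), c(4, 5, 3))
  d <- discretize(r, 25)
  n <- length(d$levels)
  rl <- compute_glrlm(d)$counts
  lens <- seq_len(dim(rl)[2])
  for (a in seq_len(13))
    expect_equal(sum(t(matrix(rl[, , a], dim(rl)[1])) * lens), n)
  z <- compute_glszm(d)
  expect_equal(sum(z$zones$size * z$zones$count), n)
  expect_equal(sum(compute_gldm(d)$counts), n)
})

test_that("features are invariant to intensity shifts and axis permutations", {
  set.seed(10)
  vals <- rnorm(5^3, 100, 35)
  r1 <- box_region(vals, c(5, 5, 5))
  f1 <- compute_features(r1)
  # shift by a multiple of the bin width
  f2 <- compute_features(box_region(vals + 75, c(5, 5, 5)))
  expect_equal(f1, f2, tolerance = 1e-12)
  # axis permutation of a cubic lesion
  arr <- array(vals, c(5, 5, 5))
  perm <- aperm(arr, c(3, 1, 2))
  f3 <- compute_features(box_region(as.vector(perm), c(5, 5, 5)))
  expect_equal(f1, f3, tolerance = 1e-9)
})

test_that("every valid region yields 75 finite canonical features", {
  expect_length(feature_names(), 75L)
  set.seed(12)
  regions <- list(
    box_region(rnorm(40, 0, 30), c(4, 5, 2)),
    lesion_region(1, "p", 50, cbind(0, 0, 0), c(1, 1, 1)),   # single voxel
    box_region(rep(9, 12), c(3, 2, 2)),                      # flat
    box_region(c(-100, 200, rnorm(25, 0, 80)), c(3, 3, 3)))  # wide range
  for (r in regions) {
    f <- compute_features(r)
    expect_identical(names(f), feature_names())
    expect_true(all(is.finite(f)))
  }
})

test_that("extraction config round-trips through the key-value file", {
  cfg <- texture_config(bin_width = 10, distance = 2, gldm_alpha = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$bin_width, 10)
  expect_equal(back$distance, 2L)
  expect_equal(back$gldm_alpha, 1)
})
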