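# The canonical 75-feature second-order set: 24 GLCM + 16 GLRLM + 16 GLSZM
# + 14 GLDM + 5 NGTDM, named original_<family>_<Feature>. Formulas follow
# the image-biomarker reference definitions; angle-dependent families
# (GLCM, GLRLM) evaluate every feature per angle and average over the 13
# angles. Degenerate cases (flat textures, single voxels) follow the
# documented cap policies and never produce NaN.

.GLCM_FEATURES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

.GLRLM_FEATURES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

.GLSZM_FEATURES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

.GLDM_FEATURES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

.NGTDM_FEATURES <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                     "Strength")

#' Canonical feature names
#'
#' The 75 second-order feature names in canonical order, prefixed
#' `original_<family>_`.
#'
#' @param family Optional subset: one of `"glcm"`, `"glrlm"`, `"glszm"`,
#'   `"gldm"`, `"ngtdm"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(family = NULL) {
  all <- c(paste0("original_glcm_", .GLCM_FEATURES),
           paste0("original_glrlm_", .GLRLM_FEATURES),
           paste0("original_glszm_", .GLSZM_FEATURES),
           paste0("original_gldm_", .GLDM_FEATURES),
           paste0("original_ngtdm_", .NGTDM_FEATURES))
  if (is.null(family)) return(all)
  family <- match.arg(family, c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  all[startsWith(all, paste0("original_", family, "_"))]
}

#' Texture extraction configuration
#'
#' Bundles the tunable discretization and matrix parameters so they can be
#' serialized next to every output for provenance.
#'
#' @param bin_width Discretization bin width in HU (default 25).
#' @param distance GLCM pair offset distance in voxels (default 1).
#' @param gldm_alpha GLDM level-difference tolerance (default 0).
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(bin_width = 25, distance = 1, gldm_alpha = 0) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  if (distance < 1 || distance != round(distance))
    stop("`distance` must be a positive integer")
  if (gldm_alpha < 0) stop("`gldm_alpha` must be >= 0")
  structure(list(bin_width = bin_width, distance = as.integer(distance),
                 gldm_alpha = gldm_alpha, connectivity = 26L),
            class = "texture_config")
}

# --- GLCM ------------------------------------------------------------------

# One symmetric normalised Ng x Ng matrix -> named numeric(24)
glcm_features_one <- function(P) {
  ng <- nrow(P)
  lev <- seq_len(ng)
  i <- matrix(lev, ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(lev * px)
  muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px))
  sigy <- sqrt(sum((lev - muy)^2 * py))

  s <- i + j
  dk <- abs(i - j)
  ks <- 2:(2 * ng)
  kd <- 0:(ng - 1)
  pplus <- vapply(ks, function(k) sum(P[s == k]), 0)
  pminus <- vapply(kd, function(k) sum(P[dk == k]), 0)

  ent <- function(w, q = w) -sum(w[q > 0] * log2(q[q > 0]))
  hx <- ent(px)
  hy <- ent(py)
  hxy <- ent(P)
  pxy <- outer(px, py)
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)

  da <- sum(kd * pminus)

  corr <- if (sigx * sigy == 0) 1 else
    (sum(i * j * P) - mux * muy) / (sigx * sigy)

  mcc <- if (ng == 1L) 1 else {
    A <- P / (px + .EPS)            # rows scaled by px
    C <- t(t(P) / (py + .EPS))      # cols scaled by py
    ev <- sort(Re(eigen(A %*% t(C), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }

  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((s - mux - muy)^4 * P),
    ClusterShade = sum((s - mux - muy)^3 * P),
    ClusterTendency = sum((s - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pminus),
    DifferenceVariance = sum((kd - da)^2 * pminus),
    Id = sum(pminus / (1 + kd)),
    Idm = sum(pminus / (1 + kd^2)),
    Idmn = sum(pminus / (1 + kd^2 / ng^2)),
    Idn = sum(pminus / (1 + kd / ng)),
    Imc1 = if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy),
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = if (ng == 1L) 0 else
      sum(pminus[-1] / kd[-1]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * pplus),
    SumEntropy = ent(pplus),
    SumSquares = sum((i - mux)^2 * P))
}

glcm_features <- function(glcm, d) {
  valid <- Filter(Negate(is.null), glcm$P)
  if (length(valid) == 0L) {
    # no voxel pair in any direction: treat as perfectly autocorrelated
    # texture with the observed level frequencies
    p <- tabulate(d$levels, d$ng) / length(d$levels)
    valid <- list(diag(p, nrow = d$ng))
  }
  fmat <- vapply(valid, glcm_features_one,
                 numeric(length(.GLCM_FEATURES)))
  stats::setNames(rowMeans(fmat), paste0("original_glcm_", .GLCM_FEATURES))
}

# --- run-length / size-zone shared core ------------------------------------

# counts: vectors level i, size/length jj, count c; np: voxel count
rlsz_features_core <- function(ii, jj, cc, np) {
  nr <- sum(cc)
  p <- cc / nr
  gl <- tapply(cc, ii, sum)          # per-level totals
  sz <- tapply(cc, jj, sum)          # per-size totals
  glp <- gl / nr
  szp <- sz / nr
  glv <- as.numeric(names(gl))
  szv <- as.numeric(names(sz))
  mug <- sum(glv * glp)
  mus <- sum(szv * szp)
  list(
    GrayLevelNonUniformity = sum(gl^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gl^2) / nr^2,
    GrayLevelVariance = sum((glv - mug)^2 * glp),
    HighGrayLevel = sum(cc * ii^2) / nr,
    Long = sum(cc * jj^2) / nr,
    LongHigh = sum(cc * ii^2 * jj^2) / nr,
    LongLow = sum(cc * jj^2 / ii^2) / nr,
    LowGrayLevel = sum(cc / ii^2) / nr,
    Entropy = -sum(p * log2(p)),
    SizeNonUniformity = sum(sz^2) / nr,
    SizeNonUniformityNormalized = sum(sz^2) / nr^2,
    Percentage = nr / np,
    SizeVariance = sum((szv - mus)^2 * szp),
    Short = sum(cc / jj^2) / nr,
    ShortHigh = sum(cc * ii^2 / jj^2) / nr,
    ShortLow = sum(cc / (ii^2 * jj^2)) / nr)
}

glrlm_features <- function(glrlm) {
  counts <- glrlm$counts
  ng <- dim(counts)[1]
  ml <- dim(counts)[2]
  feats <- matrix(NA_real_, length(.GLRLM_FEATURES), 0)
  for (a in seq_len(13L)) {
    C <- counts[, , a]
    dim(C) <- c(ng, ml)
    nz <- which(C > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) next
    co <- rlsz_features_core(nz[, 1], nz[, 2], C[nz], glrlm$n_voxels)
    feats <- cbind(feats, c(
      co$GrayLevelNonUniformity, co$GrayLevelNonUniformityNormalized,
      co$GrayLevelVariance, co$HighGrayLevel, co$Long, co$LongHigh,
      co$LongLow, co$LowGrayLevel, co$Entropy, co$SizeNonUniformity,
      co$SizeNonUniformityNormalized, co$Percentage, co$SizeVariance,
      co$Short, co$ShortHigh, co$ShortLow))
  }
  stats::setNames(rowMeans(feats),
                  paste0("original_glrlm_", .GLRLM_FEATURES))
}

glszm_features <- function(glszm) {
  z <- glszm$zones
  co <- rlsz_features_core(z$level, z$size, z$count, glszm$n_voxels)
  stats::setNames(c(
    co$GrayLevelNonUniformity, co$GrayLevelNonUniformityNormalized,
    co$GrayLevelVariance, co$HighGrayLevel, co$Long, co$LongHigh,
    co$LongLow, co$LowGrayLevel, co$SizeNonUniformity,
    co$SizeNonUniformityNormalized, co$Short, co$ShortHigh, co$ShortLow,
    co$Entropy, co$Percentage, co$SizeVariance),
    paste0("original_glszm_", .GLSZM_FEATURES))
}

gldm_features <- function(gldm) {
  C <- gldm$counts
  nz <- which(C > 0, arr.ind = TRUE)
  co <- rlsz_features_core(nz[, 1], nz[, 2], C[nz], gldm$n_voxels)
  stats::setNames(c(
    co$Entropy, co$SizeNonUniformity, co$SizeNonUniformityNormalized,
    co$SizeVariance, co$GrayLevelNonUniformity, co$GrayLevelVariance,
    co$HighGrayLevel, co$Long, co$LongHigh, co$LongLow, co$LowGrayLevel,
    co$Short, co$ShortHigh, co$ShortLow),
    paste0("original_gldm_", .GLDM_FEATURES))
}

# --- NGTDM -----------------------------------------------------------------

ngtdm_features <- function(ngtdm) {
  nvp <- ngtdm$n_valid
  nm <- paste0("original_ngtdm_", .NGTDM_FEATURES)
  if (nvp == 0) {
    # no voxel has an in-mask neighbour: flat-texture caps
    return(stats::setNames(c(0, 1e6, 0, 0, 0), nm))
  }
  p <- ngtdm$p
  s <- ngtdm$s
  lev <- seq_along(p)
  pr <- p > 0
  ngp <- sum(pr)
  pi_ <- p[pr]; si <- s[pr]; li <- lev[pr]

  den_coarse <- sum(pi_ * si)
  coarseness <- if (den_coarse == 0) 1e6 else 1 / den_coarse

  contrast <- if (ngp <= 1L) 0 else {
    sum(outer(pi_, pi_) * outer(li, li, "-")^2) / (ngp * (ngp - 1)) *
      sum(si) / nvp
  }

  den_busy <- sum(abs(outer(li * pi_, li * pi_, "-")))
  busyness <- if (den_busy == 0) 0 else sum(pi_ * si) / den_busy

  complexity <- sum(abs(outer(li, li, "-")) *
                      (outer(pi_ * si, pi_ * si, "+")) /
                      outer(pi_, pi_, "+")) / nvp

  den_str <- sum(si)
  strength <- if (den_str == 0) 0 else
    sum(outer(pi_, pi_, "+") * outer(li, li, "-")^2) / den_str

  stats::setNames(c(busyness, coarseness, complexity, contrast, strength),
                  nm)
}

# --- top level -------------------------------------------------------------

#' Compute the 75 second-order texture features of a lesion
#'
#' Discretizes the lesion and evaluates all five matrix families: 24 GLCM,
#' 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features, in canonical order.
#' All values are finite; flat or otherwise degenerate textures follow the
#' documented cap policies (e.g. NGTDM Coarseness capped at 1e6, GLCM
#' Correlation 1 on a single grey level).
#'
#' @param region A [lesion_region()].
#' @param config A [texture_config()].
#' @return Named numeric vector of length 75.
#' @export
compute_features <- function(region, config = texture_config()) {
  if (!inherits(config, "texture_config"))
    stop("`config` must be a texture_config")
  d <- discretize(region, config$bin_width)
  out <- c(
    glcm_features(compute_glcm(d, config$distance), d),
    glrlm_features(compute_glrlm(d)),
    glszm_features(compute_glszm(d)),
    gldm_features(compute_gldm(d, config$gldm_alpha)),
    ngtdm_features(compute_ngtdm(d)))
  stopifnot(identical(names(out), feature_names()))
  if (any(!is.finite(out)))
    stop("non-finite feature value for lesion ", region$lesion_id,
         ": ", paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract features for a list of lesion regions
#'
#' @param regions List of [lesion_region()] objects.
#' @param config A [texture_config()].
#' @return Data.frame: `patient_id`, `lesion_id`, then the 75 features.
#' @export
extract_features <- function(regions, config = texture_config()) {
  if (length(regions) == 0L) {
    df <- as.data.frame(setNames(
      rep(list(numeric(0)), 2L + 75L),
      c("patient_id", "lesion_id", feature_names())))
    df$patient_id <- character(0)
    return(df)
  }
  feat <- t(vapply(regions, compute_features, numeric(75L),
                   config = config))
  df <- data.frame(
    patient_id = vapply(regions, function(r) r$patient_id, ""),
    lesion_id = vapply(regions, function(r) r$lesion_id, 0L),
    stringsAsFactors = FALSE)
  cbind(df, as.data.frame(feat))
}

#' Write / read a texture extraction config as a flat key-value file
#' @param config A [texture_config()].
#' @param path Output path.
#' @return `path` invisibly (write); a [texture_config()] (read).
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(unclass(config)),
                     vapply(unclass(config), format, "")), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  texture_config(bin_width = as.numeric(vals[["bin_width"]]),
                 distance = as.integer(vals[["distance"]]),
                 gldm_alpha = as.numeric(vals[["gldm_alpha"]]))
}
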