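# Synthetic two-cohort lesion phantoms. Lesions are ellipsoidal masks filled
# with a correlated Gaussian intensity field; per-lesion texture parameters
# are drawn from patient-level parameters with a multiplicative lognormal
# dispersion tau, which is the recoverable interlesional-heterogeneity
# ground truth (parameter CV = sqrt(exp(tau^2) - 1)).

.BACKGROUND_HU <- 60  # liver-like; irrelevant to mask-restricted features

#' Texture parameters of a lesion population
#'
#' @param mean_hu Mean intensity inside lesions (HU).
#' @param sd_hu Intensity standard deviation (HU, > 0).
#' @param correlation_length_vox Spatial smoothing scale in voxels (> 0);
#'   larger values give coarser texture.
#' @param lesion_radius_vox Nominal lesion radius in voxels (>= 2).
#' @return A list of class `texture_params`.
#' @export
texture_params <- function(mean_hu = 100, sd_hu = 20,
                           correlation_length_vox = 1.2,
                           lesion_radius_vox = 6) {
  if (!is.numeric(sd_hu) || sd_hu <= 0) stop("`sd_hu` must be > 0")
  if (correlation_length_vox <= 0)
    stop("`correlation_length_vox` must be > 0")
  if (lesion_radius_vox < 2) stop("`lesion_radius_vox` must be >= 2")
  structure(list(mean_hu = mean_hu, sd_hu = sd_hu,
                 correlation_length_vox = correlation_length_vox,
                 lesion_radius_vox = lesion_radius_vox),
            class = "texture_params")
}

#' Specification of one synthetic cohort
#'
#' @param name Cohort label.
#' @param n_patients Number of patients (>= 2).
#' @param lesions_per_patient Integer range (min, max) of lesions per
#'   patient, drawn uniformly; must lie within [2, 85].
#' @param patient_texture_prior A [texture_params()]: the cohort-level mean
#'   parameters.
#' @param interlesional_dispersion tau >= 0, the log-sd of the
#'   multiplicative per-lesion parameter spread within a patient.
#' @param seed Integer seed.
#' @param spacing Voxel spacing in mm; the default mirrors a 1.5 mm slice
#'   thickness protocol.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_patients,
                        lesions_per_patient = c(2, 10),
                        patient_texture_prior = texture_params(),
                        interlesional_dispersion = 0.2,
                        seed = 1L,
                        spacing = c(0.7, 0.7, 1.5)) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop("`n_patients` must be >= 2")
  lp <- as.integer(lesions_per_patient)
  if (length(lp) != 2L || lp[1] > lp[2] || lp[1] < 2L || lp[2] > 85L)
    stop("`lesions_per_patient` must be an integer range within [2, 85]")
  if (interlesional_dispersion < 0)
    stop("`interlesional_dispersion` (tau) must be >= 0")
  if (!inherits(patient_texture_prior, "texture_params"))
    stop("`patient_texture_prior` must be a texture_params")
  structure(list(name = as.character(name),
                 n_patients = as.integer(n_patients),
                 lesions_per_patient = lp,
                 patient_texture_prior = patient_texture_prior,
                 interlesional_dispersion = interlesional_dispersion,
                 seed = as.integer(seed),
                 spacing = as.numeric(spacing)),
            class = "cohort_spec")
}

# Separable Gaussian smoothing of a 3-D array along each axis with a
# truncated, renormalised kernel (radius 3 sigma).
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 1e-8) return(arr)
  smooth_axis <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (o in -r:r) {
      ii <- seq_len(n)
      jj <- ii + o
      ok <- jj >= 1 & jj <= n
      K[cbind(ii[ok], jj[ok])] <- k[o + r + 1]
    }
    K / rowSums(K)
  }
  d <- dim(arr)
  K1 <- smooth_axis(d[1]); K2 <- smooth_axis(d[2]); K3 <- smooth_axis(d[3])
  x <- K1 %*% matrix(arr, d[1], d[2] * d[3])
  dim(x) <- d
  x <- aperm(x, c(2, 1, 3))
  x <- K2 %*% matrix(x, d[2], d[1] * d[3])
  dim(x) <- c(d[2], d[1], d[3])
  x <- aperm(x, c(3, 2, 1))
  x <- K3 %*% matrix(x, d[3], d[1] * d[2])
  dim(x) <- c(d[3], d[1], d[2])
  aperm(x, c(2, 3, 1))
}

#' Generate one synthetic lesion
#'
#' An ellipsoidal mask with semi-axes `lesion_radius_vox` jittered by up to
#' +/- 30 percent per axis, inside a padded volume. Intensities inside the
#' mask are white Gaussian noise convolved with an isotropic Gaussian
#' kernel of scale `correlation_length_vox`, then rescaled so the in-mask
#' sample mean and standard deviation equal `mean_hu` and `sd_hu` exactly.
#' Outside the mask the volume holds a constant liver-like background.
#'
#' @param params A [texture_params()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param dims Optional volume dimensions; default is sized to fit the
#'   ellipsoid plus one voxel of padding. An ellipsoid that cannot fit is
#'   an error.
#' @param spacing Voxel spacing in mm.
#' @return List with `volume` ([image_volume()]), `mask` ([label_mask()],
#'   label 1) and `semi_axes`.
#' @export
generate_lesion <- function(params, seed = NULL, dims = NULL,
                            spacing = c(0.7, 0.7, 1.5)) {
  stopifnot(inherits(params, "texture_params"))
  if (!is.null(seed)) set.seed(seed)
  ax <- params$lesion_radius_vox * stats::runif(3, 0.7, 1.3)
  need <- 2L * ceiling(ax) + 3L
  if (is.null(dims)) dims <- need
  dims <- as.integer(dims)
  if (any(dims < need))
    stop("lesion radius too large for volume dims (need >= ",
         paste(need, collapse = "x"), ")")
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  mask <- array(0L, dims)
  mask[inside] <- 1L
  noise <- array(stats::rnorm(prod(dims), params$mean_hu, params$sd_hu),
                 dims)
  sm <- gauss_smooth3(noise, params$correlation_length_vox)
  vals <- sm[inside]
  sdv <- stats::sd(vals)
  if (sdv > 0)
    vals <- params$mean_hu + (vals - mean(vals)) / sdv * params$sd_hu
  vol <- array(.BACKGROUND_HU, dims)
  vol[inside] <- vals
  list(volume = image_volume(vol, spacing),
       mask = label_mask(mask, spacing),
       semi_axes = ax)
}

# Draw patient-level params around the cohort prior (fixed 10 percent
# lognormal between-patient spread), then per-lesion params with
# multiplicative lognormal factors of log-sd tau (mean 1). The dispersion
# applies to the intensity-texture fields (mean_hu, sd_hu,
# correlation_length_vox); lesion radius carries an independent fixed
# 10 percent jitter so size heterogeneity stays decoupled from texture
# heterogeneity.
draw_patient_params <- function(spec) {
  prior <- spec$patient_texture_prior
  f <- stats::rlnorm(4, meanlog = -0.1^2 / 2, sdlog = 0.1)
  texture_params(mean_hu = prior$mean_hu * f[1],
                 sd_hu = prior$sd_hu * f[2],
                 correlation_length_vox = prior$correlation_length_vox * f[3],
                 lesion_radius_vox = max(2, prior$lesion_radius_vox * f[4]))
}

draw_lesion_params <- function(patient, tau) {
  f <- stats::rlnorm(3, meanlog = -tau^2 / 2, sdlog = tau)
  r <- stats::rlnorm(1, meanlog = -0.1^2 / 2, sdlog = 0.1)
  texture_params(mean_hu = patient$mean_hu * f[1],
                 sd_hu = patient$sd_hu * f[2],
                 correlation_length_vox =
                   patient$correlation_length_vox * f[3],
                 lesion_radius_vox = max(2, patient$lesion_radius_vox * r))
}

patient_seed <- function(spec, patient_index) {
  (spec$seed %% 1000003L) * 2011L + patient_index * 7919L
}

# In-memory patient draw: lesion regions + parameter log, no placement.
simulate_patient_regions <- function(spec, patient_index) {
  set.seed(patient_seed(spec, patient_index))
  pid <- sprintf("%s_p%02d", spec$name, patient_index)
  pp <- draw_patient_params(spec)
  lp <- spec$lesions_per_patient
  n <- sample(lp[1]:lp[2], 1L)
  tau <- spec$interlesional_dispersion
  lesions <- vector("list", n)
  log <- vector("list", n)
  for (k in seq_len(n)) {
    par_k <- draw_lesion_params(pp, tau)
    les <- generate_lesion(par_k, seed = NULL, spacing = spec$spacing)
    idx <- which(les$mask$labels == 1L)
    lesions[[k]] <- list(
      region = lesion_region(k, pid, les$volume$data[idx],
                             arrayInd(idx, dim(les$mask$labels)) - 1L,
                             spec$spacing),
      volume = les$volume, mask = les$mask)
    log[[k]] <- data.frame(
      patient_id = pid, cohort = spec$name, lesion_id = k, tau = tau,
      mean_hu = par_k$mean_hu, sd_hu = par_k$sd_hu,
      correlation_length_vox = par_k$correlation_length_vox,
      lesion_radius_vox = par_k$lesion_radius_vox,
      patient_mean_hu = pp$mean_hu, patient_sd_hu = pp$sd_hu,
      patient_correlation_length_vox = pp$correlation_length_vox,
      stringsAsFactors = FALSE)
  }
  list(patient_id = pid, lesions = lesions, log = do.call(rbind, log))
}

#' Generate one synthetic patient volume
#'
#' Draws patient-level texture parameters around the cohort prior, draws
#' per-lesion parameters with the cohort's interlesional dispersion tau,
#' and places the N lesions (N uniform in the cohort's range) without
#' overlap in a single volume with labels 1..N. Each lesion is assigned a
#' distinct cell of a cubic grid (random cell order, random offset within
#' the cell), so placements are random but can never collide.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index 1-based patient index (drives the per-patient seed).
#' @return List with `volume`, `mask`, `patient_id`, `param_log`.
#' @export
generate_patient <- function(spec, patient_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  sim <- simulate_patient_regions(spec, patient_index)
  n <- length(sim$lesions)
  sub_dims <- vapply(sim$lesions, function(l) dim(l$mask$labels),
                     integer(3))
  cell <- max(sub_dims) + 1L
  gside <- ceiling(n^(1 / 3))
  dims <- rep(gside * cell + 2L, 3L)
  vol <- array(.BACKGROUND_HU, dims)
  lab <- array(0L, dims)
  cells <- as.matrix(expand.grid(0:(gside - 1L), 0:(gside - 1L),
                                 0:(gside - 1L)))
  cells <- cells[sample.int(nrow(cells), n), , drop = FALSE]
  for (k in seq_len(n)) {
    dk <- sub_dims[, k]
    slack <- cell - dk  # >= 1 on every axis by construction of `cell`
    corner <- cells[k, ] * cell + 2L +
      vapply(1:3, function(a) sample.int(slack[a] + 1L, 1L) - 1L, 0L)
    sl <- list(corner[1]:(corner[1] + dk[1] - 1L),
               corner[2]:(corner[2] + dk[2] - 1L),
               corner[3]:(corner[3] + dk[3] - 1L))
    m <- sim$lesions[[k]]$mask$labels
    v <- sim$lesions[[k]]$volume$data
    sel <- m == 1L
    dst_lab <- lab[sl[[1]], sl[[2]], sl[[3]]]
    dst_vol <- vol[sl[[1]], sl[[2]], sl[[3]]]
    dst_lab[sel] <- k
    dst_vol[sel] <- v[sel]
    lab[sl[[1]], sl[[2]], sl[[3]]] <- dst_lab
    vol[sl[[1]], sl[[2]], sl[[3]]] <- dst_vol
  }
  list(volume = image_volume(vol, spec$spacing),
       mask = label_mask(lab, spec$spacing),
       patient_id = sim$patient_id,
       param_log = sim$log)
}

#' Generate a two-cohort synthetic study on disk
#'
#' Writes per-patient NRRD volumes and label masks, a manifest CSV
#' (`patient_id`, `cohort`, `volume_path`, `mask_path`) and a ground-truth
#' parameter log CSV (per-lesion texture parameters and the per-cohort tau).
#'
#' @param spec_a,spec_b [cohort_spec()]s with distinct names.
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Path of the manifest CSV, invisibly.
#' @export
generate_study <- function(spec_a, spec_b, out_dir, overwrite = FALSE) {
  if (identical(spec_a$name, spec_b$name))
    stop("cohort names must be distinct")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop("`out_dir` exists and is not empty; pass overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  logs <- list()
  for (spec in list(spec_a, spec_b)) {
    for (i in seq_len(spec$n_patients)) {
      pat <- generate_patient(spec, i)
      vp <- file.path(out_dir, paste0(pat$patient_id, "_volume.nrrd"))
      mp <- file.path(out_dir, paste0(pat$patient_id, "_mask.nrrd"))
      write_volume(pat$volume, vp)
      write_volume(pat$mask, mp)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pat$patient_id, cohort = spec$name,
        volume_path = basename(vp), mask_path = basename(mp),
        stringsAsFactors = FALSE)
      logs[[length(logs) + 1L]] <- pat$param_log
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  log <- do.call(rbind, logs)
  num <- vapply(log, is.numeric, TRUE)
  log[num] <- lapply(log[num], function(x) sprintf("%.12g", x))
  utils::write.csv(log, file.path(out_dir, "param_log.csv"),
                   row.names = FALSE, quote = FALSE)
  message("wrote study to ", out_dir, ": ",
          spec_a$n_patients + spec_b$n_patients, " patients, ",
          nrow(log), " lesions")
  invisible(mpath)
}

#' Simulate a two-cohort study in memory
#'
#' Fast path used for simulation studies: returns every lesion region plus
#' the manifest and ground-truth parameter log without assembling or
#' writing patient volumes. The regions are identical to what
#' [generate_study()] + [split_lesions()] produce for the same specs.
#'
#' @param spec_a,spec_b [cohort_spec()]s with distinct names.
#' @return List with `regions` (list of [lesion_region()]), `manifest`
#'   (data.frame `patient_id`, `cohort`) and `param_log`.
#' @export
simulate_study <- function(spec_a, spec_b) {
  if (identical(spec_a$name, spec_b$name))
    stop("cohort names must be distinct")
  regions <- list()
  rows <- list()
  logs <- list()
  for (spec in list(spec_a, spec_b)) {
    for (i in seq_len(spec$n_patients)) {
      sim <- simulate_patient_regions(spec, i)
      regions <- c(regions, lapply(sim$lesions, `[[`, "region"))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sim$patient_id, cohort = spec$name,
        stringsAsFactors = FALSE)
      logs[[length(logs) + 1L]] <- sim$log
    }
  }
  list(regions = regions, manifest = do.call(rbind, rows),
       param_log = do.call(rbind, logs))
}
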