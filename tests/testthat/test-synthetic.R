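test_that("lesion generation is deterministic and respects its parameters", {
  p <- texture_params(mean_hu = 120, sd_hu = 30,
                      correlation_length_vox = 1, lesion_radius_vox = 4)
  a <- generate_lesion(p, seed = 99)
  b <- generate_lesion(p, seed = 99)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$labels, b$mask$labels)
  inside <- a$mask$labels == 1L
  expect_equal(mean(a$volume$data[inside]), 120, tolerance = 1e-9)
  expect_equal(sd(a$volume$data[inside]), 30, tolerance = 1e-9)
  expect_true(all(a$volume$data[!inside] == 60))  # liver-like background

  expect_error(texture_params(sd_hu = 0), "sd_hu")
  tiny <- generate_lesion(texture_params(sd_hu = 1e-6), seed = 1)
  expect_lt(diff(range(tiny$volume$data[tiny$mask$labels == 1L])), 1e-4)
  expect_error(generate_lesion(p, seed = 1, dims = c(4, 4, 4)),
               "too large")
})

test_that("white-noise limit recovers the nominal mean and sd at large n", {
  # correlation length -> 0: per-voxel samples are iid; with >= 1e4 voxels
  # the in-mask sample moments sit within 5% of (mean_hu, sd_hu)
  p <- texture_params(mean_hu = 100, sd_hu = 20,
                      correlation_length_vox = 1e-9, lesion_radius_vox = 14)
  les <- generate_lesion(p, seed = 7)
  v <- les$volume$data[les$mask$labels == 1L]
  expect_gte(length(v), 1e4)
  expect_lt(abs(mean(v) - 100) / 100, 0.05)
  expect_lt(abs(sd(v) - 20) / 20, 0.05)
})

test_that("tau = 0 gives identical per-lesion texture parameters", {
  spec <- cohort_spec("A", 3, c(3, 3), interlesional_dispersion = 0,
                      seed = 5)
  sim <- simulate_study(spec, cohort_spec("B", 2, c(2, 2),
                                          interlesional_dispersion = 0,
                                          seed = 6))
  log_a <- sim$param_log[sim$param_log$cohort == "A", ]
  for (pid in unique(log_a$patient_id)) {
    sub <- log_a[log_a$patient_id == pid, ]
    expect_equal(diff(range(sub$sd_hu)), 0)
    expect_equal(diff(range(sub$mean_hu)), 0)
    expect_equal(diff(range(sub$correlation_length_vox)), 0)
  }
})

test_that("larger tau spreads per-lesion sd_hu more within patients", {
  mk <- function(tau, seed) {
    spec <- cohort_spec("A", 6, c(4, 8), interlesional_dispersion = tau,
                        seed = seed,
                        patient_texture_prior =
                          texture_params(lesion_radius_vox = 2.5))
    log <- simulate_study(spec, cohort_spec(
      "B", 2, c(2, 2), interlesional_dispersion = tau, seed = seed + 500,
      patient_texture_prior =
        texture_params(lesion_radius_vox = 2.5)))$param_log
    log <- log[log$cohort == "A", ]
    mean(tapply(log$sd_hu, log$patient_id,
                function(v) sd(v) / mean(v)))
  }
  expect_gt(mk(0.5, 21), mk(0.05, 21))
})

test_that("parameter-log CV of sd_hu tracks tau across seeds", {
  taus <- c(0, 0.1, 0.2, 0.4, 0.8)
  prior <- texture_params(lesion_radius_vox = 2.2)
  mean_cv <- sapply(taus, function(tau) {
    per_seed <- sapply(1:20, function(s) {
      spec <- cohort_spec("A", 3, c(3, 4), prior,
                          interlesional_dispersion = tau, seed = 3000 + s)
      log <- do.call(rbind, lapply(seq_len(spec$n_patients), function(i)
        lesioncv:::simulate_patient_regions(spec, i)$log))
      mean(tapply(log$sd_hu, log$patient_id,
                  function(v) sd(v) / mean(v)))
    })
    mean(per_seed)
  })
  expect_gte(cor(taus, mean_cv, method = "spearman"), 0.95)
})

test_that("per-lesion parameter CV approaches the lognormal analytic value", {
  # the analytic CV sqrt(exp(tau^2) - 1) is a population quantity; the
  # sample CV over a handful of lesions is biased low for skewed lognormal
  # draws, so the anchor uses many lesions per patient
  prior <- texture_params(lesion_radius_vox = 2.2)
  spec <- cohort_spec("A", 6, c(60, 60), prior,
                      interlesional_dispersion = 0.8, seed = 4001)
  log <- do.call(rbind, lapply(seq_len(spec$n_patients), function(i)
    lesioncv:::simulate_patient_regions(spec, i)$log))
  cv_obs <- mean(tapply(log$sd_hu, log$patient_id,
                        function(v) sd(v) / mean(v)))
  expect_equal(cv_obs, sqrt(exp(0.8^2) - 1), tolerance = 0.25)
})

test_that("patient assembly places the requested lesions without overlap", {
  spec <- cohort_spec("A", 2, c(2, 2), seed = 31,
                      patient_texture_prior =
                        texture_params(lesion_radius_vox = 3))
  pat <- generate_patient(spec, 1)
  expect_equal(sort(unique(as.vector(pat$mask$labels))), 0:2)
  expect_equal(nrow(pat$param_log), 2L)
  # labels partition their voxels by construction; every labelled voxel
  # holds a lesion intensity, not background
  for (k in 1:2) {
    n_k <- sum(pat$mask$labels == k)
    expect_gt(n_k, 0)
  }

  spec5 <- cohort_spec("A", 2, c(5, 5), seed = 32)
  pat5 <- generate_patient(spec5, 1)
  expect_equal(max(pat5$mask$labels), 5L)
})

test_that("study outputs are pure functions of spec and seed", {
  prior <- texture_params(lesion_radius_vox = 2.5)
  spec_a <- cohort_spec("A", 2, c(2, 3), prior, 0.2, seed = 41)
  spec_b <- cohort_spec("B", 2, c(2, 3), prior, 0.4, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(spec_a, spec_b, d1, overwrite = TRUE)
  generate_study(spec_a, spec_b, d2, overwrite = TRUE)
  for (f in c("manifest.csv", "param_log.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # refuses to clobber a non-empty directory without the flag
  expect_error(generate_study(spec_a, spec_b, d1), "overwrite")
  expect_error(generate_study(spec_a, spec_a, d2), "distinct")
  # 73-subject layout: manifest rows mirror the cohort sizes
  m <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(m), 4L)
  expect_error(cohort_spec("A", 0), "n_patients")
  expect_error(cohort_spec("A", 3, c(1, 5)), "lesions_per_patient")
})

test_that("in-memory simulation matches the on-disk pipeline regions", {
  prior <- texture_params(lesion_radius_vox = 3)
  spec_a <- cohort_spec("A", 2, c(2, 2), prior, 0.3, seed = 51)
  spec_b <- cohort_spec("B", 2, c(2, 2), prior, 0.3, seed = 52)
  sim <- simulate_study(spec_a, spec_b)
  dir <- withr::local_tempdir()
  generate_study(spec_a, spec_b, dir, overwrite = TRUE)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  disk_regions <- list()
  for (i in seq_len(nrow(m))) {
    vol <- read_volume(file.path(dir, m$volume_path[i]))
    msk <- read_mask(file.path(dir, m$mask_path[i]))
    disk_regions <- c(disk_regions,
                      split_lesions(msk, vol, m$patient_id[i]))
  }
  expect_equal(length(disk_regions), length(sim$regions))
  key <- function(r) paste(r$patient_id, r$lesion_id)
  disk_regions <- disk_regions[order(vapply(disk_regions, key, ""))]
  mem <- sim$regions[order(vapply(sim$regions, key, ""))]
  for (k in seq_along(mem)) {
    expect_equal(disk_regions[[k]]$n_voxels, mem[[k]]$n_voxels)
    expect_equal(sort(disk_regions[[k]]$intensities),
                 sort(mem[[k]]$intensities), tolerance = 1e-12)
    expect_equal(compute_features(disk_regions[[k]]),
                 compute_features(mem[[k]]), tolerance = 1e-12)
  }
})
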