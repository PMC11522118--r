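# Config-driven pipeline stages: simulate -> extract -> analyze. Each stage
# logs per-stage counts (patients, lesions, exclusions) and serialises its
# parameters next to the outputs so a run can be reproduced from the saved
# config alone.

#' Simulate a synthetic two-cohort study
#'
#' Thin driver over [generate_study()]: builds the two cohort specs from a
#' flat parameter list, writes volumes, masks, manifest and ground-truth
#' parameter log, and logs per-cohort lesion totals.
#'
#' @param out_dir Output directory.
#' @param n_patients_a,n_patients_b Cohort sizes.
#' @param lesions_per_patient Integer range (min, max).
#' @param tau_a,tau_b Interlesional dispersion per cohort.
#' @param lesion_radius_vox Nominal lesion radius (voxels).
#' @param seed Integer master seed; the two cohorts use `seed` and
#'   `seed + 1`.
#' @param overwrite Passed to [generate_study()].
#' @return Manifest path, invisibly.
#' @export
run_simulate <- function(out_dir, n_patients_a = 5, n_patients_b = 5,
                         lesions_per_patient = c(2, 6),
                         tau_a = 0.2, tau_b = 0.4,
                         lesion_radius_vox = 6, seed = 1L,
                         overwrite = FALSE) {
  prior <- texture_params(lesion_radius_vox = lesion_radius_vox)
  spec_a <- cohort_spec("A", n_patients_a, lesions_per_patient,
                        prior, tau_a, seed = seed)
  spec_b <- cohort_spec("B", n_patients_b, lesions_per_patient,
                        prior, tau_b, seed = seed + 1L)
  mpath <- generate_study(spec_a, spec_b, out_dir, overwrite = overwrite)
  log <- utils::read.csv(file.path(out_dir, "param_log.csv"))
  for (co in unique(log$cohort))
    message("cohort ", co, ": ", sum(log$cohort == co), " lesions")
  writeLines(sprintf("%s=%s",
                     c("n_patients_a", "n_patients_b", "lesions_min",
                       "lesions_max", "tau_a", "tau_b",
                       "lesion_radius_vox", "seed"),
                     c(n_patients_a, n_patients_b, lesions_per_patient,
                       tau_a, tau_b, lesion_radius_vox, seed)),
             file.path(out_dir, "simulate_config.txt"))
  invisible(mpath)
}

#' Extract per-lesion texture features for a study
#'
#' Reads the manifest, splits each patient's label mask into lesions,
#' applies the minimum-size filter, computes the 75 features and writes the
#' per-lesion feature table, a per-lesion size table and the extraction
#' config.
#'
#' @param manifest_path Manifest CSV with `volume_path` and `mask_path`
#'   columns (relative paths resolved against the manifest's directory).
#' @param out_dir Output directory (created if needed).
#' @param config A [texture_config()].
#' @param min_diameter_mm Minimum equivalent diameter (default 5 mm).
#' @return Feature table path, invisibly.
#' @export
run_extract <- function(manifest_path, out_dir,
                        config = texture_config(), min_diameter_mm = 5) {
  manifest <- read_manifest(manifest_path)
  if (!all(c("volume_path", "mask_path") %in% names(manifest)))
    stop("manifest must provide volume_path and mask_path for extraction")
  base <- dirname(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  all_regions <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(manifest))) {
    vol <- read_volume(resolve(manifest$volume_path[i]))
    msk <- read_mask(resolve(manifest$mask_path[i]))
    regions <- split_lesions(msk, vol, manifest$patient_id[i])
    kept <- filter_by_size(regions, min_diameter_mm)
    n_excluded <- n_excluded + length(regions) - length(kept)
    all_regions <- c(all_regions, kept)
  }
  message(length(all_regions), " lesions retained, ", n_excluded,
          " excluded by the ", min_diameter_mm, " mm size filter")
  feat <- extract_features(all_regions, config)
  fpath <- file.path(out_dir, "features.csv")
  write_feature_table(feat, fpath)
  sizes <- data.frame(
    patient_id = vapply(all_regions, function(r) r$patient_id, ""),
    lesion_id = vapply(all_regions, function(r) r$lesion_id, 0L),
    n_voxels = vapply(all_regions, function(r) r$n_voxels, 0L),
    volume_mm3 = vapply(all_regions, function(r) r$volume_mm3, 0),
    equivalent_diameter_mm =
      vapply(all_regions, function(r) r$equivalent_diameter_mm, 0),
    stringsAsFactors = FALSE)
  utils::write.csv(sizes, file.path(out_dir, "lesion_sizes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_config(config, file.path(out_dir, "extraction_config.txt"))
  writeLines(sprintf("min_diameter_mm=%g", min_diameter_mm),
             file.path(out_dir, "size_filter.txt"))
  invisible(fpath)
}

#' Analyze a feature table: CV matrix, cohort screen, radar, descriptives
#'
#' Computes the patient-wise CV matrix, per-cohort mean-CV summaries, the
#' per-feature two-cohort screen, the radar table of significant features,
#' and cohort descriptives; writes each as CSV and logs the significance
#' summary.
#'
#' @param feature_path Per-lesion feature CSV.
#' @param manifest_path Manifest CSV.
#' @param out_dir Output directory.
#' @param alpha Significance level (default 0.05).
#' @param exclude_features Features excluded from the mean-CV summary CSV
#'   (the screen always covers all features).
#' @param lesion_sizes_path Optional lesion-size CSV (from [run_extract()])
#'   for the volume descriptives.
#' @return List with `cv`, `report`, `radar`, `descriptives`, invisibly.
#' @export
run_analyze <- function(feature_path, manifest_path, out_dir,
                        alpha = 0.05, exclude_features = character(),
                        lesion_sizes_path = NULL) {
  feat <- read_feature_table(feature_path)
  manifest <- read_manifest(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cv <- build_cv_matrix(feat, manifest)
  utils::write.csv(data.frame(patient_id = rownames(cv$cv), cv$cv,
                              check.names = FALSE),
                   file.path(out_dir, "cv_matrix.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = rownames(cv$cv),
                              cv$mean_nonpositive, check.names = FALSE),
                   file.path(out_dir, "cv_flags.csv"), row.names = FALSE)
  utils::write.csv(heatmap_table(cv), file.path(out_dir, "cv_long.csv"),
                   row.names = FALSE)
  cohorts <- sort(unique(manifest$cohort))
  for (co in cohorts) {
    utils::write.csv(mean_cv_per_feature(cv, co, exclude_features),
                     file.path(out_dir, paste0("mean_cv_", co, ".csv")),
                     row.names = FALSE)
  }
  report <- screen_all(cv, alpha = alpha)
  utils::write.csv(report$table, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(radar_table(report), file.path(out_dir, "radar.csv"),
                   row.names = FALSE)
  lesions <- if (!is.null(lesion_sizes_path))
    utils::read.csv(lesion_sizes_path, stringsAsFactors = FALSE)
  else
    feat[c("patient_id", "lesion_id")]
  lesions$patient_id <- as.character(lesions$patient_id)
  desc <- cohort_descriptives(manifest, lesions)
  utils::write.csv(desc$per_cohort,
                   file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  message(report$counts$n_significant, " of ", report$counts$n_tested,
          " features significant at alpha = ", alpha, " (",
          report$counts$n_higher_a, " higher in ", report$cohorts[1], ", ",
          report$counts$n_higher_b, " higher in ", report$cohorts[2], ")")
  writeLines(c(sprintf("alpha=%g", alpha),
               sprintf("exclude_features=%s",
                       paste(exclude_features, collapse = ";"))),
             file.path(out_dir, "analyze_config.txt"))
  invisible(list(cv = cv, report = report, radar = radar_table(report),
                 descriptives = desc))
}

# internal: zzz hooks for the compiled code
#' @useDynLib lesioncv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"
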