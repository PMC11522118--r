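# The heterogeneity statistic: patient-wise coefficient of variation
# CV = sigma / mu * 100% of each feature across a patient's lesions, with
# the sample (n-1) standard deviation. CV is only meaningful for positive-
# mean features; nonpositive means are computed but flagged, never silently
# dropped.

#' Coefficient of variation of one patient's feature values
#'
#' @param values Numeric vector of one feature across a patient's lesions.
#' @param abs_mean Use |mu| in the denominator (flag-aware variant;
#'   default off).
#' @return List with `cv` (percent; `NA` when fewer than 2 values),
#'   `mean_nonpositive` and `insufficient_lesions` flags.
#' @export
patient_cv <- function(values, abs_mean = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    return(list(cv = NA_real_, mean_nonpositive = FALSE,
                insufficient_lesions = TRUE))
  mu <- mean(values)
  sigma <- stats::sd(values)
  denom <- if (abs_mean) abs(mu) else mu
  list(cv = sigma / denom * 100,
       mean_nonpositive = mu <= 0,
       insufficient_lesions = FALSE)
}

#' Build the patients x features CV matrix
#'
#' One CV per (patient, feature) across that patient's lesions. Patients
#' with fewer than 2 lesions have no defined CV and are dropped with a
#' message; nonpositive-mean entries are flagged but kept.
#'
#' @param feature_table Per-lesion feature table
#'   ([extract_features()] / [read_feature_table()]).
#' @param manifest Manifest data.frame with `patient_id`, `cohort`.
#' @param abs_mean Passed to [patient_cv()].
#' @return An object of class `cv_matrix`: list with `cv` (matrix patients
#'   x features, percent), `mean_nonpositive` (logical matrix), `manifest`
#'   (rows for retained patients), `dropped_patients`.
#' @export
build_cv_matrix <- function(feature_table, manifest, abs_mean = FALSE) {
  feats <- intersect(feature_names(), names(feature_table))
  if (length(feats) == 0L) stop("feature_table contains no known features")
  unknown <- setdiff(unique(feature_table$patient_id), manifest$patient_id)
  if (length(unknown))
    stop("feature table rows with unknown patient id(s): ",
         paste(unknown, collapse = ", "))
  dup <- duplicated(feature_table[c("patient_id", "lesion_id")])
  if (any(dup))
    stop("duplicated lesion rows (patient_id, lesion_id must be unique): ",
         paste(unique(feature_table$patient_id[dup]), collapse = ", "))
  counts <- table(feature_table$patient_id)
  keep <- names(counts)[counts >= 2L]
  dropped <- setdiff(unique(feature_table$patient_id), keep)
  if (length(dropped))
    message(length(dropped),
            " patient(s) with < 2 lesions dropped from CV computation: ",
            paste(dropped, collapse = ", "))
  # preserve manifest order among retained patients
  keep <- manifest$patient_id[manifest$patient_id %in% keep]
  cv <- matrix(NA_real_, length(keep), length(feats),
               dimnames = list(keep, feats))
  flag <- matrix(FALSE, length(keep), length(feats),
                 dimnames = list(keep, feats))
  for (p in keep) {
    sub <- feature_table[feature_table$patient_id == p, feats,
                         drop = FALSE]
    for (f in feats) {
      r <- patient_cv(sub[[f]], abs_mean = abs_mean)
      cv[p, f] <- r$cv
      flag[p, f] <- r$mean_nonpositive
    }
  }
  structure(list(cv = cv, mean_nonpositive = flag,
                 manifest = manifest[manifest$patient_id %in% keep, ,
                                     drop = FALSE],
                 dropped_patients = dropped),
            class = "cv_matrix")
}

#' @export
print.cv_matrix <- function(x, ...) {
  cat(sprintf("<cv_matrix> %d patients x %d features (%d dropped, <2 lesions)\n",
              nrow(x$cv), ncol(x$cv), length(x$dropped_patients)))
  invisible(x)
}

#' Mean CV per feature over one cohort's patients
#'
#' Arithmetic mean of the patient-wise CVs over the cohort, skipping
#' non-finite entries; reports the per-feature n actually used.
#'
#' @param cv A [build_cv_matrix()] result.
#' @param cohort Cohort name present in the manifest.
#' @param exclude_features Feature names to leave out of the summary (e.g.
#'   a dominant-variance feature that hides all others in a plot).
#' @return Data.frame `feature`, `mean_cv`, `n_used`.
#' @export
mean_cv_per_feature <- function(cv, cohort, exclude_features = character()) {
  stopifnot(inherits(cv, "cv_matrix"))
  pats <- cv$manifest$patient_id[cv$manifest$cohort == cohort]
  if (length(pats) == 0L) stop("no patients in cohort '", cohort, "'")
  feats <- setdiff(colnames(cv$cv), exclude_features)
  sub <- cv$cv[pats, feats, drop = FALSE]
  data.frame(
    feature = feats,
    mean_cv = apply(sub, 2L, function(v) mean(v[is.finite(v)])),
    n_used = apply(sub, 2L, function(v) sum(is.finite(v))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled cohort CV per feature
#'
#' The alternative reading of a cohort-level "mean CV": one CV per feature
#' over all of the cohort's lesions pooled, rather than the mean of
#' patient-wise CVs. Provided for sensitivity analysis.
#'
#' @param feature_table Per-lesion feature table.
#' @param manifest Manifest data.frame.
#' @param cohort Cohort name.
#' @return Data.frame `feature`, `pooled_cv`, `n_lesions`.
#' @export
pooled_cv_per_feature <- function(feature_table, manifest, cohort) {
  pats <- manifest$patient_id[manifest$cohort == cohort]
  sub <- feature_table[feature_table$patient_id %in% pats, , drop = FALSE]
  if (nrow(sub) < 2L) stop("cohort '", cohort, "' has < 2 lesions")
  feats <- intersect(feature_names(), names(sub))
  data.frame(
    feature = feats,
    pooled_cv = vapply(feats, function(f) patient_cv(sub[[f]])$cv, 0),
    n_lesions = nrow(sub),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Long-format CV table for unclustered heatmaps
#'
#' @param cv A [build_cv_matrix()] result.
#' @return Data.frame `patient_id`, `cohort`, `feature`, `cv`,
#'   `mean_nonpositive`, in input (unclustered) order.
#' @export
heatmap_table <- function(cv) {
  stopifnot(inherits(cv, "cv_matrix"))
  pats <- rownames(cv$cv)
  feats <- colnames(cv$cv)
  if (length(pats) == 0L)
    return(data.frame(patient_id = character(0), cohort = character(0),
                      feature = character(0), cv = numeric(0),
                      mean_nonpositive = logical(0)))
  data.frame(
    patient_id = rep(pats, each = length(feats)),
    cohort = rep(cv$manifest$cohort[match(pats, cv$manifest$patient_id)],
                 each = length(feats)),
    feature = rep(feats, times = length(pats)),
    cv = as.vector(t(cv$cv)),
    mean_nonpositive = as.vector(t(cv$mean_nonpositive)),
    row.names = NULL, stringsAsFactors = FALSE)
}
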