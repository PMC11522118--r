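# Per-feature two-cohort screen on patient-wise CVs: an unpaired two-sided
# t-test per feature at alpha = 0.05, no multiple-testing correction in the
# primary screen (Benjamini-Hochberg q-values are reported alongside).

#' Compare one feature's CV values between two cohorts
#'
#' Two-sided unpaired t-test (Welch by default) on the patient-wise CV
#' values. Degenerate inputs are resolved without error: identical
#' zero-variance groups give t = 0, p = 1; zero-variance groups with
#' different means give p = 0.
#'
#' @param cv_a,cv_b Numeric CV values (percent) for cohorts A and B.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance test instead of Welch.
#' @return List of class `feature_comparison`: `mean_cv_a`, `mean_cv_b`,
#'   `n_a`, `n_b`, `t`, `p`, `significant`, `higher_cv_cohort`
#'   (`"A"`/`"B"`/`"tie"`), `testable`.
#' @export
compare_feature <- function(cv_a, cv_b, alpha = 0.05, var_equal = FALSE) {
  cv_a <- cv_a[is.finite(cv_a)]
  cv_b <- cv_b[is.finite(cv_b)]
  n_a <- length(cv_a)
  n_b <- length(cv_b)
  if (n_a < 2L || n_b < 2L) {
    return(structure(list(mean_cv_a = if (n_a) mean(cv_a) else NA_real_,
                          mean_cv_b = if (n_b) mean(cv_b) else NA_real_,
                          n_a = n_a, n_b = n_b, t = NA_real_, p = NA_real_,
                          significant = NA, higher_cv_cohort = NA_character_,
                          testable = FALSE),
                     class = "feature_comparison"))
  }
  ma <- mean(cv_a)
  mb <- mean(cv_b)
  res <- tryCatch(
    stats::t.test(cv_a, cv_b, var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(res)) {  # essentially constant data
    if (isTRUE(all.equal(ma, mb)) || ma == mb) {
      tt <- 0; pp <- 1
    } else {
      tt <- sign(ma - mb) * Inf; pp <- 0
    }
  } else {
    tt <- unname(res$statistic)
    pp <- res$p.value
  }
  structure(list(
    mean_cv_a = ma, mean_cv_b = mb, n_a = n_a, n_b = n_b,
    t = tt, p = pp, significant = pp < alpha,
    higher_cv_cohort = if (ma == mb) "tie" else if (ma > mb) "A" else "B",
    testable = TRUE), class = "feature_comparison")
}

#' Screen every feature for cohort differences in CV
#'
#' Runs [compare_feature()] for each of the 75 features on the patient-wise
#' CVs split by cohort. The primary `significant` flag uses the raw p-value
#' against `alpha` (no multiple-testing correction); BH-adjusted q-values
#' are reported in a separate column and never alter the primary flag.
#' Flagged (nonpositive-mean) CV entries take part in the screen unless
#' `drop_flagged = TRUE`.
#'
#' @param cv A [build_cv_matrix()] result whose manifest holds exactly two
#'   cohorts.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param drop_flagged Exclude nonpositive-mean CV entries (sensitivity
#'   mode; default keeps them).
#' @return An object of class `comparison_report`: data.frame `table` (one
#'   row per feature: `feature`, `mean_cv_a`, `mean_cv_b`, `n_a`, `n_b`,
#'   `t`, `p`, `q`, `significant`, `higher_cv_cohort`, `testable`) plus
#'   `alpha`, `cohorts`, and the summary `counts`.
#' @export
screen_all <- function(cv, alpha = 0.05, var_equal = FALSE,
                       drop_flagged = FALSE) {
  stopifnot(inherits(cv, "cv_matrix"))
  cohorts <- sort(unique(cv$manifest$cohort))
  if (length(cohorts) != 2L)
    stop("exactly two cohorts required, found ",
         length(cohorts), ": ", paste(cohorts, collapse = ", "))
  pats_a <- cv$manifest$patient_id[cv$manifest$cohort == cohorts[1]]
  pats_b <- cv$manifest$patient_id[cv$manifest$cohort == cohorts[2]]
  rows <- lapply(colnames(cv$cv), function(f) {
    va <- cv$cv[pats_a, f]
    vb <- cv$cv[pats_b, f]
    if (drop_flagged) {
      va <- va[!cv$mean_nonpositive[pats_a, f]]
      vb <- vb[!cv$mean_nonpositive[pats_b, f]]
    }
    cmp <- compare_feature(va, vb, alpha = alpha, var_equal = var_equal)
    data.frame(feature = f, mean_cv_a = cmp$mean_cv_a,
               mean_cv_b = cmp$mean_cv_b, n_a = cmp$n_a, n_b = cmp$n_b,
               t = cmp$t, p = cmp$p, significant = cmp$significant,
               higher_cv_cohort = cmp$higher_cv_cohort,
               testable = cmp$testable, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  tab$q[tab$testable] <- stats::p.adjust(tab$p[tab$testable], method = "BH")
  tab <- tab[c("feature", "mean_cv_a", "mean_cv_b", "n_a", "n_b", "t", "p",
               "q", "significant", "higher_cv_cohort", "testable")]
  sig <- tab[isTRUE_vec(tab$significant), , drop = FALSE]
  counts <- list(
    n_tested = sum(tab$testable),
    n_significant = nrow(sig),
    n_higher_a = sum(sig$higher_cv_cohort == "A"),
    n_higher_b = sum(sig$higher_cv_cohort == "B"))
  structure(list(table = tab, alpha = alpha, cohorts = cohorts,
                 counts = counts),
            class = "comparison_report")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> cohorts %s vs %s, alpha = %g\n",
              x$cohorts[1], x$cohorts[2], x$alpha))
  cat(sprintf("  %d/%d features significant (%d higher CV in %s, %d in %s)\n",
              x$counts$n_significant, x$counts$n_tested,
              x$counts$n_higher_a, x$cohorts[1],
              x$counts$n_higher_b, x$cohorts[2]))
  invisible(x)
}

#' Radar-plot table of significant features
#'
#' @param report A [screen_all()] result.
#' @return Data.frame of the significant features (ordered by name) with
#'   the two cohort mean CVs; empty when nothing is significant.
#' @export
radar_table <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  tab <- report$table
  sig <- tab[isTRUE_vec(tab$significant),
             c("feature", "mean_cv_a", "mean_cv_b")]
  sig <- sig[order(sig$feature), , drop = FALSE]
  names(sig)[2:3] <- paste0("mean_cv_", report$cohorts)
  rownames(sig) <- NULL
  sig
}

#' Cohort descriptive statistics
#'
#' Per-cohort patient and lesion descriptives in the style of a clinical
#' characteristics table: lesion totals, per-patient lesion count summary,
#' mean lesion volume, optional categorical covariates (counts and
#' percentages), plus Wilcoxon-Mann-Whitney comparisons of per-patient
#' lesion counts and per-lesion volumes between the two cohorts (exact
#' where no ties, normal approximation otherwise).
#'
#' @param manifest Manifest data.frame (`patient_id`, `cohort`, optional
#'   covariate columns named in `categorical`).
#' @param lesion_table Data.frame with one row per lesion: `patient_id`
#'   plus, if available, `volume_mm3`.
#' @param categorical Names of manifest columns to summarise as counts and
#'   percentages.
#' @return List of class `cohort_descriptives` with `per_cohort`
#'   (data.frame), `categorical` (list of tables), `tests` (Wilcoxon
#'   p-values).
#' @export
cohort_descriptives <- function(manifest, lesion_table,
                                categorical = character()) {
  bad <- setdiff(unique(lesion_table$patient_id), manifest$patient_id)
  if (length(bad))
    stop("lesion table rows with unknown patient id(s): ",
         paste(bad, collapse = ", "))
  cohorts <- sort(unique(manifest$cohort))
  counts_by_patient <- lapply(cohorts, function(co) {
    pats <- manifest$patient_id[manifest$cohort == co]
    cnt <- table(factor(lesion_table$patient_id, levels = pats))
    as.numeric(cnt)
  })
  names(counts_by_patient) <- cohorts
  has_vol <- "volume_mm3" %in% names(lesion_table)
  vols <- lapply(cohorts, function(co) {
    pats <- manifest$patient_id[manifest$cohort == co]
    if (has_vol) lesion_table$volume_mm3[lesion_table$patient_id %in% pats]
    else numeric(0)
  })
  names(vols) <- cohorts
  per_cohort <- do.call(rbind, lapply(cohorts, function(co) {
    cnt <- counts_by_patient[[co]]
    data.frame(
      cohort = co,
      n_patients = length(cnt),
      n_lesions = sum(cnt),
      lesions_mean = mean(cnt),
      lesions_median = stats::median(cnt),
      lesions_min = min(cnt),
      lesions_max = max(cnt),
      mean_lesion_volume_mm3 =
        if (has_vol && length(vols[[co]])) mean(vols[[co]]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  tests <- list(lesion_count_p = NA_real_, lesion_volume_p = NA_real_)
  if (length(cohorts) == 2L) {
    tests$lesion_count_p <- suppressWarnings(
      stats::wilcox.test(counts_by_patient[[1]],
                         counts_by_patient[[2]])$p.value)
    if (has_vol && all(lengths(vols) > 0))
      tests$lesion_volume_p <- suppressWarnings(
        stats::wilcox.test(vols[[1]], vols[[2]])$p.value)
  }
  cat_tabs <- lapply(categorical, function(col) {
    if (!col %in% names(manifest))
      stop("manifest has no column '", col, "'")
    tab <- table(manifest[[col]], manifest$cohort)
    pct <- prop.table(tab, margin = 2L) * 100
    list(counts = tab, percent = pct)
  })
  names(cat_tabs) <- categorical
  structure(list(per_cohort = per_cohort, categorical = cat_tabs,
                 tests = tests),
            class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  print(x$per_cohort)
  cat(sprintf("Wilcoxon p: lesion count %.4g, lesion volume %.4g\n",
              x$tests$lesion_count_p, x$tests$lesion_volume_p))
  invisible(x)
}
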