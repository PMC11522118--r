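test_that("identical groups give t = 0, p = 1 and a tie direction", {
  x <- c(10, 20, 30, 40)
  cmp <- compare_feature(x, x)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_false(cmp$significant)
  expect_equal(cmp$higher_cv_cohort, "tie")
  expect_true(cmp$testable)

  # constant-but-different groups: the t.test fallback path
  con <- compare_feature(c(5, 5, 5), c(9, 9, 9))
  expect_equal(con$p, 0)
  expect_true(con$significant)
  expect_equal(con$higher_cv_cohort, "B")
  same <- compare_feature(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("the Welch test matches an independent recomputation", {
  cv_a <- c(10, 11, 9, 10)
  cv_b <- c(30, 31, 29, 30)
  cmp <- compare_feature(cv_a, cv_b)
  orc <- welch_oracle(cv_a, cv_b)
  expect_equal(cmp$t, orc$t, tolerance = 1e-12)
  expect_equal(cmp$p, orc$p, tolerance = 1e-12)
  expect_true(cmp$significant)
  expect_equal(cmp$higher_cv_cohort, "B")

  # random Welch checks across unequal sizes and variances
  set.seed(60)
  for (k in 1:50) {
    a <- rnorm(sample(3:9, 1), 20, runif(1, 1, 10))
    b <- rnorm(sample(3:9, 1), 25, runif(1, 1, 10))
    cmp <- compare_feature(a, b)
    orc <- welch_oracle(a, b)
    expect_equal(cmp$t, orc$t, tolerance = 1e-10)
    expect_equal(cmp$p, orc$p, tolerance = 1e-10)
  }

  # pooled-variance option agrees with stats::t.test(var.equal = TRUE)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  cmp_eq <- compare_feature(a, b, var_equal = TRUE)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp_eq$t, unname(ref$statistic))
  expect_equal(cmp_eq$p, ref$p.value)
})

test_that("swapping the group labels flips t and the direction only", {
  set.seed(61)
  a <- rlnorm(6, 3, 0.4)
  b <- rlnorm(8, 3.4, 0.4)
  ab <- compare_feature(a, b)
  ba <- compare_feature(b, a)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$mean_cv_a, ba$mean_cv_b)
  expect_true(ab$higher_cv_cohort != ba$higher_cv_cohort)
})

test_that("small groups and NA values make a feature untestable", {
  cmp <- compare_feature(5, c(1, 2, 3))
  expect_false(cmp$testable)
  expect_true(is.na(cmp$p))
  expect_true(is.na(cmp$significant))
  # non-finite entries are dropped before the size check
  cmp2 <- compare_feature(c(10, NA, NaN), c(1, 2, 3))
  expect_false(cmp2$testable)
  expect_equal(cmp2$n_a, 1L)
  # alpha = 1 marks everything significant (p < 1 strictly)
  expect_true(compare_feature(c(1, 2, 3), c(2, 3, 4), alpha = 1)$significant)
})

make_cv_study <- function(seed = 70, shift = 12) {
  # 6 + 6 patients, 75-column feature table; cohort B lesions are more
  # dispersed within patients for every feature
  set.seed(seed)
  pats <- c(paste0("a", 1:6), paste0("b", 1:6))
  rows <- do.call(rbind, lapply(pats, function(p) {
    n <- sample(3:5, 1)
    data.frame(patient_id = p, lesion_id = seq_len(n),
               stringsAsFactors = FALSE)
  }))
  sdlog <- ifelse(startsWith(rows$patient_id, "b"), 0.5, 0.1)
  for (f in feature_names())
    rows[[f]] <- rlnorm(nrow(rows), meanlog = 4, sdlog = sdlog)
  manifest <- data.frame(patient_id = pats,
                         cohort = rep(c("A", "B"), each = 6),
                         stringsAsFactors = FALSE)
  build_cv_matrix(rows, manifest)
}

test_that("the full screen reports one consistent row per feature", {
  cv <- make_cv_study()
  rep <- screen_all(cv)
  tab <- rep$table
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(tab), 75L)
  expect_identical(tab$feature, feature_names())
  expect_true(all(tab$testable))
  expect_equal(tab$n_a, rep(6L, 75))

  # every p recomputes from the stored group means via the cv matrix
  pats_a <- rownames(cv$cv)[1:6]
  pats_b <- rownames(cv$cv)[7:12]
  for (f in sample(feature_names(), 10)) {
    orc <- welch_oracle(cv$cv[pats_a, f], cv$cv[pats_b, f])
    expect_equal(tab$p[tab$feature == f], orc$p, tolerance = 1e-10)
  }

  # significance flag is exactly p < alpha, q is BH over the 75 p-values
  expect_identical(tab$significant, tab$p < rep$alpha)
  expect_equal(tab$q, p.adjust(tab$p, method = "BH"))
  expect_true(all(tab$q >= tab$p))

  # counts agree with the table
  sig <- tab[tab$significant, ]
  expect_equal(rep$counts$n_significant, nrow(sig))
  expect_equal(rep$counts$n_higher_a, sum(sig$higher_cv_cohort == "A"))
  expect_equal(rep$counts$n_higher_b, sum(sig$higher_cv_cohort == "B"))
  expect_equal(rep$counts$n_tested, 75L)

  # by construction B is the dispersed cohort
  expect_gt(rep$counts$n_higher_b, rep$counts$n_higher_a)
  expect_output(print(rep), "features significant")
})

test_that("screen_all requires exactly two cohorts", {
  cv <- make_cv_study()
  cv$manifest$cohort <- "A"
  expect_error(screen_all(cv), "two cohorts")
  cv3 <- make_cv_study()
  cv3$manifest$cohort[1] <- "C"
  expect_error(screen_all(cv3), "two cohorts")
})

test_that("radar table holds the significant features, sorted by name", {
  cv <- make_cv_study()
  rep <- screen_all(cv)
  rad <- radar_table(rep)
  expect_equal(nrow(rad), rep$counts$n_significant)
  expect_false(is.unsorted(rad$feature))
  expect_identical(names(rad), c("feature", "mean_cv_A", "mean_cv_B"))
  f <- rad$feature[1]
  expect_equal(rad$mean_cv_A[1],
               rep$table$mean_cv_a[rep$table$feature == f])

  # nothing significant -> empty table with the same columns
  rep0 <- screen_all(cv, alpha = 1e-300)
  expect_equal(nrow(radar_table(rep0)), 0L)
})

test_that("cohort descriptives summarise counts, volumes and covariates", {
  manifest <- data.frame(
    patient_id = c("p1", "p2", "p3", "q1", "q2"),
    cohort = c("A", "A", "A", "B", "B"),
    sex = c("male", "male", "female", "female", "male"),
    stringsAsFactors = FALSE)
  lesions <- data.frame(
    patient_id = rep(c("p1", "p2", "p3", "q1", "q2"), c(2, 4, 6, 3, 3)),
    volume_mm3 = c(rep(100, 12), rep(900, 6)),
    stringsAsFactors = FALSE)
  d <- cohort_descriptives(manifest, lesions, categorical = "sex")
  a <- d$per_cohort[d$per_cohort$cohort == "A", ]
  expect_equal(a$n_patients, 3)
  expect_equal(a$n_lesions, 12)
  expect_equal(a$lesions_mean, 4)       # mean of 2, 4, 6
  expect_equal(a$lesions_median, 4)
  expect_equal(a$mean_lesion_volume_mm3, 100)
  b <- d$per_cohort[d$per_cohort$cohort == "B", ]
  expect_equal(b$lesions_min, 3)
  expect_equal(b$lesions_max, 3)
  expect_equal(d$categorical$sex$counts["male", "A"],
               structure(2L, dim = NULL), ignore_attr = TRUE)
  expect_equal(unname(d$categorical$sex$percent["male", "A"]), 200 / 3,
               tolerance = 1e-12)
  expect_true(is.finite(d$tests$lesion_count_p))
  expect_error(cohort_descriptives(manifest,
                                   data.frame(patient_id = "zz")),
               "unknown patient")
  expect_error(cohort_descriptives(manifest, lesions,
                                   categorical = "age"), "no column")
})

test_that("the Wilcoxon comparisons match exact enumeration", {
  manifest <- data.frame(patient_id = c("p1", "p2", "p3",
                                        "q1", "q2", "q3"),
                         cohort = rep(c("A", "B"), each = 3),
                         stringsAsFactors = FALSE)
  # per-patient lesion counts 1,2,3 vs 4,5,6: exact two-sided p = 2/20 = 0.1
  lesions <- data.frame(
    patient_id = rep(manifest$patient_id, c(1, 2, 3, 4, 5, 6)),
    stringsAsFactors = FALSE)
  d <- cohort_descriptives(manifest, lesions)
  expect_equal(d$tests$lesion_count_p, 0.1)
  expect_equal(d$tests$lesion_count_p,
               wilcox_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_true(is.na(d$tests$lesion_volume_p))  # no volume column

  # identical count multisets: p = 1
  lesions2 <- data.frame(
    patient_id = rep(manifest$patient_id, c(2, 3, 4, 4, 3, 2)),
    stringsAsFactors = FALSE)
  d2 <- cohort_descriptives(manifest, lesions2)
  expect_equal(d2$tests$lesion_count_p, 1)

  # a second random configuration against the enumeration oracle
  set.seed(77)
  ca <- sample(1:9, 4); cb <- sample(10:19, 3)
  m3 <- data.frame(patient_id = paste0("r", 1:7),
                   cohort = rep(c("A", "B"), c(4, 3)),
                   stringsAsFactors = FALSE)
  l3 <- data.frame(patient_id = rep(m3$patient_id, c(ca, cb)),
                   stringsAsFactors = FALSE)
  d3 <- cohort_descriptives(m3, l3)
  expect_equal(d3$tests$lesion_count_p, wilcox_exact_oracle(ca, cb),
               tolerance = 1e-12)
})
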