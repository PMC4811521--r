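test_that("Kaplan-Meier curves behave like survival curves", {
  set.seed(41)
  n <- 300
  tm <- stats::rexp(n, 0.02); ev <- stats::rbinom(n, 1, 0.7)
  g <- sample(c("I", "II"), n, replace = TRUE)
  km <- kaplan_meier(tm, ev, g)
  expect_true(all(km$fit$surv <= 1))
  expect_true(all(diff(km$fit$surv[seq_len(km$fit$strata[1])]) <= 0))
  expect_equal(km$df, 1L)

  # without censoring the KM estimate is the empirical survival function
  km2 <- kaplan_meier(tm, rep(1, n), rep("I", n))
  s_emp <- vapply(km2$fit$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km2$fit$surv, s_emp, tolerance = 1e-12)
  expect_null(km2$p)
})

test_that("the logrank p-value is calibrated under the null", {
  set.seed(43)
  ps <- replicate(500, {
    tm <- stats::rexp(400, 0.02); ev <- stats::rbinom(400, 1, 0.7)
    g <- sample(c("I", "II"), 400, replace = TRUE)
    kaplan_meier(tm, ev, g)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the unadjusted classifier HRR equals a direct two-group Cox fit", {
  cfg <- profile_classes(n_patients = 600, seed = 47)
  coh <- generate_cohort(cfg)
  feats <- dichotomized_features(coh, profile_cutoffs(cfg))
  cls <- assign_classes(class_structure_tree(), feats)
  groups <- factor(ifelse(cls %in% c("C", "D"), "II", "I"), levels = c("I", "II"))
  res <- classifier_hrr(coh, groups, adjust = FALSE)
  direct <- survival::coxph(
    survival::Surv(coh$os_months, coh$event) ~ I(groups == "II"), ties = "efron")
  expect_equal(res$hrr, unname(exp(stats::coef(direct))), tolerance = 1e-8)

  # identical survival in both groups: HRR near one
  set.seed(48)
  nullco <- coh
  g0 <- factor(sample(c("I", "II"), nrow(coh), replace = TRUE))
  r0 <- classifier_hrr(nullco, g0, adjust = FALSE)
  expect_gt(r0$hrr, 0.8); expect_lt(r0$hrr, 1.25)

  expect_error(classifier_hrr(coh, factor(rep("I", nrow(coh)),
                                          levels = c("I", "II"))),
               "non-empty")
})

test_that("permutation correction is definitional and reproducible", {
  cfg <- profile_classes(n_patients = 500, seed = 51)
  coh <- generate_cohort(cfg)
  pr <- suppressWarnings(
    permutation_corrected_p(coh, profile_cutoffs(cfg), n_perm = 60, seed = 3))
  # the corrected p is exactly the strict counting rule on the permuted p's
  expect_equal(pr$p_corrected, mean(pr$perm_p < pr$p_uncorrected))
  expect_equal(pr$p_corrected_add_one,
               (sum(pr$perm_p < pr$p_uncorrected) + 1) / (pr$n_perm + 1))
  expect_gte(pr$p_corrected_randomized, 0)
  expect_lte(pr$p_corrected_randomized, 1)

  pr2 <- suppressWarnings(
    permutation_corrected_p(coh, profile_cutoffs(cfg), n_perm = 60, seed = 3))
  expect_identical(pr$perm_p, pr2$perm_p)
  expect_identical(pr$p_corrected_randomized, pr2$p_corrected_randomized)

  expect_warning(permutation_corrected_p(coh, profile_cutoffs(cfg),
                                         n_perm = 20, seed = 4), "resolution")

  # a strongly prognostic cohort beats every one of its permutations
  expect_equal(pr$p_corrected, 0)
  expect_output(print(pr), "corrected p = <")  # reported as below resolution
})

test_that("nested model comparison detects a real classifier effect", {
  cfg <- profile_classes(n_patients = 800, seed = 57)
  coh <- generate_cohort(cfg)
  feats <- dichotomized_features(coh, profile_cutoffs(cfg))
  cls <- assign_classes(class_structure_tree(), feats)
  groups <- factor(ifelse(cls %in% c("C", "D"), "II", "I"), levels = c("I", "II"))
  cmp <- compare_models(coh, groups)
  expect_equal(cmp$df, 1L)
  expect_lt(cmp$p, 0.05)

  # a classifier duplicating an existing covariate adds no degrees of freedom
  dup <- factor(ifelse(coh$node_positive == 1, "II", "I"), levels = c("I", "II"))
  cmp2 <- compare_models(coh, dup)
  expect_true(cmp2$df_collapsed)
  expect_equal(cmp2$chisq, 0, tolerance = 1e-6)
})

test_that("the likelihood-ratio statistic is chi-square under the null", {
  set.seed(59)
  stats_null <- replicate(200, {
    n <- 400
    tm <- stats::rexp(n, 0.02); ev <- stats::rbinom(n, 1, 0.75)
    coh <- data.frame(os_months = tm, event = ev)
    for (cf in clinical_factors()) coh[[cf]] <- stats::rbinom(n, 1, 0.4)
    g <- factor(sample(c("I", "II"), n, replace = TRUE))
    compare_models(coh, g)$chisq
  })
  ks <- suppressWarnings(stats::ks.test(stats_null, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("subgroup analyses keep the full-cohort classifier fixed", {
  # colon patients carry the class effect, rectum patients none
  cfg_c <- profile_classes(n_patients = 500, seed = 61)
  cfg_r <- profile_classes(n_patients = 500, seed = 62)
  colon <- generate_cohort(cfg_c); colon$primary_site <- "colon"
  rectum <- generate_null_cohort(cfg_r); rectum$primary_site <- "rectum"
  rectum$patient_id <- sub("^P", "R", rectum$patient_id)
  coh <- rbind(colon, rectum)

  feats <- dichotomized_features(coh, profile_cutoffs(cfg_c))
  cls <- assign_classes(class_structure_tree(), feats)
  groups <- factor(ifelse(cls %in% c("C", "D"), "II", "I"), levels = c("I", "II"))

  sub <- subgroup_analysis(coh, groups, "primary_site", n_perm = 120, seed = 5)
  expect_equal(nrow(sub), 2L)
  expect_true(all(sub$estimable))
  hrr_colon <- sub$hrr[sub$stratum == "primary_site=colon"]
  hrr_rectum <- sub$hrr[sub$stratum == "primary_site=rectum"]
  expect_gt(hrr_colon, hrr_rectum)
  expect_lt(sub$p_corrected[sub$stratum == "primary_site=colon"], 0.05)

  # an empty stratum is reported non-estimable, not an error
  coh2 <- coh; coh2$primary_site <- "colon"
  sub2 <- subgroup_analysis(coh2, groups, "primary_site", n_perm = 50, seed = 6)
  expect_false(sub2$estimable[sub2$stratum == "primary_site=rectum"])
  expect_true(is.na(sub2$hrr[sub2$stratum == "primary_site=rectum"]))
})
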