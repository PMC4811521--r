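test_that("generation is deterministic under a fixed seed", {
  cfg <- profile_markers(n_patients = 200, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfgm <- profile_classes(n_patients = 150, seed = 3, matched = TRUE)
  expect_identical(as.data.frame(generate_matched_pairs(cfgm)),
                   as.data.frame(generate_matched_pairs(cfgm)))
  expect_identical(generate_null_cohort(cfg), generate_null_cohort(cfg))
})

test_that("marginal score frequencies follow the configured distribution", {
  probs <- c(0.1, 0.2, 0.3, 0.4)
  cfg <- synthetic_config(
    n_patients = 5000,
    markers = list(M1 = marker_spec(score_probs_int = probs)),
    seed = 11)
  coh <- generate_cohort(cfg)
  freq <- as.numeric(table(factor(coh$M1_crclm_int, levels = 0:3))) / 5000
  # binomial tolerance: 4 sd of a proportion at n = 5000
  expect_true(all(abs(freq - probs) < 4 * sqrt(probs * (1 - probs) / 5000)))
})

test_that("null effects produce hazard ratios near one", {
  cfg <- profile_markers(n_patients = 5000, seed = 5)
  coh <- generate_null_cohort(cfg)
  x <- as.numeric(coh$AURKA_crclm_int >= 2)
  fit <- survival::coxph(survival::Surv(coh$os_months, coh$event) ~ x)
  expect_gt(exp(stats::coef(fit)), 0.9)
  expect_lt(exp(stats::coef(fit)), 1.1)
})

test_that("a known marker effect is recovered by an independent Cox fit", {
  cfg <- synthetic_config(
    n_patients = 5000,
    markers = list(AURKA = marker_spec(log_hrr = log(2), cutoff = 2L)),
    censor_rate = 0, admin_censor_months = Inf, baseline_rate = 0.02,
    seed = 21)
  coh <- generate_cohort(cfg)
  expect_equal(mean(coh$event), 1)  # no censoring
  x <- as.numeric(coh$AURKA_crclm_int >= 2)
  fit <- survival::coxph(survival::Surv(coh$os_months, coh$event) ~ x)
  hrr <- unname(exp(stats::coef(fit)))
  expect_gt(hrr, 1.8)
  expect_lt(hrr, 2.2)
})

test_that("zero-covariate survival matches exponential closed forms", {
  cfg <- synthetic_config(
    n_patients = 10000,
    markers = list(M = marker_spec()),
    clinical_log_hrr = 0, baseline_rate = 0.02, censor_rate = 0,
    admin_censor_months = Inf, seed = 13)
  coh <- generate_cohort(cfg)
  km <- survival::survfit(survival::Surv(os_months, event) ~ 1, data = coh)
  med <- unname(summary(km)$table["median"])
  expect_lt(abs(med - log(2) / 0.02) / (log(2) / 0.02), 0.05)

  # competing exponentials: event fraction = rate / (rate + censor_rate)
  cfg2 <- synthetic_config(
    n_patients = 10000, markers = list(M = marker_spec()),
    clinical_log_hrr = 0, baseline_rate = 0.02, censor_rate = 0.01,
    admin_censor_months = Inf, seed = 14)
  coh2 <- generate_cohort(cfg2)
  expect_lt(abs(mean(coh2$event) - 2 / 3), 0.02)
})

test_that("matched pairs realise the requested cross-lesion correlation", {
  base <- function(rho) synthetic_config(
    n_patients = 5000,
    markers = list(M = marker_spec(pair_correlation = rho)),
    seed = 31)
  r_of <- function(rho) {
    coh <- generate_matched_pairs(base(rho))
    stats::cor(coh$M_prim_int, coh$M_crclm_int)
  }
  expect_lt(abs(r_of(0)), 0.05)
  expect_equal(r_of(1), 1)

  rho <- calibrate_pair_correlation(0.34, rep(0.25, 4))
  expect_equal(implied_ordinal_correlation(rho, rep(0.25, 4)), 0.34,
               tolerance = 1e-5)
  r <- r_of(rho)
  expect_gt(r, 0.29)
  expect_lt(r, 0.39)
})

test_that("the implied ordinal correlation matches large-sample simulation", {
  probs <- c(0.4, 0.3, 0.2, 0.1)
  rho <- 0.5
  implied <- implied_ordinal_correlation(rho, probs)
  cfg <- synthetic_config(
    n_patients = 2e5,
    markers = list(M = marker_spec(score_probs_int = probs,
                                   score_probs_freq = probs,
                                   pair_correlation = rho)),
    seed = 41)
  coh <- generate_matched_pairs(cfg)
  expect_equal(stats::cor(coh$M_prim_int, coh$M_crclm_int), implied,
               tolerance = 0.012)
  expect_equal(attr(coh, "implied_pair_correlation")$implied_ordinal_r[1],
               implied)
})

test_that("null cohorts give calibrated logrank p-values", {
  ps <- vapply(1:1000, function(s) {
    cfg <- synthetic_config(
      n_patients = 300, markers = list(M = marker_spec()),
      baseline_rate = 0.015, censor_rate = 0.005, seed = 1000 + s)
    coh <- generate_null_cohort(cfg)
    g <- dichotomize(coh$M_crclm_int, 2)
    kaplan_meier(coh$os_months, coh$event, g)$p
  }, numeric(1))
  # super-uniformity check: KS against uniform not rejected
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid configurations are rejected with the field named", {
  mk <- list(M = marker_spec())
  expect_error(synthetic_config(0, mk), "n_patients")
  expect_error(synthetic_config(10, mk, baseline_rate = 0), "baseline_rate")
  expect_error(synthetic_config(10, mk, censor_rate = -1), "censor_rate")
  expect_error(synthetic_config(10, mk, missing_prob = 1), "missing_prob")
  expect_error(marker_spec(score_probs_int = c(0.5, 0.5, 0.2, 0)), "score_probs")
  expect_error(marker_spec(pair_correlation = 1.2), "pair_correlation")
  cfg <- synthetic_config(50, list(M = marker_spec()), seed = 2)
  expect_error(generate_matched_pairs(cfg), "pair_correlation")
})

test_that("missingness is applied per channel at the configured rate", {
  cfg <- synthetic_config(
    n_patients = 4000, markers = list(M = marker_spec()),
    missing_prob = 0.2, seed = 17)
  coh <- generate_cohort(cfg)
  expect_lt(abs(mean(is.na(coh$M_crclm_int)) - 0.2), 0.03)
  expect_lt(abs(mean(is.na(coh$M_crclm_freq)) - 0.2), 0.03)
  # independent across channels
  expect_gt(sum(!is.na(coh$M_crclm_int) & is.na(coh$M_crclm_freq)), 0)
})
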