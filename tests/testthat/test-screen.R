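test_that("the survival ROC cutoff matches exhaustive Youden without censoring", {
  # perfect separation at threshold 2
  times <- c(10, 20, 30, 80, 90, 100, 110, 120)
  events <- c(1, 1, 1, 0, 0, 0, 0, 0)
  scores <- c(2, 3, 2, 0, 1, 1, 0, 1)
  co <- survival_roc_cutoff(times, rep(1, 8), scores, horizon = 36)
  expect_equal(co$threshold, 2L)
  expect_equal(max(abs(attr(co, "youden"))), 1)

  # oracle equivalence on random uncensored data
  set.seed(5)
  for (i in 1:25) {
    n <- 120
    sc <- sample(0:3, n, replace = TRUE)
    tm <- stats::rexp(n, 0.02 * exp(0.6 * (sc >= 2)))
    co <- survival_roc_cutoff(tm, rep(1, n), sc, horizon = 36)
    expect_equal(co$threshold, brute_force_youden(tm, rep(1, n), sc, 36))
  }
})

test_that("a marker unrelated to survival has negligible Youden J", {
  set.seed(8)
  n <- 2000
  tm <- stats::rexp(n, 0.02)
  ev <- stats::rbinom(n, 1, 0.8)
  sc <- sample(0:3, n, replace = TRUE)
  co <- survival_roc_cutoff(tm, ev, sc, horizon = 36)
  expect_lt(max(abs(attr(co, "youden"))), 0.1)
})

test_that("degenerate cutoff inputs raise errors", {
  expect_error(survival_roc_cutoff(c(10, 20), c(1, 1), c(2, 2), 36),
               "constant")
  expect_error(survival_roc_cutoff(c(50, 60), c(1, 0), c(1, 2), 36),
               "no events")
})

test_that("opposite_proportion counts reversed-direction splits", {
  expect_equal(opposite_proportion(c(1.2, 1.5, 0.9, 1.1), 1.175), 0.25)
  expect_equal(opposite_proportion(c(1.2, 1.5, 1.1), 1.27), 0)
  expect_equal(opposite_proportion(c(2.0, 0.5), 1.25), 0.5)
  # protective average counts HRRs above one
  expect_equal(opposite_proportion(c(0.5, 0.6, 1.2), 0.7), 1 / 3)
  # exact ones count in neither direction
  expect_equal(opposite_proportion(c(1.0, 1.2, 0.8), 1.05), 1 / 3)
  expect_error(opposite_proportion(numeric(), 1.2), "empty")
})

test_that("stepwise elimination removes null covariates and keeps forced terms", {
  set.seed(12)
  n <- 5000
  x <- stats::rbinom(n, 1, 0.5)   # forced, true HRR 2
  z <- stats::rbinom(n, 1, 0.4)   # removable, no effect
  tm <- stats::rexp(n, 0.02 * exp(log(2) * x))
  ev <- rep(1, n)

  removed_ct <- 0
  for (i in 1:10) {
    idx <- sample(n, 1500)
    sw <- stepwise_backward_cox(tm[idx], ev[idx],
                                data.frame(x = x[idx], z = z[idx]),
                                stepwise_spec("x", "z"))
    expect_true("x" %in% sw$retained)
    if (!"z" %in% sw$retained) removed_ct <- removed_ct + 1
  }
  expect_gte(removed_ct, 8)  # Wald p uniform: removed when p > 0.1

  # forced effect recovered, consistent with the full independent fit
  sw_all <- stepwise_backward_cox(tm, ev, data.frame(x = x, z = z),
                                  stepwise_spec("x", "z"))
  hrr <- sw_all$hrrs$hrr[sw_all$hrrs$term == "x"]
  expect_gt(hrr, 1.8); expect_lt(hrr, 2.2)
  full <- survival::coxph(survival::Surv(tm, ev) ~ x + z)
  expect_equal(log(hrr), unname(stats::coef(full)["x"]), tolerance = 0.05)

  # no removable terms: identical to the plain fit
  sw0 <- stepwise_backward_cox(tm, ev, data.frame(x = x),
                               stepwise_spec("x", character()))
  uni <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "efron")
  expect_equal(stats::coef(sw0$fit), stats::coef(uni), tolerance = 1e-10)
})

test_that("channel selection takes the larger log-scale deviation", {
  fake <- function(marker, channel, hrr) {
    structure(list(marker = marker, channel = channel, hrr_av_multi = hrr),
              class = "cv_screen")
  }
  expect_equal(select_channel(fake("M", "intensity", 1.6),
                              fake("M", "frequency", 1.2))$channel, "intensity")
  # deviation is symmetric on the log scale
  expect_equal(select_channel(fake("M", "intensity", 0.5),
                              fake("M", "frequency", 1.5))$hrr_av_multi, 0.5)
  expect_message(tie <- select_channel(fake("M", "intensity", 1.3),
                                       fake("M", "frequency", 1.3)), "tie")
  expect_equal(tie$channel, "intensity")
})

test_that("candidate selection reproduces the screening shortlist", {
  screening <- data.frame(
    marker = c("EGFR", "PI3K", "AURKA", "Ki-67", "TK1", "KCNQ1", "IGF2",
               "VEGFA", "PDGFRB", "CEA", "MMP9", "CXCR4", "CXCL12", "MLH1",
               "MSH6", "PTGS2", "SLC2A1", "HIF1A"),
    hrr_av = c(1.54, 0.80, 1.66, 1.17, 1.31, 0.81, 0.96, 1.50, 1.10, 0.63,
               1.34, 0.91, 0.93, 1.17, 0.82, 1.59, 0.65, 0.77),
    opposite_prop = c(0.02, 0.20, 0.02, 0.20, 0.23, 0.09, 0.37, 0.02, 0.35,
                      0.05, 0.07, 0.25, 0.31, 0.21, 0.13, 0.01, 0.009, 0.06),
    stringsAsFactors = FALSE)
  sel <- select_candidates(screening, p_threshold = 0.10)
  expect_setequal(as.character(sel),
                  c("EGFR", "AURKA", "VEGFA", "PTGS2", "SLC2A1",
                    "KCNQ1", "CEA", "MMP9", "HIF1A"))

  all_half <- transform(screening, opposite_prop = 0.5)
  expect_error(select_candidates(all_half, 0.10), "threshold")
  expect_length(select_candidates(screening, 1.0), 18)
})

test_that("Monte-Carlo screening is reproducible and sane on a null cohort", {
  cfg <- profile_markers(n_patients = 1000, seed = 19)
  coh <- generate_null_cohort(cfg)

  r1 <- mccv_screen(coh, "AURKA", "intensity", n_splits = 150, seed = 4)
  r2 <- mccv_screen(coh, "AURKA", "intensity", n_splits = 150, seed = 4)
  expect_identical(r1$per_split, r2$per_split)

  expect_gt(r1$hrr_av_multi, 0.85)
  expect_lt(r1$hrr_av_multi, 1.18)
  expect_gt(r1$opposite_prop_multi, 0.3)
  expect_lt(r1$opposite_prop_multi, 0.7)
  # the two directional proportions and exact ties partition the splits
  expect_equal(r1$p_lt1_multi + r1$p_gt1_multi +
                 mean(r1$per_split$hrr_multi[r1$per_split$valid] == 1), 1)
})

test_that("screening refuses cohorts with too few scored patients", {
  cfg <- profile_markers(n_patients = 40, seed = 2, missing_prob = 0.5)
  coh <- generate_cohort(cfg)
  expect_error(mccv_screen(coh, "AURKA", "intensity", n_splits = 10, seed = 1),
               "fewer than 30")
})
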