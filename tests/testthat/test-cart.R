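three_year_factor <- function(x) {
  factor(ifelse(x == 1, "died_within_36", "survived_36"),
         levels = c("died_within_36", "survived_36"))
}

test_that("a perfectly predictive feature yields a single split with zero error", {
  set.seed(1)
  f <- stats::rbinom(300, 1, 0.5)
  m <- build_cart(data.frame(AURKA = f), three_year_factor(f), seed = 2)
  expect_equal(tree_depth(m$tree), 1L)
  expect_equal(m$markers, "AURKA")
  expect_equal(m$cv_error, 0)
})

test_that("an exclusive-or structure needs and gets a depth-two tree", {
  set.seed(3)
  n <- 400
  f1 <- stats::rbinom(n, 1, 0.5); f2 <- stats::rbinom(n, 1, 0.5)
  lab <- three_year_factor(as.numeric(xor(f1 == 1, f2 == 1)))
  # no single split separates an exclusive-or: only depth 2 attains zero error
  expect_gt(exhaustive_best_tree_errors(data.frame(f1), lab), 0)
  expect_equal(exhaustive_best_tree_errors(data.frame(f1, f2), lab), 0)
  m <- build_cart(data.frame(f1 = f1, f2 = f2), lab, seed = 4)
  expect_equal(tree_depth(m$tree), 2L)
  expect_lt(m$cv_error, 0.05)
})

test_that("the null construction is degenerate in nearly all datasets", {
  degenerate <- 0L
  for (s in 1:20) {
    cfg <- profile_classes(n_patients = 400, seed = s)
    coh <- generate_null_cohort(cfg)
    cons <- classifier_construction(coh, profile_cutoffs(cfg), seed = s)
    degenerate <- degenerate + cons$degenerate
  }
  # under the null the pruned tree is a stump or its grouping finds no
  # class beyond the HRR threshold
  expect_gte(degenerate, 18L)
})

test_that("constant labels give a root-only model", {
  m <- build_cart(data.frame(A = stats::rbinom(50, 1, 0.5)),
                  factor(rep("survived_36", 50),
                         levels = c("died_within_36", "survived_36")),
                  seed = 1)
  expect_equal(m$tree$type, "leaf")
  expect_equal(m$cv_error, 0)
  expect_error(build_cart(data.frame(), three_year_factor(c(0, 1))), "empty")
})

test_that("small-sample trees attain the exhaustively optimal training error", {
  fixtures <- list(
    list(f = expand.grid(A = 0:1, B = 0:1, C = 0:1)[rep(1:8, length.out = 12), ],
         rule = function(f) f$A),
    list(f = expand.grid(A = 0:1, B = 0:1, C = 0:1)[rep(1:8, length.out = 12), ],
         rule = function(f) pmax(f$A, f$B)),
    list(f = expand.grid(A = 0:1, B = 0:1)[rep(1:4, 3), ],
         rule = function(f) f$A * f$B))
  for (fx in fixtures) {
    lab <- three_year_factor(fx$rule(fx$f))
    m <- build_cart(fx$f, lab, cv_folds = 3, min_bucket = 1, seed = 5)
    pred_class <- assign_classes(m, fx$f)
    # training error of the selected tree: majority call within each leaf
    err <- sum(unlist(tapply(lab, pred_class,
                             function(l) length(l) - max(table(l)))))
    expect_equal(err, exhaustive_best_tree_errors(fx$f, lab))
  }
})

test_that("class letters follow the canonical depth-first low-first order", {
  model <- class_structure_tree()
  expect_equal(sort(leaf_classes(model$tree)), c("A", "B", "C", "D"))
  feats <- data.frame(AURKA = c(0, 1, 1, 1, 0, 1),
                      PTGS2 = c(1, 0, 0, 1, NA, NA),
                      MMP9  = c(0, 0, 1, NA, 1, 0))
  cls <- assign_classes(model, feats)
  expect_equal(cls[1], "A")   # low AURKA, whatever the rest
  expect_equal(cls[2], "B")   # high AURKA, low PTGS2, low MMP9
  expect_equal(cls[3], "C")   # high AURKA, low PTGS2, high MMP9
  expect_equal(cls[4], "D")   # high AURKA, high PTGS2; MMP9 not queried
  expect_equal(cls[5], "A")   # PTGS2 missing but not on the A path
  expect_true(is.na(cls[6]))  # PTGS2 missing on the queried path
  expect_error(assign_classes(model, feats[, 1:2]), "MMP9")
})

test_that("tree routing partitions every complete-feature patient", {
  cfg <- profile_classes(n_patients = 500, seed = 23)
  coh <- generate_cohort(cfg)
  feats <- dichotomized_features(coh, profile_cutoffs(cfg))
  cls <- assign_classes(class_structure_tree(), feats)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), nrow(coh))
})

test_that("class HRRs use the best-surviving class as reference", {
  set.seed(31)
  n <- 2000
  cls <- sample(c("A", "B"), n, replace = TRUE)
  tm <- stats::rexp(n, 0.02)   # identical distributions
  ev <- stats::rbinom(n, 1, 0.85)
  ch <- class_hrrs(cls, tm, ev)
  expect_equal(ch$hrr[ch$reference], 1)
  hrr_b <- ch$hrr[!ch$reference]
  expect_gt(hrr_b, 0.85); expect_lt(hrr_b, 1.18)

  # generative ratio 3 recovered, and equal to a direct two-group fit
  tm2 <- stats::rexp(n, 0.02 * exp(log(3) * (cls == "B")))
  ch2 <- class_hrrs(cls, tm2, rep(1, n))
  expect_equal(ch2$class[ch2$reference], "A")
  hrr2 <- ch2$hrr[ch2$class == "B"]
  expect_gt(hrr2, 2.6); expect_lt(hrr2, 3.5)
  direct <- survival::coxph(survival::Surv(tm2, rep(1, n)) ~ I(cls == "B"),
                            ties = "efron")
  expect_equal(hrr2, unname(exp(stats::coef(direct))), tolerance = 1e-10)

  expect_error(class_hrrs(rep("A", 10), stats::rexp(10, 0.1), rep(1, 10)),
               "two classes")
})

test_that("classes group into I and II at the HRR threshold", {
  g <- group_classes(c(B = 1.5, C = 2.8, D = 3.2), reference = "A")
  expect_equal(g$group_I, c("A", "B"))
  expect_equal(g$group_II, c("C", "D"))
  expect_true(g$discriminative)

  weak <- group_classes(c(B = 1.1, C = 1.4), reference = "A")
  expect_false(weak$discriminative)
  expect_length(weak$group_II, 0)

  # equality goes to group II
  boundary <- group_classes(c(B = 2.0), reference = "A")
  expect_equal(boundary$group_II, "B")

  expect_error(group_classes(numeric(), reference = "A"), "empty")
  expect_warning(group_classes(c(B = NA_real_, C = 2.5), reference = "A"),
                 "non-estimable")

  gr <- group_assign(g, c("A", "B", "C", "D", NA, "Z"))
  expect_equal(as.character(gr), c("I", "I", "II", "II", NA, NA))
})
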