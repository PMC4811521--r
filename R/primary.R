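#' Pearson correlation between matched primary-tumor and metastasis scores
#'
#' Ordinal scores are treated as numeric 0-3 and correlated per marker over
#' complete pairs; the two-sided p-value comes from the usual t test of the
#' correlation coefficient.
#'
#' @param cohort Cohort `data.frame` with both `*_prim_*` and `*_crclm_*`
#'   score columns.
#' @param markers Marker names to correlate.
#' @param channels Channel per marker: a single channel name recycled, or a
#'   named character vector (marker -> channel) matching the channel
#'   selected during screening.
#' @return `data.frame` (class `pair_correlation`) with `marker`, `n_pairs`,
#'   `r`, `p`; `p` is `NA` (flagged in `defined_p`) below 3 complete pairs.
#' @export
pair_correlations <- function(cohort, markers, channels = "intensity") {
  if (length(channels) == 1L && is.null(names(channels)))
    channels <- stats::setNames(rep(channels, length(markers)), markers)
  rows <- lapply(markers, function(m) {
    ch <- channels[[m]]
    x <- cohort[[score_column(m, "prim", ch)]]
    y <- cohort[[score_column(m, "crclm", ch)]]
    if (is.null(x) || is.null(y))
      stop("cohort lacks matched score columns for ", m, call. = FALSE)
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) {
      r <- if (n == 2L) suppressWarnings(stats::cor(x[ok], y[ok])) else NA_real_
      if (is.nan(r %||% NA_real_)) r <- NA_real_  # constant two-point vector
      return(data.frame(marker = m, channel = ch, n_pairs = n, r = r,
                        p = NA_real_, defined_p = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(marker = m, channel = ch, n_pairs = n,
               r = unname(ct$estimate), p = ct$p.value, defined_p = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pair_correlation", "data.frame")
  out
}

# collapse every split on `marker`; two leaf children merge into one leaf
# carrying the combined class label
prune_tree_marker <- function(tree, marker) {
  if (tree$type == "leaf") return(tree)
  tree$low <- prune_tree_marker(tree$low, marker)
  tree$high <- prune_tree_marker(tree$high, marker)
  if (tree$marker != marker) return(tree)
  if (tree$low$type == "leaf" && tree$high$type == "leaf") {
    n_lo <- tree$low$n; n_hi <- tree$high$n
    n <- if (is.na(n_lo) || is.na(n_hi)) NA_integer_ else n_lo + n_hi
    dfrac <- if (!is.na(n) && n > 0)
      (n_lo * tree$low$death_frac + n_hi * tree$high$death_frac) / n else NA_real_
    leaf <- tree_leaf(n = n, death_frac = dfrac)
    leaf$class <- paste(sort(c(tree$low$class, tree$high$class)), collapse = "/")
    return(leaf)
  }
  # split over deeper structure: keep the branch holding more patients
  warning("collapsing a non-terminal split on ", marker,
          "; keeping the larger branch")
  n_lo <- tree$low$n %||% NA_integer_; n_hi <- tree$high$n %||% NA_integer_
  if (!is.na(n_lo) && !is.na(n_hi) && n_hi > n_lo) tree$high else tree$low
}

leaf_sizes <- function(tree) {
  if (tree$type == "leaf") return(tree$n)
  sum(leaf_sizes(tree$low), leaf_sizes(tree$high))
}

# does the I/II grouping of a tree's classes coincide with a single marker's
# high/low status?  (checked by exhaustive enumeration of feature combos)
single_marker_rule <- function(model, grouping) {
  mk <- model$markers
  if (length(mk) == 0L) return(NULL)
  combos <- expand.grid(rep(list(c(0, 1)), length(mk)))
  names(combos) <- mk
  cls <- assign_classes(model, combos)
  grp <- as.character(group_assign(grouping, cls))
  for (m in mk) {
    if (all(grp == ifelse(combos[[m]] == 1, "II", "I"), na.rm = TRUE))
      return(m)
  }
  NULL
}

#' Apply the classifier to primary-tumor expression
#'
#' Markers whose expression is not concordant between the matched primary
#' tumor and the metastasis (pair correlation with `r <= 0` or `p >= 0.05`
#' by default) are pruned from the tree by collapsing their split; the
#' remaining classes are re-assigned from primary-tumor scores, their HRRs
#' re-estimated, and re-grouped at the HRR threshold.  On the canonical
#' three-marker tree, omitting MMP9 merges classes B and C and the
#' re-grouping reduces the classifier to the AURKA high-versus-low rule.
#'
#' @param model A [cart_model()] fitted on metastasis expression, carrying
#'   its `cutoffs`.
#' @param cohort Cohort `data.frame` with matched primary-tumor scores.
#' @param omit_uncorrelated Prune markers failing the concordance screen.
#' @param r_min,p_max Concordance screen: a marker is kept when its pair
#'   correlation has `r > r_min` and `p < p_max`.
#' @param grouping_threshold HRR boundary for classes I/II (default 2.0).
#' @param horizon Months for the reference-class choice (default 36).
#' @return List with `reduced_model`, `omitted` markers, `correlations`,
#'   per-patient `classes` and `groups` (over the survival analysis set),
#'   `class_hrr`, `grouping`, `hrr` (two-group Cox fit of II vs I), and
#'   `rule` (the single marker the grouping reduces to, or `NULL`).
#' @export
apply_classifier_primary <- function(model, cohort, omit_uncorrelated = TRUE,
                                     r_min = 0, p_max = 0.05,
                                     grouping_threshold = 2.0, horizon = 36) {
  stopifnot(inherits(model, "cart_model"))
  if (is.null(model$cutoffs))
    stop("model carries no cutoffs; set `cutoffs` when constructing it",
         call. = FALSE)
  channels <- vapply(model$cutoffs, `[[`, "", "channel")
  names(channels) <- vapply(model$cutoffs, `[[`, "", "marker")

  correlations <- pair_correlations(cohort, model$markers, channels)
  omitted <- character()
  tree <- model$tree
  if (omit_uncorrelated) {
    bad <- correlations$marker[correlations$r <= r_min |
                               is.na(correlations$p) | correlations$p >= p_max]
    for (m in bad) tree <- prune_tree_marker(tree, m)
    omitted <- intersect(model$markers, bad)
  }
  kept_cutoffs <- Filter(function(co) !co$marker %in% omitted, model$cutoffs)
  reduced <- cart_model(tree, cutoffs = kept_cutoffs)
  if (length(reduced$markers) == 0L)
    stop("no classifier remains after omitting uncorrelated markers",
         call. = FALSE)

  surv_set <- apply_exclusions(cohort, "survival")
  feats <- dichotomized_features(surv_set, kept_cutoffs, lesion = "prim")
  classes <- assign_classes(reduced, feats)
  ch <- class_hrrs(classes, surv_set$os_months, surv_set$event, horizon)
  grouping <- group_classes(ch, threshold = grouping_threshold)
  groups <- group_assign(grouping, classes)
  hrr <- if (grouping$discriminative)
    classifier_hrr(surv_set, groups, adjust = FALSE) else NULL

  list(reduced_model = reduced, omitted = omitted, correlations = correlations,
       classes = classes, groups = groups, class_hrr = ch, grouping = grouping,
       hrr = hrr, rule = single_marker_rule(reduced, grouping),
       cohort_surv = surv_set)
}
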