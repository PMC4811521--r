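# small deterministic cohorts and independent oracles used across tests

# a hand-rolled cohort with one marker, for IO and exclusion tests
manual_cohort <- function() {
  df <- data.frame(
    patient_id = sprintf("M%02d", 1:8),
    os_months = c(1.5, 20, 40, 36, 20, 80, 55, 10),
    event = c(1, 1, 1, 1, 0, 0, 1, 1),
    interval_lt_12mo = c(1, 0, 0, 1, 0, 1, 0, 0),
    node_positive = c(0, 1, 0, 1, 1, 0, 0, 1),
    diameter_gt_5cm = c(0, 0, 1, 0, 0, 1, 1, 0),
    multiple_crclm = c(1, 1, 0, 0, 1, 0, 0, 1),
    cea_gt_200 = c(0, 0, 0, 1, 0, 0, 1, 0),
    systemic_therapy = c(1, 0, 1, NA, 0, 1, 0, 1),
    primary_site = c("colon", "rectum", "colon", "colon", NA,
                     "rectum", "colon", "rectum"),
    AURKA_crclm_int = c(0L, 2L, 3L, 1L, 2L, 0L, 3L, NA),
    AURKA_crclm_freq = c(1L, 2L, 2L, 0L, 3L, 1L, 2L, 2L),
    MMP9_crclm_int = c(2L, NA, 1L, 3L, 0L, 2L, 1L, 0L),
    MMP9_crclm_freq = c(0L, 1L, 2L, 3L, 1L, 0L, 2L, 1L),
    stringsAsFactors = FALSE)
  df
}

# classical Youden cutoff on the uncensored died-by-horizon label,
# by exhaustive enumeration over the admissible thresholds
brute_force_youden <- function(times, events, scores, horizon) {
  died <- events == 1 & times <= horizon
  best_th <- NA_integer_; best_j <- -Inf
  for (th in 1:3) {
    if (!any(scores >= th) || !any(scores < th)) next
    sens <- mean(scores[died] >= th)
    spec <- mean(scores[!died] < th)
    j <- abs(sens + spec - 1)
    if (j > best_j + 1e-12) { best_j <- j; best_th <- th }
  }
  best_th
}

# Pearson r from first principles
brute_force_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# minimum achievable training misclassifications by ANY tree over binary
# features: every tree leaf is a union of feature cells, so the optimum
# classifies each distinct feature combination by its majority label
exhaustive_best_tree_errors <- function(features, labels) {
  cell <- apply(features, 1, paste, collapse = "")
  sum(tapply(labels, cell, function(l) min(table(factor(l, levels = unique(labels))))))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$low), tree_depth(node$high))
}

count_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  count_leaves(node$low) + count_leaves(node$high)
}

leaf_classes <- function(node) {
  if (node$type == "leaf") return(node$class)
  c(leaf_classes(node$low), leaf_classes(node$high))
}
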