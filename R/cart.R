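#' Tree node constructors
#'
#' A classifier tree is a nested structure of binary splits on dichotomised
#' markers: at a split node, patients with `low` expression of the split
#' marker go down the `low` branch and `high` expression down the `high`
#' branch.  Leaf classes are lettered A, B, C, ... in depth-first,
#' low-branch-first order, so the letters read off the tree the way the
#' class definitions are usually stated.
#'
#' @param marker Marker name the node splits on.
#' @param low,high Child nodes (further `tree_split()`s or `tree_leaf()`s).
#' @param n,death_frac Optional leaf statistics.
#' @return A tree node list.
#' @export
tree_split <- function(marker, low, high) {
  list(type = "split", marker = marker, low = low, high = high)
}

#' @rdname tree_split
#' @export
tree_leaf <- function(n = NA_integer_, death_frac = NA_real_) {
  list(type = "leaf", class = NA_character_, n = n, death_frac = death_frac)
}

# assign A, B, C, ... to leaves in depth-first low-first order
assign_leaf_letters <- function(tree) {
  counter <- 0L
  walk <- function(node) {
    if (node$type == "leaf") {
      counter <<- counter + 1L
      if (is.na(node$class %||% NA_character_))
        node$class <- LETTERS[counter]
      else counter <- counter  # merged leaves keep their combined label
      node
    } else {
      node$low <- walk(node$low)
      node$high <- walk(node$high)
      node
    }
  }
  walk(tree)
}

tree_markers <- function(tree) {
  if (tree$type == "leaf") return(character())
  unique(c(tree$marker, tree_markers(tree$low), tree_markers(tree$high)))
}

tree_classes <- function(tree) {
  if (tree$type == "leaf") return(tree$class)
  c(tree_classes(tree$low), tree_classes(tree$high))
}

#' Construct a classifier tree model
#'
#' Wraps a tree built with [tree_split()]/[tree_leaf()] (or extracted from a
#' fitted rpart object by [build_cart()]) together with the cutoffs used to
#' dichotomise its markers.
#'
#' @param tree Root node.
#' @param cutoffs Optional list of [ihc_cutoff()]s for the tree's markers.
#' @param cv_error Cross-validated misclassification proportion, if known.
#' @param cv_folds Number of CV folds used, if any.
#' @return An object of class `cart_model`.
#' @export
cart_model <- function(tree, cutoffs = NULL, cv_error = NA_real_, cv_folds = NA_integer_) {
  tree <- assign_leaf_letters(tree)
  structure(list(tree = tree, markers = tree_markers(tree), cutoffs = cutoffs,
                 cv_error = cv_error, cv_folds = cv_folds),
            class = "cart_model")
}

#' @export
print.cart_model <- function(x, ...) {
  cat("<cart_model> markers:", paste(x$markers, collapse = ", "),
      if (!is.na(x$cv_error)) sprintf("| CV error %.3f (%d-fold)", x$cv_error, x$cv_folds),
      "\n")
  show <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s%s-> class %s", pad, branch, node$class))
      if (!is.na(node$n)) cat(sprintf("  (n=%d, 3y death %.2f)", node$n, node$death_frac))
      cat("\n")
    } else {
      cat(sprintf("%s%s%s?\n", pad, branch, node$marker))
      show(node$low, indent + 1L, "low ")
      show(node$high, indent + 1L, "high ")
    }
  }
  show(x$tree, 0L, "")
  invisible(x)
}

#' The canonical three-marker class structure
#'
#' The tree whose four leaf classes are: A — low AURKA; B — high AURKA, low
#' PTGS2, low MMP9; C — high AURKA, low PTGS2, high MMP9; D — high AURKA,
#' high PTGS2.  This is the class structure the `profile_classes()`
#' synthetic profile generates hazards from.
#'
#' @return A `cart_model` with classes A-D.
#' @export
class_structure_tree <- function() {
  cart_model(
    tree_split("AURKA",
               low = tree_leaf(),
               high = tree_split("PTGS2",
                                 low = tree_split("MMP9",
                                                  low = tree_leaf(),
                                                  high = tree_leaf()),
                                 high = tree_leaf())))
}

#' Dichotomise a cohort's marker scores into a binary feature matrix
#'
#' @param cohort A cohort `data.frame`.
#' @param cutoffs List of [ihc_cutoff()] objects (one per marker).
#' @param lesion Which lesion's scores to use.
#' @return A `data.frame` of 0/1 columns named by marker (`NA` propagated).
#' @export
dichotomized_features <- function(cohort, cutoffs, lesion = c("crclm", "prim")) {
  lesion <- match.arg(lesion)
  out <- lapply(cutoffs, function(co) {
    col <- score_column(co$marker, lesion, co$channel)
    if (!col %in% names(cohort))
      stop("cohort lacks score column ", col, call. = FALSE)
    as.numeric(dichotomize(cohort[[col]], co) == "high")
  })
  names(out) <- vapply(cutoffs, `[[`, "", "marker")
  as.data.frame(out, optional = TRUE)
}

feature01 <- function(x) {
  if (is.factor(x)) as.numeric(x == "high") else as.numeric(x)
}

#' Fit a classification tree for three-year survival by cross-validated
#' cost-complexity pruning
#'
#' Grows a binary tree on dichotomised marker features by Gini-impurity
#' splitting (via \pkg{rpart}), computes the cost-complexity pruning
#' sequence, estimates each subtree's misclassification rate for the
#' three-year outcome by k-fold cross-validation, and returns the subtree
#' with the lowest cross-validated error (ties broken toward the smaller
#' tree).
#'
#' @param features `data.frame` of binary (0/1 or low/high) marker columns.
#' @param labels Three-year outcome per patient: a factor with levels
#'   `died_within_36` / `survived_36` (rows labelled `undefined` must have
#'   been excluded beforehand).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param min_bucket Minimum number of patients in a leaf (default 10).
#' @param seed Integer seed controlling the CV fold assignment.
#' @param select `"min"` picks the subtree with minimal CV error; `"1se"`
#'   the smallest subtree within one standard error of it.
#' @return A [cart_model()] with `cv_error` (absolute misclassification
#'   proportion) and the fitted rpart object in `$fit`.
#' @export
build_cart <- function(features, labels, cv_folds = 10L, min_bucket = 10L,
                       seed = 1L, select = c("min", "1se")) {
  select <- match.arg(select)
  if (NCOL(features) == 0L) stop("empty feature set", call. = FALSE)
  features <- as.data.frame(lapply(features, feature01), optional = TRUE)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) > 2L)
    stop("labels must be binary; drop `undefined` rows first", call. = FALSE)
  stopifnot(nrow(features) == length(labels))

  if (nlevels(labels) < 2L) {
    model <- cart_model(tree_leaf(n = length(labels),
                                  death_frac = mean(labels == "died_within_36")),
                        cv_error = 0, cv_folds = as.integer(cv_folds))
    return(model)
  }

  df <- cbind(.label = labels, features)
  set.seed(seed)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, xval = cv_folds, minbucket = min_bucket,
                        minsplit = 2L * min_bucket,
                        maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L))
  cpt <- fit$cptable
  if (is.null(cpt) || !"xerror" %in% colnames(cpt)) {
    best_row <- 1L
  } else if (select == "min") {
    xmin <- min(cpt[, "xerror"])
    cand <- which(cpt[, "xerror"] <= xmin + 1e-10)
    best_row <- cand[which.max(cpt[cand, "CP"])]  # equal error -> smaller tree
  } else {
    imin <- which.min(cpt[, "xerror"])
    lim <- cpt[imin, "xerror"] + cpt[imin, "xstd"]
    best_row <- min(which(cpt[, "xerror"] <= lim))
  }
  pruned <- rpart::prune(fit, cp = cpt[best_row, "CP"])

  root_err <- fit$frame$dev[1] / fit$frame$n[1]
  cv_error <- if (!is.null(cpt) && "xerror" %in% colnames(cpt))
    unname(cpt[best_row, "xerror"] * root_err) else root_err

  model <- cart_model(rpart_to_tree(pruned, died_level = "died_within_36"),
                      cv_error = cv_error, cv_folds = as.integer(cv_folds))
  model$fit <- pruned
  model
}

# convert a pruned rpart classification tree into the package's node lists
rpart_to_tree <- function(fit, died_level) {
  frame <- fit$frame
  ids <- as.integer(rownames(frame))
  ylevels <- attr(fit, "ylevels")
  died_ix <- which(ylevels == died_level)
  internal <- which(frame$var != "<leaf>")
  sp_of_frame <- integer(nrow(frame))
  sp_of_frame[internal] <- seq_along(internal)  # one split row per internal node

  build <- function(id) {
    row <- match(id, ids)
    if (frame$var[row] == "<leaf>") {
      n <- frame$n[row]
      died_n <- frame$yval2[row, 1L + died_ix]
      return(tree_leaf(n = n, death_frac = unname(died_n) / n))
    }
    marker <- as.character(frame$var[row])
    ncat <- fit$splits[sp_of_frame[row], "ncat"]
    left <- build(2L * id)
    right <- build(2L * id + 1L)
    if (ncat < 0) tree_split(marker, low = left, high = right)
    else tree_split(marker, low = right, high = left)
  }
  build(1L)
}

#' Route patients down a classifier tree
#'
#' @param model A [cart_model()].
#' @param features `data.frame` of binary marker columns covering the
#'   model's markers (0/1 or low/high).
#' @return Character vector of leaf class labels; `NA` when a marker queried
#'   on the patient's path is missing (such patients are excluded from
#'   downstream analyses).
#' @export
assign_classes <- function(model, features) {
  stopifnot(inherits(model, "cart_model"))
  missing_markers <- setdiff(model$markers, names(features))
  if (length(missing_markers))
    stop("feature matrix lacks marker(s): ", paste(missing_markers, collapse = ", "),
         call. = FALSE)
  features <- as.data.frame(lapply(features, feature01), optional = TRUE)
  n <- nrow(features)
  out <- rep(NA_character_, n)
  route <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$type == "leaf") {
      out[idx] <<- node$class
      return()
    }
    x <- features[[node$marker]][idx]
    route(node$low, idx[!is.na(x) & x == 0])
    route(node$high, idx[!is.na(x) & x == 1])
  }
  route(model$tree, seq_len(n))
  out
}

#' Hazard rate ratio of each tree class against the best-surviving class
#'
#' The reference is the class with the highest Kaplan-Meier survival at the
#' horizon (ties broken lexicographically); a Cox model with class
#' indicators then yields each class's HRR against it.
#'
#' @param classes Class label per patient (`NA` dropped).
#' @param times,events Overall survival and death indicator.
#' @param horizon Months at which reference survival is read (default 36).
#' @param conf_level Confidence level for the HRR intervals.
#' @return A `data.frame` (class `class_hrr`) with one row per class:
#'   `class`, `n`, `events`, `hrr`, `lower`, `upper`, `p`, `reference`.
#'   Classes with no events get `NA` HRR and a warning.
#' @export
class_hrrs <- function(classes, times, events, horizon = 36, conf_level = 0.95) {
  keep <- !is.na(classes) & !is.na(times) & !is.na(events)
  classes <- as.character(classes)[keep]
  times <- times[keep]; events <- events[keep]
  lev <- sort(unique(classes))
  if (length(lev) < 2L) stop("need at least two classes", call. = FALSE)

  cls <- factor(classes, levels = lev)
  km <- survival::survfit(survival::Surv(times, events) ~ cls)
  surv_at <- summary(km, times = horizon, extend = TRUE)
  s36 <- stats::setNames(surv_at$surv, sub("^cls=", "", surv_at$strata))
  s36 <- s36[lev]
  ref <- lev[which(s36 == max(s36))][1L]  # tie -> lexicographically first

  cls <- stats::relevel(cls, ref = ref)
  ev_by_class <- tapply(events, cls, sum)
  fit <- survival::coxph(survival::Surv(times, events) ~ cls, ties = "efron")
  sm <- summary(fit, conf.int = conf_level)
  out <- data.frame(class = lev, n = as.integer(table(factor(classes, levels = lev))),
                    events = as.integer(ev_by_class[lev]),
                    hrr = NA_real_, lower = NA_real_, upper = NA_real_, p = NA_real_,
                    reference = lev == ref, km_surv_horizon = unname(s36),
                    stringsAsFactors = FALSE)
  out$hrr[out$reference] <- 1
  for (lv in setdiff(lev, ref)) {
    term <- paste0("cls", lv)
    i <- match(term, rownames(sm$coefficients))
    if (ev_by_class[[lv]] == 0) {
      warning("class ", lv, " has no events; HRR non-estimable")
      next
    }
    out$hrr[out$class == lv] <- unname(sm$coefficients[i, "exp(coef)"])
    out$lower[out$class == lv] <- unname(sm$conf.int[i, 3L])
    out$upper[out$class == lv] <- unname(sm$conf.int[i, 4L])
    out$p[out$class == lv] <- unname(sm$coefficients[i, "Pr(>|z|)"])
  }
  class(out) <- c("class_hrr", "data.frame")
  out
}

#' Group tree classes into prognostic classes I and II by HRR similarity
#'
#' Classes whose HRR against the reference is below the threshold join the
#' reference in group I; classes at or above it form group II.  If every
#' class falls on one side, a single group is returned and the classifier is
#' flagged non-discriminative.
#'
#' @param hrrs A `class_hrr` data.frame from [class_hrrs()], or a named
#'   numeric vector of HRRs (in which case `reference` must name the
#'   reference class).
#' @param threshold HRR boundary (default 2.0); equality goes to group II.
#' @param reference Reference class name when `hrrs` is a bare vector.
#' @return An object of class `class_grouping` with elements `group_I`,
#'   `group_II`, `reference`, `threshold`, `discriminative`.
#' @export
group_classes <- function(hrrs, threshold = 2.0, reference = NULL) {
  if (inherits(hrrs, "class_hrr") || is.data.frame(hrrs)) {
    reference <- hrrs$class[hrrs$reference][1L]
    vec <- stats::setNames(hrrs$hrr, hrrs$class)
  } else {
    if (is.null(reference)) stop("`reference` required with a bare HRR vector", call. = FALSE)
    if (length(hrrs) == 0L) stop("empty HRR map", call. = FALSE)
    vec <- hrrs
    if (!reference %in% names(vec)) vec <- c(stats::setNames(1, reference), vec)
  }
  if (length(vec) == 0L) stop("empty HRR map", call. = FALSE)
  est <- vec[!is.na(vec)]
  if (length(est) < length(vec))
    warning("classes with non-estimable HRR excluded from grouping: ",
            paste(names(vec)[is.na(vec)], collapse = ", "))
  others <- setdiff(names(est), reference)
  group_II <- others[est[others] >= threshold]
  group_I <- c(reference, others[est[others] < threshold])
  structure(list(group_I = sort(group_I), group_II = sort(group_II),
                 reference = reference, threshold = threshold,
                 discriminative = length(group_II) > 0L && length(group_I) > 0L),
            class = "class_grouping")
}

#' @export
print.class_grouping <- function(x, ...) {
  cat(sprintf("<class_grouping> I = {%s}  II = {%s}  (reference %s, HRR threshold %.1f)%s\n",
              paste(x$group_I, collapse = ", "), paste(x$group_II, collapse = ", "),
              x$reference, x$threshold,
              if (!x$discriminative) "  [non-discriminative]" else ""))
  invisible(x)
}

#' Map leaf classes to prognostic groups I/II
#'
#' @param grouping A [group_classes()] result.
#' @param classes Leaf class label per patient.
#' @return Factor with levels `I`, `II` (`NA` for unknown classes).
#' @export
group_assign <- function(grouping, classes) {
  out <- rep(NA_character_, length(classes))
  out[classes %in% grouping$group_I] <- "I"
  out[classes %in% grouping$group_II] <- "II"
  factor(out, levels = c("I", "II"))
}
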