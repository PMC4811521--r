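#' Kaplan-Meier curves and logrank test per group
#'
#' @param times,events Overall survival outcome.
#' @param groups Group label per patient (`NA` dropped).
#' @return List with `fit` (a `survfit` object), and, when two or more
#'   groups are present, `chisq`, `df` and `p` from the logrank test
#'   (otherwise `NULL`s).
#' @export
kaplan_meier <- function(times, events, groups) {
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]
  groups <- droplevels(factor(groups[keep]))
  if (length(times) == 0L) stop("no patients with complete data", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  if (nlevels(groups) < 2L)
    return(list(fit = fit, chisq = NULL, df = NULL, p = NULL))
  lr <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(lr$n) - 1L
  list(fit = fit, chisq = unname(lr$chisq), df = df,
       p = stats::pchisq(lr$chisq, df, lower.tail = FALSE))
}

logrank_p <- function(times, events, groups) {
  kaplan_meier(times, events, groups)$p
}

#' Cox hazard rate ratio of prognostic class II versus class I
#'
#' @param cohort Cohort `data.frame` (its rows aligned with `groups`).
#' @param groups Factor `I`/`II` per patient (`NA` dropped).
#' @param adjust When `TRUE`, the five clinical risk factors enter the model
#'   and undergo stepwise backward elimination with the class term forced.
#' @param exit_p Stepwise exclusion criterion (default 0.1).
#' @return List with `hrr`, `lower`, `upper`, `p`, `retained` (clinical
#'   terms kept, when adjusting) and the fitted model.
#' @export
classifier_hrr <- function(cohort, groups, adjust = FALSE, exit_p = 0.1) {
  keep <- !is.na(groups) & !is.na(cohort$os_months) & !is.na(cohort$event)
  df <- cohort[keep, , drop = FALSE]
  g2 <- as.numeric(groups[keep] == "II")
  if (length(unique(g2)) < 2L)
    stop("both groups I and II must be non-empty", call. = FALSE)
  if (sum(df$event[g2 == 1]) < 1 || sum(df$event[g2 == 0]) < 1)
    stop("each group needs at least one event", call. = FALSE)

  if (!adjust) {
    res <- fit_coxph_flagged(survival::Surv(.time, .event) ~ .class,
                             data.frame(.time = df$os_months, .event = df$event,
                                        .class = g2))
    if (!res$converged) stop("Cox fit did not converge", call. = FALSE)
    sm <- summary(res$fit)
    return(list(hrr = unname(sm$coefficients[".class", "exp(coef)"]),
                lower = unname(sm$conf.int[".class", 3L]),
                upper = unname(sm$conf.int[".class", 4L]),
                p = unname(sm$coefficients[".class", "Pr(>|z|)"]),
                retained = character(), fit = res$fit))
  }

  covars <- cbind(.class = g2, as.data.frame(df[clinical_factors()], optional = TRUE))
  sw <- stepwise_backward_cox(df$os_months, df$event, covars,
                              stepwise_spec(".class", exit_p = exit_p))
  if (!sw$converged) stop("stepwise Cox fit did not converge", call. = FALSE)
  row <- sw$hrrs[sw$hrrs$term == ".class", ]
  list(hrr = row$hrr, lower = row$lower, upper = row$upper, p = row$p,
       retained = setdiff(sw$retained, ".class"), fit = sw$fit)
}

#' Run the classifier construction on one dataset
#'
#' The construction that the permutation correction repeats: dichotomise at
#' fixed cutoffs, fit the tree on the three-year outcome, derive class HRRs
#' against the best-surviving class, group classes at the HRR threshold,
#' and compute the logrank p of group II versus group I on overall
#' survival.  A construction whose pruned tree is a stump or whose grouping
#' is non-discriminative is degenerate and carries p = 1.
#'
#' @param cohort Cohort `data.frame`.
#' @param cutoffs List of [ihc_cutoff()]s defining the candidate features.
#' @param cv_folds,min_bucket Tree-building controls (see [build_cart()]).
#' @param grouping_threshold HRR boundary for classes I/II (default 2.0).
#' @param horizon Months defining the three-year-style outcome (default 36).
#' @param seed Seed for the CV fold assignment.
#' @param reoptimize_cutoffs When `TRUE`, the dichotomisation threshold of
#'   every marker is re-optimised on this dataset with
#'   [survival_roc_cutoff()] before the tree is built (used by the strict
#'   permutation mode).
#' @return List with `model`, `class_hrr`, `grouping`, `classes` and
#'   `groups` (per patient of the survival set), `p_uncorrected`,
#'   `degenerate`, and the survival analysis set `cohort_surv`.
#' @export
classifier_construction <- function(cohort, cutoffs, cv_folds = 10L,
                                    min_bucket = 10L, grouping_threshold = 2.0,
                                    horizon = 36, seed = 1L,
                                    reoptimize_cutoffs = FALSE) {
  surv_set <- apply_exclusions(cohort, "survival")
  if (reoptimize_cutoffs) {
    cutoffs <- lapply(cutoffs, function(co) {
      col <- score_column(co$marker, "crclm", co$channel)
      tryCatch(survival_roc_cutoff(surv_set$os_months, surv_set$event,
                                   surv_set[[col]], horizon, co$marker, co$channel),
               error = function(e) co)
    })
  }
  feats <- dichotomized_features(surv_set, cutoffs)
  labels <- label_three_year(surv_set$os_months, surv_set$event)
  build_idx <- labels != "undefined" & stats::complete.cases(feats)
  degenerate_result <- function(model = NULL) {
    list(model = model, class_hrr = NULL, grouping = NULL,
         classes = rep(NA_character_, nrow(surv_set)),
         groups = factor(rep(NA_character_, nrow(surv_set)), levels = c("I", "II")),
         p_uncorrected = 1, degenerate = TRUE, cohort_surv = surv_set,
         cutoffs = cutoffs)
  }
  if (sum(build_idx) < 2L * min_bucket) return(degenerate_result())
  model <- build_cart(feats[build_idx, , drop = FALSE],
                      droplevels(labels[build_idx]),
                      cv_folds = cv_folds, min_bucket = min_bucket, seed = seed)
  if (model$tree$type == "leaf") return(degenerate_result(model))

  classes <- assign_classes(model, feats)
  ch <- tryCatch(class_hrrs(classes, surv_set$os_months, surv_set$event, horizon),
                 error = function(e) NULL)
  if (is.null(ch)) return(degenerate_result(model))
  grouping <- suppressWarnings(group_classes(ch, threshold = grouping_threshold))
  if (!grouping$discriminative) return(degenerate_result(model))
  groups <- group_assign(grouping, classes)
  p <- tryCatch(logrank_p(surv_set$os_months, surv_set$event, groups),
                error = function(e) 1)
  list(model = model, class_hrr = ch, grouping = grouping, classes = classes,
       groups = groups, p_uncorrected = p %||% 1, degenerate = FALSE,
       cohort_surv = surv_set, cutoffs = cutoffs)
}

#' Permutation-corrected significance of the classifier
#'
#' The outcome pair (survival time, event) is permuted jointly across
#' patients while all marker and clinical columns stay fixed; for each
#' permuted dataset the full classifier construction
#' ([classifier_construction()]) is re-run and its logrank p recorded
#' (degenerate constructions contribute p = 1).  The corrected p-value is
#' the fraction of permuted p-values smaller than the original one.  Two
#' companions are reported: the add-one estimator (count + 1)/(n + 1), and
#' a randomised tie-broken rank (counting the observed dataset among its
#' own permutations) that is exactly uniform under the null and is the
#' right quantity for calibration checks — ties at p = 1 from degenerate
#' constructions otherwise create atoms in the strict estimator.
#'
#' @param cohort Cohort `data.frame`.
#' @param cutoffs Fixed screening-derived cutoffs (list of [ihc_cutoff()]);
#'   with `strict = TRUE` they are re-optimised inside every permutation.
#' @param n_perm Number of permutations (default 1000; values below 100
#'   trigger a resolution warning).
#' @param seed Master seed (one child seed per permutation).
#' @param strict Re-run the cutoff optimisation inside each permutation.
#' @param ... Passed to [classifier_construction()].
#' @return A `permutation_run`: `p_uncorrected`, `p_corrected`,
#'   `p_corrected_add_one`, `p_corrected_randomized`, the permuted p-values
#'   and the original construction.
#' @export
permutation_corrected_p <- function(cohort, cutoffs, n_perm = 1000L, seed = 1L,
                                    strict = FALSE, ...) {
  if (n_perm < 100L)
    warning("n_perm = ", n_perm, " limits the corrected-p resolution to 1/",
            n_perm)
  seeds <- spawn_seeds(seed, n_perm + 1L)
  original <- classifier_construction(cohort, cutoffs, seed = seeds[n_perm + 1L],
                                      reoptimize_cutoffs = strict, ...)
  p0 <- original$p_uncorrected

  perm_p <- vapply(seq_len(n_perm), function(b) {
    set.seed(seeds[b])
    idx <- sample.int(nrow(cohort))
    cohort_b <- cohort
    cohort_b$os_months <- cohort$os_months[idx]
    cohort_b$event <- cohort$event[idx]
    res <- classifier_construction(cohort_b, cutoffs, seed = seeds[b],
                                   reoptimize_cutoffs = strict, ...)
    res$p_uncorrected
  }, numeric(1))

  n_below <- sum(perm_p < p0)
  n_tied <- sum(perm_p == p0)
  set.seed(seeds[n_perm + 1L])
  u <- stats::runif(1)
  structure(list(
    p_uncorrected = p0,
    p_corrected = n_below / n_perm,
    p_corrected_add_one = (n_below + 1) / (n_perm + 1),
    p_corrected_randomized = (n_below + u * (n_tied + 1)) / (n_perm + 1),
    perm_p = perm_p, n_perm = n_perm, seed = seed,
    degenerate_original = original$degenerate, original = original),
    class = "permutation_run")
}

#' @export
print.permutation_run <- function(x, ...) {
  shown <- if (x$p_corrected == 0) sprintf("< %.4g", 1 / x$n_perm)
           else sprintf("%.4g", x$p_corrected)
  cat(sprintf("<permutation_run> uncorrected p = %.4g, corrected p = %s (n_perm = %d%s)\n",
              x$p_uncorrected, shown, x$n_perm,
              if (x$degenerate_original) ", original construction degenerate" else ""))
  invisible(x)
}

#' Compare the classifier against the clinicopathological model
#'
#' Analysis of deviance between nested Cox models: the clinical risk
#' factors alone versus the clinical risk factors plus the classifier
#' group.  The statistic is the difference in -2 log partial likelihood,
#' referred to a chi-square with as many degrees of freedom as estimable
#' added terms.
#'
#' @param cohort Cohort `data.frame`.
#' @param groups Factor `I`/`II` per patient (rows with `NA` dropped).
#' @param clinical_terms Covariates of the base model.
#' @return List with `chisq`, `df`, `p`, `df_collapsed` (TRUE when the
#'   added term is inestimable) and both fits.
#' @export
compare_models <- function(cohort, groups, clinical_terms = clinical_factors()) {
  keep <- !is.na(groups) & !is.na(cohort$os_months) & !is.na(cohort$event) &
    stats::complete.cases(cohort[clinical_terms])
  df <- cohort[keep, , drop = FALSE]
  df$.class <- as.numeric(groups[keep] == "II")
  fml0 <- stats::reformulate(clinical_terms,
                             response = quote(survival::Surv(os_months, event)))
  fml1 <- stats::reformulate(c(clinical_terms, ".class"),
                             response = quote(survival::Surv(os_months, event)))
  m0 <- survival::coxph(fml0, data = df, ties = "efron")
  m1 <- survival::coxph(fml1, data = df, ties = "efron")
  df_added <- sum(!is.na(stats::coef(m1))) - sum(!is.na(stats::coef(m0)))
  chisq <- max(0, 2 * (stats::logLik(m1)[1] - stats::logLik(m0)[1]))
  collapsed <- df_added < 1L
  list(chisq = chisq, df = df_added,
       p = if (collapsed) NA_real_ else stats::pchisq(chisq, df_added, lower.tail = FALSE),
       df_collapsed = collapsed, fit_clinical = m0, fit_full = m1)
}

#' Subgroup analysis of the fitted classifier
#'
#' The classifier is applied exactly as fitted on the full cohort (no
#' refit); within each stratum of the stratifier the Cox HRR of group II
#' versus group I is estimated and a permutation-corrected p-value is
#' computed by permuting the outcome pair within the stratum and
#' recomputing the logrank p of the fixed grouping.
#'
#' @param cohort Cohort `data.frame`.
#' @param groups Factor `I`/`II` per patient from the full-cohort fit.
#' @param stratifier `"systemic_therapy"` or `"primary_site"`; patients with
#'   an unknown stratifier value are excluded.
#' @param n_perm Number of within-stratum permutations (default 1000).
#' @param seed Master seed.
#' @return `data.frame` with one row per stratum: `stratum`, `n`, `events`,
#'   `hrr`, `lower`, `upper`, `p_uncorrected`, `p_corrected`, `estimable`.
#' @export
subgroup_analysis <- function(cohort, groups,
                              stratifier = c("systemic_therapy", "primary_site"),
                              n_perm = 1000L, seed = 1L) {
  stratifier <- match.arg(stratifier)
  strata_vals <- cohort[[stratifier]]
  levels_s <- if (stratifier == "primary_site") c("colon", "rectum") else c(0, 1)
  seeds <- spawn_seeds(seed, length(levels_s))

  rows <- lapply(seq_along(levels_s), function(i) {
    lv <- levels_s[i]
    idx <- which(!is.na(strata_vals) & strata_vals == lv & !is.na(groups))
    base <- data.frame(stratum = paste0(stratifier, "=", lv),
                       n = length(idx), events = sum(cohort$event[idx]),
                       hrr = NA_real_, lower = NA_real_, upper = NA_real_,
                       p_uncorrected = NA_real_, p_corrected = NA_real_,
                       estimable = FALSE, stringsAsFactors = FALSE)
    g <- droplevels(groups[idx])
    ev_by_g <- tapply(cohort$event[idx], g, sum)
    if (length(idx) == 0L || nlevels(g) < 2L || any(is.na(ev_by_g)) ||
        any(ev_by_g < 2))
      return(base)  # reported non-estimable
    fit <- classifier_hrr(cohort[idx, , drop = FALSE], g, adjust = FALSE)
    p_obs <- logrank_p(cohort$os_months[idx], cohort$event[idx], g)
    set.seed(seeds[i])
    perm_p <- replicate(n_perm, {
      jdx <- sample.int(length(idx))
      logrank_p(cohort$os_months[idx][jdx], cohort$event[idx][jdx], g)
    })
    base$hrr <- fit$hrr; base$lower <- fit$lower; base$upper <- fit$upper
    base$p_uncorrected <- p_obs
    base$p_corrected <- mean(perm_p < p_obs)
    base$estimable <- TRUE
    base
  })
  do.call(rbind, rows)
}
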