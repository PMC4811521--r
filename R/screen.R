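#' Optimal dichotomisation cutoff by time-dependent ROC analysis
#'
#' Estimates cumulative-case / dynamic-control sensitivity and specificity
#' at the horizon for each admissible ordinal threshold, using Kaplan-Meier
#' estimates of survival within the high- and low-score groups (the
#' censoring-robust analogue of classifying died-by-horizon status), and
#' returns the threshold maximising Youden's J = sensitivity + specificity
#' - 1.  For markers whose high expression is protective, J is negative at
#' every threshold under the died-by-horizon orientation, so the
#' discriminative optimum is taken as the largest |J| (Youden's J with the
#' positivity direction reversed).  Ties go to the lowest threshold.
#'
#' @param times,events Overall survival times and death indicators.
#' @param scores Ordinal marker scores 0-3 (`NA` dropped).
#' @param horizon Months at which the ROC is evaluated (default 36).
#' @param marker,channel Labels stamped on the returned cutoff.
#' @return An [ihc_cutoff()] with attributes `youden` (J per threshold),
#'   `sensitivity` and `specificity`.
#' @export
survival_roc_cutoff <- function(times, events, scores, horizon = 36,
                                marker = "marker", channel = "intensity") {
  keep <- !is.na(times) & !is.na(events) & !is.na(scores)
  times <- times[keep]; events <- events[keep]; scores <- scores[keep]
  if (length(unique(scores)) < 2L)
    stop("no admissible cutoff: marker score is constant", call. = FALSE)
  if (!any(events == 1 & times <= horizon))
    stop("no events before the horizon", call. = FALSE)

  thresholds <- Filter(function(th) any(scores >= th) && any(scores < th), 1:3)
  if (length(thresholds) == 0L)
    stop("no admissible cutoff: no threshold separates the scores", call. = FALSE)

  sens <- spec <- stats::setNames(rep(NA_real_, length(thresholds)),
                                  paste0(">=", thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[i]
    hi <- scores >= th
    p_hi <- mean(hi)
    s_hi <- km_survival_at(times[hi], events[hi], horizon)
    s_lo <- km_survival_at(times[!hi], events[!hi], horizon)
    s_all <- p_hi * s_hi + (1 - p_hi) * s_lo
    sens[i] <- p_hi * (1 - s_hi) / (1 - s_all)
    spec[i] <- (1 - p_hi) * s_lo / s_all
  }
  j <- sens + spec - 1
  # protective markers make the died-by-horizon ROC run below the diagonal
  # (J < 0 everywhere); the discriminative optimum is then the largest |J|,
  # i.e. Youden's J after reversing the positivity orientation
  best <- thresholds[which.max(abs(j))]  # which.max takes the first (lowest) on ties
  out <- ihc_cutoff(marker, channel, best)
  attr(out, "youden") <- stats::setNames(j, thresholds)
  attr(out, "sensitivity") <- stats::setNames(sens, thresholds)
  attr(out, "specificity") <- stats::setNames(spec, thresholds)
  out
}

km_survival_at <- function(times, events, horizon) {
  if (length(times) == 0L) return(NA_real_)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  summary(fit, times = horizon, extend = TRUE)$surv
}

#' Specification of a stepwise backward Cox elimination
#'
#' @param forced_terms Covariates never removed (the biomarker or classifier
#'   term under study).
#' @param removable_terms Covariates subject to elimination (typically the
#'   five clinical risk factors).
#' @param exit_p Exclusion criterion: the removable term with the largest
#'   Wald p is dropped while that p exceeds `exit_p` (default 0.1).
#' @return A `stepwise_spec` list.
#' @export
stepwise_spec <- function(forced_terms, removable_terms = clinical_factors(),
                          exit_p = 0.1) {
  if (exit_p <= 0 || exit_p >= 1) abort_field("exit_p", "must be in (0, 1)")
  structure(list(forced_terms = forced_terms, removable_terms = removable_terms,
                 exit_p = exit_p), class = "stepwise_spec")
}

fit_coxph_flagged <- function(formula, data) {
  warn <- character()
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(formula, data = data, ties = "efron"),
             error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error"))
    return(list(fit = NULL, converged = FALSE, warnings = conditionMessage(fit)))
  cf <- stats::coef(fit)
  bad <- any(is.na(cf)) || any(abs(cf[!is.na(cf)]) > 15) ||
    any(grepl("converge|infinite|beta may be infinite", warn, ignore.case = TRUE))
  list(fit = fit, converged = !bad, warnings = warn)
}

#' Multivariate Cox regression with stepwise backward elimination
#'
#' Iteratively removes the removable covariate with the largest Wald
#' p-value among those exceeding the exit criterion, refitting after each
#' removal; forced terms are never removed.  Covariates whose coefficient
#' is inestimable (collinearity) are removed first.
#'
#' @param times,events Survival outcome.
#' @param data `data.frame` holding all covariate columns (numeric 0/1 for
#'   binary terms).
#' @param spec A [stepwise_spec()].
#' @return List with elements `fit` (the final `coxph`), `retained`,
#'   `removed` (with the p-value at removal), `hrrs` (data.frame of HRR,
#'   CI and p per retained term) and `converged`.
#' @export
stepwise_backward_cox <- function(times, events, data, spec) {
  stopifnot(inherits(spec, "stepwise_spec"))
  if (sum(events, na.rm = TRUE) < 1) stop("no events in data", call. = FALSE)
  terms_now <- c(spec$forced_terms, spec$removable_terms)
  missing_terms <- setdiff(terms_now, names(data))
  if (length(missing_terms))
    stop("data lacks covariate(s): ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  removed <- data.frame(term = character(), p_at_removal = numeric())
  df <- cbind(.time = times, .event = events, data)

  repeat {
    fml <- stats::reformulate(terms_now, response = quote(survival::Surv(.time, .event)))
    res <- fit_coxph_flagged(fml, df)
    if (!res$converged && is.null(res$fit))
      return(list(fit = NULL, retained = terms_now, removed = removed,
                  hrrs = NULL, converged = FALSE))
    removable_now <- intersect(spec$removable_terms, terms_now)
    if (length(removable_now) == 0L) break
    cf <- stats::coef(res$fit)
    sm <- summary(res$fit)$coefficients
    pvals <- vapply(removable_now, function(tm) {
      if (is.na(cf[tm])) return(1)  # inestimable -> drop first
      unname(sm[tm, "Pr(>|z|)"])
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= spec$exit_p) break
    removed <- rbind(removed, data.frame(term = removable_now[worst],
                                         p_at_removal = pvals[worst]))
    terms_now <- setdiff(terms_now, removable_now[worst])
  }

  sm <- summary(res$fit)
  hrrs <- data.frame(term = rownames(sm$coefficients),
                     hrr = unname(sm$coefficients[, "exp(coef)"]),
                     lower = unname(sm$conf.int[, 3L]),
                     upper = unname(sm$conf.int[, 4L]),
                     p = unname(sm$coefficients[, "Pr(>|z|)"]),
                     stringsAsFactors = FALSE)
  list(fit = res$fit, retained = terms_now, removed = removed, hrrs = hrrs,
       converged = res$converged)
}

#' Proportion of cross-validation HRRs pointing against the average
#'
#' The screening stability statistic: when the average HRR indicates harm
#' (HRR_av > 1), the fraction of split HRRs below 1; when it indicates
#' protection, the fraction above 1.  Splits with HRR exactly 1 count in
#' neither direction; if the average is exactly 1 the larger one-sided
#' proportion is returned (conservative).
#'
#' @param hrrs Positive HRRs from the validation splits.
#' @param hrr_av Their average.
#' @return The opposite-direction proportion in `[0, 1]`.
#' @export
opposite_proportion <- function(hrrs, hrr_av) {
  if (length(hrrs) == 0L) stop("empty HRR vector", call. = FALSE)
  if (hrr_av > 1) mean(hrrs < 1)
  else if (hrr_av < 1) mean(hrrs > 1)
  else max(mean(hrrs < 1), mean(hrrs > 1))
}

#' Monte-Carlo cross-validated screening of one biomarker
#'
#' For each of `n_splits` random train/validation partitions (stratified on
#' event status): the dichotomisation cutoff is optimised on the training
#' set by [survival_roc_cutoff()]; the validation set then yields a crude
#' (univariate) Cox HRR of high versus low expression and a multivariate
#' HRR from a stepwise backward Cox model over the five clinical risk
#' factors with the marker forced in.  Splits with non-convergent or
#' degenerate fits are dropped from the averages and logged.
#'
#' @param cohort A cohort `data.frame` (survival exclusions are applied
#'   internally; patients missing the marker's score are dropped).
#' @param marker Marker name.
#' @param channel Score channel to screen.
#' @param n_splits Number of Monte-Carlo splits (default 500).
#' @param horizon ROC horizon in months (default 36).
#' @param train_fraction Fraction of patients in each training set
#'   (default 2/3).
#' @param exit_p Stepwise exclusion criterion (default 0.1).
#' @param min_valid_fraction Minimum fraction of valid splits required
#'   (default 0.5).
#' @param seed Master seed; one child seed is spawned per split, so split k
#'   is reproducible regardless of execution order.
#' @return A `cv_screen` object: per-split table, `hrr_av_uni`,
#'   `hrr_av_multi`, opposite-direction proportions `p_lt1`/`p_gt1` for
#'   both fits, the modal cutoff across valid splits, and counts.
#' @export
mccv_screen <- function(cohort, marker, channel = c("intensity", "frequency"),
                        n_splits = 500L, horizon = 36, train_fraction = 2 / 3,
                        exit_p = 0.1, min_valid_fraction = 0.5, seed = 1L) {
  channel <- match.arg(channel)
  cohort <- apply_exclusions(cohort, "survival")
  col <- score_column(marker, "crclm", channel)
  if (!col %in% names(cohort)) stop("cohort lacks score column ", col, call. = FALSE)
  keep <- !is.na(cohort[[col]])
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) < 30L)
    stop("fewer than 30 patients with a ", marker, " ", channel, " score",
         call. = FALSE)

  times <- cohort$os_months; events <- cohort$event
  scores <- cohort[[col]]
  clin <- as.data.frame(cohort[clinical_factors()], optional = TRUE)
  spec <- stepwise_spec(forced_terms = ".marker", exit_p = exit_p)
  idx_ev <- which(events == 1); idx_ce <- which(events == 0)
  split_seeds <- spawn_seeds(seed, n_splits)

  per_split <- data.frame(split = seq_len(n_splits), cutoff = NA_integer_,
                          hrr_uni = NA_real_, hrr_multi = NA_real_,
                          valid = FALSE, reason = NA_character_,
                          stringsAsFactors = FALSE)
  for (k in seq_len(n_splits)) {
    set.seed(split_seeds[k])
    train <- c(sample(idx_ev, round(train_fraction * length(idx_ev))),
               sample(idx_ce, round(train_fraction * length(idx_ce))))
    val <- setdiff(seq_along(times), train)

    co <- tryCatch(survival_roc_cutoff(times[train], events[train], scores[train],
                                       horizon, marker, channel),
                   error = function(e) e)
    if (inherits(co, "error")) {
      per_split$reason[k] <- "cutoff optimisation failed"
      next
    }
    per_split$cutoff[k] <- co$threshold
    x <- as.numeric(scores[val] >= co$threshold)
    if (length(unique(x)) < 2L || sum(events[val]) == 0) {
      per_split$reason[k] <- "degenerate validation split"
      next
    }
    uni <- fit_coxph_flagged(survival::Surv(.time, .event) ~ .marker,
                             data.frame(.time = times[val], .event = events[val],
                                        .marker = x))
    if (!uni$converged) {
      per_split$reason[k] <- "univariate fit non-convergent"
      next
    }
    multi <- tryCatch(
      stepwise_backward_cox(times[val], events[val],
                            cbind(.marker = x, clin[val, , drop = FALSE]), spec),
      error = function(e) list(converged = FALSE))
    if (!isTRUE(multi$converged) ||
        abs(stats::coef(multi$fit)[".marker"]) > 15) {
      per_split$reason[k] <- "multivariate fit non-convergent"
      next
    }
    per_split$hrr_uni[k] <- unname(exp(stats::coef(uni$fit)[".marker"]))
    per_split$hrr_multi[k] <- unname(exp(stats::coef(multi$fit)[".marker"]))
    per_split$valid[k] <- TRUE
  }

  valid <- per_split[per_split$valid, , drop = FALSE]
  if (nrow(valid) < min_valid_fraction * n_splits) {
    tab <- table(per_split$reason[!per_split$valid])
    stop("only ", nrow(valid), "/", n_splits, " valid splits; failures: ",
         paste(names(tab), tab, sep = " = ", collapse = "; "), call. = FALSE)
  }

  hrr_av_uni <- mean(valid$hrr_uni)
  hrr_av_multi <- mean(valid$hrr_multi)
  modal_thr <- as.integer(names(which.max(table(valid$cutoff))))
  structure(list(
    marker = marker, channel = channel,
    per_split = per_split,
    hrr_av_uni = hrr_av_uni, hrr_av_multi = hrr_av_multi,
    p_lt1_uni = mean(valid$hrr_uni < 1), p_gt1_uni = mean(valid$hrr_uni > 1),
    p_lt1_multi = mean(valid$hrr_multi < 1), p_gt1_multi = mean(valid$hrr_multi > 1),
    opposite_prop_uni = opposite_proportion(valid$hrr_uni, hrr_av_uni),
    opposite_prop_multi = opposite_proportion(valid$hrr_multi, hrr_av_multi),
    modal_cutoff = ihc_cutoff(marker, channel, modal_thr),
    n_valid_splits = nrow(valid), n_splits = n_splits, seed = seed),
    class = "cv_screen")
}

#' @export
print.cv_screen <- function(x, ...) {
  dir_stat <- if (x$hrr_av_multi > 1) "P(HRR < 1)" else "P(HRR > 1)"
  cat(sprintf(
    "<cv_screen> %s (%s): HRR_av uni %.2f / multi %.2f, %s = %.3f, modal cutoff >= %d (%d/%d valid splits)\n",
    x$marker, x$channel, x$hrr_av_uni, x$hrr_av_multi, dir_stat,
    x$opposite_prop_multi, x$modal_cutoff$threshold, x$n_valid_splits, x$n_splits))
  invisible(x)
}

#' Pick the score channel with the stronger cross-validated effect
#'
#' Of the intensity and frequency screening results of one marker, returns
#' the one whose multivariate HRR_av deviates more from 1 on the log scale;
#' an exact tie goes to intensity (logged).
#'
#' @param result_int,result_freq `cv_screen` results for the two channels.
#' @return The selected `cv_screen` result.
#' @export
select_channel <- function(result_int, result_freq) {
  stopifnot(result_int$marker == result_freq$marker)
  d_int <- abs(log(result_int$hrr_av_multi))
  d_freq <- abs(log(result_freq$hrr_av_multi))
  if (d_int == d_freq)
    message("channel tie for ", result_int$marker, "; preferring intensity")
  if (d_int >= d_freq) result_int else result_freq
}

#' Select candidate markers for tree construction
#'
#' Markers whose opposite-direction proportion does not exceed the
#' threshold are retained, ordered by that proportion and then by effect
#' size (|log HRR_av|, descending).
#'
#' @param results List of `cv_screen` objects (one per marker, channel
#'   already selected), or a `data.frame` with columns `marker`, `hrr_av`
#'   and `opposite_prop`.
#' @param p_threshold Maximum admissible opposite-direction proportion
#'   (default 0.10).
#' @return Character vector of selected markers, with the ranking table as
#'   attribute `ranking`.
#' @export
select_candidates <- function(results, p_threshold = 0.10) {
  if (is.data.frame(results)) {
    tab <- results[c("marker", "hrr_av", "opposite_prop")]
  } else {
    tab <- data.frame(
      marker = vapply(results, `[[`, "", "marker"),
      hrr_av = vapply(results, `[[`, 0, "hrr_av_multi"),
      opposite_prop = vapply(results, `[[`, 0, "opposite_prop_multi"),
      stringsAsFactors = FALSE)
  }
  tab <- tab[order(tab$opposite_prop, -abs(log(tab$hrr_av))), , drop = FALSE]
  sel <- tab[tab$opposite_prop <= p_threshold, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no marker passes the opposite-direction threshold ", p_threshold,
         "; consider raising it", call. = FALSE)
  structure(sel$marker, ranking = tab)
}
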