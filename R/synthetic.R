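#' Per-marker generative settings
#'
#' @param score_probs_int,score_probs_freq Category probabilities over the
#'   four ordinal score levels 0-3 for the intensity and frequency channels.
#' @param log_hrr Log hazard ratio applied when the marker's effect-channel
#'   score is at or above `cutoff`.
#' @param cutoff True ordinal dichotomisation threshold (1-3).
#' @param channel Which score channel carries the survival effect.
#' @param pair_correlation Latent (Gaussian-copula) correlation between the
#'   primary-tumor and metastasis scores of this marker; `NA` when matched
#'   scores are not generated.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(score_probs_int = rep(0.25, 4),
                        score_probs_freq = rep(0.25, 4),
                        log_hrr = 0, cutoff = 2L,
                        channel = c("intensity", "frequency"),
                        pair_correlation = NA_real_) {
  channel <- match.arg(channel)
  for (p in list(score_probs_int, score_probs_freq)) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      abort_field("score_probs", "must be 4 non-negative entries summing to 1")
  }
  if (!cutoff %in% 1:3) abort_field("cutoff", "must be in 1..3")
  if (!is.na(pair_correlation) && abs(pair_correlation) > 1)
    abort_field("pair_correlation", "must satisfy |rho| <= 1")
  list(score_probs_int = score_probs_int, score_probs_freq = score_probs_freq,
       log_hrr = log_hrr, cutoff = as.integer(cutoff), channel = channel,
       pair_correlation = pair_correlation)
}

#' Configuration of the synthetic cohort generator
#'
#' Survival times follow a proportional-hazards model with (by default)
#' constant baseline hazard: the linear predictor is the sum of per-marker
#' effects, applied when the effect-channel score reaches the marker's true
#' cutoff, plus the clinical risk-factor effects.  Alternatively, when
#' `class_effects`/`class_tree` are supplied, the hazard is driven directly
#' by the tree class the patient's dichotomised scores route to.  Observed
#' time is the minimum of the event time, an independent exponential
#' censoring time, and an administrative follow-up cap (default 120 months,
#' i.e. ten years of follow-up).
#'
#' @param n_patients Number of patients.
#' @param markers Named list of [marker_spec()] objects.
#' @param clinical_prevalence Probability of each of the five clinical risk
#'   factors (scalar or named vector over [clinical_factors()]).
#' @param clinical_log_hrr Log hazard ratio of each clinical risk factor
#'   (scalar or named vector).
#' @param baseline_rate Baseline hazard per month (> 0).
#' @param censor_rate Independent exponential censoring rate per month (>= 0).
#' @param admin_censor_months Administrative follow-up cap in months.
#' @param missing_prob Per-channel probability that a score is missing
#'   (missing completely at random), in `[0, 1)`.
#' @param subgroup_probs Named probabilities `systemic_therapy` (treated) and
#'   `colon` (primary site colon rather than rectum).
#' @param weibull_shape Weibull shape of the baseline hazard; 1 = exponential.
#' @param class_effects Optional named log-hazard per tree class; overrides
#'   the additive marker effects.
#' @param class_tree The [cart_model()] whose classes `class_effects` refers
#'   to (required with `class_effects`).
#' @param hazard_lesion Which lesion's scores drive the hazard (`"crclm"` or
#'   `"prim"`; the latter only for matched-pair generation).
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param truth Optional named list of generative target quantities carried
#'   along for calibration checks.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients,
                             markers,
                             clinical_prevalence = 0.4,
                             clinical_log_hrr = 0,
                             baseline_rate = 0.01,
                             censor_rate = 0.005,
                             admin_censor_months = 120,
                             missing_prob = 0,
                             subgroup_probs = c(systemic_therapy = 0.4, colon = 0.6),
                             weibull_shape = 1,
                             class_effects = NULL,
                             class_tree = NULL,
                             hazard_lesion = c("crclm", "prim"),
                             seed = 1L,
                             truth = list()) {
  hazard_lesion <- match.arg(hazard_lesion)
  if (!is.numeric(n_patients) || n_patients < 1)
    abort_field("n_patients", "must be a positive count")
  if (is.null(names(markers)) || any(names(markers) == ""))
    abort_field("markers", "must be a named list of marker_spec()")
  if (baseline_rate <= 0) abort_field("baseline_rate", "must be > 0")
  if (censor_rate < 0) abort_field("censor_rate", "must be >= 0")
  if (missing_prob < 0 || missing_prob >= 1)
    abort_field("missing_prob", "must be in [0, 1)")
  if (weibull_shape <= 0) abort_field("weibull_shape", "must be > 0")
  expand5 <- function(x, what) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, 5L), clinical_factors())
    if (!all(clinical_factors() %in% names(x)))
      abort_field(what, "must be a scalar or named over all five clinical factors")
    x[clinical_factors()]
  }
  clinical_prevalence <- expand5(clinical_prevalence, "clinical_prevalence")
  clinical_log_hrr <- expand5(clinical_log_hrr, "clinical_log_hrr")
  if (any(clinical_prevalence < 0 | clinical_prevalence > 1))
    abort_field("clinical_prevalence", "probabilities must be in [0, 1]")
  if (!is.null(class_effects) && is.null(class_tree))
    abort_field("class_tree", "required when class_effects is given")
  structure(list(
    n_patients = as.integer(n_patients), markers = markers,
    clinical_prevalence = clinical_prevalence, clinical_log_hrr = clinical_log_hrr,
    baseline_rate = baseline_rate, censor_rate = censor_rate,
    admin_censor_months = admin_censor_months, missing_prob = missing_prob,
    subgroup_probs = subgroup_probs, weibull_shape = weibull_shape,
    class_effects = class_effects, class_tree = class_tree,
    hazard_lesion = hazard_lesion, seed = as.integer(seed), truth = truth),
    class = "synthetic_config")
}

draw_scores <- function(n, probs) {
  sample(0:3, n, replace = TRUE, prob = probs)
}

# threshold a standard normal into the four ordinal categories
categorize_latent <- function(z, probs) {
  cum <- cumsum(probs)[1:3]
  cum <- pmin(pmax(cum, 0), 1)
  findInterval(z, stats::qnorm(cum))
}

marker_effect_scores <- function(df, config, lesion) {
  vapply(names(config$markers), function(m) {
    spec <- config$markers[[m]]
    df[[score_column(m, lesion, spec$channel)]]
  }, numeric(nrow(df)))
}

linear_predictor <- function(df, config) {
  n <- nrow(df)
  lp <- rep(0, n)
  lesion <- config$hazard_lesion
  if (!is.null(config$class_effects)) {
    feats <- dichotomized_features(df, generative_cutoffs(config), lesion = lesion)
    cls <- assign_classes(config$class_tree, feats)
    lp <- lp + unname(config$class_effects[cls])
  } else {
    for (m in names(config$markers)) {
      spec <- config$markers[[m]]
      sc <- df[[score_column(m, lesion, spec$channel)]]
      lp <- lp + spec$log_hrr * as.numeric(sc >= spec$cutoff)
    }
  }
  for (cf in clinical_factors())
    lp <- lp + config$clinical_log_hrr[[cf]] * df[[cf]]
  lp
}

# the generator's own true cutoffs, as ihc_cutoff objects
generative_cutoffs <- function(config) {
  lapply(names(config$markers), function(m) {
    spec <- config$markers[[m]]
    ihc_cutoff(m, spec$channel, spec$cutoff)
  })
}

generate_core <- function(config, matched) {
  set.seed(config$seed)
  n <- config$n_patients
  df <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (cf in clinical_factors())
    df[[cf]] <- stats::rbinom(n, 1L, config$clinical_prevalence[[cf]])
  df$systemic_therapy <- stats::rbinom(n, 1L, config$subgroup_probs[["systemic_therapy"]])
  df$primary_site <- ifelse(stats::rbinom(n, 1L, config$subgroup_probs[["colon"]]) == 1,
                            "colon", "rectum")

  for (m in names(config$markers)) {
    spec <- config$markers[[m]]
    for (channel in c("intensity", "frequency")) {
      probs <- if (channel == "intensity") spec$score_probs_int else spec$score_probs_freq
      if (matched) {
        rho <- spec$pair_correlation
        if (is.na(rho))
          abort_field("pair_correlation",
                      paste0("must be set for marker ", m, " to generate matched pairs"))
        z_m <- stats::rnorm(n)
        z_p <- if (abs(rho) == 1) sign(rho) * z_m
               else rho * z_m + sqrt(1 - rho^2) * stats::rnorm(n)
        df[[score_column(m, "crclm", channel)]] <- categorize_latent(z_m, probs)
        df[[score_column(m, "prim", channel)]] <- categorize_latent(z_p, probs)
      } else {
        df[[score_column(m, "crclm", channel)]] <- draw_scores(n, probs)
      }
    }
  }

  lp <- linear_predictor(df, config)
  u <- stats::rexp(n, 1)
  t_event <- (u / (config$baseline_rate * exp(lp)))^(1 / config$weibull_shape)
  t_cens <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, config$admin_censor_months)
  df$os_months <- pmax(round(pmin(t_event, t_cens), 4), 1e-4)
  df$event <- as.integer(t_event <= t_cens)

  if (config$missing_prob > 0) {
    score_cols <- grep("_(crclm|prim)_(int|freq)$", names(df), value = TRUE)
    for (sc in score_cols) {
      miss <- stats::rbinom(n, 1L, config$missing_prob) == 1
      df[[sc]][miss] <- NA_integer_
    }
  }

  df <- df[c("patient_id", "os_months", "event", clinical_factors(),
             "systemic_therapy", "primary_site",
             grep("_(crclm|prim)_(int|freq)$", names(df), value = TRUE))]
  cohort <- new_cohort(df, provenance = "synthetic", seed = config$seed)
  attr(cohort, "config") <- config
  cohort
}

#' Generate a synthetic CRCLM cohort
#'
#' @param config A [synthetic_config()].
#' @return A cohort `data.frame` with metastasis scores only; deterministic
#'   given `config$seed`.  The generating configuration is attached as
#'   attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  generate_core(config, matched = FALSE)
}

#' Generate a cohort with matched primary-tumor and metastasis scores
#'
#' Each marker's two lesions are drawn from a Gaussian copula: a bivariate
#' standard-normal latent pair with correlation `pair_correlation` is
#' thresholded into the four ordinal categories of that marker's score
#' distribution.  The attribute `implied_pair_correlation` reports, per
#' marker and channel, the deterministic ordinal-scale Pearson correlation
#' implied by the latent correlation and the category thresholds (see
#' [implied_ordinal_correlation()]), which is the quantity calibration
#' should target.
#'
#' @param config A [synthetic_config()] with `pair_correlation` set for every
#'   marker.
#' @return A cohort `data.frame` with both `*_crclm_*` and `*_prim_*` score
#'   columns.
#' @export
generate_matched_pairs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cohort <- generate_core(config, matched = TRUE)
  implied <- do.call(rbind, lapply(names(config$markers), function(m) {
    spec <- config$markers[[m]]
    data.frame(marker = m,
               channel = c("intensity", "frequency"),
               latent_correlation = spec$pair_correlation,
               implied_ordinal_r = c(
                 implied_ordinal_correlation(spec$pair_correlation, spec$score_probs_int),
                 implied_ordinal_correlation(spec$pair_correlation, spec$score_probs_freq)),
               stringsAsFactors = FALSE)
  }))
  attr(cohort, "implied_pair_correlation") <- implied
  cohort
}

#' Generate a cohort with all survival effects removed
#'
#' Identical to [generate_cohort()] except that every marker and clinical
#' log hazard ratio is forced to zero, so survival is independent of all
#' covariates — the null fixture for permutation-calibration checks.
#'
#' @param config A [synthetic_config()].
#' @return A cohort `data.frame`.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$markers <- lapply(config$markers, function(spec) {
    spec$log_hrr <- 0
    spec
  })
  config$clinical_log_hrr[] <- 0
  config$class_effects <- NULL
  config$class_tree <- NULL
  generate_core(config, matched = FALSE)
}

# bivariate standard normal CDF P(Z1 <= a, Z2 <= b) with correlation rho,
# by univariate quadrature over the conditional distribution
pbinorm <- function(a, b, rho) {
  if (a == -Inf || b == -Inf) return(0)
  if (a == Inf && b == Inf) return(1)
  if (a == Inf) return(stats::pnorm(b))
  if (b == Inf) return(stats::pnorm(a))
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(a, b)))
  if (rho <= -1 + 1e-12) return(max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) stats::dnorm(z) * stats::pnorm((b - rho * z) / s),
                   -Inf, a, rel.tol = 1e-10)$value
}

#' Ordinal-scale Pearson correlation implied by a Gaussian copula
#'
#' For two four-level ordinal scores obtained by thresholding a bivariate
#' standard normal with latent correlation `rho` at the quantiles of the
#' given category probabilities, returns the exact Pearson correlation of
#' the resulting 0-3 scores.  This is the deterministic mapping used to
#' calibrate `pair_correlation` against a target observed correlation.
#'
#' @param rho Latent correlation in `[-1, 1]`.
#' @param probs_x,probs_y Category probabilities (4 entries summing to 1).
#' @return The implied ordinal Pearson correlation.
#' @export
implied_ordinal_correlation <- function(rho, probs_x, probs_y = probs_x) {
  stopifnot(abs(rho) <= 1, length(probs_x) == 4L, length(probs_y) == 4L)
  thr <- function(p) c(-Inf, stats::qnorm(pmin(pmax(cumsum(p)[1:3], 0), 1)), Inf)
  ax <- thr(probs_x); by <- thr(probs_y)
  exy <- 0
  for (i in 0:3) for (j in 0:3) {
    if (i == 0 || j == 0) next  # zero score contributes nothing to E[XY]
    pij <- pbinorm(ax[i + 2], by[j + 2], rho) - pbinorm(ax[i + 1], by[j + 2], rho) -
           pbinorm(ax[i + 2], by[j + 1], rho) + pbinorm(ax[i + 1], by[j + 1], rho)
    exy <- exy + i * j * pij
  }
  mu <- function(p) sum((0:3) * p)
  sdv <- function(p) sqrt(sum((0:3)^2 * p) - mu(p)^2)
  (exy - mu(probs_x) * mu(probs_y)) / (sdv(probs_x) * sdv(probs_y))
}

#' Latent correlation whose implied ordinal correlation matches a target
#'
#' Inverts [implied_ordinal_correlation()] by root finding.
#'
#' @param target_r Target ordinal-scale Pearson correlation.
#' @param probs_x,probs_y Category probabilities (4 entries summing to 1).
#' @return The latent Gaussian-copula correlation.
#' @export
calibrate_pair_correlation <- function(target_r, probs_x, probs_y = probs_x) {
  if (abs(target_r) < 1e-12) return(0)
  f <- function(rho) implied_ordinal_correlation(rho, probs_x, probs_y) - target_r
  stats::uniroot(f, lower = -0.9999, upper = 0.9999, tol = 1e-7)$root
}
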