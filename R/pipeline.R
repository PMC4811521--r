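#' Configuration of the end-to-end pipeline
#'
#' @param markers Markers to screen (default: every marker in the cohort).
#' @param channels Channels screened per marker: `"both"` screens intensity
#'   and frequency and keeps the stronger one per marker
#'   ([select_channel()]), otherwise a single channel name.
#' @param n_splits Monte-Carlo splits per marker/channel (default 500).
#' @param horizon ROC and three-year horizon in months (default 36).
#' @param train_fraction Training fraction of each split (default 2/3).
#' @param p_threshold Candidate-selection bound on the opposite-direction
#'   proportion (default 0.10).
#' @param cv_folds,min_bucket Tree-building controls.
#' @param grouping_threshold HRR boundary for classes I/II (default 2.0).
#' @param n_perm Permutations for the corrected p (default 1000).
#' @param strict Re-optimise cutoffs inside each permutation.
#' @param subgroups Stratifiers for subgroup analyses (subset of
#'   `"systemic_therapy"`, `"primary_site"`; empty to skip).
#' @param subgroup_n_perm Permutations per subgroup stratum.
#' @param primary_analysis Run the primary-tumor concordance analysis and
#'   the reduced classifier (needs `*_prim_*` columns).
#' @param seed Master seed; named substreams are spawned for screening,
#'   tree building, permutation and subgroups.
#' @param out_dir Directory for stage artifacts (`NULL`: keep in memory).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(markers = NULL, channels = "both",
                            n_splits = 500L, horizon = 36,
                            train_fraction = 2 / 3, p_threshold = 0.10,
                            cv_folds = 10L, min_bucket = 10L,
                            grouping_threshold = 2.0,
                            n_perm = 1000L, strict = FALSE,
                            subgroups = character(), subgroup_n_perm = 1000L,
                            primary_analysis = FALSE,
                            seed = 1L, out_dir = NULL) {
  if (!channels %in% c("both", "intensity", "frequency"))
    abort_field("channels", "must be 'both', 'intensity' or 'frequency'")
  if (length(subgroups) && !all(subgroups %in% c("systemic_therapy", "primary_site")))
    abort_field("subgroups", "must be a subset of systemic_therapy, primary_site")
  if (is.null(seed)) abort_field("seed", "a seed is mandatory")
  structure(list(markers = markers, channels = channels,
                 n_splits = as.integer(n_splits), horizon = horizon,
                 train_fraction = train_fraction, p_threshold = p_threshold,
                 cv_folds = as.integer(cv_folds), min_bucket = as.integer(min_bucket),
                 grouping_threshold = grouping_threshold,
                 n_perm = as.integer(n_perm), strict = strict,
                 subgroups = subgroups, subgroup_n_perm = as.integer(subgroup_n_perm),
                 primary_analysis = primary_analysis,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                              auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full classifier-construction pipeline
#'
#' Screens every marker by Monte-Carlo cross-validation, selects the
#' stronger channel per marker and the candidate set, dichotomises at the
#' modal screening cutoffs, builds and prunes the tree on the three-year
#' outcome, groups its classes into prognostic classes I/II, and evaluates
#' the resulting classifier: Kaplan-Meier/logrank, univariate and
#' covariate-adjusted Cox HRRs, permutation-corrected p, comparison against
#' the clinicopathological model, and optional subgroup and primary-tumor
#' analyses.  With `out_dir` set, every stage writes a delimited or JSON
#' artifact stamped with the configuration hash.
#'
#' @param cohort Cohort `data.frame`.
#' @param config A [pipeline_config()].
#' @return A `classifier_report` list with all stage results.
#' @export
run_pipeline <- function(cohort, config) {
  stopifnot(inherits(config, "pipeline_config"))
  markers <- config$markers %||% cohort_markers(cohort)
  if (length(markers) == 0L)
    stop("no markers to screen: the cohort has no score columns", call. = FALSE)
  hash <- config_hash(config)
  seeds <- spawn_seeds(config$seed, 4L)  # screening, cart, permutation, subgroups

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  screen_seeds <- spawn_seeds(seeds[1L], 2L * length(markers))
  screens <- stage("screen", {
    res <- vector("list", length(markers))
    names(res) <- markers
    for (i in seq_along(markers)) {
      m <- markers[i]
      run1 <- function(ch, sd) mccv_screen(
        cohort, m, ch, n_splits = config$n_splits, horizon = config$horizon,
        train_fraction = config$train_fraction, seed = sd)
      res[[m]] <- if (config$channels == "both")
        select_channel(run1("intensity", screen_seeds[2L * i - 1L]),
                       run1("frequency", screen_seeds[2L * i]))
      else run1(config$channels, screen_seeds[2L * i - 1L])
    }
    res
  })

  candidates <- stage("select", select_candidates(screens, config$p_threshold))
  cutoffs <- lapply(screens[candidates], `[[`, "modal_cutoff")

  construction <- stage("cart", classifier_construction(
    cohort, cutoffs, cv_folds = config$cv_folds, min_bucket = config$min_bucket,
    grouping_threshold = config$grouping_threshold, horizon = config$horizon,
    seed = seeds[2L]))

  report <- list(config = config, config_hash = hash, screens = screens,
                 candidates = candidates, cutoffs = cutoffs,
                 construction = construction)

  if (!construction$degenerate) {
    surv_set <- construction$cohort_surv
    groups <- construction$groups
    report$km <- kaplan_meier(surv_set$os_months, surv_set$event, groups)
    report$hrr_uni <- stage("hrr", classifier_hrr(surv_set, groups, adjust = FALSE))
    report$hrr_multi <- stage("hrr", classifier_hrr(surv_set, groups, adjust = TRUE))
    report$model_comparison <- stage("compare",
      compare_models(surv_set, groups))
    report$permutation <- stage("permtest", permutation_corrected_p(
      cohort, construction$cutoffs, n_perm = config$n_perm, seed = seeds[3L],
      strict = config$strict, cv_folds = config$cv_folds,
      min_bucket = config$min_bucket,
      grouping_threshold = config$grouping_threshold, horizon = config$horizon))
    if (length(config$subgroups)) {
      report$subgroups <- stage("subgroups", {
        out <- lapply(config$subgroups, function(s)
          subgroup_analysis(surv_set, groups, s,
                            n_perm = config$subgroup_n_perm, seed = seeds[4L]))
        do.call(rbind, out)
      })
    }
    if (config$primary_analysis) {
      model <- construction$model
      model$cutoffs <- construction$cutoffs[
        vapply(construction$cutoffs, `[[`, "", "marker") %in% model$markers]
      report$primary <- stage("primary",
        apply_classifier_primary(model, cohort,
                                 grouping_threshold = config$grouping_threshold,
                                 horizon = config$horizon))
    }
  }

  class(report) <- "classifier_report"
  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> config", x$config_hash, "\n")
  cat("candidates:", paste(x$candidates, collapse = ", "), "\n")
  if (x$construction$degenerate) {
    cat("construction degenerate: no discriminative classifier\n")
    return(invisible(x))
  }
  print(x$construction$model)
  print(x$construction$grouping)
  cat(sprintf("logrank p (uncorrected) = %.4g\n", x$km$p))
  cat(sprintf("HRR II vs I: univariate %.2f [%.2f, %.2f], adjusted %.2f [%.2f, %.2f]\n",
              x$hrr_uni$hrr, x$hrr_uni$lower, x$hrr_uni$upper,
              x$hrr_multi$hrr, x$hrr_multi$lower, x$hrr_multi$upper))
  if (!is.null(x$permutation)) print(x$permutation)
  if (!is.null(x$model_comparison))
    cat(sprintf("vs clinicopathological model: chi-square %.2f (df %d), p = %.4g\n",
                x$model_comparison$chisq, x$model_comparison$df,
                x$model_comparison$p))
  invisible(x)
}

screen_table <- function(screens) {
  do.call(rbind, lapply(screens, function(s) data.frame(
    marker = s$marker, channel = s$channel,
    hrr_av_uni = s$hrr_av_uni, hrr_av_multi = s$hrr_av_multi,
    p_lt1_multi = s$p_lt1_multi, p_gt1_multi = s$p_gt1_multi,
    opposite_prop = s$opposite_prop_multi,
    modal_cutoff = s$modal_cutoff$threshold,
    n_valid_splits = s$n_valid_splits, stringsAsFactors = FALSE)))
}

describe_tree <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf")
    return(sprintf("%sleaf class %s (n=%s, death_frac=%s)", pad, node$class,
                   node$n, signif(node$death_frac, 3)))
  c(sprintf("%ssplit %s", pad, node$marker),
    sprintf("%s low:", pad), describe_tree(node$low, indent + 1L),
    sprintf("%s high:", pad), describe_tree(node$high, indent + 1L))
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(sprintf("# config_hash: %s", report$config_hash))
  wr <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, qmethod = "double"))
  }
  wr(screen_table(report$screens), "screening.csv")
  if (!report$construction$degenerate) {
    model_lines <- c(stamp,
                     sprintf("cv_error: %s", report$construction$model$cv_error),
                     describe_tree(report$construction$model$tree),
                     sprintf("group_I: %s", paste(report$construction$grouping$group_I, collapse = ",")),
                     sprintf("group_II: %s", paste(report$construction$grouping$group_II, collapse = ",")))
    writeLines(model_lines, file.path(out_dir, "model.txt"))
    wr(report$construction$class_hrr, "class_hrrs.csv")
    summary_json <- list(
      config_hash = report$config_hash,
      candidates = report$candidates,
      logrank_p = report$km$p,
      hrr_uni = report$hrr_uni$hrr, hrr_multi = report$hrr_multi$hrr,
      p_corrected = report$permutation$p_corrected,
      p_corrected_add_one = report$permutation$p_corrected_add_one,
      model_comparison_p = report$model_comparison$p)
    writeLines(jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
               file.path(out_dir, "report.json"))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("crclmcart")),
                   r_version = R.version.string,
                   config_hash = report$config_hash,
                   created = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
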