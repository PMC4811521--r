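#' Cohort data model
#'
#' A cohort is a plain `data.frame` with one row per patient, carrying
#' overall survival (months from CRCLM resection, death indicator), the five
#' binary clinicopathological risk factors (see [clinical_factors()]),
#' subgroup labels (`systemic_therapy`, `primary_site`), and per-marker
#' ordinal immunohistochemistry scores.  Each marker contributes up to four
#' score columns: `<marker>_crclm_int`, `<marker>_crclm_freq` for the liver
#' metastasis and `<marker>_prim_int`, `<marker>_prim_freq` for the matched
#' primary tumor.  Scores are integers 0-3 (intensity: negative, weak,
#' moderate, strong; frequency: 0-25%, 26-50%, 51-75%, 76-100%); `NA` marks
#' a missing score.
#'
#' @name cohort-format
NULL

cohort_fixed_columns <- function() {
  c("patient_id", "os_months", "event", clinical_factors(),
    "systemic_therapy", "primary_site")
}

#' Column dictionary for the cohort file format
#'
#' @param markers Character vector of marker names; defaults to none (fixed
#'   columns only).
#' @return A `data.frame` with one row per column: name, type and meaning.
#' @export
cohort_columns <- function(markers = character()) {
  fixed <- data.frame(
    column = cohort_fixed_columns(),
    type = c("character", "numeric > 0", "0/1",
             rep("0/1", 5L), "0/1 or empty", "colon/rectum or empty"),
    meaning = c(
      "unique patient identifier",
      "overall survival in months after CRCLM resection",
      "1 = died, 0 = censored",
      "primary tumor-to-CRCLM interval < 12 months",
      "lymph-node positive primary tumor",
      "maximal CRCLM diameter > 5.0 cm",
      "number of CRCLM > 1",
      "serum CEA > 200 ng/ml",
      "systemic therapy for the CRCLM",
      "location of the primary tumor"),
    stringsAsFactors = FALSE)
  if (length(markers) == 0L) return(fixed)
  score <- expand.grid(lesion = c("crclm", "prim"),
                       channel = c("intensity", "frequency"),
                       marker = markers, stringsAsFactors = FALSE)
  score_cols <- data.frame(
    column = mapply(score_column, score$marker, score$lesion, score$channel),
    type = "integer 0-3 or empty",
    meaning = paste0(score$marker, " ", score$channel, " score, ",
                     ifelse(score$lesion == "crclm", "liver metastasis", "primary tumor")),
    stringsAsFactors = FALSE)
  rbind(fixed, score_cols)
}

#' Extract marker names from a cohort's score columns
#'
#' @param cohort A cohort `data.frame`.
#' @return Character vector of marker names with at least one score column.
#' @export
cohort_markers <- function(cohort) {
  cols <- grep("_(crclm|prim)_(int|freq)$", names(cohort), value = TRUE)
  unique(sub("_(crclm|prim)_(int|freq)$", "", cols))
}

validate_cohort <- function(df) {
  missing_cols <- setdiff(c("patient_id", "os_months", "event"), names(df))
  if (length(missing_cols))
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    stop("duplicated patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_os <- which(!is.na(df$os_months) & df$os_months <= 0)
  if (length(bad_os))
    stop("os_months must be > 0; offending rows: ",
         paste(bad_os, collapse = ", "), call. = FALSE)
  bad_ev <- which(!is.na(df$event) & !df$event %in% c(0, 1))
  if (length(bad_ev))
    stop("event must be 0/1; offending rows: ",
         paste(bad_ev, collapse = ", "), call. = FALSE)
  score_cols <- grep("_(crclm|prim)_(int|freq)$", names(df), value = TRUE)
  for (sc in score_cols) {
    v <- df[[sc]]
    bad <- which(!is.na(v) & (!v %in% 0:3))
    if (length(bad))
      stop("score column ", sc, " outside 0-3; offending rows: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

new_cohort <- function(df, provenance = "file", seed = NULL) {
  validate_cohort(df)
  attr(df, "provenance") <- provenance
  if (!is.null(seed)) attr(df, "generator_seed") <- seed
  class(df) <- unique(c("crclm_cohort", class(df)))
  df
}

#' Read a cohort table from a delimited text file
#'
#' The file is comma-separated UTF-8 with one header row; missing values are
#' empty fields.  See [cohort_columns()] for the column dictionary.
#'
#' @param path Path to the cohort CSV file.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                        colClasses = c(patient_id = "character"))
  if (nrow(df) == 0L)
    warning("cohort file ", path, " contains a header but no rows")
  if ("primary_site" %in% names(df)) {
    bad <- !is.na(df$primary_site) & !df$primary_site %in% c("colon", "rectum")
    df$primary_site[bad] <- NA_character_
  }
  message("read ", nrow(df), " patient rows from ", path)
  new_cohort(df, provenance = "file")
}

#' Write a cohort table to a delimited text file
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Dichotomize ordinal scores at a cutoff
#'
#' Expression is called `"high"` when the ordinal score is greater than or
#' equal to the threshold, `"low"` otherwise; the cutpoint sits between
#' adjacent score categories.  Missing scores stay missing.
#'
#' @param scores Integer vector of ordinal scores 0-3 (`NA` allowed).
#' @param cutoff An [ihc_cutoff()] object, or a bare threshold in 1-3.
#' @return Factor with levels `low`, `high`; `NA` propagated.
#' @export
dichotomize <- function(scores, cutoff) {
  threshold <- if (inherits(cutoff, "ihc_cutoff")) cutoff$threshold else cutoff
  if (!is.numeric(threshold) || length(threshold) != 1L || !threshold %in% 1:3)
    stop("cutoff threshold must be one of 1, 2, 3", call. = FALSE)
  factor(ifelse(scores >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Construct a marker cutoff
#'
#' @param marker Marker name.
#' @param channel Which score channel the cutoff applies to.
#' @param threshold Ordinal boundary in 1-3; scores at or above it are "high".
#' @return An object of class `ihc_cutoff`.
#' @export
ihc_cutoff <- function(marker, channel = c("intensity", "frequency"), threshold) {
  channel <- match.arg(channel)
  if (!is.numeric(threshold) || length(threshold) != 1L || !threshold %in% 1:3)
    stop("cutoff threshold must be one of 1, 2, 3", call. = FALSE)
  structure(list(marker = marker, channel = channel, threshold = as.integer(threshold)),
            class = "ihc_cutoff")
}

#' @export
print.ihc_cutoff <- function(x, ...) {
  cat(sprintf("<cutoff> %s (%s): high iff score >= %d\n",
              x$marker, x$channel, x$threshold))
  invisible(x)
}

#' Label three-year survival status
#'
#' Patients who died at or before 36 months are failures; patients observed
#' beyond 36 months (dead or alive) are survivors; patients censored at or
#' before 36 months carry no three-year label.
#'
#' @param os_months Positive survival times in months.
#' @param event Binary death indicator.
#' @return Factor with levels `died_within_36`, `survived_36`, `undefined`.
#' @export
label_three_year <- function(os_months, event) {
  stopifnot(length(os_months) == length(event))
  out <- ifelse(is.na(os_months) | is.na(event), NA_character_,
         ifelse(os_months > 36, "survived_36",
         ifelse(event == 1, "died_within_36", "undefined")))
  factor(out, levels = c("died_within_36", "survived_36", "undefined"))
}

#' Apply the per-analysis patient exclusion rules
#'
#' Survival analyses drop patients with unknown survival or less than two
#' months of follow-up.  Three-year analyses additionally drop patients whose
#' three-year status is undefined (censored at or before 36 months).
#' Classifier analyses additionally drop patients missing any required marker
#' score.  Exclusion counts per reason are attached as attribute
#' `exclusion_log` (retrievable with [exclusion_log()]).
#'
#' @param cohort A cohort `data.frame`.
#' @param analysis One of `"survival"`, `"three_year"`, `"classifier"`.
#'   Each level includes the exclusions of the previous ones.
#' @param required_cutoffs For `"classifier"`: list of [ihc_cutoff()] objects
#'   (or a character vector of marker names, in which case the intensity
#'   channel is required) whose scores must be present.
#' @param lesion Which lesion's scores the classifier requirement refers to.
#' @return The filtered cohort with an `exclusion_log` attribute.
#' @export
apply_exclusions <- function(cohort,
                             analysis = c("survival", "three_year", "classifier"),
                             required_cutoffs = NULL,
                             lesion = c("crclm", "prim")) {
  analysis <- match.arg(analysis)
  lesion <- match.arg(lesion)
  df <- cohort
  log <- data.frame(reason = character(), n_excluded = integer(),
                    stringsAsFactors = FALSE)
  drop_rows <- function(df, keep, reason) {
    n_drop <- sum(!keep)
    log <<- rbind(log, data.frame(reason = reason, n_excluded = n_drop))
    df[keep, , drop = FALSE]
  }

  keep <- !is.na(df$os_months) & !is.na(df$event)
  df <- drop_rows(df, keep, "unknown survival")
  keep <- df$os_months >= 2
  df <- drop_rows(df, keep, "survival < 2 months")

  if (analysis %in% c("three_year", "classifier")) {
    lab <- label_three_year(df$os_months, df$event)
    df <- drop_rows(df, lab != "undefined", "three-year status undefined")
  }

  if (analysis == "classifier") {
    if (is.null(required_cutoffs))
      stop("classifier exclusions need `required_cutoffs`", call. = FALSE)
    if (is.character(required_cutoffs))
      required_cutoffs <- lapply(required_cutoffs, ihc_cutoff,
                                 channel = "intensity", threshold = 2L)
    for (co in required_cutoffs) {
      col <- score_column(co$marker, lesion, co$channel)
      if (!col %in% names(df))
        stop("cohort lacks score column ", col, call. = FALSE)
      df <- drop_rows(df, !is.na(df[[col]]),
                      paste0("missing ", co$marker, " ", co$channel, " score"))
    }
  }

  if (nrow(df) == 0L) stop("no evaluable patients", call. = FALSE)
  attr(df, "exclusion_log") <- log
  df
}

#' Retrieve the exclusion log attached by [apply_exclusions()]
#'
#' @param cohort A cohort returned by [apply_exclusions()].
#' @return A `data.frame` with columns `reason` and `n_excluded`.
#' @export
exclusion_log <- function(cohort) {
  attr(cohort, "exclusion_log") %||%
    data.frame(reason = character(), n_excluded = integer())
}
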