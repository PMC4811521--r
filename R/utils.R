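`%||%` <- function(x, y) if (is.null(x)) y else x

#' Names of the five clinicopathological risk factors
#'
#' The binary risk factors routinely recorded for resected colorectal-cancer
#' liver metastases: primary tumor-to-metastasis interval below 12 months,
#' nodal positivity of the primary tumor, maximal metastasis diameter above
#' 5 cm, more than one metastasis, and serum CEA above 200 ng/ml.
#'
#' @return Character vector of the five cohort column names.
#' @export
clinical_factors <- function() {
  c("interval_lt_12mo", "node_positive", "diameter_gt_5cm",
    "multiple_crclm", "cea_gt_200")
}

# one reproducible child seed per independent task, so task k does not
# depend on how many tasks run before it
spawn_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x[!is.na(x)] %in% c(0, 1))
}

# column name for one score channel of one marker
score_column <- function(marker, lesion = c("crclm", "prim"),
                         channel = c("intensity", "frequency")) {
  lesion <- match.arg(lesion)
  channel <- match.arg(channel)
  paste0(marker, "_", lesion, "_", switch(channel, intensity = "int", frequency = "freq"))
}
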