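#' Read and write cohort tables
#'
#' The cohort CSV dialect is a plain UTF-8 header CSV with columns
#' `participant_id, age, group, id_level`, one column per marker, and
#' optionally `truth_stage` (synthetic cohorts only). Empty cells are missing
#' values.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @param panel Marker panel used to validate columns on read; defaults to
#'   [default_panel()].
#' @return `read_cohort()` returns a cohort data frame with the panel
#'   attached; `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, panel = default_panel()) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), check.names = FALSE)
  out <- structure(df, panel = panel, class = c("cohort", "data.frame"))
  validate_cohort(out)
  out
}

#' Write or read the ground-truth sidecar of a synthetic cohort
#'
#' Stores the planted event ordering, onset ages and per-participant latent
#' stages as JSON, for use by tests and recovery checks.
#'
#' @param cohort A synthetic cohort from [generate_cohort()].
#' @param path JSON file path.
#' @return `read_truth()` returns a list with elements `ordering`,
#'   `onset_ages`, `truth_stage`; `write_truth()` returns `path` invisibly.
#' @export
write_truth <- function(cohort, path) {
  truth <- attr(cohort, "truth")
  if (is.null(truth) || is.null(cohort$truth_stage))
    stop("cohort carries no ground truth (not synthetic?)")
  jsonlite::write_json(
    list(ordering = truth$ordering, onset_ages = truth$onset_ages,
         participant_id = cohort$participant_id,
         truth_stage = cohort$truth_stage),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
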