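#' Cohort metadata: samples, subjects, donor pairing
#'
#' Bundles the per-sample annotation table (who was sampled, when, in what
#' role) with optional per-subject clinical covariates. Construction
#' validates the cross-references the engraftment analysis depends on:
#' every recipient is paired to exactly one existing donor, donor samples sit
#' at week 0, timepoints lie on the study grid, and recipients lacking a
#' baseline sample are flagged (never silently dropped) in `$exclusions`.
#'
#' @param samples tibble/data.frame with columns `sample_id`, `subject_id`,
#'   `role` (`"donor"` or `"recipient"`), `donor_id` (NA for donors),
#'   `timepoint_weeks`.
#' @param subjects optional tibble with `subject_id` plus numeric per-subject
#'   covariates (e.g. `delta_homa2ir`, diet, cytokines, lipids, bile acids).
#' @param timepoint_grid allowed sampling weeks; the study visits are
#'   baseline, 2, 6 and 12 weeks post-FMT.
#' @return An `fmt_metadata` object: list with `$samples`, `$subjects`,
#'   `$exclusions` (subjects without a baseline sample) and `$timepoint_grid`.
#' @export
cohort_metadata <- function(samples, subjects = NULL,
                            timepoint_grid = c(0L, 2L, 6L, 12L)) {
  required <- c("sample_id", "subject_id", "role", "donor_id", "timepoint_weeks")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort_format(paste("metadata missing column(s):",
                       paste(missing_cols, collapse = ", ")))
  }
  samples <- tibble::as_tibble(samples)
  samples$timepoint_weeks <- as.integer(samples$timepoint_weeks)
  check_unique_ids(samples$sample_id, "sample")
  if (!all(samples$role %in% c("donor", "recipient"))) {
    abort_validation("role must be 'donor' or 'recipient'")
  }
  off_grid <- setdiff(unique(samples$timepoint_weeks), timepoint_grid)
  if (length(off_grid) > 0) {
    abort_validation(paste("timepoint_weeks outside the study grid:",
                           paste(off_grid, collapse = ", ")))
  }
  donors <- unique(samples$subject_id[samples$role == "donor"])
  if (any(samples$timepoint_weeks[samples$role == "donor"] != 0L)) {
    abort_validation("donor samples must have timepoint_weeks = 0")
  }
  rec <- samples[samples$role == "recipient", ]
  if (nrow(rec) > 0) {
    if (anyNA(rec$donor_id)) abort_linkage("every recipient needs a donor_id")
    unknown <- setdiff(unique(rec$donor_id), donors)
    if (length(unknown) > 0) {
      abort_linkage(paste("recipient references unknown donor(s):",
                          paste(unknown, collapse = ", ")))
    }
    multi <- tapply(rec$donor_id, rec$subject_id, function(d) length(unique(d)))
    if (any(multi > 1)) {
      abort_linkage(paste("recipient(s) paired to more than one donor:",
                          paste(names(multi)[multi > 1], collapse = ", ")))
    }
  }
  with_baseline <- unique(rec$subject_id[rec$timepoint_weeks == 0L])
  lacking <- setdiff(unique(rec$subject_id), with_baseline)
  exclusions <- tibble::tibble(subject_id = lacking,
                               reason = rep("no baseline (week 0) sample",
                                            length(lacking)))
  if (nrow(exclusions) > 0) {
    rlang::warn(paste("recipient(s) without a week-0 baseline sample:",
                      paste(lacking, collapse = ", ")),
                class = "fmtgraft_missing_baseline")
  }
  if (!is.null(subjects)) {
    subjects <- tibble::as_tibble(subjects)
    if (!"subject_id" %in% names(subjects)) {
      abort_format("subjects table requires a 'subject_id' column")
    }
    check_unique_ids(subjects$subject_id, "subject")
  }
  structure(list(samples = samples, subjects = subjects,
                 exclusions = exclusions,
                 timepoint_grid = as.integer(timepoint_grid)),
            class = "fmt_metadata")
}

#' @export
print.fmt_metadata <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<fmt_metadata> %d samples; %d donors, %d recipients; weeks {%s}; %d excluded\n",
    nrow(s), length(unique(s$subject_id[s$role == "donor"])),
    length(unique(s$subject_id[s$role == "recipient"])),
    paste(sort(unique(s$timepoint_weeks)), collapse = ","), nrow(x$exclusions)))
  invisible(x)
}

#' Read cohort metadata (and optional covariates) from TSV
#'
#' @param path sample metadata TSV with the columns documented in
#'   [cohort_metadata()].
#' @param covariates_path optional per-subject covariate TSV
#'   (`subject_id` + named numeric columns).
#' @inheritParams cohort_metadata
#' @return An `fmt_metadata` object.
#' @export
read_metadata <- function(path, covariates_path = NULL,
                          timepoint_grid = c(0L, 2L, 6L, 12L)) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  samples <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", subject_id = "c", role = "c", donor_id = "c",
    timepoint_weeks = "i", .default = "c"), progress = FALSE)
  subjects <- if (!is.null(covariates_path)) read_covariates(covariates_path)
  cohort_metadata(samples, subjects, timepoint_grid)
}

#' Read a per-subject covariate table from TSV
#'
#' @param path TSV with a `subject_id` column and numeric covariate columns.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  cov <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = "c", .default = "d"), progress = FALSE)
  if (!"subject_id" %in% names(cov)) {
    abort_format("covariate table requires a 'subject_id' column")
  }
  check_unique_ids(cov$subject_id, "subject")
  cov
}

#' Write cohort metadata to TSV
#'
#' @param metadata an `fmt_metadata` object.
#' @param path output path for the sample table.
#' @param covariates_path optional output path for the subject table.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, covariates_path = NULL) {
  stopifnot(inherits(metadata, "fmt_metadata"))
  readr::write_tsv(metadata$samples, path, progress = FALSE)
  if (!is.null(covariates_path) && !is.null(metadata$subjects)) {
    readr::write_tsv(metadata$subjects, covariates_path, progress = FALSE)
  }
  invisible(path)
}

# recipients with a usable baseline, in stable order
eligible_recipients <- function(metadata) {
  s <- metadata$samples
  rec <- unique(s$subject_id[s$role == "recipient"])
  setdiff(rec, metadata$exclusions$subject_id)
}

# sample id for (subject, week); NA if absent, error if ambiguous
sample_at <- function(metadata, subject, week) {
  s <- metadata$samples
  hit <- s$sample_id[s$subject_id == subject & s$timepoint_weeks == week]
  if (length(hit) > 1) {
    abort_validation(sprintf("subject %s has %d samples at week %d",
                             subject, length(hit), week))
  }
  if (length(hit) == 0) NA_character_ else hit
}
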