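#' Presence/absence calls on a rarefied table
#'
#' Binary detection underlying all engraftment bookkeeping: an ASV is called
#' present in a sample when its rarefied count reaches `min_count`. No
#' detection rule removes the dependence on sequencing depth entirely, so
#' calls are only comparable across samples rarefied to the same even depth;
#' the threshold is recorded and surfaced so sensitivity to it can be
#' checked.
#'
#' @param x a rarefied [feature_table()].
#' @param min_count minimum rarefied count to call presence (default 1).
#' @return An `fmt_presence` object: logical ASV x sample matrix with
#'   attribute `min_count`.
#' @export
call_presence <- function(x, min_count = 1) {
  stopifnot(inherits(x, "fmt_feature_table"))
  if (min_count < 1) abort_validation("min_count must be >= 1")
  p <- unclass(x) >= min_count
  structure(p, class = c("fmt_presence", "matrix", "array"),
            min_count = as.integer(min_count))
}

presence_of <- function(presence, samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) == 0) return(NULL)
  if (length(samples) == 1) return(unclass(presence)[, samples])
  apply(unclass(presence)[, samples, drop = FALSE], 1, any)
}

donor_samples_of <- function(metadata, donor_id) {
  s <- metadata$samples
  s$sample_id[s$subject_id == donor_id & s$role == "donor"]
}

#' Partition one recipient timepoint against its donor-recipient baselines
#'
#' Classifies the ASV universe of a donor-recipient pair by origin:
#' *donor-specific* ASVs are present in the donor baseline and absent from
#' the recipient baseline (species shared only with the donor); *shared*
#' ASVs sit in both baselines; *recipient-specific* in the recipient
#' baseline only; *novel* ASVs appear at follow-up without being in either
#' baseline. The retained fraction is the share of the donor-specific pool
#' detected at follow-up. If the donor-specific pool is empty the fraction
#' is undefined and flagged, never reported as 0. When a donor has several
#' baseline samples, donor presence is their union.
#'
#' @param donor,recipient_baseline,recipient_followup logical presence
#'   vectors over a shared ASV universe (named), e.g. columns of
#'   [call_presence()].
#' @return An `fmt_partition` list: the five ASV sets, `retained_fraction`,
#'   and `undefined` flag.
#' @export
partition_pair <- function(donor, recipient_baseline, recipient_followup) {
  ids <- names(donor)
  if (is.null(ids) || !identical(ids, names(recipient_baseline)) ||
      !identical(ids, names(recipient_followup))) {
    abort_validation("the three presence vectors must share one named ASV universe")
  }
  donor_specific <- ids[donor & !recipient_baseline]
  present <- donor_specific[recipient_followup[donor_specific]]
  out <- list(
    donor_specific_present = present,
    donor_specific_absent = setdiff(donor_specific, present),
    shared = ids[donor & recipient_baseline],
    recipient_specific = ids[!donor & recipient_baseline],
    novel = ids[recipient_followup & !donor & !recipient_baseline],
    retained_fraction = if (length(donor_specific) == 0) NA_real_ else
      length(present) / length(donor_specific),
    undefined = length(donor_specific) == 0
  )
  structure(out, class = "fmt_partition")
}

#' @export
print.fmt_partition <- function(x, ...) {
  cat(sprintf(
    "<fmt_partition> donor-specific %d (retained %s), shared %d, recipient-specific %d, novel %d\n",
    length(x$donor_specific_present) + length(x$donor_specific_absent),
    if (x$undefined) "undefined" else sprintf("%.2f", x$retained_fraction),
    length(x$shared), length(x$recipient_specific), length(x$novel)))
  invisible(x)
}

#' Donor-specific ASV retention across the cohort
#'
#' Applies [partition_pair()] to every eligible recipient at every post-FMT
#' timepoint with a sample, using each donor-recipient pair's own baselines.
#'
#' @param presence an [call_presence()] object covering all cohort samples.
#' @param metadata an [cohort_metadata()] object.
#' @param timepoints post-FMT weeks to evaluate.
#' @return Tibble with one row per (recipient, timepoint): set sizes,
#'   `retained_fraction`, `undefined`.
#' @export
engraftment_partitions <- function(presence, metadata, timepoints = c(2, 6, 12)) {
  stopifnot(inherits(presence, "fmt_presence"), inherits(metadata, "fmt_metadata"))
  s <- metadata$samples
  avail <- colnames(presence)
  rows <- list()
  for (rid in eligible_recipients(metadata)) {
    donor_id <- unique(s$donor_id[s$subject_id == rid & s$role == "recipient"])
    dsamp <- intersect(donor_samples_of(metadata, donor_id), avail)
    bsamp <- sample_at(metadata, rid, 0L)
    if (length(dsamp) == 0 || is.na(bsamp) || !bsamp %in% avail) next
    donor_p <- presence_of(presence, dsamp)
    base_p <- unclass(presence)[, bsamp]
    for (tp in timepoints) {
      fsamp <- sample_at(metadata, rid, as.integer(tp))
      if (is.na(fsamp) || !fsamp %in% avail) next
      part <- partition_pair(donor_p, base_p, unclass(presence)[, fsamp])
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = rid, donor_id = donor_id, timepoint_weeks = as.integer(tp),
        n_donor_specific = length(part$donor_specific_present) +
          length(part$donor_specific_absent),
        n_retained = length(part$donor_specific_present),
        n_shared = length(part$shared),
        n_recipient_specific = length(part$recipient_specific),
        n_novel = length(part$novel),
        retained_fraction = part$retained_fraction,
        undefined = part$undefined)
    }
  }
  dplyr::bind_rows(rows)
}

# per-recipient eligibility and retention indicators for one timepoint:
# rows = donor-specific-eligible (recipient, asv) combinations
retention_indicators <- function(presence, metadata, timepoints = c(2, 6, 12)) {
  s <- metadata$samples
  avail <- colnames(presence)
  rows <- list()
  for (rid in eligible_recipients(metadata)) {
    donor_id <- unique(s$donor_id[s$subject_id == rid & s$role == "recipient"])
    dsamp <- intersect(donor_samples_of(metadata, donor_id), avail)
    bsamp <- sample_at(metadata, rid, 0L)
    if (length(dsamp) == 0 || is.na(bsamp) || !bsamp %in% avail) next
    donor_p <- presence_of(presence, dsamp)
    base_p <- unclass(presence)[, bsamp]
    eligible <- names(donor_p)[donor_p & !base_p]
    if (length(eligible) == 0) next
    for (tp in timepoints) {
      fsamp <- sample_at(metadata, rid, as.integer(tp))
      if (is.na(fsamp) || !fsamp %in% avail) next
      fol_p <- unclass(presence)[, fsamp]
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = rid, donor_id = donor_id,
        timepoint_weeks = as.integer(tp), asv_id = eligible,
        retained = as.integer(fol_p[eligible]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-ASV engraftment rates by response group
#'
#' The engraftment rate of a donor-specific ASV at a timepoint is the
#' fraction of eligible recipients in which it is detected. The primary
#' denominator is pair-restricted: a recipient is eligible for an ASV only
#' if its *own* donor carries the ASV and the recipient lacked it at
#' baseline (donors differ, so an ASV can only engraft where it was given).
#' The unrestricted denominator (all recipients in the group) is also
#' reported as `rate_all`. ASV-timepoint-group cells with no eligible
#' recipient are marked inestimable (`NA` rate).
#'
#' @inheritParams engraftment_partitions
#' @param labels tibble with `subject_id` and `label`
#'   (`"responder"`/`"non_responder"`), from [classify_responders()].
#' @return Tibble: `asv_id`, `timepoint_weeks`, `group`, `numerator`,
#'   `denominator`, `rate`, `rate_all`.
#' @export
engraftment_rates <- function(presence, metadata, labels,
                              timepoints = c(2, 6, 12)) {
  ind <- retention_indicators(presence, metadata, timepoints)
  if (nrow(ind) == 0) abort_validation("no eligible (recipient, ASV) pairs")
  ind <- dplyr::inner_join(ind, labels[, c("subject_id", "label")],
                           by = "subject_id")
  n_group <- labels |>
    dplyr::count(.data$label, name = "n_recipients")
  universe <- tidyr::expand_grid(
    asv_id = unique(ind$asv_id),
    timepoint_weeks = as.integer(timepoints),
    label = unique(labels$label))
  rates <- ind |>
    dplyr::group_by(.data$asv_id, .data$timepoint_weeks, .data$label) |>
    dplyr::summarise(numerator = sum(.data$retained),
                     denominator = dplyr::n(), .groups = "drop")
  universe |>
    dplyr::left_join(rates, by = c("asv_id", "timepoint_weeks", "label")) |>
    dplyr::left_join(n_group, by = "label") |>
    dplyr::mutate(
      numerator = dplyr::coalesce(.data$numerator, 0L),
      denominator = dplyr::coalesce(.data$denominator, 0L),
      rate = ifelse(.data$denominator > 0,
                    .data$numerator / .data$denominator, NA_real_),
      rate_all = .data$numerator / .data$n_recipients) |>
    dplyr::rename(group = "label") |>
    dplyr::select(-"n_recipients")
}

#' Select ASVs engrafting preferentially in responders
#'
#' At each timepoint, per-recipient retention indicators of every
#' donor-specific ASV are compared between responders and non-responders
#' with Welch's t-test; an ASV is selected when any timepoint shows
#' `p < alpha` with the responder mean above the non-responder mean
#' (two-sided test, direction applied post hoc). Timepoints where either
#' group has fewer than two eligible recipients are skipped and reported.
#'
#' @inheritParams engraftment_rates
#' @param alpha selection threshold on the per-timepoint p-value.
#' @return Tibble with one row per (ASV, timepoint): group means, sizes,
#'   `p_value`, `responder_greater`, plus per-ASV `selected`. Attribute
#'   `selected` carries the selected ASV ids; attribute `skipped` the
#'   (ASV, timepoint) cells with insufficient group sizes.
#' @export
differential_engrafters <- function(presence, metadata, labels, alpha = 0.05,
                                    timepoints = c(2, 6, 12)) {
  ind <- retention_indicators(presence, metadata, timepoints) |>
    dplyr::inner_join(labels[, c("subject_id", "label")], by = "subject_id")
  if (nrow(ind) == 0) abort_validation("no eligible (recipient, ASV) pairs")
  cells <- ind |>
    dplyr::group_by(.data$asv_id, .data$timepoint_weeks) |>
    dplyr::group_split()
  rows <- purrr::map(cells, function(cell) {
    r <- cell$retained[cell$label == "responder"]
    nr <- cell$retained[cell$label == "non_responder"]
    base <- tibble::tibble(
      asv_id = cell$asv_id[1], timepoint_weeks = cell$timepoint_weeks[1],
      n_responder = length(r), n_nonresponder = length(nr),
      mean_responder = if (length(r)) mean(r) else NA_real_,
      mean_nonresponder = if (length(nr)) mean(nr) else NA_real_)
    if (length(r) < 2 || length(nr) < 2) {
      return(dplyr::mutate(base, p_value = NA_real_, skipped = TRUE))
    }
    wt <- welch_t(r, nr)
    dplyr::mutate(base, p_value = wt$p_value, skipped = FALSE)
  })
  tests <- dplyr::bind_rows(rows) |>
    dplyr::mutate(responder_greater = !is.na(.data$p_value) &
                    .data$mean_responder > .data$mean_nonresponder)
  sel <- tests |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(selected = any(.data$p_value < alpha &
                                      .data$responder_greater, na.rm = TRUE))
  out <- dplyr::left_join(tests, sel, by = "asv_id")
  attr(out, "selected") <- sel$asv_id[sel$selected]
  attr(out, "skipped") <- dplyr::filter(tests, .data$skipped)[
    , c("asv_id", "timepoint_weeks")]
  attr(out, "alpha") <- alpha
  out
}

#' Loss of recipient-baseline ASVs after FMT
#'
#' For every ASV carried by at least one recipient at baseline, the fraction
#' of carriers (per response group) in which it is no longer detected at the
#' follow-up visit, with a Welch t-test on the per-recipient loss
#' indicators between groups.
#'
#' @inheritParams engraftment_rates
#' @param followup_week visit at which loss is assessed (default week 6).
#' @return Tibble: per ASV, carrier counts, per-group loss fractions,
#'   overall `loss_fraction`, and `p_value` (NA when a group has < 2
#'   carriers).
#' @export
removed_asvs <- function(presence, metadata, labels, followup_week = 6) {
  s <- metadata$samples
  avail <- colnames(presence)
  rows <- list()
  for (rid in eligible_recipients(metadata)) {
    bsamp <- sample_at(metadata, rid, 0L)
    fsamp <- sample_at(metadata, rid, as.integer(followup_week))
    if (is.na(bsamp) || is.na(fsamp) || !all(c(bsamp, fsamp) %in% avail)) next
    base_p <- unclass(presence)[, bsamp]
    fol_p <- unclass(presence)[, fsamp]
    carried <- names(base_p)[base_p]
    if (length(carried) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = rid, asv_id = carried, lost = as.integer(!fol_p[carried]))
  }
  carr <- dplyr::bind_rows(rows)
  if (nrow(carr) == 0) abort_validation("no baseline carriers found")
  carr <- dplyr::inner_join(carr, labels[, c("subject_id", "label")],
                            by = "subject_id")
  per_asv <- carr |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::group_split()
  dplyr::bind_rows(purrr::map(per_asv, function(cell) {
    r <- cell$lost[cell$label == "responder"]
    nr <- cell$lost[cell$label == "non_responder"]
    p <- if (length(r) >= 2 && length(nr) >= 2) welch_t(r, nr)$p_value else NA_real_
    tibble::tibble(
      asv_id = cell$asv_id[1],
      n_carriers = nrow(cell),
      n_carriers_responder = length(r), n_carriers_nonresponder = length(nr),
      loss_fraction = mean(cell$lost),
      loss_responder = if (length(r)) mean(r) else NA_real_,
      loss_nonresponder = if (length(nr)) mean(nr) else NA_real_,
      p_value = p)
  }))
}
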