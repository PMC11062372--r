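presence_vec <- function(ids, present) {
  stats::setNames(ids %in% present, ids)
}

test_that("presence calls respect the threshold and are monotone in it", {
  ft <- tiny_table()
  p1 <- call_presence(ft, min_count = 1)
  expect_false(unclass(p1)["ASV3", "S1"])  # count 0
  expect_true(unclass(p1)["ASV2", "S1"])   # count 1
  expect_error(call_presence(ft, min_count = 0),
               class = "fmtgraft_validation_error")
  for (k in 2:6) {
    pk <- call_presence(ft, min_count = k)
    # raising the threshold never turns an absent call present
    expect_true(all(unclass(pk) <= unclass(call_presence(ft, k - 1))))
  }
})

test_that("pair partition matches the set definitions", {
  ids <- c("A", "B", "C", "D", "E")
  part <- partition_pair(
    donor = presence_vec(ids, c("A", "B", "C")),
    recipient_baseline = presence_vec(ids, c("B", "D")),
    recipient_followup = presence_vec(ids, c("A", "B", "D")))
  expect_setequal(part$donor_specific_present, "A")
  expect_setequal(part$donor_specific_absent, "C")
  expect_equal(part$retained_fraction, 1 / 2)
  expect_setequal(part$shared, "B")
  expect_setequal(part$recipient_specific, "D")
  expect_equal(part$novel, character(0))
  expect_false(part$undefined)

  # followup identical to baseline -> nothing retained
  part2 <- partition_pair(
    presence_vec(ids, c("A", "C")), presence_vec(ids, c("B", "D")),
    presence_vec(ids, c("B", "D")))
  expect_equal(part2$retained_fraction, 0)

  # donor subset of recipient baseline -> undefined, flagged (not 0)
  part3 <- partition_pair(
    presence_vec(ids, "B"), presence_vec(ids, c("B", "D")),
    presence_vec(ids, c("B", "E")))
  expect_true(part3$undefined)
  expect_true(is.na(part3$retained_fraction))
  expect_setequal(part3$novel, "E")
})

test_that("partition sets are disjoint, exhaustive and relabeling-invariant", {
  set.seed(51)
  ids <- paste0("A", 1:40)
  for (i in 1:20) {
    d <- presence_vec(ids, sample(ids, 15))
    b <- presence_vec(ids, sample(ids, 15))
    f <- presence_vec(ids, sample(ids, 15))
    part <- partition_pair(d, b, f)
    sets <- list(part$donor_specific_present, part$donor_specific_absent,
                 part$shared, part$recipient_specific)
    expect_equal(sum(lengths(sets)), length(unique(unlist(sets))))
    # donor-specific + shared + recipient-specific + neither = universe
    neither <- setdiff(ids, unlist(sets))
    expect_true(all(!d[neither] & !b[neither]))
    expect_true(all(part$novel %in% neither))
    # adding an everywhere-absent ASV leaves the retained fraction unchanged
    ids2 <- c(ids, "ZZZ")
    part_aug <- partition_pair(
      presence_vec(ids2, names(d)[d]), presence_vec(ids2, names(b)[b]),
      presence_vec(ids2, names(f)[f]))
    expect_equal(part_aug$retained_fraction, part$retained_fraction)
  }
})

test_that("engraftment rates use pair-restricted eligibility", {
  # donor carries A,B; R1 baseline lacks both, R2 baseline has A
  counts <- matrix(0L, nrow = 2, ncol = 7,
                   dimnames = list(c("A", "B"),
                                   c("D1_wk0", "R1_wk0", "R1_wk2", "R1_wk6",
                                     "R2_wk0", "R2_wk2", "R2_wk6")))
  counts["A", c("D1_wk0", "R1_wk2", "R2_wk0", "R2_wk2", "R2_wk6")] <- 5L
  counts["B", c("D1_wk0", "R2_wk2")] <- 5L
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    subject_id = c("D1", rep("R1", 3), rep("R2", 3)),
    role = c("donor", rep("recipient", 6)),
    donor_id = c(NA, rep("D1", 6)),
    timepoint_weeks = c(0L, 0L, 2L, 6L, 0L, 2L, 6L))
  md <- cohort_metadata(samples)
  pres <- call_presence(feature_table(counts))
  labels <- tibble::tibble(subject_id = c("R1", "R2"),
                           label = c("responder", "non_responder"))
  rates <- engraftment_rates(pres, md, labels, timepoints = c(2, 6))
  # ASV A: R2 carried it at baseline -> only R1 eligible
  a_resp_wk2 <- rates[rates$asv_id == "A" & rates$group == "responder" &
                        rates$timepoint_weeks == 2, ]
  expect_equal(a_resp_wk2$denominator, 1L)
  expect_equal(a_resp_wk2$rate, 1)
  # no eligible non-responder for A -> inestimable
  a_nr <- rates[rates$asv_id == "A" & rates$group == "non_responder" &
                  rates$timepoint_weeks == 2, ]
  expect_equal(a_nr$denominator, 0L)
  expect_true(is.na(a_nr$rate))
  # numerators never exceed denominators
  expect_true(all(rates$numerator <= pmax(rates$denominator, rates$numerator * 0)))
})

test_that("differential engrafter selection separates maximal from null patterns", {
  cohort <- simulate_cohort(
    cohort_config(n_donors = 2, n_recipients = 12, n_responders = 6,
                  p_engraft_responder = 1, p_engraft_nonresponder = 0,
                  p_loss_per_visit = 0),
    seed = 9)
  r <- rarefy_counts(cohort$table, 9518, seed = 1)
  pres <- call_presence(r)
  lab <- classify_responders(cohort$metadata$subjects)
  de <- differential_engrafters(pres, cohort$metadata, lab)
  planted <- unique(cohort$truth$donor_pools$asv_id)
  sel <- attr(de, "selected")
  # responders engraft everything, non-responders nothing: planted ASVs with
  # both groups eligible must be selected (up to rarefaction dropout)
  tested <- de[de$asv_id %in% planted & !de$skipped &
                 de$timepoint_weeks == 2, ]
  expect_gt(nrow(tested), 0)
  expect_gte(mean(tested$asv_id %in% sel), 0.95)
  # identical retention in both groups is never selected
  expect_false(any(de$p_value[de$mean_responder == de$mean_nonresponder] <
                     attr(de, "alpha"), na.rm = TRUE))
})

test_that("zero engraftment probability gives zero retained fractions", {
  cohort <- simulate_cohort(
    cohort_config(n_recipients = 8, n_responders = 5,
                  p_engraft_responder = 0, p_engraft_nonresponder = 0),
    seed = 10)
  r <- rarefy_counts(cohort$table, 9518, seed = 2)
  pres <- call_presence(r)
  parts <- engraftment_partitions(pres, cohort$metadata)
  planted <- cohort$truth$donor_pools
  # restrict the check to the planted donor-specific pools: retained counts
  # among them must be zero at every visit
  ind <- fmtgraft:::retention_indicators(pres, cohort$metadata)
  ind_planted <- dplyr::semi_join(
    ind, dplyr::rename(planted, donor_id2 = "donor_id"), by = "asv_id")
  expect_equal(sum(ind_planted$retained), 0)
  expect_true(all(parts$n_donor_specific > 0))
})

test_that("memoryless per-visit loss matches its closed form", {
  p_loss <- 0.1
  cohort <- simulate_cohort(
    cohort_config(n_recipients = 20, n_responders = 14,
                  p_loss_per_visit = p_loss),
    seed = 12)
  r <- rarefy_counts(cohort$table, 9518, seed = 3)
  pres <- call_presence(r)
  lab <- classify_responders(cohort$metadata$subjects)
  rem <- removed_asvs(pres, cohort$metadata, lab, followup_week = 6)
  # two visit transitions by week 6: expected loss 1 - (1 - p)^2 = 0.19
  expected <- 1 - (1 - p_loss)^2
  carriers <- sum(rem$n_carriers)
  se <- sqrt(expected * (1 - expected) / carriers)
  expect_lt(abs(weighted.mean(rem$loss_fraction, rem$n_carriers) - expected),
            4 * se + 0.02)  # small allowance for detection dropout
  # boundary behaviours
  expect_true(all(rem$loss_fraction >= 0 & rem$loss_fraction <= 1))
})
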