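test_that("simulation is bit-identical for a fixed seed", {
  cfg <- cohort_config(n_recipients = 8, n_responders = 5)
  a <- simulate_cohort(cfg, seed = 1)
  b <- simulate_cohort(cfg, seed = 1)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$metadata$samples, b$metadata$samples)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cfg, seed = 2)
  expect_false(identical(unclass(a$table), unclass(c$table)))
})

test_that("infeasible and invalid configurations are rejected", {
  expect_error(cohort_config(n_donors = 4, donor_specific_per_pair = 80,
                             n_asvs_global = 300),
               class = "fmtgraft_validation_error")
  expect_error(cohort_config(n_responders = 30, n_recipients = 29),
               class = "fmtgraft_validation_error")
  expect_error(cohort_config(p_engraft_responder = 1.2),
               class = "fmtgraft_validation_error")
  expect_error(cohort_config(depth_mean = 5000, rarefaction_depth = 9518),
               class = "fmtgraft_validation_error")
  expect_error(cohort_config(diversity_coupling = 0.5),
               class = "fmtgraft_validation_error")
})

test_that("donor pools are disjoint and absent from recipient baselines", {
  co <- default_cohort()
  pools <- split(co$truth$donor_pools$asv_id, co$truth$donor_pools$donor_id)
  for (i in seq_along(pools)) for (j in seq_along(pools)) {
    if (i < j) expect_length(intersect(pools[[i]], pools[[j]]), 0)
  }
  # planted pools never appear in any recipient baseline (pre-noise truth:
  # zero reads, not just below detection)
  s <- co$metadata$samples
  base_samples <- s$sample_id[s$role == "recipient" & s$timepoint_weeks == 0]
  planted <- unique(co$truth$donor_pools$asv_id)
  expect_equal(sum(unclass(co$table)[planted, base_samples]), 0)
})

test_that("responder counts, labels and HOMA2-IR deltas are consistent", {
  co <- default_cohort()
  rec <- co$truth$recipients
  expect_equal(sum(rec$responder), 21)
  expect_equal(nrow(rec), 29)
  expect_true(all(rec$delta_homa2ir[rec$responder] < 0))
  expect_true(all(rec$delta_homa2ir[!rec$responder] > 0))
  lab <- classify_responders(co$metadata$subjects)
  expect_equal(sum(lab$label == "responder"), 21)
  expect_equal(sum(lab$label == "non_responder"), 8)
})

test_that("engraftment frequencies converge to the group probabilities", {
  cfg <- cohort_config(n_recipients = 200, n_responders = 145,
                       covariate_effect = 0)
  co <- simulate_cohort(cfg, seed = 77)
  tr <- dplyr::inner_join(co$truth$engraftment, co$truth$recipients,
                          by = "subject_id")
  wk2 <- tr[tr$timepoint_weeks == 2, ]
  for (grp in c(TRUE, FALSE)) {
    p_true <- if (grp) 0.6 else 0.2
    x <- wk2$engrafted[wk2$responder == grp]
    se <- sqrt(p_true * (1 - p_true) / length(x))
    expect_lt(abs(mean(x) - p_true), 3 * se)
  }
})

test_that("diversity coupling is planted at the configured strength", {
  cfg <- cohort_config(n_recipients = 200, n_responders = 145)
  co <- simulate_cohort(cfg, seed = 78)
  rec <- co$truth$recipients
  rs <- stats::cor(rec$true_baseline_richness, rec$richness_gain,
                   method = "spearman")
  expect_lt(abs(rs - (-0.75)), 0.15)
})

test_that("label permutation preserves counts, breaks group structure", {
  co <- default_cohort()
  perm <- permute_response_labels(co, seed = 5)
  expect_equal(sum(perm$truth$recipients$responder), 21)
  expect_identical(unclass(perm$table), unclass(co$table))
  # labels stay consistent with delta signs
  expect_true(all((perm$truth$recipients$delta_homa2ir < 0) ==
                    perm$truth$recipients$responder))
  expect_identical(permute_response_labels(co, seed = 5)$truth$recipients,
                   perm$truth$recipients)
  # over many permutations the group difference in true engraftment vanishes
  co_small <- simulate_cohort(cohort_config(n_recipients = 16,
                                            n_responders = 10), seed = 6)
  diffs <- vapply(1:100, function(s) {
    p <- permute_response_labels(co_small, seed = s)
    tr <- dplyr::inner_join(p$truth$engraftment, p$truth$recipients,
                            by = "subject_id")
    wk2 <- tr[tr$timepoint_weeks == 2, ]
    mean(wk2$engrafted[wk2$responder]) - mean(wk2$engrafted[!wk2$responder])
  }, numeric(1))
  true_diff <- {
    tr <- dplyr::inner_join(co_small$truth$engraftment,
                            co_small$truth$recipients, by = "subject_id")
    wk2 <- tr[tr$timepoint_weeks == 2, ]
    mean(wk2$engrafted[wk2$responder]) - mean(wk2$engrafted[!wk2$responder])
  }
  expect_lt(abs(mean(diffs)), abs(true_diff) / 3)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("responders retain nearly everything when engraftment is certain", {
  cfg <- cohort_config(n_recipients = 10, n_responders = 7,
                       p_engraft_responder = 1, p_loss_per_visit = 0)
  co <- simulate_cohort(cfg, seed = 13)
  r <- rarefy_counts(co$table, cfg$rarefaction_depth, seed = 14)
  pres <- call_presence(r)
  ind <- fmtgraft:::retention_indicators(pres, co$metadata,
                                         timepoints = 2)
  planted <- unique(co$truth$donor_pools$asv_id)
  resp <- co$truth$recipients$subject_id[co$truth$recipients$responder]
  obs <- ind$retained[ind$subject_id %in% resp & ind$asv_id %in% planted]
  # brute-force dropout oracle: resample the generated week-2 profiles at
  # the rarefaction depth and measure how often a truly-present planted ASV
  # yields zero reads
  s <- co$metadata$samples
  drop_est <- local({
    misses <- 0; total <- 0
    for (rid in resp) {
      samp <- paste0(rid, "_wk2")
      counts <- unclass(co$table)[, samp]
      prob <- counts / sum(counts)
      for (b in 1:20) {
        sub <- stats::rmultinom(1, cfg$rarefaction_depth, prob)[, 1]
        present_true <- intersect(planted, names(counts)[counts > 0])
        misses <- misses + sum(sub[present_true] == 0)
        total <- total + length(present_true)
      }
      }
    misses / total
  })
  # sequencing (multinomial) dropout also affects the original library: a
  # truly colonized ASV can miss the library itself, so allow both layers
  expect_gte(mean(obs), (1 - drop_est) * 0.97)
  expect_gte(mean(obs), 0.9)
})
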