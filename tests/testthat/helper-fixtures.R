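# shared in-code fixtures and small independent oracles

tiny_table <- function() {
  feature_table(matrix(c(5L, 1L, 0L, 0L, 2L, 7L), nrow = 3,
                       dimnames = list(c("ASV1", "ASV2", "ASV3"),
                                       c("S1", "S2"))))
}

# one donor, two recipients with full visit grids
tiny_metadata <- function() {
  samples <- tibble::tibble(
    sample_id = c("D1_wk0", paste0("R1_wk", c(0, 2, 6, 12)),
                  paste0("R2_wk", c(0, 2, 6, 12))),
    subject_id = c("D1", rep("R1", 4), rep("R2", 4)),
    role = c("donor", rep("recipient", 8)),
    donor_id = c(NA, rep("D1", 8)),
    timepoint_weeks = c(0L, 0L, 2L, 6L, 12L, 0L, 2L, 6L, 12L))
  cohort_metadata(samples)
}

# brute-force Bray-Curtis double loop (independent of vegan)
bray_oracle <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
  }
  d
}

# all permutations of 1:n (for exact envfit enumeration at small n)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# default synthetic cohort, cached per test run
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config(), seed = 101)
    cache
  }
})
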