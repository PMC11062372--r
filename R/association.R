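#' Univariate association statistics
#'
#' The group-comparison and correlation statistics used across the analysis:
#' Welch's t-test (per-timepoint engraftment comparisons), the Wilcoxon
#' rank-sum test (predictor abundance between responders and
#' non-responders), Spearman rank correlation (baseline factors vs diversity
#' change), donor-adjusted ANCOVA, and Benjamini-Hochberg FDR. Each returns
#' a one-row tibble with a common column set so results from one analysis
#' family can be row-bound and FDR-corrected together.
#'
#' @param x,y numeric vectors for the two groups (or the two variables, for
#'   [spearman_cor()]).
#' @return A tibble with columns `method`, `estimate`, `statistic`,
#'   `p_value`, `n_used`, `donor_adjusted`.
#' @name associations
NULL

assoc_row <- function(method, estimate, statistic, p_value, n_used,
                      donor_adjusted = FALSE) {
  tibble::tibble(method = method, estimate = estimate, statistic = statistic,
                 p_value = p_value, n_used = as.integer(n_used),
                 donor_adjusted = donor_adjusted)
}

#' @describeIn associations Welch two-sample t-test (unequal variances,
#'   Satterthwaite df, two-sided). When both groups are constant the test is
#'   degenerate: equal means give `t = 0, p = 1`; unequal means are treated
#'   as infinite separation (`t = +/-Inf`, `p = 0`).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort_validation("welch_t needs >= 2 observations per group")
  }
  est <- mean(x) - mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (est == 0) return(assoc_row("welch_t", 0, 0, 1, length(x) + length(y)))
    return(assoc_row("welch_t", est, sign(est) * Inf, 0, length(x) + length(y)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  assoc_row("welch_t", est, unname(ht$statistic), ht$p.value,
            length(x) + length(y))
}

#' @describeIn associations Wilcoxon rank-sum test, two-sided, ties
#'   mid-ranked. Exact enumeration when the combined sample size is at most
#'   12 and the data are tie-free; otherwise the normal approximation with
#'   continuity and tie correction. All values identical across both groups
#'   gives `p = 1`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    abort_validation("wilcoxon_ranksum needs >= 1 observation per group")
  }
  n <- length(x) + length(y)
  if (length(unique(c(x, y))) == 1) {
    return(assoc_row("wilcoxon_ranksum", 0, length(x) * length(y) / 2, 1, n))
  }
  exact <- n <= 12 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  est <- stats::median(x) - stats::median(y)
  assoc_row("wilcoxon_ranksum", est, unname(ht$statistic), ht$p.value, n)
}

#' @describeIn associations Spearman rank correlation (`r_s`, Pearson
#'   correlation of mid-ranks) with the t-approximation p-value. Constant
#'   input is flagged with a warning and an `NA` estimate.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) abort_validation("spearman_cor needs n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("constant input: Spearman correlation undefined",
                class = "fmtgraft_degenerate")
    return(assoc_row("spearman", NA_real_, NA_real_, NA_real_, length(x)))
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  assoc_row("spearman", unname(ht$estimate), unname(ht$statistic),
            ht$p.value, length(x))
}

#' Donor-adjusted association (ANCOVA by OLS)
#'
#' Ordinary least squares of a per-recipient outcome on a predictor plus
#' donor indicator covariates, mirroring ANCOVA with donor selection as a
#' covariable: donors differ, so between-group and slope contrasts are
#' estimated within donor. A numeric predictor is tested by the t-test on
#' its coefficient; a factor predictor (e.g. responder group) by the partial
#' F-test of its levels given donor. The design is closed-form (normal
#' equations); no iterative fitting. Donor levels that are aliased in the
#' design (e.g. a lone recipient whose donor indicator is collinear with the
#' predictor) are merged into the reference level with a warning.
#'
#' @param data data frame with one row per recipient.
#' @param outcome,predictor,donor column names in `data`; `donor` defaults
#'   to `"donor_id"`.
#' @return One-row tibble as in [associations], with `estimate` the
#'   predictor slope (or non-reference group effect) adjusted for donor.
#' @export
donor_adjusted_assoc <- function(data, outcome, predictor, donor = "donor_id") {
  stopifnot(all(c(outcome, predictor, donor) %in% names(data)))
  df <- data.frame(.y = data[[outcome]], .x = data[[predictor]],
                   .donor = factor(data[[donor]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.donor <- droplevels(df$.donor)
  if (nlevels(df$.donor) < 2) {
    abort_validation("donor_adjusted_assoc needs >= 2 donors represented")
  }
  if (nrow(df) <= nlevels(df$.donor) + 2) {
    abort_validation("too few recipients for the donor-adjusted design")
  }
  fit <- stats::lm(.y ~ .x + .donor, data = df)
  cf <- stats::coef(fit)
  aliased_donor <- grepl("^\\.donor", names(cf)) & is.na(cf)
  if (any(aliased_donor)) {
    bad <- sub("^\\.donor", "", names(cf)[aliased_donor])
    rlang::warn(paste("aliased donor level(s) merged into reference:",
                      paste(bad, collapse = ", ")),
                class = "fmtgraft_collinear_donor")
    levels(df$.donor)[levels(df$.donor) %in% bad] <- levels(df$.donor)[1]
    fit <- stats::lm(.y ~ .x + .donor, data = df)
    cf <- stats::coef(fit)
  }
  xterms <- grep("^\\.x", names(cf), value = TRUE)
  if (any(is.na(cf[xterms]))) {
    abort_validation("predictor is collinear with the donor design")
  }
  if (is.numeric(df$.x)) {
    sm <- summary(fit)$coefficients
    assoc_row("donor_adjusted_ols", sm[".x", "Estimate"], sm[".x", "t value"],
              sm[".x", "Pr(>|t|)"], nrow(df), donor_adjusted = TRUE)
  } else {
    an <- stats::anova(stats::lm(.y ~ .donor, data = df), fit)
    est <- unname(cf[xterms][1])
    assoc_row("donor_adjusted_ols", est, an$F[2], an$`Pr(>F)`[2], nrow(df),
              donor_adjusted = TRUE)
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} m * p_(j) / j`, returned in
#' the input order. Applied within one analysis family at a time.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    abort_validation("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
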