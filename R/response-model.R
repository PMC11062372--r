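#' Classify recipients as HOMA2-IR responders
#'
#' The trial's responder rule: a recipient whose HOMA2-IR fell from baseline
#' to week 6 (`delta < 0`) is a responder; a rise (`delta > 0`) is a
#' non-responder. A delta of exactly 0 is outside the rule and is flagged
#' unclassifiable and excluded with a warning, never silently assigned;
#' recipients with a missing delta are excluded and reported.
#'
#' @param data data frame with `subject_id` and the delta column.
#' @param delta name of the HOMA2-IR change column (follow-up minus
#'   baseline, see [paired_delta()]).
#' @return Tibble `subject_id`, `delta_homa2ir`, `label`; attribute
#'   `excluded` is a tibble of dropped subjects with reasons.
#' @export
classify_responders <- function(data, delta = "delta_homa2ir") {
  stopifnot(all(c("subject_id", delta) %in% names(data)))
  d <- data[[delta]]
  excluded <- tibble::tibble(subject_id = character(0), reason = character(0))
  if (anyNA(d)) {
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      subject_id = data$subject_id[is.na(d)], reason = "missing delta"))
  }
  zeros <- !is.na(d) & d == 0
  if (any(zeros)) {
    rlang::warn(paste("delta of exactly 0 is unclassifiable; excluded:",
                      paste(data$subject_id[zeros], collapse = ", ")),
                class = "fmtgraft_unclassifiable")
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      subject_id = data$subject_id[zeros], reason = "delta == 0"))
  }
  keep <- !is.na(d) & d != 0
  out <- tibble::tibble(
    subject_id = data$subject_id[keep],
    delta_homa2ir = d[keep],
    label = ifelse(d[keep] < 0, "responder", "non_responder"))
  attr(out, "excluded") <- excluded
  out
}

#' Baseline genus relative-abundance features
#'
#' Builds the recipients-by-genera feature table the response classifier is
#' trained on: per-sample relative abundances of each recipient's baseline
#' (week 0) sample, keeping genera detected in at least `min_prevalence`
#' recipients.
#'
#' @param genus_table a genus-level [feature_table()] (see
#'   [collapse_to_genus()]); raw or rarefied counts (proportions are taken).
#' @param metadata an [cohort_metadata()].
#' @param min_prevalence minimum number of recipients a genus must be
#'   detected in to enter the model (default 2).
#' @return Tibble with `subject_id` plus one numeric column per genus.
#' @export
baseline_genus_features <- function(genus_table, metadata, min_prevalence = 2) {
  stopifnot(inherits(genus_table, "fmt_feature_table"),
            inherits(metadata, "fmt_metadata"))
  recips <- eligible_recipients(metadata)
  samp <- vapply(recips, function(r) sample_at(metadata, r, 0L), character(1))
  keep <- !is.na(samp) & samp %in% sample_ids(genus_table)
  recips <- recips[keep]; samp <- samp[keep]
  if (length(recips) == 0) abort_validation("no recipient baseline samples found")
  m <- unclass(genus_table)[, samp, drop = FALSE]
  rel <- sweep(m, 2, colSums(m), "/")
  prevalent <- rowSums(rel > 0) >= min_prevalence
  rel <- t(rel[prevalent, , drop = FALSE])
  dplyr::bind_cols(tibble::tibble(subject_id = recips),
                   tibble::as_tibble(rel))
}

#' Random-forest response prediction with replicated LOOCV
#'
#' The prediction protocol: for each of `n_replicates` replicates (each on a
#' fresh RNG substream), every recipient is held out in turn, a random
#' forest is trained on the remaining n-1 with default settings (500 trees,
#' `sqrt(p)` candidate features per split, unlimited depth), and the
#' held-out responder probability is recorded; the n out-of-fold
#' probabilities are pooled into one ROC curve and its AUC. A full-data
#' forest per replicate supplies the out-of-bag error and variable
#' importances. Headline numbers are the mean and SD of the per-replicate
#' AUCs, the mean OOB error, and importances averaged over replicates (Gini
#' primary, permutation accuracy also kept); the AUC of all replicates'
#' predictions pooled together is emitted as `auc_pooled`. The accuracy
#' gate — mean AUC at least 0.7 and mean OOB error below 0.6 — marks a
#' classifier with usable prediction accuracy.
#'
#' @param features data frame: `subject_id` plus complete numeric feature
#'   columns (e.g. [baseline_genus_features()]).
#' @param labels tibble from [classify_responders()]; at least two
#'   recipients per class.
#' @param n_replicates number of LOOCV replicates (default 100).
#' @param seed integer seed; the full prediction matrix is reproducible
#'   bit-for-bit given the seed.
#' @param ntree,mtry forest hyperparameters; defaults follow the
#'   randomForest package defaults (`ntree = 500`, `mtry = sqrt(p)`).
#' @return An `fmt_rfc` object; see [tidy.fmt_rfc()] / [glance.fmt_rfc()].
#' @export
rfc_loocv <- function(features, labels, n_replicates = 100, seed = NULL,
                      ntree = 500, mtry = NULL) {
  stopifnot("subject_id" %in% names(features))
  df <- dplyr::inner_join(labels[, c("subject_id", "label")], features,
                          by = "subject_id")
  n <- nrow(df)
  y <- factor(df$label, levels = c("non_responder", "responder"))
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2) {
    abort_validation("need >= 2 recipients in each response class")
  }
  x <- as.data.frame(df[, setdiff(names(features), "subject_id")])
  if (anyNA(x)) abort_validation("features must be complete (no missing values)")
  zero_var <- vapply(x, function(col) stats::sd(col) == 0, logical(1))
  if (any(zero_var)) {
    rlang::warn(paste("zero-variance feature(s) retained:",
                      paste(names(x)[zero_var], collapse = ", ")),
                class = "fmtgraft_degenerate")
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))

  with_rng_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      set.seed(rep_seeds[r])
      prob <- vapply(seq_len(n), function(i) {
        fit <- randomForest::randomForest(
          x = x[-i, , drop = FALSE], y = y[-i],
          ntree = ntree, mtry = mtry)
        unname(stats::predict(fit, x[i, , drop = FALSE],
                              type = "prob")[, "responder"])
      }, numeric(1))
      roc <- pROC::roc(response = y, predictor = prob,
                       levels = c("non_responder", "responder"),
                       direction = "<", quiet = TRUE)
      full <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                         mtry = mtry, importance = TRUE)
      list(prob = prob,
           auc = as.numeric(pROC::auc(roc)),
           oob = unname(full$err.rate[ntree, "OOB"]),
           imp_gini = full$importance[, "MeanDecreaseGini"],
           imp_acc = full$importance[, "MeanDecreaseAccuracy"])
    })
    aucs <- vapply(reps, `[[`, numeric(1), "auc")
    probs <- vapply(reps, `[[`, numeric(n), "prob")
    if (n == 1) probs <- matrix(probs, nrow = 1)
    pooled <- pROC::roc(response = rep(as.character(y), n_replicates),
                        predictor = as.numeric(probs),
                        levels = c("non_responder", "responder"),
                        direction = "<", quiet = TRUE)
    imp <- tibble::tibble(
      feature = names(reps[[1]]$imp_gini),
      importance_gini = rowMeans(vapply(reps, `[[`, numeric(ncol(x)), "imp_gini")),
      importance_accuracy = rowMeans(vapply(reps, `[[`, numeric(ncol(x)), "imp_acc"))
    ) |>
      dplyr::arrange(dplyr::desc(.data$importance_gini))
    auc_mean <- mean(aucs)
    oob_mean <- mean(vapply(reps, `[[`, numeric(1), "oob"))
    structure(list(
      auc = aucs, auc_mean = auc_mean, auc_sd = stats::sd(aucs),
      auc_pooled = as.numeric(pROC::auc(pooled)),
      oob_error_mean = oob_mean,
      importance = imp,
      predictions = tibble::tibble(
        subject_id = rep(df$subject_id, n_replicates),
        label = rep(as.character(y), n_replicates),
        replicate = rep(seq_len(n_replicates), each = n),
        prob_responder = as.numeric(probs)),
      n_replicates = n_replicates, n_recipients = n,
      n_features = ncol(x), ntree = ntree, mtry = mtry, seed = seed,
      passes_gate = passes_prediction_gate(auc_mean, oob_mean)
    ), class = "fmt_rfc")
  })
}

# accuracy gate: mean AUC-ROC >= 0.7 and mean out-of-bag error < 0.6
passes_prediction_gate <- function(auc_mean, oob_error_mean) {
  auc_mean >= 0.7 && oob_error_mean < 0.6
}

#' @export
print.fmt_rfc <- function(x, ...) {
  cat(sprintf(
    "<fmt_rfc> %d replicates x LOOCV over %d recipients, %d features\n  mean AUC %.3f (sd %.3f), mean OOB error %.3f -> gate %s\n",
    x$n_replicates, x$n_recipients, x$n_features,
    x$auc_mean, x$auc_sd, x$oob_error_mean,
    if (x$passes_gate) "PASS" else "fail"))
  invisible(x)
}

#' Tidy and summarise a response-model fit
#'
#' `tidy()` returns the replicate-averaged importance ranking (Gini
#' primary); `glance()` the one-row performance summary with the accuracy
#' gate.
#'
#' @param x an `fmt_rfc` object from [rfc_loocv()].
#' @param ... unused.
#' @method tidy fmt_rfc
#' @export
tidy.fmt_rfc <- function(x, ...) {
  dplyr::mutate(x$importance, rank = dplyr::row_number())
}

#' @rdname tidy.fmt_rfc
#' @method glance fmt_rfc
#' @export
glance.fmt_rfc <- function(x, ...) {
  tibble::tibble(
    auc_mean = x$auc_mean, auc_sd = x$auc_sd, auc_pooled = x$auc_pooled,
    oob_error_mean = x$oob_error_mean, n_replicates = x$n_replicates,
    n_recipients = x$n_recipients, n_features = x$n_features,
    passes_gate = x$passes_gate)
}

#' Top predictive features with group-difference tests
#'
#' Ranks features by replicate-averaged Gini importance and, for each of the
#' top `k`, tests the feature between responders and non-responders with a
#' two-sided Wilcoxon rank-sum test, reporting the direction of difference.
#'
#' @param report an `fmt_rfc` object.
#' @param features,labels the inputs given to [rfc_loocv()].
#' @param k number of top features (default 10; truncated to the feature
#'   count).
#' @return Tibble: `feature`, `rank`, `importance_gini`, group medians,
#'   `direction`, `p_value`.
#' @export
rank_predictors <- function(report, features, labels, k = 10) {
  stopifnot(inherits(report, "fmt_rfc"))
  k <- min(k, nrow(report$importance))
  top <- report$importance[seq_len(k), ]
  df <- dplyr::inner_join(labels[, c("subject_id", "label")], features,
                          by = "subject_id")
  dplyr::bind_rows(purrr::imap(top$feature, function(f, i) {
    r <- df[[f]][df$label == "responder"]
    nr <- df[[f]][df$label == "non_responder"]
    wt <- wilcoxon_ranksum(r, nr)
    tibble::tibble(
      feature = f, rank = i,
      importance_gini = top$importance_gini[i],
      median_responder = stats::median(r),
      median_nonresponder = stats::median(nr),
      direction = dplyr::case_when(
        stats::median(r) > stats::median(nr) ~ "higher_in_responders",
        stats::median(r) < stats::median(nr) ~ "lower_in_responders",
        TRUE ~ "equal"),
      p_value = wt$p_value)
  }))
}
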