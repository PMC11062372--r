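# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers never perturb each other.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Rarefy a feature table to an even depth
#'
#' Subsamples every sample without replacement (multivariate hypergeometric)
#' to exactly `depth` reads; the study's even depth is 9518 reads per sample.
#' Samples shallower than `depth` are dropped and reported in the `dropped`
#' attribute rather than silently discarded. One draw is taken per sample;
#' the seed makes it reproducible.
#'
#' @param x an [feature_table()] object.
#' @param depth target depth (reads per sample).
#' @param seed integer seed for the subsampling draw.
#' @return An `fmt_feature_table` in which every retained sample sums to
#'   `depth`, with attribute `dropped` naming removed samples, `depth` and
#'   `seed` recording the draw.
#' @export
rarefy_counts <- function(x, depth = 9518, seed = NULL) {
  stopifnot(inherits(x, "fmt_feature_table"))
  if (length(depth) != 1 || depth < 1) abort_validation("depth must be >= 1")
  depths <- sample_depths(x)
  keep <- names(depths)[depths >= depth]
  dropped <- setdiff(names(depths), keep)
  if (length(keep) == 0) {
    abort_validation(sprintf("all %d samples are below depth %d", ncol(x), depth))
  }
  m <- unclass(x)[, keep, drop = FALSE]
  # rrarefy's "observed counts" heuristic warns whenever no count equals 1;
  # our inputs are genuine counts, so the warning is noise
  rar <- with_rng_seed(seed, suppressWarnings(
    t(vegan::rrarefy(t(m), sample = depth))))
  out <- feature_table(rar)
  attr(out, "dropped") <- dropped
  attr(out, "depth") <- as.integer(depth)
  attr(out, "seed") <- seed
  out
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))`, where `f1`
#' and `f2` are the numbers of singleton and doubleton taxa. The correction
#' keeps the estimator finite when no doubletons are observed; with no
#' singletons it collapses to the observed richness. Meaningful across
#' samples only after rarefaction to an even depth.
#'
#' @param counts non-negative integer vector of taxon counts for one sample.
#' @return Chao1 estimate (always `>=` observed richness).
#' @examples
#' chao1(c(2, 2, 1, 1, 1)) # 5 + 3*2/(2*3) = 6
#' @export
chao1 <- function(counts) {
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort_validation("counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort_validation("all-zero sample: Chao1 undefined")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity table
#'
#' @param x an `fmt_feature_table`, normally already rarefied with
#'   [rarefy_counts()].
#' @return Tibble with `sample_id`, `observed_richness`, `chao1` and a
#'   `rarefied` flag recording whether `x` carries a rarefaction depth.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "fmt_feature_table"))
  m <- unclass(x)
  tibble::tibble(
    sample_id = colnames(m),
    observed_richness = apply(m, 2, function(v) sum(v > 0)),
    chao1 = apply(m, 2, chao1),
    rarefied = !is.null(attr(x, "depth"))
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` between sample count
#' profiles; compute on rarefied counts so depths are even (at even depth,
#' counts and relative abundances give identical distances).
#'
#' @param x an `fmt_feature_table` with at least two samples.
#' @return A `dist` object labelled by sample id, values in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "fmt_feature_table"))
  if (ncol(x) < 2) abort_validation("Bray-Curtis needs >= 2 samples")
  depths <- sample_depths(x)
  if (any(depths == 0)) {
    abort_validation(paste("all-zero sample(s), distance undefined:",
                           paste(names(depths)[depths == 0], collapse = ", ")))
  }
  vegan::vegdist(t(unclass(x)), method = "bray")
}

#' Paired change scores (follow-up minus baseline)
#'
#' The change convention used throughout: `delta = followup - baseline`, so a
#' recipient whose HOMA2-IR fell by week 6 has a negative delta (a
#' responder), and a richness gain is positive. Subjects missing either
#' timepoint are excluded and reported in the `excluded` attribute.
#'
#' @param data tibble with columns `subject_id`, `timepoint_weeks` and the
#'   value column named by `value`.
#' @param value name of the value column.
#' @param baseline_week,followup_week the two visits to difference.
#' @return Tibble `subject_id`, `baseline`, `followup`, `delta`; attribute
#'   `excluded` lists subjects lacking a visit.
#' @export
paired_delta <- function(data, value, baseline_week = 0, followup_week = 6) {
  stopifnot(all(c("subject_id", "timepoint_weeks", value) %in% names(data)))
  wide <- data |>
    dplyr::filter(.data$timepoint_weeks %in% c(baseline_week, followup_week)) |>
    dplyr::mutate(.visit = ifelse(.data$timepoint_weeks == baseline_week,
                                  "baseline", "followup")) |>
    dplyr::select("subject_id", ".visit", value = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = ".visit", values_from = "value")
  if (!"baseline" %in% names(wide)) wide$baseline <- NA_real_
  if (!"followup" %in% names(wide)) wide$followup <- NA_real_
  complete <- !is.na(wide$baseline) & !is.na(wide$followup)
  out <- wide |>
    dplyr::filter(complete) |>
    dplyr::mutate(delta = .data$followup - .data$baseline)
  attr(out, "excluded") <- wide$subject_id[!complete]
  out
}
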