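#' Principal coordinates analysis (metric MDS)
#'
#' Classical PCoA of a dissimilarity matrix: Gower double-centring of
#' `-d^2 / 2`, symmetric eigendecomposition, and scores equal to
#' eigenvectors scaled by the square root of their eigenvalues, with equal
#' sample weights (metric MDS with uniform weights). Axes are ordered by
#' eigenvalue; axes with negative eigenvalues (possible for semi-metric
#' dissimilarities such as Bray-Curtis) carry no scores — their total
#' magnitude is reported as `negative_mass` instead of being corrected
#' (no Lingoes/Cailliez adjustment). Axis signs are fixed deterministically
#' (largest-magnitude loading positive).
#'
#' @param d a `dist` object or symmetric matrix of dissimilarities with
#'   sample labels.
#' @param n_axes number of axes to return; truncated (with a warning) to the
#'   number of positive eigenvalues.
#' @return An `fmt_pcoa` object: list with `scores` (samples x axes,
#'   columns `PCo1`, `PCo2`, ...), `eigenvalues` (all, descending),
#'   `proportion_explained` (per positive axis, of the positive total),
#'   `negative_mass`, and `sample_ids`.
#' @export
pcoa <- function(d, n_axes = 2) {
  dm <- as.matrix(d)
  if (nrow(dm) < 2 || !isTRUE(all.equal(dm, t(dm))) || any(diag(dm) != 0)) {
    abort_validation("d must be a symmetric dissimilarity matrix with zero diagonal")
  }
  if (n_axes < 1) abort_validation("n_axes must be >= 1")
  ids <- rownames(dm) %||% paste0("sample", seq_len(nrow(dm)))
  n <- nrow(dm)
  a <- -0.5 * dm^2
  # Gower centring: (I - 11'/n) A (I - 11'/n)
  g <- sweep(a, 1, rowMeans(a))
  g <- sweep(g, 2, colMeans(g))
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- which(e$values > tol)
  neg_mass <- sum(abs(e$values[e$values < -tol]))
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    rlang::warn(sprintf("only %d positive eigenvalue(s); axes truncated from %d",
                        length(pos), n_axes))
  }
  scores <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), nrow = k)
  # deterministic sign: largest-magnitude loading positive on each axis
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(ids, paste0("PCo", seq_len(k)))
  structure(list(
    scores = scores,
    eigenvalues = e$values,
    proportion_explained = e$values[pos] / sum(e$values[pos]),
    negative_mass = neg_mass,
    sample_ids = ids
  ), class = "fmt_pcoa")
}

#' @export
print.fmt_pcoa <- function(x, ...) {
  cat(sprintf("<fmt_pcoa> %d samples, %d axes; first axes explain %s; negative mass %.3g\n",
              length(x$sample_ids), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained,
                                                        ncol(x$scores))),
                    collapse = ", "),
              x$negative_mass))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy fmt_pcoa
#' @export
tidy.fmt_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids),
                   tibble::as_tibble(x$scores))
}

#' @method glance fmt_pcoa
#' @export
glance.fmt_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$sample_ids),
    n_axes = ncol(x$scores),
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (length(x$proportion_explained) > 1) x$proportion_explained[2] else NA_real_,
    negative_mass = x$negative_mass
  )
}

env_vector_r2 <- function(v, scores) {
  vc <- v - mean(v)
  ss_tot <- sum(vc^2)
  fit <- stats::lm.fit(scores, vc)
  list(r2 = 1 - sum(fit$residuals^2) / ss_tot, coef = fit$coefficients)
}

#' Fit environmental vectors onto an ordination
#'
#' For each continuous variable, regresses the (centred) variable on the
#' first `axes` PCoA score columns by least squares; `r2` is the squared
#' multiple correlation with the ordination plane and the direction is the
#' unit coefficient vector (the arrow of maximal correlation, as drawn on
#' envfit biplots). Significance is a permutation test: variable values are
#' permuted across samples and `p = (1 + #{r2_perm >= r2_obs}) / (1 +
#' n_perm)`, so the smallest attainable p at 999 permutations is 0.001.
#' Samples with a missing value are excluded variable-wise (and counted in
#' `n_used`); a constant variable is flagged with `r2 = 0`, `p = 1`.
#'
#' @param ord an [pcoa()] result.
#' @param data data frame with a `sample_id` column and numeric baseline
#'   variables; rows are matched to the ordination samples.
#' @param axes number of leading axes to fit against (default 2, the plane
#'   of the biplot).
#' @param permutations either a single integer (number of random
#'   permutations, default 999) or an integer matrix whose rows are explicit
#'   permutations of `1:n_used` (e.g. a full enumeration for small n).
#' @param seed integer seed for the permutation stream.
#' @param standardize z-score each variable first (does not change `r2` or
#'   `p`, only the recorded effect scale).
#' @return An `fmt_envfit` tibble: `variable`, `r2`, direction columns
#'   (`axis_1`, `axis_2`, ...), `p_value`, `n_perm`, `n_used`, `flagged`.
#' @export
fit_env_vectors <- function(ord, data, axes = 2, permutations = 999,
                            seed = NULL, standardize = FALSE) {
  stopifnot(inherits(ord, "fmt_pcoa"))
  if (!"sample_id" %in% names(data)) {
    abort_format("envfit data requires a 'sample_id' column")
  }
  if (axes > ncol(ord$scores)) {
    abort_validation("axes exceeds the ordination's available axes")
  }
  idx <- match(ord$sample_ids, data$sample_id)
  if (anyNA(idx)) {
    abort_linkage(paste("variables missing for sample(s):",
                        paste(ord$sample_ids[is.na(idx)], collapse = ", ")))
  }
  vars <- setdiff(names(data), "sample_id")
  vars <- vars[vapply(data[vars], is.numeric, logical(1))]
  if (length(vars) == 0) abort_validation("no numeric variables to fit")
  x_full <- ord$scores[, seq_len(axes), drop = FALSE]
  perm_given <- is.matrix(permutations)
  n_perm <- if (perm_given) nrow(permutations) else as.integer(permutations)
  if (n_perm < 1) abort_validation("need >= 1 permutation")

  with_rng_seed(seed, {
    rows <- purrr::map(vars, function(vn) {
      v <- data[[vn]][idx]
      keep <- !is.na(v)
      v <- v[keep]
      n_used <- length(v)
      if (n_used < axes + 2 || stats::sd(v) == 0) {
        dir <- stats::setNames(rep(NA_real_, axes), paste0("axis_", seq_len(axes)))
        return(dplyr::bind_cols(
          tibble::tibble(variable = vn, r2 = 0),
          tibble::as_tibble(as.list(dir)),
          tibble::tibble(p_value = 1, n_perm = n_perm,
                         n_used = n_used, flagged = TRUE)))
      }
      if (standardize) v <- as.numeric(scale(v))
      xs <- scale(x_full[keep, , drop = FALSE], center = TRUE, scale = FALSE)
      obs <- env_vector_r2(v, xs)
      direction <- obs$coef / sqrt(sum(obs$coef^2))
      perm_r2 <- if (perm_given) {
        apply(permutations, 1, function(p) env_vector_r2(v[p], xs)$r2)
      } else {
        vapply(seq_len(n_perm),
               function(i) env_vector_r2(sample(v), xs)$r2, numeric(1))
      }
      p_val <- (1 + sum(perm_r2 >= obs$r2 - 1e-12)) / (1 + n_perm)
      dir <- stats::setNames(as.numeric(direction), paste0("axis_", seq_len(axes)))
      dplyr::bind_cols(
        tibble::tibble(variable = vn, r2 = obs$r2),
        tibble::as_tibble(as.list(dir)),
        tibble::tibble(p_value = p_val, n_perm = n_perm,
                       n_used = n_used, flagged = FALSE))
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "axes") <- axes
    attr(out, "seed") <- seed
    class(out) <- c("fmt_envfit", class(out))
    out
  })
}
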