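#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the study's stated
#' defaults: rarefaction at 9518 reads, presence threshold of 1 rarefied
#' read, per-timepoint selection at alpha = 0.05, 999 permutations for
#' envfit, 100 LOOCV replicates for the response model, top-10 predictor
#' ranking. Each stochastic stage gets its own named seed, derived from one
#' global seed by fixed offsets, so any stage can be re-run in isolation.
#'
#' @param simulate an [cohort_config()] to generate inputs, or `NULL` to
#'   read them from files.
#' @param feature_table_path,metadata_path,covariates_path,taxonomy_path
#'   input TSVs (used when `simulate` is NULL; taxonomy optional).
#' @param rarefaction_depth,min_count,alpha,n_permutations,rfc_replicates,top_k,min_prevalence
#'   analysis parameters (see the stage functions).
#' @param seed global seed expanded into per-stage seeds (`simulate` +0,
#'   `rarefy` +1, `envfit` +2, `rfc` +3).
#' @param out_dir optional directory; when set, every stage table is written
#'   as TSV alongside a JSON summary and a run manifest.
#' @return An `fmt_pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_config(),
                            feature_table_path = NULL, metadata_path = NULL,
                            covariates_path = NULL, taxonomy_path = NULL,
                            rarefaction_depth = 9518, min_count = 1,
                            alpha = 0.05, n_permutations = 999,
                            rfc_replicates = 100, top_k = 10,
                            min_prevalence = 2, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(simulate) &&
      (is.null(feature_table_path) || is.null(metadata_path))) {
    abort_validation("either a simulate block or input paths are required")
  }
  if (n_permutations < 1) abort_validation("n_permutations must be >= 1")
  if (rfc_replicates < 1) abort_validation("rfc_replicates must be >= 1")
  if (rarefaction_depth < 1) abort_validation("rarefaction_depth must be >= 1")
  if (min_count < 1) abort_validation("min_count must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort_validation("alpha must lie in (0, 1)")
  cfg$seeds <- list(simulate = seed, rarefy = seed + 1L,
                    envfit = seed + 2L, rfc = seed + 3L)
  structure(cfg, class = "fmt_pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 class = "fmtgraft_stage_error", parent = e)
  })
}

#' Week-6 engrafted donor-specific ASV community
#'
#' Builds the recipients-by-ASV count matrix ordination works on: for each
#' recipient with a week-`week` sample, the rarefied counts of the ASVs
#' that are donor-specific *for that recipient* (its own donor's baseline
#' minus its own baseline) and detected at that visit; all other cells are
#' zero. Recipients with nothing engrafted are excluded (distance to an
#' empty profile is undefined) and reported in the `excluded` attribute.
#'
#' @param rarefied a rarefied [feature_table()].
#' @param presence the matching [call_presence()] object.
#' @param metadata an [cohort_metadata()].
#' @param week visit to evaluate (default 6).
#' @return An `fmt_feature_table` with recipients as "samples" (columns
#'   named by subject id).
#' @export
engrafted_community <- function(rarefied, presence, metadata, week = 6) {
  s <- metadata$samples
  avail <- colnames(presence)
  cols <- list()
  for (rid in eligible_recipients(metadata)) {
    donor_id <- unique(s$donor_id[s$subject_id == rid & s$role == "recipient"])
    dsamp <- intersect(donor_samples_of(metadata, donor_id), avail)
    bsamp <- sample_at(metadata, rid, 0L)
    fsamp <- sample_at(metadata, rid, as.integer(week))
    if (length(dsamp) == 0 || is.na(bsamp) || is.na(fsamp) ||
        !all(c(bsamp, fsamp) %in% avail)) next
    donor_p <- presence_of(presence, dsamp)
    base_p <- unclass(presence)[, bsamp]
    fol_p <- unclass(presence)[, fsamp]
    ds_present <- names(donor_p)[donor_p & !base_p & fol_p]
    v <- stats::setNames(integer(nrow(presence)), rownames(presence))
    v[ds_present] <- unclass(rarefied)[ds_present, fsamp]
    cols[[rid]] <- v
  }
  if (length(cols) == 0) abort_validation("no recipients with engrafted community")
  m <- do.call(cbind, cols)
  nonzero <- colSums(m) > 0
  excluded <- colnames(m)[!nonzero]
  out <- feature_table(m[, nonzero, drop = FALSE])
  attr(out, "excluded") <- excluded
  out
}

#' Run the full engraftment-and-response analysis
#'
#' Executes, in order: input (read or simulate), rarefaction, alpha
#' diversity and change scores, responder classification, engraftment
#' partitioning and rates, responder-enriched ASV selection, removed-ASV
#' screening, Bray-Curtis ordination of the week-6 engrafted donor-specific
#' community with environmental vector fitting of baseline factors, the
#' replicated LOOCV random-forest response model on baseline genus
#' composition, and the univariate association family (baseline richness
#' and covariates vs diversity change, donor-adjusted group contrast) with
#' Benjamini-Hochberg correction. Any stage failure aborts naming the
#' stage; tables written so far are preserved. Identical configurations
#' produce byte-identical outputs.
#'
#' @param config an [pipeline_config()].
#' @return An `fmt_pipeline` list of stage results (see names of the
#'   returned list), including a `manifest` with config hash and seeds.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fmt_pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, x) {
    if (!is.null(out_dir) && is.data.frame(x)) {
      readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
    x
  }

  inputs <- run_stage("input", {
    if (!is.null(config$simulate)) {
      simulate_cohort(config$simulate, seed = config$seeds$simulate)
    } else {
      list(table = read_feature_table(config$feature_table_path),
           metadata = read_metadata(config$metadata_path,
                                    config$covariates_path),
           taxonomy = if (!is.null(config$taxonomy_path)) {
             read_taxonomy(config$taxonomy_path)
           },
           truth = NULL)
    }
  })
  table <- inputs$table
  metadata <- inputs$metadata

  rarefied <- run_stage("rarefy", {
    rarefy_counts(table, depth = config$rarefaction_depth,
                  seed = config$seeds$rarefy)
  })
  diversity <- run_stage("diversity", {
    ad <- alpha_diversity(rarefied)
    emit("alpha_diversity",
         dplyr::left_join(ad, metadata$samples, by = "sample_id"))
  })
  deltas <- run_stage("diversity_delta", {
    rec_div <- dplyr::inner_join(
      diversity, metadata$samples[metadata$samples$role == "recipient", ],
      by = intersect(names(diversity), names(metadata$samples)))
    emit("chao1_delta", paired_delta(rec_div, "chao1"))
  })
  labels <- run_stage("responders", {
    if (is.null(metadata$subjects) ||
        !"delta_homa2ir" %in% names(metadata$subjects)) {
      abort_validation("metadata$subjects must provide delta_homa2ir")
    }
    emit("responder_labels", classify_responders(metadata$subjects))
  })
  presence <- run_stage("presence", call_presence(rarefied, config$min_count))
  partitions <- run_stage("engraftment_partitions", {
    emit("engraftment_partitions", engraftment_partitions(presence, metadata))
  })
  rates <- run_stage("engraftment_rates", {
    emit("engraftment_rates", engraftment_rates(presence, metadata, labels))
  })
  engrafters <- run_stage("differential_engrafters", {
    emit("differential_engrafters",
         differential_engrafters(presence, metadata, labels,
                                 alpha = config$alpha))
  })
  removed <- run_stage("removed_asvs", {
    emit("removed_asvs", removed_asvs(presence, metadata, labels))
  })

  ordination <- run_stage("ordination", {
    comm <- engrafted_community(rarefied, presence, metadata, week = 6)
    ord <- pcoa(bray_curtis(comm), n_axes = 2)
    baseline_factors <- baseline_factor_table(metadata, diversity)
    env <- fit_env_vectors(
      ord, dplyr::rename(baseline_factors, sample_id = "subject_id"),
      axes = 2, permutations = config$n_permutations,
      seed = config$seeds$envfit)
    emit("pcoa_scores", tidy(ord))
    emit("envfit", tibble::as_tibble(env))
    list(community = comm, pcoa = ord, envfit = env)
  })

  response <- run_stage("response_model", {
    genus_tab <- if (!is.null(inputs$taxonomy)) {
      collapse_to_genus(table, inputs$taxonomy)
    } else {
      table
    }
    features <- baseline_genus_features(genus_tab, metadata,
                                        min_prevalence = config$min_prevalence)
    report <- rfc_loocv(features, labels,
                        n_replicates = config$rfc_replicates,
                        seed = config$seeds$rfc)
    top <- rank_predictors(report, features, labels, k = config$top_k)
    emit("rfc_importance", tidy(report))
    emit("rfc_predictions", report$predictions)
    emit("top_predictors", top)
    list(features = features, report = report, top_predictors = top)
  })

  associations <- run_stage("associations", {
    df <- dplyr::inner_join(
      deltas, metadata$subjects, by = "subject_id") |>
      dplyr::inner_join(labels[, c("subject_id", "label")], by = "subject_id") |>
      dplyr::inner_join(
        dplyr::distinct(metadata$samples[metadata$samples$role == "recipient",
                                         c("subject_id", "donor_id")]),
        by = "subject_id")
    fam <- dplyr::bind_rows(
      dplyr::mutate(spearman_cor(df$baseline, df$delta),
                    variable = "baseline_chao1", .before = 1),
      purrr::map_dfr(
        setdiff(names(metadata$subjects), c("subject_id", "delta_homa2ir")),
        function(v) dplyr::mutate(spearman_cor(df[[v]], df$delta),
                                  variable = v, .before = 1)),
      dplyr::mutate(
        donor_adjusted_assoc(dplyr::mutate(df, label = factor(.data$label)),
                             "delta", "label"),
        variable = "response_group", .before = 1))
    fam$q_value <- {
      q <- rep(NA_real_, nrow(fam))
      ok <- !is.na(fam$p_value)
      q[ok] <- bh_fdr(fam$p_value[ok])
      q
    }
    emit("diversity_associations", fam)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fmtgraft")),
    seeds = config$seeds,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    parameters = config[c("rarefaction_depth", "min_count", "alpha",
                          "n_permutations", "rfc_replicates", "top_k",
                          "min_prevalence")])
  result <- structure(list(
    inputs = inputs, rarefied = rarefied, diversity = diversity,
    chao1_delta = deltas, labels = labels, partitions = partitions,
    rates = rates, engrafters = engrafters, removed = removed,
    ordination = ordination, response = response,
    associations = associations, manifest = manifest, config = config
  ), class = "fmt_pipeline")

  if (!is.null(out_dir)) {
    summary <- list(
      n_recipients = nrow(labels),
      n_responders = sum(labels$label == "responder"),
      n_selected_engrafters = length(attr(engrafters, "selected")),
      auc_mean = response$report$auc_mean,
      oob_error_mean = response$report$oob_error_mean,
      passes_gate = response$report$passes_gate,
      top_envfit_r2 = max(ordination$envfit$r2))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

# per-recipient baseline factor table for envfit: covariates + baseline chao1
baseline_factor_table <- function(metadata, diversity) {
  s <- metadata$samples
  base <- s[s$role == "recipient" & s$timepoint_weeks == 0L,
            c("sample_id", "subject_id")]
  chao <- dplyr::inner_join(base, diversity[, c("sample_id", "chao1")],
                            by = "sample_id")
  out <- tibble::tibble(subject_id = chao$subject_id,
                        baseline_chao1 = chao$chao1)
  if (!is.null(metadata$subjects)) {
    cov <- metadata$subjects[, setdiff(names(metadata$subjects),
                                       "delta_homa2ir"), drop = FALSE]
    out <- dplyr::left_join(out, cov, by = "subject_id")
  }
  out
}

#' @export
print.fmt_pipeline <- function(x, ...) {
  cat(sprintf(
    "<fmt_pipeline> %d recipients (%d responders); %d ASVs selected; mean AUC %.3f; top envfit R2 %.3f\n",
    nrow(x$labels), sum(x$labels$label == "responder"),
    length(attr(x$engrafters, "selected")),
    x$response$report$auc_mean, max(x$ordination$envfit$r2)))
  invisible(x)
}
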