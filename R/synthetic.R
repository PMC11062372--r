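#' Configuration for the synthetic FMT cohort generator
#'
#' Defaults emulate the study design the analysis targets: 4 stool donors,
#' 29 recipients of whom 21 respond (HOMA2-IR fell by week 6), visits at
#' weeks 0/2/6/12, an ASV universe of 300 with 30 donor-specific ASVs per
#' donor, engraftment probabilities of 0.6 (responders) vs 0.2
#' (non-responders) per donor-specific ASV, memoryless per-visit loss of
#' 0.1, sequencing depth Poisson around 20000 with rarefaction at 9518, and
#' a net diversity response whose Spearman coupling to baseline richness is
#' -0.75. The engraftment probabilities are effect sizes chosen for
#' testability (the study reports significance, not rates); everything else
#' follows the study's stated quantities.
#'
#' @param n_donors,n_recipients,n_responders cohort sizes.
#' @param n_asvs_global size of the ASV universe.
#' @param donor_specific_per_pair exclusive ASVs per donor (absent from all
#'   recipient baselines by construction).
#' @param p_engraft_responder,p_engraft_nonresponder per-ASV colonization
#'   probability at week 2 by response group.
#' @param p_loss_per_visit probability an established ASV (baseline or
#'   engrafted) is lost at each subsequent visit.
#' @param depth_mean mean sequencing depth (Poisson).
#' @param rarefaction_depth even depth downstream rarefaction will use.
#' @param covariate_effect coupling of the standardized soluble-fiber intake
#'   to the engraftment logit.
#' @param diversity_coupling target Spearman correlation (in `[-1, 0]`)
#'   between true baseline richness and the net richness change by week 6.
#' @param marker_effect multiplier on responders' baseline abundance of the
#'   marker genus (the planted discriminative predictor; < 1 means depleted
#'   in responders).
#' @param seed default seed used by [simulate_cohort()].
#' @return An `fmt_cohort_config` list.
#' @export
cohort_config <- function(n_donors = 4, n_recipients = 29, n_responders = 21,
                          n_asvs_global = 300, donor_specific_per_pair = 30,
                          p_engraft_responder = 0.6,
                          p_engraft_nonresponder = 0.2,
                          p_loss_per_visit = 0.1,
                          depth_mean = 20000, rarefaction_depth = 9518,
                          covariate_effect = 0.8,
                          diversity_coupling = -0.75,
                          marker_effect = 0.35,
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_engraft_responder, p_engraft_nonresponder, p_loss_per_visit)
  if (any(probs < 0 | probs > 1)) abort_validation("probabilities must lie in [0, 1]")
  if (n_responders > n_recipients) {
    abort_validation("n_responders cannot exceed n_recipients")
  }
  if (donor_specific_per_pair * n_donors >= n_asvs_global) {
    abort_validation("donor-specific pools exhaust the ASV universe; increase n_asvs_global")
  }
  if (depth_mean < rarefaction_depth) {
    abort_validation("depth_mean must be >= rarefaction_depth")
  }
  if (diversity_coupling < -1 || diversity_coupling > 0) {
    abort_validation("diversity_coupling must lie in [-1, 0]")
  }
  structure(cfg, class = "fmt_cohort_config")
}

# Pearson correlation of the latent Gaussians that induces a target
# Spearman correlation in a bivariate normal pair.
latent_pearson <- function(rho_s) 2 * sin(rho_s * pi / 6)

#' Simulate a donor/recipient FMT cohort with known ground truth
#'
#' Two layers are generated separately so detection limits can be studied:
#' a biological "colonization state" (which ASVs truly live in which subject
#' at each visit) and a sequencing layer (multinomial reads at Poisson
#' depth over log-normal abundance weights). Donor communities draw from a
#' donor-exclusive pool plus a shared common pool; each recipient's baseline
#' is built from the common pool only, so its donor's exclusive ASVs are
#' donor-specific by construction. At week 2 each donor-specific ASV
#' colonizes its recipient with the group's engraftment probability,
#' shifted on the logit scale by `covariate_effect` times the standardized
#' soluble-fiber intake; established ASVs are lost memorylessly at each
#' later visit. The net week-6 richness change is planted with Spearman
#' coupling `diversity_coupling` to baseline richness, realized by adding
#' newly gained common-pool ASVs on top of the engraftment and loss
#' processes. Responders' HOMA2-IR change is drawn negative
#' (`-|N(0.5, 0.2)|`), non-responders' positive; responders' baseline
#' abundance of a designated marker genus is multiplied by `marker_effect`.
#' Clinical covariates (cholesterol, LDL, sugars, carbohydrates higher in
#' non-responders; tauro-muricholic acid negatively coupled to the
#' diversity response) give the ordination and association stages realistic
#' targets.
#'
#' @param config an [cohort_config()].
#' @param seed integer seed; the full output is bit-identical given the
#'   seed (defaults to `config$seed`).
#' @return List with `table` (an [feature_table()]), `metadata` (an
#'   [cohort_metadata()] whose subject table carries `delta_homa2ir` and the
#'   covariates), `taxonomy` (ASV to genus tibble), and `truth` (list:
#'   `recipients`, per-visit `engraftment` flags, `donor_pools`,
#'   `marker_genus`, `config`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "fmt_cohort_config"))
  cf <- config
  with_rng_seed(seed, {
    n_asv <- cf$n_asvs_global
    asvs <- sprintf("ASV%03d", seq_len(n_asv))
    donors <- sprintf("D%d", seq_len(cf$n_donors))
    recips <- sprintf("R%02d", seq_len(cf$n_recipients))
    weeks_post <- c(2L, 6L, 12L)

    # pools: donor-exclusive blocks first, common pool after
    pool_of <- rep(NA_character_, n_asv)
    for (d in seq_len(cf$n_donors)) {
      idx <- ((d - 1) * cf$donor_specific_per_pair + 1):(d * cf$donor_specific_per_pair)
      pool_of[idx] <- donors[d]
    }
    common <- asvs[is.na(pool_of)]

    # taxonomy: consecutive blocks of 5 ASVs per genus; the marker genus is
    # the first genus fully inside the common pool
    genus <- sprintf("genus_%03d", ceiling(seq_len(n_asv) / 5))
    taxonomy <- tibble::tibble(asv_id = asvs, kingdom = "Bacteria",
                               genus = genus)
    marker_genus <- genus[match(common[1], asvs)]
    marker_asvs <- asvs[genus == marker_genus]
    marker_asvs <- intersect(marker_asvs, common)

    # donor communities: own pool + ~60% of the common pool
    donor_present <- lapply(seq_len(cf$n_donors), function(d) {
      own <- asvs[which(pool_of == donors[d])]
      c(own, common[stats::runif(length(common)) < 0.6])
    })
    names(donor_present) <- donors
    donor_weights <- lapply(donor_present, function(p) {
      stats::setNames(stats::rlnorm(length(p), 0, 1), p)
    })

    # recipients: pairing, response, covariates, baseline communities
    donor_id <- donors[(seq_len(cf$n_recipients) - 1) %% cf$n_donors + 1]
    responder <- seq_len(cf$n_recipients) %in%
      sample(cf$n_recipients, cf$n_responders)
    delta_homa2ir <- ifelse(responder, -1, 1) *
      abs(stats::rnorm(cf$n_recipients, 0.5, 0.2))
    z_fiber <- stats::rnorm(cf$n_recipients)
    soluble_fiber_g <- 15 + 5 * z_fiber
    z_b <- stats::rnorm(cf$n_recipients)
    rho <- latent_pearson(cf$diversity_coupling)
    z_g <- rho * z_b + sqrt(1 - rho^2) * stats::rnorm(cf$n_recipients)
    rho_t <- latent_pearson(-0.46)
    tmca_umol <- 5 + 1.5 * (rho_t * z_g +
                              sqrt(1 - rho_t^2) * stats::rnorm(cf$n_recipients))
    nonresp <- as.numeric(!responder)
    cholesterol_mmol <- 5 + 0.8 * nonresp + stats::rnorm(cf$n_recipients, 0, 0.7)
    ldl_mmol <- 3 + 0.6 * nonresp + stats::rnorm(cf$n_recipients, 0, 0.5)
    sugars_g <- 90 + 25 * nonresp + stats::rnorm(cf$n_recipients, 0, 20)
    carbohydrates_g <- 250 + 40 * nonresp + stats::rnorm(cf$n_recipients, 0, 35)

    b_max <- length(common) - 10
    base_rich <- pmin(pmax(round(90 + 15 * z_b), 30), b_max)
    net_target <- round(25 + 10 * z_g)

    p_logit <- stats::qlogis(ifelse(responder, cf$p_engraft_responder,
                                    cf$p_engraft_nonresponder)) +
      cf$covariate_effect * z_fiber
    p_engraft <- stats::plogis(p_logit)
    survive <- 1 - cf$p_loss_per_visit

    sample_rows <- list(); truth_eng <- list(); truth_rec <- list()
    profiles <- list()  # per sample: named weight vectors

    add_sample <- function(sid, subject, role, donor, week, weights) {
      sample_rows[[length(sample_rows) + 1]] <<- tibble::tibble(
        sample_id = sid, subject_id = subject, role = role,
        donor_id = donor, timepoint_weeks = week)
      profiles[[sid]] <<- weights
    }

    for (d in seq_len(cf$n_donors)) {
      add_sample(paste0(donors[d], "_wk0"), donors[d], "donor",
                 NA_character_, 0L, donor_weights[[d]])
    }

    for (i in seq_len(cf$n_recipients)) {
      rid <- recips[i]
      own_pool <- asvs[which(pool_of == donor_id[i])]
      # baseline: marker genus forced in, remainder sampled from common pool
      others <- sample(setdiff(common, marker_asvs),
                       max(0, base_rich[i] - length(marker_asvs)))
      baseline_set <- c(marker_asvs, others)
      w_base <- stats::setNames(stats::rlnorm(length(baseline_set), 0, 1),
                                baseline_set)
      if (responder[i]) {
        w_base[marker_asvs] <- w_base[marker_asvs] * cf$marker_effect
      }
      add_sample(paste0(rid, "_wk0"), rid, "recipient", donor_id[i], 0L, w_base)

      # colonization states
      eng_wk2 <- stats::runif(length(own_pool)) < p_engraft[i]
      eng_wk6 <- eng_wk2 & stats::runif(length(own_pool)) < survive
      eng_wk12 <- eng_wk6 & stats::runif(length(own_pool)) < survive
      eng <- cbind(`2` = eng_wk2, `6` = eng_wk6, `12` = eng_wk12)
      keep_wk2 <- stats::runif(length(baseline_set)) < survive
      keep_wk6 <- keep_wk2 & stats::runif(length(baseline_set)) < survive
      keep_wk12 <- keep_wk6 & stats::runif(length(baseline_set)) < survive
      keep <- cbind(`2` = keep_wk2, `6` = keep_wk6, `12` = keep_wk12)

      n_lost6 <- sum(!keep_wk6)
      n_eng6 <- sum(eng_wk6)
      avail <- setdiff(common, baseline_set)
      n_gain <- min(max(net_target[i] - n_eng6 + n_lost6, 0), length(avail))
      gained_set <- sample(avail, n_gain)
      w_eng <- stats::setNames(stats::rlnorm(length(own_pool), 0, 1), own_pool)
      w_gain <- stats::setNames(stats::rlnorm(n_gain, 0, 1), gained_set)

      for (t in weeks_post) {
        tn <- as.character(t)
        present <- c(w_base[keep[, tn]], w_eng[eng[, tn]], w_gain)
        jitter <- exp(stats::rnorm(length(present), 0, 0.3))
        add_sample(paste0(rid, "_wk", t), rid, "recipient", donor_id[i],
                   t, present * jitter)
      }
      truth_eng[[i]] <- tibble::tibble(
        subject_id = rid,
        asv_id = rep(own_pool, times = 3),
        timepoint_weeks = rep(weeks_post, each = length(own_pool)),
        engrafted = c(eng_wk2, eng_wk6, eng_wk12),
        p_engraft = p_engraft[i])
      is_resp <- responder[i]
      truth_rec[[i]] <- tibble::tibble(
        subject_id = rid, donor_id = donor_id[i],
        responder = is_resp,
        label = if (is_resp) "responder" else "non_responder",
        delta_homa2ir = delta_homa2ir[i],
        true_baseline_richness = length(baseline_set),
        richness_gain = n_gain + n_eng6 - n_lost6,
        n_engrafted_wk6 = n_eng6, n_lost_wk6 = n_lost6,
        p_engraft = p_engraft[i])
    }

    meta_samples <- dplyr::bind_rows(sample_rows)
    counts <- matrix(0L, nrow = n_asv, ncol = nrow(meta_samples),
                     dimnames = list(asvs, meta_samples$sample_id))
    for (sid in meta_samples$sample_id) {
      w <- profiles[[sid]]
      depth <- stats::rpois(1, cf$depth_mean)
      counts[names(w), sid] <- as.integer(
        stats::rmultinom(1, depth, w / sum(w)))
    }

    subjects <- dplyr::bind_rows(truth_rec) |>
      dplyr::select("subject_id", "delta_homa2ir") |>
      dplyr::mutate(soluble_fiber_g = soluble_fiber_g,
                    tmca_umol = tmca_umol,
                    cholesterol_mmol = cholesterol_mmol,
                    ldl_mmol = ldl_mmol,
                    sugars_g = sugars_g,
                    carbohydrates_g = carbohydrates_g)

    list(
      table = feature_table(counts),
      metadata = cohort_metadata(meta_samples, subjects),
      taxonomy = taxonomy,
      truth = list(
        recipients = dplyr::bind_rows(truth_rec),
        engraftment = dplyr::bind_rows(truth_eng),
        donor_pools = tibble::tibble(
          donor_id = pool_of[!is.na(pool_of)],
          asv_id = asvs[!is.na(pool_of)]),
        marker_genus = marker_genus,
        config = cf)
    )
  })
}

#' Permute responder labels of a synthetic cohort
#'
#' Null-model fixture for classifier calibration: the per-recipient
#' (responder flag, HOMA2-IR delta) pairs are permuted jointly across
#' recipients — keeping labels consistent with delta signs and the
#' responder count unchanged — while communities, covariates and everything
#' else stay identical. With permuted labels the generative group
#' difference in engraftment probability is destroyed in expectation.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param seed integer seed for the permutation.
#' @return A cohort list of the same shape with permuted response labels.
#' @export
permute_response_labels <- function(cohort, seed = NULL) {
  rec <- cohort$truth$recipients
  with_rng_seed(seed, {
    perm <- sample(nrow(rec))
    rec$responder <- rec$responder[perm]
    rec$label <- rec$label[perm]
    rec$delta_homa2ir <- rec$delta_homa2ir[perm]
    cohort$truth$recipients <- rec
    subj <- cohort$metadata$subjects
    subj$delta_homa2ir <- rec$delta_homa2ir[match(subj$subject_id,
                                                  rec$subject_id)]
    cohort$metadata$subjects <- subj
    cohort
  })
}
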