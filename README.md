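# fmtgraft

Donor-specific ASV engraftment tracking and responder prediction for fecal
microbiota transplantation (FMT) trials.

In paired donor–recipient FMT designs with 16S amplicon sequencing (stool at
weeks 0, 2, 6, 12), two questions drive the analysis: which of the donor's
amplicon sequence variants (ASVs) actually engrafted in each recipient — and
can a recipient's baseline state predict whether their insulin resistance
(HOMA2-IR) improves? fmtgraft implements the full analysis for both, plus a
synthetic cohort generator with known ground truth so every stage can be
validated.

## What it computes

* **Engraftment partitioning** — for each recipient and visit, the ASV
  universe splits against the pair's own baselines into *donor-specific*
  (donor baseline only; the engraftment candidates), *shared*,
  *recipient-specific* and *novel* sets, with the retained fraction of the
  donor-specific pool per visit. Per-ASV **engraftment rates** (fraction of
  eligible recipients retaining the ASV; eligibility is pair-restricted:
  the recipient's own donor carries it and the recipient lacked it at
  baseline) are tracked over weeks 2/6/12 and compared between responders
  and non-responders by Welch's *t*-test at each visit; recipient-baseline
  ASVs *lost* after FMT are screened the same way.
* **Diversity dynamics** — rarefaction to an even depth (default 9518
  reads), bias-corrected Chao1 `S_obs + f1(f1−1)/(2(f2+1))`, change scores
  (week 6 − baseline), and Spearman associations of the diversity response
  with baseline factors, with donor-adjusted ANCOVA (OLS with donor
  dummies) and Benjamini–Hochberg FDR.
* **Ordination** — principal coordinates (metric MDS, written from first
  principles: Gower double-centring + eigendecomposition) of the
  Bray–Curtis dissimilarities `Σ|u−v|/Σ(u+v)` among the week-6 engrafted
  donor-specific communities, with environmental vector fitting: each
  baseline variable regressed on the ordination plane, `R²` reported, and
  significance from a seeded permutation test (999 permutations,
  `p = (1 + #{R²_perm ≥ R²_obs}) / (1 + n_perm)`).
* **Response prediction** — recipients stratified by the sign rule
  (ΔHOMA2-IR < 0 ⇒ responder); a random forest on baseline genus relative
  abundances evaluated by 100 replicates of leave-one-out cross-validation
  (per-replicate pooled out-of-fold ROC/AUC, out-of-bag error,
  replicate-averaged Gini importance), with the accuracy gate mean
  AUC ≥ 0.7 and mean OOB error < 0.6, and Wilcoxon tests on the top-ranked
  predictors.

Results are tibbles throughout; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(fmtgraft)

cohort <- simulate_cohort(cohort_config(), seed = 1)
cohort$table
#> <fmt_feature_table> 300 ASVs x 120 samples; depth range [19656, 20370]
cohort$metadata
#> <fmt_metadata> 120 samples; 4 donors, 29 recipients; weeks {0,2,6,12}; 0 excluded

rar    <- rarefy_counts(cohort$table, depth = 9518, seed = 2)
labels <- classify_responders(cohort$metadata$subjects)
dplyr::count(labels, label)
#> # A tibble: 2 × 2
#>   label             n
#>   <chr>         <int>
#> 1 non_responder     8
#> 2 responder        21

pres  <- call_presence(rar, min_count = 1)
parts <- engraftment_partitions(pres, cohort$metadata)
head(parts, 3)
#> # A tibble: 3 × 10
#>   subject_id donor_id timepoint_weeks n_donor_specific n_retained n_shared
#>   <chr>      <chr>              <int>            <int>      <int>    <int>
#> 1 R01        D1                     2               84         22       52
#> 2 R01        D1                     6               84         22       52
#> 3 R01        D1                    12               84         22       52
#> # ℹ 4 more variables: n_recipient_specific <int>, n_novel <int>,
#> #   retained_fraction <dbl>, undefined <lgl>

genus  <- collapse_to_genus(cohort$table, cohort$taxonomy)
feats  <- baseline_genus_features(genus, cohort$metadata)
report <- rfc_loocv(feats, labels, n_replicates = 10, seed = 3)
report
#> <fmt_rfc> 10 replicates x LOOCV over 29 recipients, 36 features
#>   mean AUC 0.723 (sd 0.016), mean OOB error 0.310 -> gate PASS
head(tidy(report), 3)
#> # A tibble: 3 × 4
#>   feature   importance_gini importance_accuracy  rank
#>   <chr>               <dbl>               <dbl> <int>
#> 1 genus_025           1.65              0.0348      1
#> 2 genus_049           1.03              0.0174      2
#> 3 genus_042           0.586             0.00281     3
```

Reading the output: recipient R01 had 84 ASVs that only its donor carried
at baseline, of which 22 were detected at each post-FMT visit (retained
fraction 0.26). The classifier discriminates responders from
non-responders with mean cross-validated AUC 0.723 and passes the accuracy
gate; the top-ranked predictor, `genus_025`, is the generator's planted
marker genus (depleted in responders at baseline) — recovered from the
data, not read from the ground truth.

The end-to-end pipeline — rarefaction through engraftment, ordination +
envfit, the response model and the association family, with every stage
table written as TSV plus a summary and manifest — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
```

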