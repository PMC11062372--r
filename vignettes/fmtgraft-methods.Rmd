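---
title: "Tracking donor ASV engraftment and predicting FMT response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking donor ASV engraftment and predicting FMT response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fecal microbiota transplantation (FMT) trials in metabolic disease face two
linked questions. First, *did the donor's microbes actually engraft* — which
amplicon sequence variants (ASVs) given by the donor established themselves in
each recipient, and for how long? Second, *who benefits* — can a recipient's
pre-treatment state predict whether their insulin resistance (HOMA2-IR)
improves? fmtgraft implements a complete analysis for a paired donor–recipient
16S design with stool sampled at weeks 0, 2, 6 and 12: donor-specific ASV
partitioning and longitudinal retention, rarefied Chao1 diversity dynamics,
Bray–Curtis ordination of the engrafted community with environmental vector
fitting, responder stratification by the sign of the HOMA2-IR change, and a
replicated leave-one-out random-forest prediction protocol.

Because trial-scale sequencing data are rarely redistributable, the package
also ships a synthetic cohort generator with full ground truth, so every
stage can be validated against known parameters rather than eyeballed.

## Engraftment bookkeeping

All engraftment logic runs on presence/absence calls made on counts rarefied
to an even depth (default 9518 reads, the depth used with this visit
structure in practice). For a recipient–donor pair at a post-FMT visit, the
ASV universe splits into five sets:

* **donor-specific**: in the donor baseline, absent from the recipient
  baseline — the candidates for engraftment ("species shared only with the
  donor");
* within those, **present** vs **absent** at the visit, giving the
  *retained fraction*;
* **shared**: in both baselines (origin unattributable);
* **recipient-specific**: recipient baseline only;
* **novel**: at the visit but in neither baseline.

Two definitions were genuinely open and are resolved as follows.
*Donor-specificity is per pair*: donors differ, so an ASV is donor-specific
relative to the recipient's own donor and baseline, and the engraftment-rate
denominator counts only recipients whose donor carries the ASV and who
lacked it at baseline. The unrestricted per-group denominator is also
emitted (`rate_all`) for comparison. *Novel ASVs are excluded from
engraftment rates*: without strain resolution they cannot be attributed to
the donor. An empty donor-specific pool yields an `NA` retained fraction
with an `undefined` flag — never a 0, which would conflate "nothing to
engraft" with "nothing engrafted".

The detection threshold (`min_count`, default 1 rarefied read) is a surfaced
parameter rather than a constant: binary presence at even depth is what the
retained-fraction and rate definitions imply, but no threshold removes the
detection limit, so the threshold is recorded in every presence object and
its monotonicity (raising it can only remove calls) is under test.

Responder-enriched ASVs are selected per timepoint by Welch's *t*-test on
the per-recipient 0/1 retention indicators (responders vs non-responders),
two-sided, with the responder-greater direction applied post hoc; an ASV is
selected if any timepoint has p below `alpha` (default 0.05) in that
direction. Timepoints with fewer than two eligible recipients in either
group are skipped and reported, since a variance estimate needs two points.

## Diversity

Chao1 uses the bias-corrected estimator
`S_obs + f1 (f1 - 1) / (2 (f2 + 1))` (f1 singletons, f2 doubletons), which
stays finite when no doubletons are observed and collapses to `S_obs`
without singletons; this is the variant QIIME2-era pipelines compute. The
classical `f1^2 / (2 f2)` form is a one-line swap in `chao1()` if needed.
Rarefaction is a single seeded multivariate-hypergeometric draw per sample
(no replicates — one draw with a recorded seed keeps every downstream table
reproducible); samples below the target depth are dropped and reported, a
policy choice the reader surfaces rather than hides. Change scores are
always `followup - baseline`, so responders have negative HOMA2-IR deltas
and richness gains are positive; the responder rule consumes only the sign,
and a delta of exactly zero is flagged unclassifiable rather than assigned.

Bray–Curtis (`sum |u - v| / sum (u + v)`) is computed on rarefied counts: at
even depth, counts and relative abundances give proportional profiles, so
the distinction is immaterial and counts avoid a silent renormalisation.

## Ordination and environmental fitting

`pcoa()` is classical metric MDS written out directly: Gower double-centring
of `-d^2/2`, a symmetric eigendecomposition, scores scaled by the square
root of the eigenvalues. Sample weights are equal — weighted MDS with
uniform weights reduces to exactly this, and no other weighting is
defensible without stated weights. Negative eigenvalues (Bray–Curtis is
semi-metric) are dropped, not corrected; their summed magnitude is reported
as `negative_mass` so the embedding error is visible. Axis signs are fixed
deterministically (largest loading positive), and eigenvalues within
`1e-8` of zero (relative to the spectrum) are treated as zero.

`fit_env_vectors()` regresses each centred baseline variable on the first
two score columns by least squares; `r2` is the squared multiple correlation
and the arrow is the unit coefficient vector. Inference is by permutation:
`p = (1 + #{r2_perm >= r2_obs}) / (1 + n_perm)` with 999 permutations by
default, so the smallest attainable p is 0.001. The permutation stream is
seeded, and a matrix of explicit permutations can be supplied — the test
suite exploits this to check exact agreement with a full 720-permutation
enumeration at n = 6. Variables are fitted untransformed (an optional
z-score flag exists; `r2` and `p` are invariant to affine rescaling, only
the recorded effect scale changes). Constant variables get `r2 = 0`,
`p = 1` and a flag; missing values are excluded variable-wise with `n_used`
recording the effective sample.

## Response prediction

Recipients are classified by the sign rule (HOMA2-IR fell by week 6 ⇒
responder). The classifier is a random forest on baseline genus-level
relative abundances (genus counts are member-ASV sums; unlabeled ASVs pool
into a reserved `unassigned` genus; genera detected in fewer than two
recipients are dropped, a surfaced `min_prevalence` flag). Forest settings
follow the randomForest defaults — 500 trees, `sqrt(p)` candidates per
split, unlimited depth — overridable but not tuned.

The protocol: 100 replicates, each on its own RNG substream; within a
replicate every recipient is predicted by a forest trained on the other
n − 1, the n out-of-fold probabilities form one ROC/AUC, and a full-data
forest contributes the out-of-bag error and importances. The headline is
the mean (and SD) of per-replicate AUCs; the AUC of all replicates pooled
is also emitted, since both pooling conventions are defensible. Importance
is averaged over replicates, with Gini impurity as the primary ranking and
permutation accuracy importance alongside. A model passes the accuracy gate
when mean AUC ≥ 0.7 and mean OOB error < 0.6. Top-ranked predictors get a
two-sided Wilcoxon rank-sum test between response groups with the direction
of difference, mirroring how importance rankings are annotated in practice.

## Univariate statistics

Welch's *t* (unequal variances, Satterthwaite df), Wilcoxon rank-sum (exact
enumeration when the combined n is at most 12 and tie-free, otherwise the
normal approximation with continuity and tie corrections), and Spearman's
`r_s` (t-approximation p) wrap the base-R implementations behind a common
one-row-tibble surface so whole analysis families can be row-bound and
FDR-corrected together with `bh_fdr()` (Benjamini–Hochberg step-up, applied
within one family at a time). Degenerate inputs have explicit conventions:
two constant equal groups give t = 0, p = 1; constant unequal groups are
treated as infinite separation (p = 0); all-tied rank-sum data give p = 1;
a constant correlation input is flagged with `NA`.

Donor-adjusted association is ANCOVA by closed-form OLS: outcome on
predictor plus donor indicator dummies, with the predictor tested by its
coefficient t-test (numeric) or a partial F-test (group factor). With two
timepoints per contrast, the change-score-plus-donor-covariate model is the
standard non-iterative equivalent of a random-intercept repeated-measures
fit, which is why no REML machinery is used (full mixed models are out of
scope); the adjustment is recorded in every result row. Donor levels
aliased in the design are merged into the reference with a warning rather
than silently dropped.

## The synthetic cohort generator

The generator is first-class, tested code. Defaults encode the emulated
study conditions: 4 donors, 29 recipients of whom 21 respond, visits at
weeks 0/2/6/12, 300 ASVs with 30 donor-exclusive ASVs per donor, sequencing
depth Poisson(20 000), rarefaction at 9518. Two layers are generated
separately so detection limits can be studied: a biological colonization
state, then multinomial reads over log-normal(0, 1) abundance weights with a
per-visit log-normal(0, 0.3) jitter for visit-to-visit fluctuation.

* **Engraftment**: each donor-exclusive ASV colonizes its recipient at week
  2 with probability 0.6 (responders) vs 0.2 (non-responders) — effect
  sizes chosen for testability, since only significance levels are
  published — shifted on the logit scale by `covariate_effect` (default
  0.8) times the standardized soluble-fiber intake. Established ASVs
  (baseline or engrafted) are lost memorylessly with probability 0.1 at
  each subsequent visit, so recipient-baseline ASVs are lost by week 6 at
  rate `1 - 0.9^2` (two post-FMT transitions) — the closed form the
  removed-ASV tests check.
* **Diversity response**: the *net* week-6 richness change is planted with
  Spearman coupling −0.75 to baseline richness (via the bivariate-normal
  latent correlation `2 sin(ρπ/6)`), realized by adding newly gained
  common-pool ASVs on top of the engraftment and loss processes. The net
  change is the coupled quantity because it is what a Chao1 change-score
  analysis measures.
* **Response signal**: responders' baseline abundance of a designated
  marker genus is multiplied by 0.35 (a depleted predictor genus), and
  ΔHOMA2-IR is drawn as `-|N(0.5, 0.2)|` for responders, `+|N(0.5, 0.2)|`
  for non-responders — only the sign matters downstream.
* **Covariates**: cholesterol, LDL, sugars and carbohydrate intake are
  shifted upward in non-responders; tauro-muricholic acid is negatively
  coupled (−0.46 latent Spearman) to the diversity response.

What the generator does *not* emulate: taxonomic correlation structure
(genera are arbitrary 5-ASV blocks), ecological interactions (no
competition or succession — loss is memoryless by design), compositional
constraints beyond the multinomial, strain-level variation, and donor
communities drifting over time (a donor's presence profile is one
baseline). Tests passing on this generator therefore validate the
*bookkeeping and inference machinery* — partition identities, estimator
formulas, calibration of tests, parameter recovery — not the ecological
realism of any particular dataset.

## Validation problem sizes

The suite validates estimator formulas exactly (Chao1 closed form, hand
Bray–Curtis, BH step-up, exact Wilcoxon enumeration), geometry to 1e-8
(planar PCoA recovery), envfit against full permutation enumeration at
n = 6, type-I error of all four tests at 10⁴ null replicates (nominal 0.05,
accepted within [0.042, 0.058]), rarefaction against hypergeometric moments
over 10⁴ draws, and parameter recovery on a 200-recipient cohort (rates
within 3 binomial SE of the realized truth; diversity coupling within
±0.15). Classifier calibration uses label-permuted cohorts (mean AUC
expected in [0.35, 0.65] — leave-one-out AUC under the null sits *below*
0.5 because the held-out subject's class is underrepresented in training),
a separable fixture (AUC ≥ 0.95), and a 100-seed marker-genus recovery
study (importance from 2 replicates of 150-tree forests per seed, enough
for a stable top-10 ranking at this feature count).

One validation target is knowingly not met: with pair-restricted
eligibility, a planted ASV is only testable on its own donor's ~50
recipients (~36 vs ~14 per group), where a Welch test on 0/1 indicators at
0.6 vs 0.2 has per-timepoint power around 0.7, and the three visits are
strongly dependent; observed selection sensitivity is ~0.66–0.73 rather
than ≥ 0.8. This is a property of the design (per-pair denominators),
not of the implementation; pooling all recipients into every ASV's
denominator would contradict the per-pair definition adopted above.

## Reproducibility

Every stochastic stage takes an explicit seed; `pipeline_config()` expands
one global seed into per-stage seeds by fixed offsets (simulate +0, rarefy
+1, envfit +2, forest +3), so stages can be re-run in isolation. Two runs
with the same configuration produce byte-identical output tables, and the
run manifest records the configuration hash, seeds and package version.
Exclusions (recipients without baselines, samples under the rarefaction
depth, inestimable rate cells, skipped test cells) are first-class outputs,
because the eligible-recipient denominators drive every engraftment rate.

## Limitations

Attribution is presence-based: a "retained" donor-specific ASV could in
principle be an independently acquired identical sequence, and `shared`
ASVs are unattributable without strain resolution. Engraftment rates
condition on detection at a fixed rarefied depth, so low-abundance
engraftment is undercounted (the detection threshold is surfaced for
sensitivity analysis). The donor-adjusted OLS is the two-timepoint
equivalent of a mixed model, not a replacement for one across all four
visits. And the classifier protocol reports cross-validated discrimination,
not calibrated individual risk. Pooled leave-one-out probabilities carry
a class-prior artifact under imbalance: holding out a member of the rare
class makes the training set *more* imbalanced, shifting that fold's
predicted probabilities upward for the majority class, so when the feature
signal is weak the pooled AUC is dragged well below 0.5 (and with 29
recipients, cross-validated AUC has large seed-to-seed variance in
general). The package reports the protocol's AUC as defined — with a fixed
ROC direction, never auto-flipped — so a collapsed AUC is visible rather
than silently rounded up to chance.
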