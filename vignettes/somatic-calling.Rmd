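---
title: "Calling somatic SNVs in low-pass tumor-normal data with somaticRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic SNVs in low-pass tumor-normal data with somaticRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticRF)
```

## The problem and the model

Somatic single-nucleotide variants distinguish a tumor genome from its
matched normal. In low-pass sequencing (around 30X) they are hard to
separate from sequencing and alignment errors: a subclonal variant at VAF
0.15 is supported by only a handful of reads, exactly like a recurrent
artifact. Model-based callers that assume well-behaved error profiles
degrade quickly on such data.

somaticRF treats the problem as supervised classification. Candidate sites
are first *screened* with deliberately permissive rules, then each candidate
is summarised as a numeric *feature vector*, and a *Random Forest* trained
on orthogonally validated calls (variants confirmed or refuted by
independent re-sequencing) assigns each candidate a class, true somatic
variant (`TP`) or error (`FP`), with a vote-based class probability. Because
the forest is trained on the same kind of data it will classify, it learns
the platform's systematic error signatures instead of assuming them.

### Screening

A locus enters the candidate set when

* declared coverage is at least 8X in **both** samples,
* the tumor carries at least one read supporting a non-reference allele
  with base quality (BQV) $\ge 20$ on a read with mapping quality (MQV)
  $\ge 10$.

Each distinct alternative allele at a locus becomes its own candidate. The
coverage test uses the raw declared depth, while the quality thresholds
apply only to the alt-supporting reads: the stated coverage requirement
carries no quality qualifier, and interpreting it pre-filter keeps the two
rules independent. Candidates overlapping user-supplied BED tracks
(germline variant sets, blacklisted regions) can be removed; BED intervals
are 0-based half-open, so a candidate at 1-based position $p$ is dropped
when $start < p \le end$.

Every candidate also receives a **somatic p-value**: a two-sided Fisher's
exact test on the table $[[t_{ref}, t_{alt}], [n_{ref}, n_{alt}]]$
comparing ref/alt read counts between tumor and normal. Two-sidedness is a
deliberate choice — it matches the usual somatic-test convention and makes
the statistic symmetric in the two samples. The p-value is *not* used as a
hard filter: it is carried into the feature vector and the output VCF, and
thresholding is left to the classifier and the user.

### The 15 features

Features fall into five groups; `feature_names()` lists them in order.
Where a feature compares alt-supporting against ref-supporting reads at the
same locus it is a *vs_ref* feature; where it is a ratio to a background
median it is a *vs_med* feature.

| group | features |
|---|---|
| quality bias of alt bases | mean alt BQV (vs_med), mean alt MQV (vs_med), rank-sum p of alt-vs-ref BQV, rank-sum p of alt-vs-ref MQV |
| coverage and VAF | tumor depth (vs_med), normal depth (vs_med), tumor VAF, normal VAF |
| location along the read | mean relative read position of alt bases, rank-sum p of alt-vs-ref read positions, fraction of alt bases within 5 bp of a read end |
| strand bias | Fisher p of alt fwd/rev vs ref fwd/rev, fraction of alt reads on the majority strand |
| others | somatic Fisher p, number of distinct non-reference alleles |

Design notes behind the less obvious choices:

* **vs_med normalization.** Absolute depths and qualities are
  platform-dependent; dividing by the median of the same raw quantity over
  `n_positions` randomly sampled loci (default 10,000, seeded, recorded in
  the model) makes features transferable between runs of one dataset. A
  guard `raw / max(median, 1e-6)` keeps ratios finite when a background
  median is zero.
* **Rank tests.** Two-sided Wilcoxon rank-sum with midranks; the exact U
  distribution is used when both sides have fewer than 50 observations and
  no ties, otherwise the tie-corrected normal approximation with continuity
  correction. When a site has no ref-supporting reads the tests return the
  neutral value 1: absence of reads is treated as absence of evidence of
  bias, not as bias.
* **Read length proxy.** mpileup does not carry read lengths, so relative
  positions are computed against the maximum within-read position observed
  at the locus.
* **Multi-allelic sites** contribute one candidate per alternative allele,
  keeping downstream rows atomic; the distinct-alt-allele count feature
  lets the classifier see the local noise level anyway.

### The cost-sensitive forest

The classifier is a bagged ensemble of unpruned binary trees (default
`n_trees = 300`). Each tree trains on a bootstrap drawn **with probability
proportional to instance weight**, and splits maximize **weighted
information gain** (class entropy in bits) over midpoint thresholds, with
$\lfloor \log_2 M \rfloor + 1$ features drawn at random per node from the
$M$ available. The floor convention resolves the integer ambiguity in the
features-per-node rule: $M = 15 \Rightarrow 4$, $M = 16 \Rightarrow 5$.

Class imbalance — hundreds of validated somatic variants against tens of
thousands of validated errors, or roughly one true variant per million
candidates at calling time — is handled by *cost-sensitive reweighting*:
`apply_costs()` multiplies FP-class weights by `cost_fp` and TP-class
weights by `cost_fn`. Because weights drive both the bootstrap and the
split criterion, a stronger FP cost trains a forest that is more reluctant
to call variants. Among the mechanisms a cost-sensitive wrapper could use
(reweighting, resampling, threshold shifting), instance reweighting was
chosen because it composes naturally with weighted bagging and keeps
prediction untouched. One behavioral consequence is worth knowing:
reweighting lowers the false-call rate of the *hard* PASS/REJ prediction,
but it does not necessarily improve the vote-fraction *ranking* in the
high-recall tail — down-weighted borderline variants can drop below errors
there, so a fixed-recall operating point chosen on the score sweep may
collect more errors under a heavier FP cost.

Training utilities mirror standard practice: `rank_features()` ranks
features by information gain (supervised binary-threshold discretization
for continuous features, deterministic midpoints, alphabetical tie-break)
and `top_k` performs optional dimensionality reduction;
`filter_vaf_interval()` restricts training to a tumor-VAF band for targeted
(e.g. subclonal) models; the out-of-bag error is reported with every model;
`cross_validate()` runs seeded, stratified k-fold CV (default 10) and pools
out-of-fold votes into ROC/PR curves.

Prediction is majority vote. The reported class probability is the vote
fraction of the winning label, hence in $[0.5, 1]$; an exact 150/150 tie is
resolved to `FP` — the conservative direction for somatic calling. VCF
output keeps `REJ` records alongside `PASS` so users can re-threshold
numerically (`SPV`, `CP` INFO fields) rather than being bound by the
categorical prediction.

### Evaluation

`roc_pr_curves()` sweeps a threshold across the distinct scores in
descending order (ties move together). ROC AUC uses the trapezoid rule and
is checked in the tests against the normalized Mann-Whitney U statistic; PR
AUC defaults to the rectangle-under-step convention with precision carried
across each recall increment, with a trapezoid variant behind
`pr_method = "trapezoid"` since the two conventions differ slightly and
published areas may use either. The precision at recall 0 is pinned to the
precision of the highest-score group rather than interpolated through 0/0.
Cohen's kappa is computed from the marginals, with the chance-agreement
degenerate case ($p_e = 1$) defined as 0.

## The simulator and what it does (not) show

`simulate_pair()` generates matched tumor/normal pileups with known truth:
negative-binomial depths per sample, per-read errors at a configurable
rate, planted somatic variants (tumor only, VAF drawn from a configurable
range, defaulting to the subclonal-to-clonal band 0.10-0.58) and germline
heterozygotes (both samples, VAF 0.5). Erroneous bases draw lower
base/mapping qualities than correct bases, a configurable fraction of
error-prone sites confines its errors to one strand, and a fraction of
error reads is biased towards read ends — the three signatures the feature
groups iii and iv are designed to see. Errors are drawn independently per
observation: mpileup carries no read pairing, and every feature is
per-observation, so read-level structure would be invisible anyway.

Presets (`sim_preset()`): `lowpass30x`, `wgs90x`, and `imbalanced-test`
(100,000 sites at 30X, 1% error, 50 planted somatics with VAF 0.10-0.60 —
a calling scenario where errors outnumber true variants by three orders of
magnitude among candidates). `subsample_coverage()` thins observations
binomially to emulate coverage-reduction experiments (90X thinned at 0.5
gives ~45X).

The simulator's error model is an idealisation: quality distributions are
truncated normals, error positions are exchangeable across sites, and
there is no alignment structure, homopolymer context or platform-specific
chemistry. Passing the recovery tests therefore demonstrates that the
pipeline's machinery — screening, features, weighting, training, calling —
recovers signal whose separability is configured, not that any particular
real platform is separable to the same degree.

## Numerical and reproducibility choices

* Fisher p-values sum hypergeometric point probabilities `<=` the observed
  one with the conventional `1 + 1e-7` relative tolerance; degenerate
  tables (an empty margin) give 1; the all-zero table is an error.
* All randomness (background sampling, bootstraps, feature subsets, fold
  assignment, simulation) derives from explicit integer seeds; identical
  seeds give byte-identical model archives and VCFs. Background sampling
  and fold assignment restore the caller's RNG state.
* The model archive is versioned JSON with full-precision numbers, so a
  reloaded model predicts identically.
* Training requires both classes and at least 2 instances; `k` must not
  exceed the minority class count so every training fold keeps both
  classes.

## Problem sizes used in the shipped checks

The test-suite recovery experiments use cohorts of 250 true against 30,000
false training instances screened from a 70,000-site simulation (10-fold
CV with 300 trees), and the end-to-end check trains on a 30,000-site
cohort and calls the 100,000-site `imbalanced-test` scenario at default
equal costs: because the training cohort shares the test regime's error
profile, precision is already high there and an extra FP cost would only
sacrifice sensitivity to low-VAF subclonal variants (the cost option's
effect is exercised by its own property test instead). The acceptance script uses the same
30,000-site training cohort and reports cross-validated ROC/PR AUC, kappa,
out-of-bag error, and recall/precision on the planted somatics.

## Limitations

* SNVs only: indel and reference-skip symbols are consumed by the parser
  but never become alleles.
* The mpileup dialect must include per-base mapping qualities and
  within-read positions (`samtools mpileup -s -O`); without them the
  read-position and mapping-quality features are uncomputable.
* Sequence context (homopolymers, GC-rich motifs) is not modelled.
* `vs_med` backgrounds are re-sampled from the dataset being called, so a
  model applied to data from a very different depth regime relies on the
  normalization transferring — the coverage-subsampling utilities exist
  precisely to test that.
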