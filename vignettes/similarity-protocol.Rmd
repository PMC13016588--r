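---
title: "Pairwise SNP-similarity learning: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise SNP-similarity learning: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsim)
```

## The model

Rare-disease genetics offers too few associated variants for per-SNP
classification, so `snpsim` learns a *pairwise* similarity function
instead. The training signal is cheap to construct: every pair of known
disease-associated SNPs is a "similar" example, and every
(disease SNP, background SNP) pair is a "dissimilar" example, where the
background pool holds variants associated with *other* traits. A set of
$n$ positives yields $\binom{n}{2}$ similar pairs — for $n = 189$ that is
17,766 — so even a tiny positive set supports a real training task.

Each pair is represented by five absolute differences of engineered
per-SNP features: chromosome code, base-pair position, $-\log_{10} p$,
mapped-gene count, and the intergenic indicator. The classifier is a
random forest of 100 trees with maximum depth 5 and inverse-frequency
class weights. The central assumption is **genetic proximity**: variants
near each other on the genome (small `pos_diff` on the same chromosome)
are often in linkage disequilibrium and tend to have related effects.
The model does not observe LD itself — only coordinates — so proximity is
a proxy, and predicted candidates always need experimental follow-up.

A scored candidate's similarity is the fraction of trees voting
"similar", a value in $[0, 1]$ reported downstream as a percentage.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_per_class` | 848 | pairs | 1,696 total pairs gives a hold-out support of ~339 pairs at a 20% split, the scale at which the reference protocol was evaluated; the protocol itself never fixes this, so it is surfaced in the config |
| `test_fraction` | 0.2 | — | standard 80/20 hold-out |
| `n_trees` | 100 | trees | variance reduction saturates well before this for five features |
| `max_depth` | 5 | levels | enough to express interactions among five features; a hard cap against overfitting small pair sets |
| `class_balancing` | on | — | background pools dwarf positive sets in real use; weights keep the minority class visible |
| `threshold` | 0.5 | score | decision threshold for the confusion matrix; a plain default, not calibrated |
| `k` | 10 | candidates | candidates kept per reference; recurrence across references is the enrichment signal |
| `logp_threshold` | 7.3 | $-\log_{10} p$ | genome-wide significance, $p \le 5\times 10^{-8}$ |
| `min_recurrence` | 6 | references | below 6, prediction multiplicities are common enough to be noise; at 6+ they are rare under chance |

## Pair construction and the split

Similar pairs are drawn uniformly without replacement from the unordered
positive pairs; dissimilar pairs are drawn uniformly from the
positive × negative cross product via linear codes, so the cross product
(which can reach $10^8$ pairs against a full catalog) is never
materialized. In every pair the positive SNP is the `ref` member, and
positive-positive pairs are ordered by rsID — the features are symmetric,
so the convention only serves reproducibility. The 80/20 split is
stratified by pair label. Pairs sharing an underlying SNP may straddle the
split; this mirrors the plain pair-level protocol and is a known leakage
channel at the SNP level, which is why the simulated-group study below and
cross-validation complement the hold-out estimate.

## Validation design

Three checks guard against a broken learner:

1. **Simulated similarity groups** — 500 SNPs in 10 groups, each group on
   its own chromosome, inside a 100 kb position window and a disjoint
   $-\log_{10} p$ band of width 2 (gap 2 between bands), with a
   group-constant gene count. Groups are separated along exactly the axes
   the features measure, so any competent pipeline must reach held-out
   ROC-AUC 1.0 on 400/200 balanced pairs. "Pre-defined similarity groups"
   admits many realizations; clusters in (chromosome, position window,
   p-value band) were chosen because they are what the model can in
   principle see — the test is of the pipeline, not of biology.
2. **Stratified 5-fold cross-validation** on pairs built from the
   catalogs, reporting per-fold and mean ± sd ROC-AUC.
3. **Linear baselines** — an L2-penalized logistic classifier and a ridge
   (penalized least-squares) classifier fitted on the identical split with
   the same penalty strength ($\lambda = 1/n$, the conventional default
   scaling), compared on six metrics. Ridge regression has no native
   probability, so its decision value is thresholded at 0 for the
   confusion matrix and min–max mapped to $[0,1]$ for AUC/AP; the mapping
   is rank-preserving, so the ranking metrics are unaffected.

## Filtering and reporting

The filter retains a prediction row when the candidate's *own* catalog
p-value reaches genome-wide significance and/or the candidate recurs in
at least `min_recurrence` top-$k$ lists. The tested p-value is the
candidate's original-trait association — candidates were selected from
other traits' results precisely because no disease-specific p-value exists
for them. Candidate lists are *not* deduplicated across references
(recurrence is the signal); unique-SNP summaries (chromosome distribution,
Manhattan table) deduplicate explicitly. Allele annotation is a local
left-join against a user-supplied three-column table; no live lookup is
performed.

## Numerical choices

- p-values of 0 — and anything below $10^{-300}$, where parsed strings
  underflow — are clamped to $10^{-300}$, bounding `log_pvalue` at 300.
- No feature scaling: trees are scale-invariant.
- Tree growth is limited by depth only (`min.node.size = 1`), so the
  depth cap is the single regularizer and tiny fixtures behave the same
  way as full-size runs.
- Top-$k$ ties break by ascending rsID after descending score, making
  outputs bit-reproducible.
- AUC ties count 0.5 concordance (the standard Mann–Whitney convention);
  average precision is the step-interpolated sum
  $\sum_n (R_n - R_{n-1}) P_n$ with tied scores collapsed to one
  threshold.
- Pool scoring streams in fixed-size batches; results are independent of
  batch size (asserted in the tests).
- All randomness flows through explicit integer seeds; model files embed a
  format version, the config and the feature order, and loading refuses
  anything else.

## What the synthetic data does and does not emulate

The catalog generator reproduces the *format* faithfully — both TSV
dialects, allele-suffixed rsIDs, `chromosome:position` tokens, mixed
`,`/`;` gene separators, `-`/blank/`NA` intergenic placeholders, p-values
spanning 1 down to exact 0 — and two structural signals: background SNPs
planted near positive loci (so end-to-end runs have recoverable structure)
and a chromosome-18-style excess (so the chromosome summary has a planted
mode). It does **not** simulate LD, allele frequencies, genotypes or
realistic gene annotation; gene symbols are invented (`GENE0001`, …) to
avoid accidental biological claims. Passing tests therefore demonstrate
that the machinery is correct and that recoverable structure is recovered
— not that any particular real variant is disease-relevant.

Degenerate inputs are handled conservatively: records with unparseable
positions or p-values are dropped and counted (the source protocol says
such values "were corrected" without specifying how; dropping with a
report is the conservative reading), multi-location rows use their first
location and are counted, and single-class training or test sets raise
errors rather than returning undefined metrics.

## Problem sizes in the test suite

The suite exercises the full protocol at reduced scale — positive sets of
3–189 SNPs, pools of up to 2,000, pair sets of up to 1,696 — and the
simulated-group study at its native 500-SNP size, including a 20-seed
stability sweep. These sizes were chosen so every oracle (full-sort
top-$k$, brute-force AUC concordance, set-union filter) can be computed
exactly alongside the implementation.

## Known limitations

- Proximity is a proxy for LD, not a measurement of it; no LD pruning or
  clumping is applied to retained candidates.
- The candidate's significance filter uses its original-trait p-value,
  which is evidence of functional relevance, not of association with the
  disease under study.
- Population structure is invisible to the model: the same variant may be
  benign in one population and pathogenic in another.
- The plain pair-level split can leak SNP-level information between train
  and test; interpret the hold-out metrics together with the
  cross-validation and simulated-study results.
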