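---
title: "Predicting m6A sites with cost-sensitive imbalance learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting m6A sites with cost-sensitive imbalance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6acs)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal modification of
mRNA. Methylated adenines sit almost exclusively on the degenerate
consensus motif DRACH, `[G/A/C][G/A]AC[U/A/C]`, with the candidate
adenine at the third position, and are enriched in the 3'UTR near the
stop codon. The prediction task is to decide, for every DRACH adenine
on a mature transcript, whether it is a genuine m6A site. Because every
motif-conforming adenine is a candidate, negatives outnumber validated
positives roughly 10:1, and a classifier trained on a balanced
subsample of negatives both wastes data and changes with the subsample.
This package instead trains on the *entire* imbalanced candidate set
and handles the skew with a cost-sensitive objective.

## Model

The classifier is a gradient-boosted tree ensemble (binary logistic
objective, probability output) in which each positive training sample's
loss is multiplied by a class weight. The hyperparameters, fixed in
`m6acs_config()`, are:

| parameter | default | meaning |
|---|---|---|
| `lambda` | 700 | L2 penalty on leaf weights; strong shrinkage against overfitting the large negative class |
| `max_depth` | 6 | tree depth |
| `eta` | 0.1 | learning rate |
| `nrounds` | 400 | boosting rounds |
| `scale_pos_weight` | 6 | positive-class cost multiplier |
| `eval_metric` | AUC | training evaluation signal |
| `threshold` | 0.5 | probability cut-off for hard labels (boundary counts as positive) |

The positive weight defaults to 6 even though the full-corpus imbalance
is nearer 10:1; the configuration accepts the empirical ratio if a user
prefers it. The classification threshold is exposed because the
upstream method never states one; 0.5 is the neutral choice.

## Feature space (509 dimensions)

Each candidate is described by a 51-nt window (`flank = 25`) centred on
the adenine, plus transcript-level context. Blocks, in fixed order:

1. **Binary, 204** — per-position one-hot over A,C,G,U.
2. **Chemical property, 153** — per-position 3-bit overlapping code
   (ring number, hydrogen bonding, functional group):
   A-(1,1,1), C-(0,0,1), G-(1,0,0), U-(0,1,0).
3. **Density, 51** — at position *i*, the frequency of the resident
   nucleotide within the prefix 1..*i* (`d_i = #{j ≤ i : s_j = s_i}/i`).
4. **k-mers, 80** — 2-mer (16) and 3-mer (64) sliding-window
   frequencies, lexicographic A<C<G<U, normalised by the number of
   valid windows.
5. **Entropy/composition, 7** — the four nucleotide frequencies, the
   Shannon entropy `En`, the relative entropy against the uniform
   reference `REn = -Σ p_i log2(p_i / 0.25)` and the information gain
   score `IGS = En - REn`.
6. **Location, 2** — distance from the transcript start (position − 1)
   and that distance divided by the transcript length.
7. **SNP, 12** — the 0/1 variant state of the window offsets selected
   by the SNP-specificity ranking (below), in ranked order.

A note on the entropy block: with the sign written into the `REn`
definition above, `REn ≡ En − 2` and therefore `IGS ≡ 2` bits for every
window. The definitions are implemented exactly as given rather than
silently "fixed"; the identity is asserted as a regression test, and
constant features are harmless to tree learners (they are never chosen
for a split and score 0 importance).

### Handling of edge padding

Windows that run past a transcript end are padded with `N` so that edge
candidates are not silently dropped. `N` is legal only as padding:
every encoder maps it to all-zero codes, it is excluded from
composition and k-mer frequencies (both numerator and denominator), it
contributes density 0 and increments no letter's prefix count (the
density denominator stays the prefix length *i*), and padded offsets
have SNP state 0. An all-`N` window has no defined entropy and is
rejected.

## SNP-specificity position selection

Single-nucleotide variants can disrupt the motif or the flanking
protein-binding context, and they do so class-specifically at certain
window offsets. Each sample's window is converted to a 51-bit variant
state vector, and the 51 offsets are ranked two ways:

* **Fisher's exact test** — per offset, the two-sided p-value of the
  2×2 table (variant / no variant) × (positive / negative), ranked
  ascending.
* **MRMR** — greedy maximum-relevance minimum-redundancy ordering with
  the MID (difference) criterion: the first pick maximises the mutual
  information `I(x; class)`; each later pick maximises
  `I(x; class) − mean over selected s of I(x; s)`, with plug-in mutual
  information in bits over the binary variables.

The two ranks are fused by their average, and the 12 offsets with the
smallest average rank become the SNP feature block. Ties — which only
arise on degenerate or synthetic data — break deterministically:
smaller Fisher rank, then smaller absolute offset, then the negative
offset before the positive. Constant (zero-entropy) offsets are
appended after all informative ones, in offset order. The fitted model
stores the training-time ranking, and prediction reuses it; selection
is never re-run on test data, which would leak label information.

## Evaluation protocols

Headline metrics are precision, recall, F1 and the Matthews correlation
coefficient, computed from confusion counts; AUROC/AUPRC are
deliberately not headline outputs so results stay comparable with
predictors that return only hard labels. Degenerate denominators
(no predicted positives, a single-class transcript) yield 0 by
convention — per-transcript evaluation makes this unavoidable, since a
transcript can receive zero predicted positives.

* `per_transcript_average()` scores each transcript separately and
  averages unweighted, matching practical use where predictions are
  made one transcript at a time.
* `build_imbalance_subsets()` + `robustness_curve()` rebuild test sets
  at negative:positive ratios 1:1 … 9:1 (all positives kept, negatives
  drawn uniformly without replacement, seeded) and trace F1/MCC
  against the ratio.
* `cross_validate()` runs stratified k-fold CV with SNP selection
  re-run inside every training fold.
* `feature_importance()` reports split-count importance (how many tree
  splits use each feature), which makes unused and constant features
  visibly 0; gain-based importance is available as an option.

## The synthetic corpus generator

`simulate_corpus()` generates corpora with exactly the statistical
structure the method exploits, so the whole pipeline is testable with
no downloads:

* transcript lengths lognormal with median ~2000 nt; sequence content
  uniform over A,C,G,U (DRACH then occurs at ~1.8% of positions);
* a nominal stop codon at 80% of the length; positive labels drawn
  from the DRACH candidates with weights from a normal bump at the
  stop codon (sd 10% of length), negatives being all remaining
  candidates — this makes the location features informative, the
  minimal structure for that purpose;
* a global negative:positive ratio of 10 by default, allocated across
  transcripts by largest remainder so the realised ratio is within 1%;
* SNP variants at background rate 0.05 per transcript position, with
  window offsets {−2, −1, 2} topped up to a 0.30 variant rate in
  positive samples.

What it does **not** emulate: real nucleotide composition and motif
context biases, transcript secondary structure, correlated SNP
placement, or any sequence-level difference between classes beyond the
motif. Passing tests on simulated corpora therefore demonstrate that
the machinery recovers planted location/SNP structure under a
realistic imbalance — not that the package attains any particular
accuracy on real transcriptomes, which requires the full experimental
dataset and real variant annotations.

The worked single-transcript fixtures (`simulate_worked_case()`)
reproduce only the published class sizes and confusion counts of the
c-Jun and CBFB (HIV-1) case studies with synthetic sequence content;
they exercise the evaluation arithmetic end-to-end.

## Numerical and design choices

* Coordinates are 1-based and fully closed on the mature transcript;
  window offsets are labelled −25…+25 with 0 at the candidate adenine.
* `T` is transliterated to `U` and sequences upper-cased on every
  input path; all other invariant violations are errors, never
  repaired.
* The k-mer denominator is the number of valid sliding windows
  (`L − k + 1` without padding) — "frequency" is otherwise ambiguous.
* The density block is appended after the chemical-property block, not
  interleaved with it; feature indices are therefore exposed as
  block-qualified *names* (`density_-3`, `loc_rel`, …), never bare
  column numbers.
* Fold assignment, subset draws and the simulator are all driven by
  explicit integer seeds; fitted boosters are serialised raw inside a
  versioned artifact so reloaded models predict bit-identically.
* Desk-scale problem sizes: the test-suite corpora run at roughly
  1,400–5,000 samples (40–200 transcripts) and the planted-SNP
  recovery check uses ~2,000-sample corpora over 20 seeds; these sizes
  are where the planted effects are comfortably detectable while the
  whole suite stays quick to run.

## A complete run

```{r pipeline}
sim <- simulate_corpus(sim_config(n_transcripts = 40, seed = 11))
table(sim$samples$label)

fit <- m6acs(sim$samples, sim$snp, m6acs_config(seed = 11))
fit

ranking <- fit$ranking
head(ranking[ranking$selected, ], 5)

pred <- predict(fit, sim$samples, sim$snp, type = "class")
evaluate_predictions(sim$samples$label, pred)$metrics
```

## Limitations

* The SNP features require variant positions already mapped to
  transcript coordinates; genomic liftover is out of scope.
* Comparator predictors are not reimplemented; published numbers for
  them are reference points only.
* Reproducing the full-scale published tables requires the original
  supplementary dataset plus Ensembl variant annotations; the package
  provides the pipeline (readers accept the published table layout)
  but ships no real data.
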