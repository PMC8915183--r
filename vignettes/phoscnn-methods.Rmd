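---
title: "Methods: models, parameters and design choices in phoscnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phoscnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phoscnn)
```

This vignette is the package's own account of its methods: what each
component assumes, which knobs matter, and where the design was
genuinely open and a choice had to be made.

## The prediction problem

A candidate phosphorylation site is an S, T or Y residue in a protein.
The classifier sees only the peptide window of length $L = 2n + 1$
centred on the site, with flank $n$ on each side; positions beyond the
protein termini are filled with the dummy residue `X` so all windows
share one length. This is a standard framing for PTM-site prediction:
the local sequence context carries most of the kinase-recognition
signal, and fixed-length windows let a convolutional model consume raw
sequence without any hand-crafted features.

Coordinates are 1-based and inclusive in all user-facing tables;
0-based arithmetic exists only inside `extract_window()`.

## Encodings

Two numeric representations are used, and they are mutually
convertible without loss:

* **One-hot** (`onehot_encode()`): a 20 × L binary matrix, rows in the
  fixed alphabetical one-letter order `A C D E F ... Y`. The padding
  symbol `X` is the all-zero column rather than a 21st row. This keeps
  the convolution filter height at exactly 20, which is what the
  architecture specifies; an explicit pad row would change every
  filter's geometry while encoding the same information.
* **Ordinal ("dictionary")** (`ordinal_encode()`): each residue mapped
  to 1..20 in the same alphabetical order, `X` to 0, giving an
  L-vector. This is the input to the classical baselines, which cannot
  consume raw sequence. The letter→code table ships as a JSON asset
  (`inst/extdata/aa_index.json`).

The alphabetical row order is a free choice — any fixed published
order yields an equivalent model — so the simplest canonical one is
used and documented.

## Dataset construction

`build_dataset()` composes four steps, in this order:

1. **Window extraction** for every positive annotation.
2. **Redundancy removal** within the positives: greedy incremental
   clustering in input order; a window joins the first retained
   representative with identity ≥ 0.7, else becomes a representative.
   Identity between equal-length windows is positionwise (Hamming)
   identity with `X`–`X` counting as a match. Because all windows have
   identical length by construction, the alignment machinery of
   CD-HIT-style clustering reduces exactly to this; implementing it
   directly makes the step deterministic and auditable. Dedup is
   idempotent and the survivor set is pairwise below threshold (both
   properties are tested against a brute-force all-pairs oracle).
3. **Negative sampling**: candidate pool = every unannotated residue
   of the same type on proteins that carry at least one positive
   (matching how the original negatives were drawn from
   positive-bearing proteins), window-extracted, deduplicated, purged
   of windows identical to a positive window, then sampled uniformly
   to exactly the deduplicated positive count. Residue-type matching
   (S negatives for the S model, etc.) is implied by the per-residue
   model structure. Negatives are fixed once per dataset build rather
   than re-drawn per validation repeat; the protocol leaves this open,
   and fixing them keeps every scheme comparable on one dataset.
4. **Merge and shuffle** under the build seed.

Cross-set redundancy (a negative similar-but-not-identical to a
positive) is intentionally only removed at exact identity: removing
near-duplicates across classes would delete precisely the hard
negatives a classifier must learn to reject.

## The network

```
conv (F filters, 20×k, stride 1, no padding) → ReLU
→ max-pool 1×2 (stride 2) → flatten
→ dense (H, ReLU) → dropout → dense (2) → softmax
```

Geometry is symbolic and tested: conv map length $L - k + 1$, pooled
length $\lfloor (L-k+1)/2 \rfloor$ (floor division is what reproduces
the published 133 → 66 pair for the serine preset), flattened dimension
$F \cdot \lfloor (L-k+1)/2 \rfloor$, and a closed-form parameter count
$F(20k) + F + H \cdot F\lfloor (L-k+1)/2 \rfloor + H + 2H + 2$ that is
asserted against the actual weight arrays.

The output head is a 2-node softmax reporting the positive-class
probability. (The source narrative mentions a sigmoid output in one
sentence and a 2-node SoftMax in another; the two are equivalent for
binary classification, and the explicit 2-node softmax matches the
described architecture diagram, so that reading is implemented.)

Architecture-defining hyperparameters follow the published per-residue
optima (`cnn_preset()`): Ser (141, 9, 50, 200, 100 epochs), Tyr (121,
9, 100, 50, 80), Thr (41, 7, 200, 100, 40). Training details that the
protocol does not fix are package defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| optimizer | Adam | robust default for small networks |
| learning rate | 1e-3 | Adam's conventional step size |
| batch size | 64 | small-data friendly; one gradient step ≈ 1–2% of a typical dataset |
| dropout | 0.5 after the hidden layer | the classical rate for dense layers |
| weight init | fan-in-scaled normal | keeps ReLU pre-activations O(1) at any (L, k, F, H) |

The implementation is a purpose-built, fully vectorised R engine: the
convolution over one-hot input is expressed as a sparse patch-matrix
multiplication (each row of the patch matrix is the one-hot of one
k-mer), which makes both the forward pass and the weight gradient a
single sparse matrix product. Backpropagation is exact (verified
against central finite differences to ~1e-11) and training is
reproducible from the seed. Dropout uses inverted scaling and is
disabled at prediction time, so predictions are deterministic and
batch-composition invariant. A non-finite loss aborts with a
diagnostic rather than silently continuing.

## Transfer learning

`transfer_cnn()` implements shared-parameter transfer: the new model
inherits the pre-model's hyperparameters *and* weights, and every
layer — including the convolution — is retrained on the small dataset
(warm-start fine-tuning, not layer freezing; that is the stated
protocol). "Sharing the optimal parameters" could alternatively be
read as sharing hyperparameters only with random re-initialisation;
both readings are available via `init = c("pretrained", "random")`,
with warm start the default because it is the reading under which
transfer can actually help at very small n (and the paired-seed
acceptance property confirms it does on synthetic tasks).
`epochs = 0` returns the warm-started model unchanged, which is the
identity case used in tests.

## Baselines

SVM, naive Bayes, KNN, random forest and XGBoost consume the ordinal
encoding under the identical evaluation protocol. Their settings are
*not* inherited from any publication — none were stated — and are the
conventional defaults of each R ecosystem (radial SVM at cost 1,
k = 5, 200 trees, 50 boosting rounds at eta 0.3/depth 6), frozen in
`baseline_spec()` and echoed by every fitted object. SVM probabilities
come from the standard Platt-scaling option so AUC is computable
uniformly. `compare_methods()` guarantees shared splits: one
stratified 90/10 draw per repeat, reused by all six methods, with a
hash per repeat certifying the shared indices.

## Validation schemes and metrics

* **Metrics**: SE, SP, ACC and MCC from thresholded probabilities
  (default 0.5). The printed MCC formula in the source is
  typographically corrupted; the canonical MCC with denominator
  $\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$ is implemented. Any metric
  with a zero denominator is reported as `NA` — an explicit
  "undefined" marker — never as `NaN` arithmetic fallout.
* **ROC/AUC**: threshold sweep over distinct scores with ties grouped,
  trapezoidal integration; equals the Mann–Whitney concordance
  statistic exactly (tested by exhaustive pair enumeration, and
  cross-checked against an independent ROC implementation).
* **10-fold CV** is stratified by label — the protocol is silent, but
  stratification is what prevents class-empty folds on small balanced
  sets. Metrics are fold-averaged (matching "average prediction
  results"); pooled-confusion aggregation is available via a flag.
* **Leave-one-out** pools the n single-window confusions before
  computing metrics, since per-round metrics are degenerate.
* **Cluster-stratified repeats**: 90% of each K-means cluster to
  training, 10% to testing, repeated (default 100×). Clusters with
  fewer than 10 windows cannot give a non-degenerate 90/10 split; they
  are flagged and kept whole in training for that repeat.

## Motif analysis

**K selection.** The published "average entropy" elbow criterion is not
defined anywhere in the source, so the package uses the elbow (maximum
second difference) of the mean within-cluster squared distance across
`K_range`, emits the full criterion curve, and treats the selection
rule as a plug-in point — users can apply any rule to the curve.

**Position-specific enrichment.** A t-test on binary occurrence
indicators is unconventional but is what the protocol names; it is
implemented as a vectorised two-sample Welch test on the Bernoulli
indicators (sample variance $\frac{n}{n-1}f(1-f)$), with a standard
two-proportion z-test available via `test = "prop"`. Degenerate cells
(both samples constant) get p = 1 when equal and p = 0 when different.
Frequencies are reported over the 21-symbol alphabet (20 residues +
`X`) so each position's frequencies sum to 1.

**Filter PWMs.** For each filter, k-mers whose rectified activation
exceeds the per-filter 0.99 quantile (the activation threshold is
unstated in the source; a high per-filter quantile adapts to each
filter's scale) are stacked and converted to a PWM with 0.5
pseudocounts per cell. Motif recovery is scored as the best-offset
Pearson correlation between a learned PWM and the planted motif table.
Filters with no super-threshold activation are omitted with a notice.

## The synthetic generator

`generate_synthetic()` emulates the statistical structure the pipeline
is designed for, not any real phosphoproteome:

* proteins drawn i.i.d. from near-uniform human-proteome residue
  frequencies (lengths uniform in a configurable range);
* positive sites planted with a proline-directed motif — Proline
  probability 0.8 at offsets +1..+4 — reflecting the downstream-proline
  clustering characteristic of real phosphosite logos; 0.8 makes the
  motif strong but stochastic, the regime the method targets;
* each positive assigned to one of 3 latent clusters (default), whose
  flank positions within ±10 (outside the motif offsets) mix a
  cluster-specific residue-triplet fingerprint (weight 0.6) into the
  background — this is what makes cluster-stratified validation
  meaningful and recoverable;
* negatives are simply unplanted S/T/Y positions, so they share the
  background composition;
* the cluster ids and planted offsets live in a separate truth table
  that the pipeline never consumes.

What this does **not** emulate: homology between proteins, kinase
families with competing motifs, disorder preference of real
phosphosites, annotation noise, or class imbalance in the wild.
Consequently, passing the synthetic end-to-end checks demonstrates
that the machinery is correct and can recover planted structure; it
does not certify real-data accuracy, which depends on data that this
package deliberately does not fetch.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen so each
property is measured with adequate power while the whole suite stays
fast: the end-to-end recovery check trains on ~2,000 + 2,000 windows
at flank 20 with a 32-filter network (10 epochs); the transfer
property uses 20 paired seeds on 50 + 50-window small tasks against a
500-window test set; cluster recovery uses 600 windows per seed across
10 seeds. Determinism contracts: every stochastic operation takes a
seed; identical seeds give identical output, including byte-identical
serialised artifacts. Ties in max-pooling resolve to the earlier
position; ties in greedy dedup resolve to input order; ties in ROC
scores are grouped before integration. Degenerate inputs (single-class
training data, un-poolable geometry where
$\lfloor (L-k+1)/2 \rfloor = 0$, windows whose centre is not S/T/Y,
empty negative pools) are hard errors naming the offending quantity.

## Known limitations

* The greedy dedup is O(n·r) in the number of windows and retained
  representatives; fine for 10⁴-scale window sets, not for millions.
* The CNN engine is CPU-only and single-threaded by design; the
  published per-residue presets train in minutes at the dataset sizes
  used here, but very large corpora would favour a GPU framework.
* Welch-on-Bernoulli p-values are approximate for rare residues at
  small n; the two-proportion option shares the limitation. Exact
  tests are not provided.
* The elbow rule needs at least three K values; with fewer, the
  smallest K within 1% of the minimum criterion is returned.
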