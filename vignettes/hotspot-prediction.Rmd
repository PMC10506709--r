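---
title: "Predicting hot-spot residues from sequence windows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hot-spot residues from sequence windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotcnn)
```

## The model

A hot-spot residue is an interface residue whose alanine mutation changes
binding free energy by more than 2 kcal/mol. `hotspotcnn` casts hot-spot
prediction as binary classification of *sequence windows*: the label of a
residue is predicted from the `w × D` matrix of per-residue feature vectors
for the `w` residues centered on it. The central modeling assumption is
therefore that the signal distinguishing hot spots is contained in the
local sequence neighborhood — no structure, no explicit energetics, no
evolutionary profile. Features enter either as a 21-dimensional one-hot
encoding (20 standard amino acids in alphabetical one-letter order, the
catch-all `X` last) or as precomputed per-residue embeddings from a
pretrained protein language model, which this package deliberately treats
as a black box: embedding matrices are loaded from a keyed store and only
their shape is relied upon. Concatenating a 4096-dim embedding with the
one-hot block yields the 4117-dim combined representation.

The classifier is a one-dimensional CNN. Its kernels span the full feature
depth `D` and slide only along the window axis: with 'same' zero padding
each convolution preserves the window length, and each block ends in
max-pooling of size 2. The reference depth-3 architecture is

| block | kernels | kernel size | after pooling (w = 33) |
|-------|---------|-------------|------------------------|
| 1     | 64      | 7           | 16 |
| 2     | 16      | 5           | 8  |
| 3     | 4       | 3           | 4  |

followed by dropout (rate 0.5), a dense ReLU layer of 8 units and one
sigmoid output; 14 949 trainable parameters at `w = 33`, `D = 21`.
Training minimizes binary cross-entropy with RMSprop, checkpointing the
weights whenever the validation F1 at threshold 0.5 improves and stopping
after `patience` epochs without improvement.

## Dataset construction

Curated ΔΔG corpora are about 1:63 imbalanced, and the pipeline's data
assembly addresses that twice:

* **Stride (interval) undersampling.** The labeled non-hotspots, in
  deterministic (protein id, position) order, are sampled every
  `interval`-th item. Subsets at distinct offsets are provably disjoint.
  The working set joins all hotspots with the offset-0 subset truncated to
  the hotspot count, giving an exactly balanced evaluation pool; further
  offsets provide extra training negatives. The truncation matters: a
  strict stride over the full pool yields slightly more than one subset's
  worth, so subsets are cut to `subset_size` to keep them equal-sized.
* **SMOTE oversampling.** Each synthetic minority sample is
  `x_old + r (x_nn − x_old)` with `x_old` a uniformly drawn minority
  point, `x_nn` uniform among its `k` Euclidean nearest minority
  neighbors (self excluded, ties broken by stable order), and
  `r ~ U(0, 1)` on the open interval — so exact duplicates arise only
  through the `r = 0` test hook. SMOTE runs on *flattened* windows
  (`w · D` vectors), so synthetic examples are valid CNN inputs; exactly
  enough are generated to balance the classes. `k` defaults to 5, the
  setting of the original SMOTE publication.

The alternative to SMOTE is loss weighting with balanced inverse
frequencies `w_c = N / (2 N_c)`, which leaves the data untouched and makes
each class contribute equally to the expected loss.

Splits take a rounded fifth of the working set for testing and a fifth of
the remainder for validation (round half away from zero: 698 examples give
140 test, 112 validation, 446 training). Splits are **not** stratified by
class by default — the class counts of each partition are then themselves
random — because uniform sampling is the simplest protocol consistent with
slightly uneven published partition counts; a `stratify` flag exists.
Every assembly path enforces a leakage check: no (protein, position) key
of the validation or test partitions may enter training, and the extra
negative subsets are disjoint from the working set by the stride-offset
argument.

## Tunable parameters

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| ΔΔG threshold | 2 | kcal/mol | the field's hot-spot definition; strictly `>`, ties are non-hotspots |
| window width `w` | 33 | residues | best-performing width in the 21–41 sweep; must be odd, ≥ 8 for three pooling halvings |
| `interval` | corpus ratio floor (≈ 63) | – | one negative per imbalance unit keeps subsets disjoint and exhaustive |
| extra negative subsets | 4 | – | grows training fivefold while leaving ≥ 58 offsets unused |
| SMOTE `k` | 5 | neighbors | original SMOTE setting; must be < minority size |
| dropout | 0.5 | – | heavy regularization for small corpora |
| learning rate | 0.001 | – | RMSprop convention (ρ = 0.9, ε = 1e-7) |
| `max_epochs` / `patience` | 200 / 20 | epochs | generous cap; early stopping does the real work |
| batch size | 32 | examples | small-data default |
| threshold | 0.5 | – | symmetric operating point for balanced evaluation pools |

The training-loop values (epochs, patience, batch size, learning rate) are
choices of this package — the architecture itself does not pin them down —
and are recorded in every run log.

## Depth variants

`n_conv_layers` may be 2–5. Added layers are copies of block 2 (16 kernels,
size 5) inserted before the final block; the two-layer variant removes
block 2, so the entry block (64 kernels, size 7) and exit block (4 kernels,
size 3) always keep their shapes. Removing the *middle* layer rather than
the last is a genuine choice: it preserves the architecture's wide-in /
narrow-out funnel, which dropping block 3 would destroy.

## Numerical choices

* **Indexing.** Residue positions are 1-based everywhere — in annotation
  files, in `meta` tables, and in `extract_window()`. R is 1-based, so a
  0-based internal convention would add a conversion layer and a class of
  off-by-one bugs for no benefit.
* **Padding.** Out-of-range window rows are exactly zero, *not* the
  one-hot `X` column: a padded row (sum 0) is thereby distinguishable from
  every real residue row (sum 1 in one-hot coding).
* **Pooling ties.** Max-pooling ties keep the earlier position;
  gradient routing follows the same rule, so training is deterministic.
* **Initialization.** Glorot-uniform weights, zero biases, drawn under the
  config seed; two builds with the same seed are bit-identical.
* **Determinism.** Every stochastic step (splits, SMOTE draws, shuffles,
  dropout masks, initialization) runs under an explicitly scoped seed that
  never leaks into or reads the caller's RNG state. Identical config and
  seed reproduce byte-identical split manifests and training histories.
* **Degenerate metrics.** Any metric with a zero denominator (e.g.
  precision when nothing is called positive) is reported `NA`, not 0 —
  except inside the early-stopping comparison, where an undefined F1
  counts as 0 so that a useless epoch can never be "best".
* **Specificity.** Implemented as `TN / (TN + FP)`, the standard
  definition, which is also the only form consistent with jointly high
  published specificity and precision on imbalanced test sets.
* **AUC.** Trapezoidal integration over the tie-grouped ROC curve, which
  equals the Mann–Whitney pair-counting statistic (ties counted half);
  the test suite checks that identity exhaustively and against an
  independent ROC implementation.
* **SMOTE endpoint exactness.** With the `r = 0` hook, output equals
  `x_old` bit for bit; with `r = 1`, `x_old + (x_nn − x_old)` equals
  `x_nn` only to one floating-point round trip, and tests assert
  accordingly.

## The synthetic generator, and what the tests do (and do not) show

`generate_proteins()` emulates a curated corpus as random sequences over
the 20 standard residues, each carrying one planted odd-length motif whose
center residue is the hotspot. Non-hotspots are sampled corpus-wide from
all non-motif positions, so per-protein annotation density varies the way
it does in real corpora while the global imbalance is exact — important,
because pathological regularity (e.g. exactly `interval` negatives per
protein) would make stride sampling systematically pick same-rank
positions within each protein and confound position-in-protein with class.
ΔΔG values are drawn consistently with the labels (hotspots above, others
below the 2 kcal/mol cutoff) so fixtures exercise the real labeling path,
and `substitution_noise` / `background_hotspot_rate` corrupt the motif and
the labels respectively.

Under this generator the Bayes decision depends only on window content,
exactly matching the pipeline's assumption. End-to-end, the default
experiment (150 proteins of 80–120 residues, 10% motif corruption, 1:63
imbalance, width 33, depth 3, SMOTE balancing, 60 epochs with patience 12)
recovers held-out AUC ≳ 0.99 and F1 ≳ 0.95, and a label-permutation
control sits at chance. The permutation control permutes *every* label the
training procedure sees — gradient labels and the validation labels used
for early-stopping selection — because selecting the best checkpoint
against true labels would itself reintroduce signal; with a 60-example
test set the per-run AUC has standard deviation ≈ 0.075, so the control is
averaged over three independent permutations.

Passing these tests shows the machinery is correct and the learner can
extract a localized sequence signal at realistic imbalance. It does *not*
show that real hot spots are predictable at these accuracies: real signal
is weaker, distributed, and structure-dependent, and real corpora carry
measurement noise, redundancy and database-reconciliation ambiguity that
the generator does not model. Published headline metrics on curated data
additionally require the specific curated corpus and the pretrained
4096-dim embedding model, neither of which ships here.

## Problem sizes

The test suite and the acceptance script deliberately run at moderate
scale: the assembly arithmetic runs at the full published corpus
composition (349 hotspots, 22 244 non-hotspots, 120 proteins) since it is
cheap, while CNN training experiments use the 150-protein one-hot setting
above (training sets of ~1400 windows of 33 × 21), where a full training
run takes well under a minute on one CPU. Larger feature dimensions (4117)
flow through the identical code paths and are covered by shape-level
tests.

## Known limitations

* Sequence windows only: no structural neighborhoods, no interface
  geometry, no ΔΔG regression — classification only.
* The embedding model is consumed, never trained; reproducing published
  results on real corpora requires obtaining those embeddings externally.
* SMOTE in `w · D` dimensions interpolates in a space where one-hot
  blocks lose their simplex structure; synthetic windows are fractional
  and live only in the training set, never in evaluation pools.
* The CNN is implemented in vectorized base R. It is exact (gradient
  checks to 1e-9) and fast enough for corpora of this scale, but it is not
  a GPU framework and is not meant for millions of examples.
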