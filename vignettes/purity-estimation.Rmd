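---
title: "Estimating tumor purity from bulk RNA-seq with simulation-trained regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor purity from bulk RNA-seq with simulation-trained regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkpurity)
```

## The problem

Bulk RNA-seq profiles a tumor sample as one mixture: malignant cells together
with immune, stromal and other nonmalignant cells. The malignant fraction —
tumor purity — confounds essentially every downstream comparison, because a
difference between two cohorts can reflect composition rather than cell-
intrinsic biology. `bulkpurity` estimates purity directly from a raw bulk
count matrix using a small feed-forward regression network trained on
pseudobulk tumors of *known* purity, simulated on the fly from an annotated
single-cell corpus in which every cell carries a malignant/nonmalignant label
and a sample (patient) id.

The design has three ideas:

1. **Simulated supervision.** Summing single-cell count vectors produces a
   bulk-like profile whose purity is known exactly, because the labels of the
   summed cells are known. Drawing cells at a target purity `p` turns a
   labeled corpus into an unlimited stream of labeled training tumors.
2. **Within-patient mixing.** Cells for one simulated tumor are drawn from a
   single sample only. Mixing across patients would average away
   inter-patient heterogeneity and make the training distribution easier than
   reality; staying within-sample preserves it.
3. **Cross-modality feature selection.** Single-cell and bulk platforms
   disagree systematically for many genes. Training only on genes whose
   expression distributions look alike in per-sample pseudobulks and in a real
   bulk cohort keeps the network from keying on modality artifacts.

## Normalisation and the model input

Raw counts `x_ij` (gene `i`, column `j`) are normalised as

- CPM: `x_ij / sum_k x_kj * 1e6` — library size only; used by the feature
  screen.
- TPM: `(x_ij / l_i) / sum_k (x_kj / l_k) * 1e6` with gene length `l_i` in
  bases — used for model input so that bulk cohorts quantified at gene level
  are comparable.

The network consumes `log2(TPM / 100 + 1)`. The division by 100 rescales TPM
(which sums to 10^6 per column) into a range where the log transform neither
saturates nor leaves long tails; the pseudocount keeps zeros at exactly zero.
TPM is always computed on the **full** uploaded matrix before subsetting to
the model's feature set: the denominator then reflects the real library, and
feature genes missing from an upload are zero-filled rather than silently
renormalised away. That zero-fill choice is also why missing genes bias
predictions *downward*, which the inference guards are built around.

## Feature selection

Both cohorts are CPM-normalised on their shared gene universe (after
stripping Ensembl version suffixes, configurable). Two screens follow:

- **Prevalence.** A gene is excluded if, in either modality, at least 50% of
  samples have CPM < 1. The printed 50% is treated as the exclusion
  boundary: a gene low in exactly half the samples is out. Boundary behavior
  is unit-tested explicitly.
- **Distribution similarity.** For each surviving gene the two-sample
  Kolmogorov–Smirnov distance `D` is computed between its CPM values across
  bulk samples and across per-sample pseudobulks; genes with `D > 0.4` are
  excluded. `D` is computed exactly by breakpoint enumeration over the merged
  sorted values (ties handled), not by an asymptotic approximation; no
  p-values are involved, the screen is on the distance itself.

Prevalence runs before the KS screen; both are per-gene, so the order does
not change the result, only the stage counts that get logged. The surviving
genes, in the pseudobulk matrix's row order, become the frozen `feature_set`
that fixes the network's input layout forever after.

## Simulating labeled tumors

A simulated tumor needs two random numbers: target purity
`p ~ Uniform(0, 1)` and cell count `N ~ DiscreteUniform{200, …, 4000}`.
Uniform is the minimal-assumption reading for both, and both ranges are
exposed in `simulation_config()`. Then `Nm = round(p * N)` malignant and
`Nn = N − Nm` nonmalignant cells are drawn uniformly **with replacement**
(independently per class) from one sample, and their count vectors are
summed. Rounding is half-away-from-zero; no bias enters the labels because
the training target is the *realized* fraction `Nm / N`, not `p` (they differ
by at most `0.5 / N`). Samples with fewer than 5 malignant or 5 nonmalignant
cells are excluded from simulation entirely, since they cannot support the
whole purity range. The sample for each tumor is chosen uniformly among
eligible samples — not weighted by cell count — to preserve inter-patient
balance.

One seeded RNG threads through batch → tumor → cell draws in a documented
order (sample index, `p`, `N`, malignant indices, nonmalignant indices, then
the dropout mask), so any batch is replayable.

## The network and its training

The model is a multilayer perceptron `|features| → 32 → 16 → 1` with ReLU
after each hidden layer, no output activation, and dropout (probability 0.4,
inverted) on the **input layer only**, active only during training. Defaults
in `model_config()` are the tuned operating point:

| parameter | default | role |
|---|---|---|
| learning rate | 3e-5 | Adam step size |
| weight decay | 1e-5 | L2 penalty, added to the gradient (coupled Adam) |
| batch size | 64 | simulated tumors per step |
| input dropout | 0.4 | regularisation against single-gene reliance |
| window | 25 batches | sliding mean of the L1 loss |
| patience | 200 batches | stop when no new sliding-mean minimum |
| max_batches | 20000 | compute guard; patience normally fires first |

Training minimises the L1 loss — chosen over squared error because labels
inherit noise from malignant-cell assignment, and absolute error keeps such
outliers from dominating the gradient. Each batch is freshly simulated, so
the network never sees the same tumor twice and the train loss is itself a
noisy estimate; convergence is therefore judged on the 25-batch sliding mean.
Weights are snapshotted whenever that mean reaches a new minimum, and
training stops once 200 consecutive batches pass without a new minimum. The
returned model is the best snapshot, not the last state. Adam uses the
conventional β = (0.9, 0.999), ε = 1e-8; initialisation is the fan-in
uniform scheme U(±1/√fan_in), seeded. Single-threaded runs are exactly
reproducible: the same seed yields byte-identical serialized artifacts.

Raw outputs are unbounded (no output activation; the loss sees them
unclipped during training). At inference only, predictions are clipped to
[0, 1].

## Inference guards

Uploaded matrices rarely contain every feature gene. Missing features are
zero-filled, which systematically drags predictions down, so `predict()`
enforces two thresholds: above 1% missing it warns with the exact fraction;
at 20% or more it refuses outright rather than return a silently biased
number. Eval-mode prediction is deterministic — repeated calls agree exactly
— and a save/load round-trip reproduces predictions bit-for-bit (weights are
serialized as full-precision decimal strings for that reason).

## Evaluation metrics

`evaluate_purity()` reports MAE, RMSE, Pearson correlation and Lin's
concordance correlation coefficient
`CCC = 2σ_yŷ / (σ_y² + σ_ŷ² + (ȳ − ŷ̄)²)`, computed with population (1/n)
moments — the classical concordance definition; Pearson is denominator-
invariant to that choice. CCC is the headline metric because it penalises
location and scale shift, not just scatter: a model that ranks samples well
but compresses toward 0.5 has high Pearson and poor CCC. Correlations of
constant vectors are undefined and reported as `NA` with a warning rather
than coerced to 0.

## The synthetic data generator

No external single-cell atlas ships with the package; `generate_corpus()`
builds a corpus with the structural features the method actually relies on:

- two expression programs sharing lognormal base rates, with 30 malignant
  and 30 nonmalignant marker genes up-regulated 4-fold in their own program
  (and reciprocally down-regulated);
- per-patient lognormal gene effects (sd 0.15 on the log scale) creating
  inter-patient heterogeneity;
- per-cell library sizes uniform in 1000–2500 and negative-binomial counts
  (size 2), the standard overdispersed surrogate for UMI data;
- per-sample malignant fractions uniform in 0.15–0.9, roughly the purity
  spread seen across real glioblastoma cohorts.

Gene programs (base rates, marker assignment, lengths) are fixed by
`program_seed` independently of the cell-level seed, so a corpus and a
bulk cohort generated from the same configuration share one synthetic
biology. `generate_bulk_cohort()` mixes freshly drawn cells from *held-out*
synthetic patients at drawn purities and Poisson-resamples the profile — a
bulk-like cohort that shares programs but no cells with the corpus.
`inject_modality_shift()` multiplies a recorded random gene subset to give
the KS screen something it must catch.

The defaults (200 genes, 8 samples, ~300 cells per sample) keep the full
pipeline — selection, training to patience, evaluation on 200 held-out
pseudobulks — at around a minute on one CPU. These sizes are the package's
chosen study conditions for its own acceptance experiment: on 200 pseudobulks
from 2 unseen synthetic patients the trained model is required to reach
MAE ≤ 0.10 and CCC ≥ 0.9, which the test suite checks at fixed seed.

What the generator does **not** emulate: discrete malignant cell states,
realistic cell-type hierarchies within the nonmalignant pool, doublets,
ambient RNA, batch chemistry, or dropout structure beyond what the negative
binomial induces. Passing tests show the method's machinery is correct and
that the estimator recovers composition under faithful assumptions — not
that any particular accuracy transfers to real tumors.

## Numerical and design notes

- **Two convergence phrasings, one rule.** "Loss failed to decrease over a
  25-batch window" and "stopped after 200 batches without improvement" are
  reconciled as: track the 25-batch sliding mean, count batches since its
  last new minimum, stop at 200. Both printed constants are used as printed.
- **Training labels.** The realized `Nm / N` is used rather than the target
  `p`; it is the true malignant fraction of the simulated tumor.
- **Per-class draws.** Malignant and nonmalignant cells are drawn with
  replacement independently per class.
- **CPM on raw values.** The KS screen runs on raw CPM, not log-CPM.
- **Degenerate inputs.** Zero-total columns are errors naming the column;
  missing gene lengths are errors listing the ids; an empty feature
  selection is an error carrying the stage counts rather than an empty set.
- **Compositional limit of the shift screen.** Multiplying 10% of genes by
  20 inflates library totals ~2.9×, so after CPM renormalisation *every*
  gene's distribution moves; the screen then correctly rejects everything.
  Sensitivity to injected shifts is therefore measured per gene, and the
  all-rejected outcome is asserted as the pipeline's contracted error.
- **TPM for pseudobulks.** UMI-derived pseudobulks are TPM-transformed with
  gene lengths exactly as bulk is — one transform for every input, matching
  how a deployed estimator must treat uploads. At inference all genes enter
  the TPM denominator; restricting to protein-coding genes is left to the
  caller's input matrix rather than a hidden filter.

## Worked example

```{r example, eval = FALSE}
library(bulkpurity)

cfg <- fixture_config()
corpus <- generate_corpus(cfg, seed = 11)
lengths <- generate_gene_lengths(cfg)
bulk <- generate_bulk_cohort(cfg, n_bulk = 50, seed = 12)

sel <- select_features(bulk$counts, pseudobulk_per_sample(corpus)$counts)
glance(sel)

fit <- train_purity_model(corpus, sel$feature_set, lengths, seed = 7)
glance(fit)
autoplot(fit$training_log)

pred <- predict(fit, bulk$counts, lengths)
head(pred)
```

A full held-out evaluation — the same computation the acceptance script
performs — is shown in the README.

## Limitations

- Purity is defined by the corpus labels; label noise in a real corpus
  propagates into the supervision.
- The nonmalignant pool is mixed at its natural within-sample composition;
  varying immune/stromal ratios independently of purity is out of scope.
- The network is small by design; it estimates a single scalar and does not
  decompose the nonmalignant fraction into cell types.
- Training assumes raw (unnormalised) counts on both sides; pre-normalised
  inputs violate the TPM step's assumptions.
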