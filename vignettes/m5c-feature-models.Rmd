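---
title: "Feature encodings and evaluation protocol for m5C site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature encodings and evaluation protocol for m5C site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnam5c)
```

## The prediction problem

RNA 5-methylcytosine (m5C) classifiers operate on fixed-length windows
*R = R₁…R₂ξ₊₁* over {A,C,G,U}, centered on a candidate cytosine. The
package's conventions, shared by every encoder:

- Default half-width ξ = 20, so L = 41. The width is a parameter of
  `rna_windows()`/`read_windows()`, but the documented preset
  dimensionalities (120, 84, …, 287) are specific to L = 41: the
  position-specific encoders contribute L, L−1 and L−2 features, and ENAC
  contributes (L−4)×4.
- Positions are reported as −ξ…+ξ with 0 at the candidate C (internally
  0-based indexing is used).
- T is normalized to U on input. Degenerate IUPAC codes (N, R, Y, …) are
  rejected rather than imputed: silent imputation would bias every
  frequency-derived feature, and windows with ambiguous calls are better
  dropped explicitly (`on_invalid = "skip"`).
- Strict center checking (`strict_center = TRUE`) is the default. For
  negative sets whose windows may not be cytosine-centered the flag can be
  relaxed; the encoders themselves are center-agnostic.

## Encoders

**Position-specific propensities (PSNP/PSDP/PSTP).** `fit_propensity()`
estimates, for each k-mer *i* and start position *j*, the raw per-class
frequencies Z⁺ and Z⁻ and their difference Z = Z⁺ − Z⁻. No smoothing is
applied: a k-mer unobserved in a class contributes frequency 0, matching
the raw-frequency definition; with very small training sets the entries are
correspondingly noisy. The k-mer row order is frozen as lexicographic over
(A,C,G,U) and preserved by the TSV save/load round trip, so fitted matrices
are portable artifacts. Encoding is a per-position lookup in Z, giving
L−k+1 features; swapping the classes negates Z and hence every encoding.

Because these features are functions of the training labels, fitting them
on data that includes the evaluation fold leaks labels into the features.
`cross_validate()` therefore refits all propensity matrices inside each
training fold by default (`psp_fit = "per_fold"`). The alternative
(`"global"`) — one fit on the full dataset before splitting — is retained
because published pipelines often did exactly that and the difference is
worth measuring; on weak signal the global mode visibly inflates CV
accuracy.

**Compositions.** `encode_kmer()` (k = 1, 2, 3) returns overlapping k-mer
frequencies normalized by L−k+1 (a `counts` flag returns raw counts).
`encode_enac()` slides a `win`-length window (default 5 nt, the
conventional choice) with stride 1 and records the four nucleotide
frequencies per placement. `encode_xxkgap()` counts gapped patterns
(mono–gap–mono, mono–gap–di, di–gap–mono) *cumulatively* over gap sizes
1..kgap — this cumulativity is forced by the family's published feature
counts (mM with kgap = 2 spans 4×2×4 = 32 features, not 16). Each gap size
has its own number of valid placements, so each g-block is normalized by
its own placement count rather than pooled; the choice is frozen and the
per-block sum-to-one property is tested.

**Property-based encoders.** EIIP uses the fixed electron-ion interaction
pseudopotentials A 0.1260, C 0.1340, G 0.0806, and 0.1335 for U (U inherits
the T value). PseEIIP multiplies each of the 64 trinucleotide frequencies
by the sum of its three EIIP values; the identity
`PseEIIP = TNC * EIIP-sums` is used as a cross-module consistency test.
PC-PseDNC is the type-1 (parallel-correlation) pseudo-dinucleotide
composition: Θ between two dinucleotides is the squared property difference
averaged over the property set, tier θ_g averages Θ over all pairs at lag
g, and the 16 + λ components are jointly normalized to sum to 1. Properties
are standardized to mean 0 / variance 1 (population variance) across the 16
dinucleotides before use, so Θ is scale-free.

The bundled property table (`inst/extdata/dinuc_properties_synthetic.tsv`)
deserves a caveat: the 22 upstream property values used in the reference
pipelines are not redistributable, so the default table contains 8 exact
compositional scales (base, GC, purine, keto content of the dinucleotide)
plus 14 deterministic synthetic scales, and is labelled synthetic in its
filename. Any table with the same layout can be swapped in via the `table`
argument of `encode_pc_psednc()`; all structural guarantees (normalization,
zero-correlation limit, monotone w response) hold for any standardized
table, and the test suite checks PC-PseDNC values against an independent
double-loop oracle under both the bundled and a toy table.

**BE and NCP+ND** are position-major: 4 columns per position. The
nucleotide-density component at position i is the frequency of the base at
i within the prefix 1..i (so d₁ = 1 always and d ∈ (0, 1]); the published
formulation of the density is typographically garbled in places, and this
prefix-frequency reading is the established meaning in the encoding
literature.

## Fusion and presets

`fuse()` concatenates encoder blocks in spec order; column names are
prefixed by encoder id so fused vectors are auditable, and fusion is
associative. Each preset carries its expected dimension and `fuse()`
validates against it. Two published combination totals (476 for the six-way
combination, whose constituents sum to 467, and the 1,571-feature "all"
row) cannot be reconciled with the per-encoder dimensions under any
assignment we could construct (closest reconstructions range 836–1,668);
those two combinations are therefore not shipped as presets and are
excluded from dimension validation rather than forced.

No feature scaling is applied by default — propensity and frequency
features are already bounded in [−1, 1] — but a min-max scaler
(`scale = TRUE`) is available for SVM stability; it is fit on training data
only (per fold within CV) and recorded in the fitted model.

## Classifiers and evaluation

Four backends, defaults chosen to match common practice for this task: RBF
SVM with C = 1 and gamma = "scale" = 1/(n_features · var(X)) (the tuned
setting for the headline 287-feature combination is C = 1.5 with default
gamma); random forest with 100 trees; discrete AdaBoost (SAMME) over
depth-1 rpart stumps, 50 rounds — implemented in-package over rpart's
weighted trees; Gaussian naive Bayes via e1071, with constant columns
dropped first because a zero within-class variance makes the Gaussian
density degenerate.

Cross-validation is stratified ("equal division" leaves fold class balance
to chance; stratification keeps per-fold metrics defined for balanced
two-class designs and is standard). Reported Sn/Sp/Acc/MCC are means over
the k test folds; held-out decision scores are pooled into a single
ROC/AUC. Decision scores are the signed SVM margin and the positive-class
probability for the other backends. MCC is computed from the contingency
table (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)) because the popular
algebraic rewriting in terms of misclassification counts is fragile at the
boundaries; a test asserts the two agree to 1e−12 wherever the rewriting is
defined, and a zero denominator reports MCC = 0 with a warning. ROC uses a
descending-threshold sweep with tied scores sharing one step; trapezoidal
AUC then equals the normalized Mann–Whitney U with half-credit for ties
(tested, including against pROC).

`grid_search()` maximizes CV accuracy over a parameter grid at a fixed fold
assignment. Ties are broken toward smaller parameter values in grid order
(for `list(C = …, gamma = …)`: smaller C first), preferring simpler
models. Besides the exhaustive mode there is an axis-wise mode — one
parameter at a time, others held at their current best — matching how
C/gamma searches are usually reduced in dimension; the axis-wise result is
not guaranteed to be the global argmax and the full trace is returned.

The independent-test protocol (`evaluate()`) scores a disjoint test set
with a model refit on the entire training split — the conventional reading
of train/test evaluation.

## The synthetic generator

`generator_model()` defines per-position emission probabilities for each
class. The default geometry mirrors the class contrast reported around real
m5C sites: C and U enriched at the 20 upstream positions of positives, A
and G enriched downstream at half strength, center fixed at C in both
classes. `delta` is defined as the *positive-minus-negative frequency
difference*: designated nucleotides get +delta/2 in the positive class and
−delta/2 in the negative class, compensated uniformly on the remaining
nucleotides so each distribution still sums to 1. Under this
parameterization the planted contrast is exactly `delta` (no
renormalization shrinkage), which makes propensity parameter recovery a
sharp test: fitted Z entries at enriched positions are unbiased estimates
of `delta`, with binomial standard errors. An additive-then-renormalize
parameterization was considered and rejected because the realized contrast
would then depend nonlinearly on `delta` and the recovery analysis would
need a correction factor.

Positions are drawn independently by default — the simplest model in which
each encoder's signal is identifiable. `neighbor_rho` adds first-order
neighbor copying so dinucleotide/trinucleotide encoders and PC-PseDNC can
be exercised on genuinely correlated sequence; note it perturbs marginal
frequencies toward the chain's stationary mix, so recovery tests use
`neighbor_rho = 0`.

What the generator does *not* emulate: real transcriptome context
(codon structure, GC gradients, secondary structure), redundancy structure
between windows (real benchmarks deduplicate at an identity threshold), or
empirical enrichment profiles varying position by position. Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
recoverability of planted signal — not expected accuracy on biological
data, which is dominated by how informative real flanking sequence is.

## Problem sizes and numerical choices

Tolerances: exact count/lookup encoders are tested to machine precision;
PC-PseDNC and PseEIIP to 1e−12 (float accumulation); normalization and
standardization invariants to 1e−12/1e−9. Degenerate inputs are errors, not
NaNs: empty datasets, single-class training data, λ outside 1..L−2,
patterns wider than the window, delta driving a probability negative.

The test suite's study-scale checks use sizes chosen to make the
statistics sharp while keeping a full run comfortably fast on one CPU:
delta = 0.15 recovery at 1,000 windows per class (10-fold, 287-feature
SVM, C = 1.5, expecting ≥ 0.85 accuracy); the null (delta = 0) at 150 per
class over 20 repeats, compared with chance by a 3-standard-error band;
monotonicity in delta ∈ {0, 0.05, 0.10, 0.15} at 400 per class with 3
repeats per level; and propensity recovery at delta = 0.05 with 5,000 per
class, where the per-entry standard error is ≈ 0.009 so a joint 4σ bound
distinguishes bias from noise. `scripts/acceptance.R` re-runs the same
pipeline end to end from a single `--seed`.

## Known limitations

- Preset dimensionalities assume L = 41; presets on other widths validate
  against recomputed sums, not the published constants.
- The bundled PC-PseDNC property table is a synthetic stand-in (above);
  absolute PC-PseDNC feature values are not comparable across property
  tables, though all normalization properties are table-independent.
- AdaBoost uses depth-1 stumps and a simple SAMME weight update; it is a
  faithful small implementation, not a tuned gradient-boosting replacement.
- Pooled-score ROC across CV folds concatenates scores from differently
  trained models; this is the common convention but mildly optimistic
  compared with per-fold AUC averaging.
- The package predicts from sequence windows only; it does not scan
  transcripts for candidate cytosines or handle genomic coordinates.
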