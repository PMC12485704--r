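---
title: "Gauss-integral descriptors and flexibility models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gauss-integral descriptors and flexibility models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaussflex)
```

This vignette documents the scientific model behind `gaussflex`, the
numerical choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about behaviour on real
structures.

## 1. The backbone as a curve, and its invariants

A protein chain is reduced to its ordered Cα positions and treated as an
open polygonal curve. Two line segments of that curve subtend a mutual
solid angle on the sphere of projection directions; a quarter of that
(signed) solid angle over 4π is the segment pair's contribution to the
Gauss double integral of the curve with itself. We normalize so that the
pairwise quantity `W(i, j)` is the *total* mutual contribution of the pair
(both integration orders). This convention has two useful consequences:

* `|W(i, j)|` is exactly the probability that segments *i* and *j* cross in
  a projection along a uniformly random direction, which makes the
  Monte-Carlo crossing-count estimator (`acn_projection_estimate()`) an
  unbiased oracle for the closed form;
* the order-1 invariants are literally the writhe
  `I(1,2) = Σ_{i<j} W(i,j)` and the average crossing number
  `I|1,2| = Σ_{i<j} |W(i,j)|`.

**Numerical form.** We evaluate the solid angle as the signed area of the
spherical quadrilateral spanned by the four unit vectors connecting the
segment endpoints, splitting it into two triangles evaluated with the
van Oosterom–Strackee `atan2` formula. An earlier implementation summed
four arcsines of face-normal dot products; it lost up to ~1e-8 of precision
on nearly planar configurations (straight strand arms), whereas the
`atan2` form is stable to ~1e-15 and needs no clamping. Segments that share
an endpoint, or configurations whose connecting vectors degenerate below
1e-12, contribute exactly zero — adjacent segments subtend no solid angle,
so no exclusion window beyond the diagonal band is applied.

**Higher orders.** A chord pattern of order *k* is a perfect matching of 2k
index slots; its invariant is the sum over strictly increasing index tuples
of the product of the matched `W` entries, each optionally passed through
an absolute value. The engine evaluates order 1 and 2 in O(n²) and order 3
in O(n³) with O(n²) memory, by eliminating the outermost indices with
row-prefix/column-suffix cumulative tables and leaving at most a triple
loop per pattern. Every one of the 15 order-3 reductions is verified against
brute-force enumeration (all tuples, n ≤ 12) to 1e-10 relative error in the
test suite; a 500-segment chain completes all 30 descriptors in seconds.

**The 30-component registry.** The default registry is chain length `N`,
`I(1,2)`, `I|1,2|`, the three order-2 matchings in all four abs variants,
and the fifteen pure order-3 matchings: 1 + 2 + 12 + 15 = 30. The classic
descriptor family this follows is ambiguous about whether length is counted
among the 30 and whether any order-3 abs variants replace pure patterns, so
the registry is data-driven: `read_registry()`/`write_registry()` load an
alternative enumeration from JSON without code changes.

**Symmetries.** All descriptors are invariant to rigid motions; all except
`N` are invariant to uniform scaling; mirror reflection negates exactly the
descriptors with an odd number of non-abs chords. These are asserted as
properties in the tests (drift below 1e-8) and are useful diagnostics for
any registry swapped in.

**Chain breaks.** Traces flag Cα–Cα steps above 4.5 Å but are still treated
as one connected curve: the integral formalism needs a single curve, and
per-chain descriptor vectors are computed that way regardless. Users who
prefer to exclude fragmented chains can filter on the `breaks` field.
Residues lacking a Cα are skipped with a warning; alternate locations are
resolved by highest occupancy, ties alphabetically.

## 2. Flexibility from coordinate ensembles

Per-replicate RMSF uses an iteratively refined mean reference: all frames
are superposed (Kabsch, proper rotation enforced through the determinant
correction) onto the running mean structure, the mean is recomputed, and
iteration stops when the mean shifts by less than 1e-6 Å or after 10
rounds. `RMSF_i` is the root mean squared deviation of residue *i* about
its mean position. Replicates are averaged per residue, then residues
averaged, to one scalar per protein; the two averaging orders commute for
equal-length replicates, so this choice is presentational.

Binary labels call a protein *flexible* iff its scalar exceeds the
dataset-mean threshold — strictly: a value exactly at the mean is
non-flexible. The threshold is computed on the raw scalar; log-RMSF is only
a display transform.

For isotropic Gaussian noise of standard deviation σ per coordinate the
expected RMSF is σ√3; with 2,000 frames and 100 residues the recovered
profile is within 5% of that value despite the superposition absorbing six
rigid degrees of freedom, and a planted step profile is recovered with
correlation above 0.99. These figures are recomputed by both the test suite
and `scripts/acceptance.R`.

## 3. Descriptor statistics

Descriptor matrices are normalized to unit variance per column without
centering — the networks consume uncentered, variance-scaled features, so
each component keeps its characteristic magnitude. Centering happens only
inside the PCA. Zero-variance columns are left unscaled with a warning. The
pipeline default fits the scaler on the training pool and applies it to the
test set (leakage-safe); `paper_mode = TRUE` fits it on the whole dataset.

PCA is centered SVD with signs fixed by making each loading's
largest-magnitude entry positive. Clusters are k-means (k = 4, 10 restarts)
on the first two PC scores, the cluster count fixed to match the four
structural groups of the study design; the algorithm itself is an explicit,
replaceable stand-in because the source analysis reports clusters in PC
space without naming one. Labels are renumbered by descending cluster size
(ties by PC1 centre) so assignments are reproducible. Dominant secondary
structure is a majority vote with the fixed tie priority
helix > sheet > coil.

## 4. Model architectures and training

The attention-CNN maps the 30-vector, read as a single-channel sequence,
through four conv blocks (kernel 3, padding 1, stride 1, ReLU) with widths
32, 64, 64, 128 — interior widths are our choice; the final width of 128 and
the kernel/padding are fixed by the study design — so the positional axis
stays length 30 throughout. Additive attention (tanh projection to 64
dimensions, scalar score, softmax over the 30 positions) pools the
position-wise 128-dim features into one 128-vector, followed by a dense
layer and a sigmoid (classification) or identity (regression) head. The
plain CNN replaces attention with mean pooling; the RNN is a single-layer
GRU with hidden size 64 reading the 30 scalars sequentially; the SVM-RBF
baseline uses cost 1 and gamma = 1/(30 · var(x)), hyperparameters the study
leaves unstated. Regression reuses the classification hyperparameters with
an MSE loss.

All neural parameters are initialized from uniform distributions on
±1/√fan_in, seeded per model; Gaussian He-style initialization saturated
the GRU gates under inputs whose components carry large fixed offsets.
Training is mini-batch Adam (learning rate 1e-3, weight decay 1e-4 folded
into the gradient, batch 32), with gradients clipped to a global L2 norm of
5 — this markedly stabilizes the GRU, which otherwise trains to the epoch
cap with high run-to-run variance. Early stopping monitors validation loss
(patience 7, max 50 epochs) and restores the best-validation weights;
validation accuracy is used only for fold selection. After 5-fold stratified
cross-validation the best fold's configuration is re-initialized and
retrained on the full pool for that fold's early-stopped epoch count — no
validation set remains at that stage, so the epoch budget is the only
defensible stopping rule. Everything is funnelled through explicit integer
seeds; two runs with the same seeds are bitwise identical.

## 5. Evaluation

AUC is the rank statistic (ties count one half); its confidence interval is
a percentile bootstrap over 2,000 resamples of test indices, chosen because
the reported interval in the study is not attributed to a method. Average
precision is the step-wise area under the precision–recall curve. The
Youden threshold maximizes TPR − FPR with ties broken toward the lower
(more sensitive) threshold, and the confusion matrix at that threshold is
row-normalized. Calibration uses 10 equal-width probability bins, empty
bins omitted. Regression reports Pearson r, r², the least-squares slope of
predicted on true, and the *median* absolute error. Integrated Gradients
integrates the model's input gradient along the straight path from a
baseline (zero by default) using midpoint Riemann sums; 256 steps keep the
completeness gap below 1% of the largest prediction difference, and the
attribution is exact for a linear scorer at any step count.

## 6. The synthetic generators, and what the tests show

`make_backbone()` produces ideal helices (rise 1.5 Å, turn 100°, radius
2.3 Å, uniformly rescaled so the Cα step equals the requested 3.8 Å bond
length — the canonical parameters imply 3.83 Å, and we let the bond length
bind since the descriptors are scale-invariant), pleated strands, hairpins,
exactly planar zigzags (on which every integral vanishes), and fixed-step
self-avoiding random coils. Coils use a fixed 3.8 Å step and a 3.0 Å
non-bonded exclusion rather than Ramachandran sampling: only curve geometry
matters to the descriptors.

`make_trajectory()` adds i.i.d. per-residue Gaussian noise plus a random
rigid motion per frame — enough to force the superposition machinery to
work, with no pretence of physical realism (no correlated motions, no
anisotropy, no time structure).

`make_labeled_set()` emulates the unit-variance, uncentered descriptor
tables the models consume: each component fluctuates with unit variance
about a fixed component-specific offset (a spread over ±5 in a fixed
scrambled order), and the target depends on the centred values of the
informative components. The offsets matter: convolutions with content-based
attention are translation-invariant, so with fully exchangeable i.i.d.
columns an interior informative component is unidentifiable *in principle*
— no training procedure could find it. Real descriptor components are
distinguishable by their characteristic magnitudes after variance scaling
(chain length, crossing numbers and high-order correlations live on very
different scales), and the offsets reproduce exactly that property. Setting
`component_means = rep(0, 30)` restores the exchangeable variant.

Because the latent signal is Gaussian, the attainable performance is known
in closed form: the Bayes AUC is ½ + (2/π)·asin(ρ/√2) with
ρ = τ/√(τ² + σ²) (a trivariate-normal orthant identity), and the latent r²
is τ²/(τ² + σ²). The learnability tests run at Bayes AUC 0.95 (n = 1,000,
three informative components) and true r² 0.7; the attention-CNN reaches
holdout AUC ≥ 0.85 and the GRU test r² ≥ 0.5 under the study's training
protocol. Problem sizes throughout the tests (n = 1,000 rows, 2,000-frame
trajectories, traces of 8–100 residues) were chosen as the smallest at
which the statistical targets are stable.

**What this does not show.** Synthetic backbones and planted linear signals
exercise the machinery, not the biology: passing these tests says the
engine computes the invariants correctly and the models can extract a
signal of known strength, not that flexibility of real proteins is
predictable at any particular accuracy. The study-scale numbers (test AUC
near 0.77 against MD-derived labels) require the full trajectory database,
which this package can ingest through the same pipeline but does not ship.

## 7. Known limitations

* mmCIF reading relies on bio3d's reader, which is marked beta upstream;
  PDB is the reference path and both are cross-checked on fixtures.
* Chains with breaks are analysed as single curves (flagged, not split).
* The SVM baseline is not checkpointable to JSON (kernel state lives in
  `e1071`); refit it from data.
* Per-residue flexibility is out of scope: the target is one scalar per
  protein, matching the study design.
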