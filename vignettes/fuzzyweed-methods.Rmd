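---
title: "Methods: from image blocks to an interpretable fuzzy weed classifier"
author: "fuzzyweed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from image blocks to an interpretable fuzzy weed classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyweed)
```

`fuzzyweed` classifies small RGB image blocks of peanut plants and
broadleaf weeds. Its distinguishing design is that the final classifier is
not the decision tree itself but a Mamdani fuzzy inference system compiled
from the tree, so that the crisp, axis-aligned decision boundary becomes a
smooth surface a field controller can act on. This vignette documents the
models, the parameters that matter, the choices made where the published
description is silent, and what the test suite does and does not
demonstrate.

## The 98-feature block descriptor

Each block is an `H x W x 3` array of 8-bit intensities (`rgb_block`).
Three families of features are computed, in a fixed canonical order
(`feature_names()`):

* **Color (18)** — mean and population standard deviation of nine planes:
  R, G, B on `[0, 255]`; H, S, V from `grDevices::rgb2hsv()`, with hue as
  a fraction of a turn in `[0, 1)`; CIELAB L\*, a\*, b\* via sRGB with the
  D65 white point (`grDevices::convertColor()`). The population form of
  the standard deviation is used because a block is the entire population
  of its pixels; at `10^4` pixels the difference from the sample form is
  negligible but the convention must be fixed. Hue is averaged
  arithmetically, ignoring its circular topology — this mirrors common
  toolbox usage and is adequate for the mid-range greens of vegetation,
  but it is a documented caveat for hues near the wrap-around point.
* **Co-occurrence texture (16)** — the gray plane
  (`round(0.2989 R + 0.5870 G + 0.1140 B)`) is quantized into `G = 8`
  equal-width bins over its own range, and a gray-level co-occurrence
  matrix is accumulated at distance 1 for each of the directions 0°, 45°,
  90°, 135°, with symmetric pair counting; the four normalized matrices
  are averaged. Sixteen Haralick-family descriptors are computed with
  indices `i, j = 1..G` and base-2 logarithms (entropies in bits). A
  constant image has zero marginal variance; its correlation is defined
  as 0 (with a note). `G = 8`, symmetric counting and distance 1 are
  package conventions, not published facts: the source names the
  features and directions but not its quantization or symmetry settings.
  Symmetric counting plus four-direction averaging makes the 16 features
  invariant under 90° rotations, which the suite verifies to `1e-9`.
* **Wavelet texture (64)** — a one-level separable orthonormal Haar
  analysis (low-pass `(1, 1)/sqrt(2)`, high-pass `(1, -1)/sqrt(2)`,
  rows then columns) yields the LL, LH, HL, HH subbands; the transform
  conserves energy and reconstructs perfectly, and both identities are
  tested. Each subband is re-quantized over its own `[min, max]` before
  its GLCM is built — detail coefficients are signed and unbounded, so a
  shared absolute scale would put most subbands into one or two bins.
  The 16 descriptors per subband give 64 features named
  `<descriptor>_<band>`.

Block dimensions must be even (the transform halves them); no padding is
applied because the design block size is 100 × 100 px.

## Synthetic study conditions

The field images behind the published study are not deposited, so the
package carries a first-class generator (`class_spec()`,
`generate_block()`, `generate_dataset()`) that emulates what the feature
families respond to:

* per-pixel color = a base HSV triple plus Gaussian jitter (hue wraps,
  saturation/value clip), giving non-degenerate color means and
  standard deviations;
* an additive luminance texture field: white noise band-pass filtered to
  an isotropic annulus (relative width ± 20%) around a dominant spatial
  frequency, scaled to a chosen amplitude and added to the value channel
  before HSV→RGB conversion — this gives direct leverage on the wavelet
  subband statistics;
* one global seed streams into a deterministic per-block substream, so
  datasets are bitwise reproducible and independent of generation order.

The default two-class table (`default_class_specs(2)`) emulates the
crop-versus-weed setting at the published design scale — 50 blocks per
class of 100 × 100 px — with a peanut class (hue 0.32, saturation 0.60,
texture frequency 0.06 cycles/px) and a weed class (hue 0.22, saturation
0.35, frequency 0.25) chosen once as clearly separated in both color and
texture; the four-class table adds two intermediate weed classes with
smaller pairwise differences. These are fixtures, not biology: no
quantitative appearance statistics for the four real species are
published. The generator does not model leaf morphology, shadows, soil
background or field illumination (the original acquisition controlled
illumination physically with a sunshade), so a pipeline that separates
these synthetic classes demonstrates that the machinery — features,
selection, induction, compilation — works end to end, not that it would
reach any particular accuracy on real field imagery.

One generator-driven direction deserves note. For classes differing only
in texture frequency, the diagonal-subband energy rises with frequency,
as expected. The *sum entropy* of the HH co-occurrence matrix moves the
other way: texture inside the HH band leaves spatially correlated
coefficients whose co-occurrences concentrate (lower entropy), while for
low-frequency classes the HH band contains only the near-white noise of
8-bit quantization, whose co-occurrences are close to uniform (higher
entropy). The suite asserts this computed direction.

## Feature selection

`cfs_select()` maximizes the CFS merit
`M(S) = k r̄_cf / sqrt(k + k (k − 1) r̄_ff)`, with `r̄_cf` the mean
absolute feature–class correlation over the subset and `r̄_ff` the mean
absolute pairwise feature–feature correlation. Feature–class correlation
is the absolute point-biserial correlation against the class indicator
(for more than two classes, the mean over one-vs-rest indicators). This
correlation-based dialect is simpler and fully deterministic; the
best-known reference implementation instead discretizes and uses
symmetrical uncertainty, so selections are not expected to coincide with
it feature-for-feature. The search is best-first forward search with a
stall limit of 5 consecutive non-improving expansions (the common
default; the original study does not state its search settings), with
ties broken by canonical column order. On small tables the suite checks
the search against exhaustive enumeration of all subsets.

`pca_reduce()` standardizes to z-scores, eigendecomposes the correlation
matrix (signs fixed so each component's largest-magnitude loading is
positive), and keeps the smallest number of leading components reaching
`variance_kept` (default 0.95, the usual default of the tool family that
produced "18 components" in the original study). It ignores the class
column entirely, and the suite verifies invariance under label
permutation.

## Decision trees

All three inducers perform binary splits on numeric features, with
candidate thresholds at midpoints between consecutive distinct sorted
values and both children required to hold at least `min_leaf` (default 2)
samples. Ties between equally scoring splits are broken by canonical
feature order and then by the lower threshold, so fitting is fully
deterministic.

* **`j48`** scores candidates by gain ratio among splits with positive
  information gain, with the standard C4.5 guard that gain ratios are
  compared only among splits achieving at least the average information
  gain. Without the guard, near-useless end-cut splits win on their tiny
  split information and the trees grow spindly; the guard is part of the
  C4.5 family definition even though a terse description of the
  algorithm often omits it. Pruning is bottom-up subtree replacement by
  the pessimistic-error criterion with confidence factor `cf` (default
  0.25), using the normal-approximation upper confidence bound on the
  leaf error rate.
* **`rep`** grows with plain information gain and prunes by
  reduced-error pruning against the held-out validation set: a subtree
  is replaced by its majority leaf whenever that does not increase error
  on the pruning set (ties prune, preferring the smaller tree; a node
  reached by no pruning data collapses for the same reason).
* **`rt`** samples `ceiling(log2(M) + 1)` of the `M` features at each
  node, takes the best information-gain split among them, and never
  prunes; it is deterministic given its seed, and with `M` small enough
  that the sample is the full set it coincides with the unpruned
  information-gain tree.

The published experiment names a 20% "cross-validation" subset without
stating its use; here it is the REP pruning set, and optionally (with
`cf = NA`) the selection set for the J48 confidence factor.

`evaluate()` reports accuracy as trace over total of the confusion matrix
(the two-class `(TP + TN)/(TP + TN + FP + FN)` generalized), Cohen's
kappa with chance agreement from marginal products, and RMSE between the
leaf's class-frequency estimates and the one-hot observed encoding,
averaged over instances and classes — the convention under which a
probabilistic classifier's RMSE is comparable across class counts. The
suite checks all three against an independent implementation on random
confusion patterns.

## Compiling a tree into a Mamdani system

`as_fis()` maps a fitted tree onto a fuzzy system:

* one input variable per distinct feature, universe = the feature's
  training range padded by `band` on each side;
* one trapezoidal membership function per internal node, crossing 0.5
  exactly at the node's threshold with transition half-width
  `band * (universe width)`; a feature used by `k` nodes gets `k`
  functions;
* one rule per leaf: the conjunction of the conditions along the
  root-to-leaf path, with `is` on the branch the membership covers and
  `is not` on the other. By default the named function covers the left
  (`<=`) branch; `side = "above"` names the right branch instead, which
  is the convention of the published reference models.

The output variable spans `[0, n_classes]` with one trapezoid per class.
For two classes the shapes are `(0, 0, 0.4, 1.0)` and `(1.0, 1.6, 2, 2)`:
asymmetric on purpose, so that a single fully fired rule defuzzifies
strictly inside `(0, 1)` or `(1, 2)` as the published response surfaces
require. Inference is min–min–max with centroid defuzzification on a
fixed 1001-point grid of the output universe, which makes crisp outputs
bit-reproducible. The class is read off the unit interval the crisp value
falls into (`< 1` → first class), not by rounding to the nearest integer:
rounding would assign 0.7 to the second class, contradicting the stated
interpretation of the intervals, and the source's own account is
inconsistent on this point (its interval semantics are kept; its rounding
sentence is recorded as the inconsistency).

Away from every transition band exactly one rule fires, at strength 1,
and the fuzzy decision equals the tree's; the suite verifies 100%
agreement on 10^4 off-band points per compiled tree, at least 95%
agreement on uniform in-universe points at the default `band = 0.05`, and
convergence of the agreement toward 100% as `band` shrinks. The `band`
default is a package choice: the published membership plots are images
from which corner coordinates cannot be recovered, and behavior away
from the bands is invariant to it.

Degenerate cases are defined, not left to chance: inputs outside a
universe are clipped (with a warning); if no rule fires the output is the
universe midpoint (with an "uncovered input" warning); a leaf-only tree
is rejected, since it has no thresholds to fuzzify.

## The reference classifiers

Only a handful of numbers from the published two-class models are printed:
the rule tables (seven rules and three rules), the thresholds 19.31
(`ave_Bs`), 822.1 (`cluster_shade_LL`), 2.39 (`sum_entropy_HH`; a
neighbouring sentence says 2.36 — 2.39 is the default, and the
discrepancy is kept on record) and 0.36 (`ave_S`, second node).
`reference_rep_tree()` and `reference_j48_tree()` rebuild the implied
binary trees; compiling them reproduces the published rule counts and
antecedent patterns exactly, which the suite asserts. The remaining
thresholds of the seven-rule model are never printed; they are exposed as
documented `UNKNOWN-IN-PAPER` parameters with defaults chosen on each
feature's natural scale (the root `ave_Bs` threshold borrows 19.31 from
the three-rule model of the same feature). Feature ranges
(`ave_Bs` 0–40, `cluster_shade_LL` 0–2500, `sum_entropy_HH` 0–4,
`ave_S` 0–1, `correlation_LL` −1–1) are reconstruction choices spanning
the printed thresholds, and the placeholder leaf counts are labelled
synthetic — they never influence crisp inference.

## Problem sizes and defaults at a glance

| Parameter | Default | Where | Why |
|---|---|---|---|
| block size | 100 × 100 px | generator, extraction | published design |
| blocks per class | 50 | generator | published design |
| GLCM levels `G` | 8 | `quantize()` | toolbox-family default; unstated in source |
| GLCM distance / directions | 1 / four, averaged | `glcm_mean()` | published design |
| symmetric counting | on | `glcm_single()` | rotation robustness; unstated in source |
| split | 60/20/20 stratified | `split_data()` | published design |
| `min_leaf` | 2 | `tree_control()` | C4.5 default |
| `cf` | 0.25 | `tree_control()` | C4.5 default |
| CFS stall | 5 | `cfs_select()` | common default |
| PCA variance kept | 0.95 | `pca_reduce()` | tool-family default |
| fuzzy `band` | 0.05 | `as_fis()` | unrecoverable from published figures |
| defuzzification grid | 1001 points | inference | bit-stable centroid |

The test suite runs the full pipeline at the design scale (two classes,
50 + 50 blocks of 100 × 100 px, five split seeds) and smaller structural
checks on 16–64 px blocks; the whole suite completes in well under a
minute on one core.

## Known limitations

* The synthetic classes are fixtures; passing tests bound the machinery,
  not field performance. The published Tables of accuracies and selected
  feature lists cannot be reproduced without the original images.
* CFS here is the correlation dialect, not the symmetrical-uncertainty
  dialect; selections can differ from WEKA's.
* Hue statistics are non-circular; blocks with hues near the wrap-around
  point would bias `ave_H`/`std_H`.
* Greedy induction does not find minimal trees for interaction-only
  (XOR-like) structure; it fits such data only when grown to purity.
* Multi-class trees compile and infer, but only the two-class path
  carries the reference checks — the published study itself abandoned the
  four-class fuzzy system as too complex.
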