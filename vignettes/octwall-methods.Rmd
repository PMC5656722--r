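---
title: "Wall-layer segmentation and healthy-region detection in intracoronary OCT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall-layer segmentation and healthy-region detection in intracoronary OCT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intravascular OCT resolves the three tunicas of a healthy coronary wall
— intima, media, adventitia — as a bright/dark/bright triplet beneath
the lumen. In diseased segments an atherosclerotic plaque blocks the
view and usually only a single bright, rapidly attenuating layer is
visible. `octwall` exploits exactly this contrast twice: first it
extracts the three inter-layer interfaces everywhere around the
circumference, whether or not layering is truly present; then it asks,
per angular sector, whether the tentative contours and the image
statistics around them look like a layered wall. The result is a set of
closed contours (for thickness quantification where the wall is
healthy) plus a healthy/diseased partition of the circumference.

Assumptions worth stating up front:

* the lumen is star-shaped around its centroid, so one boundary point
  per ray is well defined;
* the wall interfaces are nearly parallel, nearly horizontal curves in
  the lumen-flattened polar sub-image, separated by at least a minimal
  gap `g`;
* interfaces coincide with extrema of the axial intensity gradient at
  scale `σ`;
* the imaging geometry is polar with one axial pixel size (µm/px), and
  a pullback provides neighbouring frames of similar anatomy.

## Stage 1 — simultaneous multi-layer segmentation

**Polar flattening.** The lumen contour (either supplied per frame as a
CSV, or extracted by a single-contour version of the same dynamic
program on the negated axial gradient of the native polar image) is
converted to Cartesian coordinates; its polygon centroid becomes the
ray origin. One hundred equiangular rays (column `c` covering the
half-open arc `[c, c+1)·3.6°`, column 0 on the +x axis) are sampled
bilinearly from the lumen boundary down to a depth of 1 mm
(`depth_px = ceil(1000/pixel size)`, so coverage is never short). The
guidewire shadow — the single darkest contiguous circular band in the
pullback-averaged below-lumen intensity profile, at most one run, dark
meaning below half the median profile, minimum three columns — is
masked and carried along.

**Edge costs.** Each column is convolved with the first derivative of a
Gaussian (`σ = 30 µm` by default, sampled to pixels, truncated at ±4σ,
sum-to-zero corrected, scaled so a unit intensity step responds with
magnitude 1). Positive responses mark dark→bright transitions with
depth, so the MA interface is a positive extremum and IM/AP negative
ones. The gradient image is replicated three times horizontally; a path
found over the triple width and then truncated to the central third is
approximately closed across the 0°/360° seam, which is how contour
closure is obtained without a circular DP. Costs are the min–max
normalisation of `±I'''_G` to [0, 1] over one shared global range, so
`C⁺ + C⁻ = 1` holds exactly and relative edge strength between columns
is preserved (the gradient features of stage 2 rely on that). Guidewire
columns carry no wall signal; their costs are replaced by the row-wise
mean cost of the unmasked columns so the optimal path interpolates
smoothly through the shadow rather than being attracted or repelled by
it.

**4D front propagation.** States are triples `(y1, y2, y3)` of
interface depths, restricted to `y1 + g ≤ y2 ≤ y3 − g` with
`g = max(1, round(45 µm / pixel size))` pixels. Column 0 is initialised
to zero cost; each subsequent column relaxes every admissible state
over the `(2N+1)³` displacement combinations (default `N = 3`), adding
per interface `ω_n (1 + κ|dy_n|)(C^±(x, y_n) + C^±(x−1, y_n + dy_n))`.
The smoothness penalty uses `|dy|`: a signed penalty would reward
downward drift, while the intent is to penalise any non-horizontal
displacement symmetrically. The weights `ω = (0.2, 1, 1)` de-emphasise
the IM interface, whose negative edge is easily confused with AP; the
gap constraint plus simultaneity is what disambiguates the two.
Backtracking starts from the admissible final state of minimal cost and
follows stored predecessors.

Because the transition cost is additive across the three interfaces,
the joint `(2N+1)³` minimisation is computed exactly as three nested
1-D minimisations (over `dy3`, then `dy2`, then `dy1` — `dy1`
outermost). With ascending `dy` loops and strict-inequality updates the
nested scheme realises the deterministic tie policy: lexicographically
smallest final `(y1, y2, y3)`, then lexicographically smallest
`(dy1, dy2, dy3)` at every backward step. The exhaustive-enumeration
oracle used in the tests implements the same policy independently (it
compares full candidate paths from the last column backwards), so on
tie-rich instances the two agree on the path, not just on the cost.

**Coarse-to-fine state space.** The dense state cube is `O(depth³)` per
column; at 114–223 rows that is impractical, so when the sub-image is
deeper than `max_dp_depth` (default 48) the cost maps are block-min
pooled along depth by the smallest sufficient integer factor `f`
(block-min keeps the attractive low-cost edge rows visible at the
coarse scale), the 4D program runs at the pooled resolution with
`g_coarse = max(1, round(g/f))`, and each interface is then refined at
full resolution by a banded single-contour pass around the upsampled
coarse path, chained with the full-resolution gap (`y2`'s band is
bounded below by the refined `y1 + g`, and so on). One subtlety: the
pooled program bounds steps per *pooled* column, i.e. `N·f` full-res
pixels, so its upsampled path may be unreachable under the
full-resolution bound `|dy| ≤ N`; the band therefore starts at
half-width `N + f` and doubles until a feasible path exists. The
returned contours always satisfy the gap and step constraints at full
resolution by construction. With `max_dp_depth = 48` the refined result
on noise-free phantoms stays within the same 2-px envelope as the exact
program (the package's tests measure this), and a frame segments in a
fraction of a second instead of minutes.

## Stage 2 — healthy-region classification

**Region and features.** For every column, region `R` spans row 0 (the
flattened lumen interface) to `ceil(300 µm / pixel size)` rows below
the AP contour, clamped at the image bottom (clamped columns are
flagged). Seventeen features are computed per column, keyed by name:
five Haralick statistics (contrast, homogeneity, correlation, entropy,
energy) of a 16-level, symmetric, normalised gray-level co-occurrence
matrix built from vertically adjacent pixel pairs within the column —
a column is one-dimensional, so the 1-px depth offset is the only
well-defined direction; the mean squared residual of a degree-1
least-squares fit to the intensity profile; the gradient values at the
LI (row 0), IM and MA depths; a monotony index (median absolute index
displacement under a stable descending sort — zero for a profile that
already decays monotonically, as diseased attenuation does, and
invariant to monotone intensity rescaling); the sum of negative
gradients over `R`; median intensities between consecutive interfaces
(interface rows inclusive, so the medians are defined even at minimal
gaps); and the three LI-to-interface distances in µm. Features are
min–max normalised with training-set statistics; at inference,
out-of-range values clip to [0, 1] and zero-range features map to 0.5.

**Relevance screen.** A shadow-feature procedure decides which features
matter: each random-forest run (ranger, impurity importance) sees every
feature alongside a shuffled copy; a feature scores a hit when it beats
the best shadow. Hits accumulate over runs until a two-sided binomial
test at `α = 0.01`, Bonferroni-corrected across features, confirms or
rejects the feature (or 1000 runs elapse). The whole screen repeats 51
times on random 100-column subsets; features confirmed in at least 26
repeats are relevant. The default classifier uses the fixed 8-name
relevant subset (texture contrast/homogeneity/correlation, the three
gradient features, the linear-fit residual and the monotony index); a
config switch (`features = "all17"`) uses everything, and
`boruta_select()` re-runs the screen on new data.

**Classifier, voting, morphology.** Discrete AdaBoost over depth-1
decision stumps, 100 rounds, with deterministic stump search
(tie-breaks: lower weighted error, then lower feature index, then lower
threshold) and early stopping once a round separates the training data
— further rounds would re-select the same stump with unchanged weights.
A column's final label is the majority over the classifier's verdicts
on frames `k−1, k, k+1`; at pullback ends the missing neighbour is
dropped and a 1–1 tie falls back to the current frame's own label.
Labels then undergo circular erosion (length 4) and dilation (length
9), anchored at `floor(K/2)`; guidewire columns are transparent during
morphology (temporarily taking their nearest unmasked neighbour's
value) and restored to `NA` afterwards. Note the kernel asymmetry: any
erosion-then-larger-dilation pair grows every surviving healthy run by
`K_D − K_E` columns in total, independent of anchoring — a deliberate
bias of the cleanup toward aggregating healthy regions, and the main
source of boundary false positives when the per-column classifier is
otherwise accurate.

## Evaluation metrics

Point-to-point contour error: per-column `|y_auto − y_ref|` along the
ray through the lumen centre, in µm, mean ± SD per interface, skipping
guidewire and unannotated columns. Layer thickness (intima `y1`, media
`y2 − y1`, adventitia `y3 − y2`): absolute error, signed bias, 95%
limits of agreement (`bias ± 1.96 SD`), and relative error against the
reference thickness (zero-thickness reference columns excluded and
counted). Healthy-arc agreement: Dice `2|A∩B|/(|A|+|B|)` on column
counts (two empty regions count as identical, `D = 1`), plus accuracy,
sensitivity and specificity with healthy as the positive class; a
zero-denominator metric is `NA` with counts intact. Metrics are
reported per frame and pooled over columns, since the aggregation level
(column / image / pullback) is a genuine reporting choice — the
acceptance script reports per-frame medians.

## The synthetic phantom

No clinical OCT data ships with the package, so every stage is
exercised on a generated phantom with exact ground truth. It emulates:
a lumen of ~1.3 mm radius with a low-order harmonic perturbation;
healthy arcs rendered as bright intima (0.80) / dark media (0.22) /
bright adventitia (0.70) with mean thicknesses 130/95/105 µm (the scale
of adult coronary tunicas), smooth angular variation and a bounded
random-walk drift along the pullback; an exponentially decaying
periadventitial tail; diseased arcs as a single bright, layerless,
attenuating slab at least 600 µm thick; multiplicative gamma speckle
(mean 1, SD 0.2 by default — a standard surrogate for fully developed
speckle); and a 24-A-line guidewire shadow zeroed below the lumen.
Scanner presets follow the two common polar geometries (4.5 and
8.8 µm/px); the cohort generator mixes fully healthy, fully diseased
and partly diseased vessels and mirrors a 14-pullback training /
26-pullback testing protocol with 10 frames per pullback.

What the phantom does **not** model: tangential catheter incidence and
eccentric-beam blurring, catheter sheath reflections, stents,
bifurcations, thrombus, spatially correlated speckle, and — most
importantly — *gradual degradation of layer visibility*. Phantom
healthy arcs are always crisply layered, so the per-column classifier
is nearly perfect on them and the residual labelling errors are
boundary effects of the morphological cleanup (see above). Passing
tests therefore demonstrate correctness of the machinery and recovery
under speckle, not clinical-grade robustness; in particular the
false-negative-dominated error profile seen on real vessels with
blurred layering (which makes specificity exceed sensitivity there) is
not reproduced by this generator — on the phantom the ordering
reverses, sensitivity ~1 against specificity slightly below 1.

## Numerical choices and degenerate inputs

* Convolution boundary: reflect padding along depth, which suppresses a
  spurious edge at row 0 (the lumen interface is already a strong
  positive edge just above the sub-image).
* Normalisation scope for the cost pair: global over the replicated
  matrix (not per column), preserving inter-column edge strength; a
  constant gradient degenerates to both costs ≡ 0.5 with a warning.
* `gap_px = max(1, round(g_µm / pixel size))`; depth and margin use
  `ceil` so coverage promises hold.
* All tie-breaks are deterministic (documented above), so a fixed seed
  and config reproduce byte-identical CSV outputs.
* Degenerate inputs: frames with no intensity or no dynamic range raise
  "no lumen detected"; a state space emptied by the gap constraint
  raises "depth too small for gap constraint"; a constant feature maps
  to 0.5 with a warning; single-class training data is an error; the
  enumeration oracle aborts beyond its extension bound.
* The monotony index uses a stable sort (ties keep original order) and
  the even-count median is the mean of the middle two.

## Problem sizes used by the tests

The oracle-equivalence tests enumerate instances up to replicated width
6 and depth 10 (`N ≤ 2`, gap 1), jointly sized to keep exhaustive
enumeration under 10⁷ path extensions. Constraint and recovery tests
run on 100 speckled phantom frames and on 1 noise-free plus 10 speckled
seeds; the classifier study uses the full 14/26 × 10-frame protocol
(400 segmented frames). These sizes were chosen so the whole suite and
the acceptance script each complete in minutes on a single CPU while
still exercising every code path at the study's sample sizes.

## Known limitations

* The lumen extractor is a deliberately simple single-contour stand-in;
  frames with grossly non-star-shaped lumina (dissections, bifurcation
  takeoffs) should use externally supplied lumen CSVs.
* Contours are always produced, including over plaque, by design — they
  are *tentative* inputs to the classifier there, not anatomy.
* The morphological cleanup's net dilation (`K_D > K_E`) trades a small
  specificity loss at arc boundaries for suppression of isolated
  misclassified columns.
* Tissue-type characterisation (lipid/fibrous/calcium) is out of scope;
  the binary partition is intended as a front end for such methods.
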