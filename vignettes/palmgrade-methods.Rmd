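---
title: "Methods: color-vision ripeness grading of oil-palm fruit bunches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: color-vision ripeness grading of oil-palm fruit bunches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmgrade)
```

## The problem

Oil-palm fresh fruit bunches (FFB) are graded at harvest into four ripeness
classes — unripe, underripe, ripe, overripe — because oil content peaks at
ripeness. Inspectors do this visually: the fruit surface progresses from
deep violet through reddish black and red to reddish orange. `palmgrade`
implements an automated color-vision version of that judgment for outdoor
bunch photographs, in four stages:

1. **Segmentation** — separate fruit pixels from the spiky stalk structures
   ("spikes") using color markers in the a\*b\* chromaticity plane,
2. **Features** — summarize the fruit region as a 100-bin hue histogram,
3. **Reduction (optional)** — project the histogram onto leading principal
   components,
4. **Classification** — a single-hidden-layer perceptron maps features to a
   ripeness class.

Because outdoor light intensity varies strongly while hue is nearly
invariant under brightness scaling, hue is the sole feature basis.

## Segmentation: color markers in a\*b\*

Each training image is converted to CIE L\*a\*b\* (sRGB companding, D65
white point) and its chromaticity pixels (a\*, b\*) clustered with K-means,
k = 3 per image by default. All per-image centroids are pooled and
agglomeratively merged: while any two pooled centroids are closer than
`mergeRadius` (default 8 a\*b\* units), the closest pair is replaced by its
pixel-count-weighted mean. The survivors are the *color markers*; their
count is emergent from the data rather than fixed. Each marker is labeled
`fruit` or `spike` by the majority ground-truth region of the pixels it
attracts (synthetic data) or by an explicit labeling (real images, where no
truth mask exists). Segmentation of any image is then nearest-marker
classification of every pixel in a\*b\* Euclidean distance, ties to the
lowest marker index; the binary fruit mask multiplies the original image.

Two numerical choices matter here:

* **K-means initialization** is farthest-point: the first centroid is a
  distinct pixel color drawn under the seed, each later one the point
  maximizing its minimum distance to those chosen. Random-subset
  initialization converges to a local optimum whenever the draw misses one
  of several well-separated color groups (probability roughly 2/3 on a
  small three-group palette), and a segmentation stage should not lose a
  color group to initialization luck. Farthest-point keeps the algorithm
  deterministic per seed and recovers the exhaustive-partition optimum on
  separable palettes, which the test suite verifies by brute force.
* **Empty clusters** are re-seeded to the point farthest from its assigned
  centroid; iteration stops when assignments stop changing (max 300). The
  within-cluster sum of squares is recorded per iteration and is
  non-increasing.

* **Marker-set order invariance**: every per-image clustering uses the same
  derived sub-seed and pooled centroids are kept in canonical (a\*, b\*)
  order during merging, so the final marker set does not depend on the
  order in which training images are supplied.

## Hue features

Hue is computed per pixel with the arccos form
$$H=\cos^{-1}\frac{\tfrac12[(R-G)+(R-B)]}{\sqrt{(R-G)^2+(R-B)(G-B)}},
\qquad H \leftarrow 360^\circ - H \text{ if } B > G.$$
Substituting $u = 2R-G-B$ and $v = G-B$ shows the denominator equals
$\sqrt{u^2+3v^2}/2$, so $H$ is exactly the angle
$\operatorname{atan2}(\sqrt3\,v,\,u)$ of the pixel's projection onto the
plane orthogonal to the gray axis. The familiar max/min "hexcone" hue is
only a piecewise-linear approximation of this angle: the two agree at
multiples of 30° but deviate by up to about 1.15° mid-sextant. The test
suite therefore checks exact (1e-6°) agreement against an independent atan2
implementation and separately pins the hexcone deviation bound. The formula
is scale-free — multiplying a pixel by any positive constant leaves $H$
unchanged — which is precisely why hue tolerates outdoor lighting variance.

Achromatic pixels ($R=G=B$) make the denominator vanish (it is a positive
definite quadratic form in $u,v$); they carry no hue and are excluded from
histograms rather than assigned $H=0$, which would bias the first bin.

Fruit-region hues are binned into 100 half-open bins of 3.6°, normalized to
relative frequencies because fruit-region area varies per image. A bin
becomes a *feature* if its frequency is strictly positive in at least one
**training** histogram (an exposed threshold generalizes "positive" to
"above t"); selection is fitted on training data only and reused unchanged
on validation and test sets to avoid leakage. On real bunch imagery this
kind of occupancy rule retains roughly half the circle (the published
pipeline kept 59 of 100 bins); on the synthetic generator it typically
retains 50–60.

## PCA reduction (method MB)

Features are standardized to zero mean and unit variance with training
statistics, so the covariance of the standardized data is the correlation
matrix and its eigenvalues sum to q. The symmetric eigendecomposition is
sorted by descending eigenvalue; the retained count m is the smallest m
whose *residual* variance fraction $\sum_{i>m}\lambda_i / \sum_i\lambda_i$
drops to a threshold, with an explicit override available. (Stated with
ascending-ordered eigenvalues, the same quantity is the cumulative fraction
of the first q−m; retention thresholds therefore *decrease* as more
components are kept.) Zero-variance columns are dropped with a warning
before standardization. Projection always standardizes with the training
mean and standard deviation; training scores are pairwise uncorrelated with
variances equal to the eigenvalues, and the training mean row projects to
zero — all asserted in tests, with 3×3 eigenvalues cross-checked against a
closed-form characteristic-polynomial solver.

## The MLP classifier

A single hidden layer; processing element j computes
$net_j=\sum_i W_{ji}x_i (+b_j)$ and applies its layer's transfer function —
logistic sigmoid, hyperbolic tangent, or identity. Six combinations are
investigated, pairing a hidden transfer (logsig for CA/CC/CE, tansig for
CB/CD/CF) with an output coding:

| Combination | Output neurons | Codewords (unripe, underripe, ripe, overripe) |
|---|---|---|
| CA, CB | 4 | one-hot |
| CC, CD | 2 | 00, 01, 10, 11 |
| CE, CF | 1 | 1, 2, 3, 4 |

Decoding maps an output vector to the nearest codeword (Euclidean; ties to
the lowest class index), which for the scalar codings reduces to
round-and-clamp. Bias terms are included by default — standard practice for
this architecture — with `useBias = FALSE` restoring the literal bias-free
weighted sum.

**Training** is full-batch gradient descent on mean squared error with an
adaptive learning rate: a step that increases the training loss is undone
and the rate halved; otherwise the rate grows by 5%. The recorded training
loss is therefore non-increasing. Early stopping watches the validation
set: performance is classification accuracy with validation MSE breaking
ties (so epochs that reduce validation MSE while accuracy plateaus still
count as progress), and training stops after `patience` (default 6)
consecutive non-improving epochs or `maxEpochs` (default 1000), restoring
the best-validation weights. Weights initialize uniformly within
±1/√fan-in under the seed. Each configuration is trained from 5 seeded
restarts and the best-validation model kept, realizing the
highest-classification-accuracy selection rule reproducibly. The default
hidden width is 15; `growHidden()` re-derives it by network growing
(train at h = 1, 2, … until validation accuracy stalls).

## Synthetic data: what it emulates, and what it does not

The generator exists because the original 208-image bunch dataset is not
public. It renders, per image: an elliptical bunch filled with spike-colored
matrix, thin radial spike strokes protruding past the outline, and 60
overlapping fruit disks (radius 5–10 px at the default 120×160); fruit
pixel hue is circular-normal around the class center, brightness normal
around a class level, and the whole frame is multiplied by a per-image
lighting gain drawn from [0.85, 1.15], emulating outdoor illumination
variance. The ternary ground-truth mask (background/fruit/spike) partitions
every frame.

Defaults were fixed from the qualitative MPOB color descriptions before any
end-to-end measurement: hue centers 280° (deep violet), 350° (reddish
black), 10° (red), 30° (reddish orange) with 8° circular SD; fruit
saturation 0.85; value means 0.30/0.40/0.55/0.65 rising with ripeness;
spikes a dark brown RGB (0.24, 0.16, 0.09); background a low-chroma bluish
gray (0.45, 0.47, 0.52) chosen analytically so that its nearest a\*b\*
prototype is a spike marker, never a fruit marker (its chromaticity sits
~20 units from the brown spike region but 35+ from any fruit color).
Splitting into 120/28/60 is stratified by class even though only "random
division" is required of it: with a 60-image test set, stratification
removes a needless source of variance.

These images are deliberately easy relative to field photographs: classes
are well separated in hue, there is no specular highlight, occlusion, dirt,
inter-bunch variation, or mixed-ripeness surface. Passing tests therefore
demonstrate that the pipeline machinery is correct and leak-free — markers,
bin selection, standardization, PCA and early stopping all fit on
training/validation data only — not that field accuracy would reach the
same level. End-to-end grids on the synthetic default conditions saturate
near 100%, whereas the published experiment on real imagery peaked at
91.67% (full features) and 93.33% (PCA-reduced); the difference is the
difficulty of the data, not the method.

## Problem sizes and runtime choices

Unit tests run on 48×64 images and 8–52-image datasets; the end-to-end
acceptance test and `scripts/acceptance.R` use the full study design — 208
images of 120×160 at 52 per class, split 120/28/60, the six-combination
full-feature grid and a PCA grid over {2, 5, 10, 15} components — which
completes in a few minutes on one CPU. Images default to 120×160 rather
than the camera's 480×640 because accuracy depends on hue distributions,
not resolution; the generator supports larger frames.

## Known limitations

* Only PNG I/O is provided; the generator writes PNG natively.
* Marker labeling for real (mask-less) imagery must be supplied by the
  user; the package cannot infer fruit vs spike without ground truth.
* The MLP trainer is plain batch gradient descent — adequate for ≤60-input
  problems at these sample sizes, but no match for second-order methods on
  larger ones.
* `hca()` follows the two-decimal percentage convention of the original
  tables; comparisons of grids should use the unrounded accuracy only if
  recomputed from predictions.
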