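---
title: "Methods: land use and cover mapping from satellite image time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land use and cover mapping from satellite image time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucmap)
```

`lucmap` implements a complete map-production method for annual land
use/cover classification of vegetation-index satellite image time series:
SOM-based quality control of training samples, RBF-SVM classification into
class probabilities, Bayesian neighborhood smoothing, and rule-based
post-processing that enforces temporal consistency and detects secondary
vegetation. This vignette documents the model assumptions, the tunable
parameters, the synthetic world used for testing, and the design decisions
taken where the method leaves room for interpretation.

## Data model

A sample is one labelled pixel-year: four band series (NDVI, EVI, NIR, MIR)
of 23 observations each, spanning an agricultural year that runs 1
September to 31 August; a map year is named after its harvest (end)
calendar year. Feature vectors concatenate the bands band-major into 92
dimensions. Values are kept on the physical index/reflectance scale
(integer products divided by 10^4, so NDVI/EVI lie in [-1, 1]) and are
*never* standardized: the SVM kernel width default `gamma = 1/92` is
defined on this raw scale, and the SOM uses plain Euclidean distance in the
same space, so both stages see identical geometry. Nine training classes
(cerrado, fallow-cotton, forest, pasture, and five soy-* double/single
crop classes) can appear in training data; water, urban, sugarcane and
secondary-vegetation are auxiliary classes that only enter maps through
masks or rules. Raster code 0 is reserved for no-data.

## SOM quality control

Mislabelled ground samples are the main quality risk for classifier
training. The screening model assumes that a mislabelled sample keeps the
*spectral* profile of its true class, so in feature space it clusters with
samples of the true class, and the lattice neuron it maps to will be
labelled - by majority vote - with the true class rather than the claimed
one.

Training is classic online Kohonen learning: per presented sample, the
best-matching unit (BMU) and its lattice neighborhood move toward the
sample. Parameters and defaults:

* grid: square, side `ceiling(sqrt(5 * sqrt(n)))` (the usual ~`5 sqrt(n)`
  neurons heuristic); configurable, since the method itself does not fix a
  size.
* epochs: 100 passes in random order; learning rate decays linearly 0.05 to
  0.01.
* neighborhood: Gaussian over lattice distance. The scheduled "radius"
  (decaying linearly from `max(xdim, ydim)/2` to 1) is interpreted as the
  *3-sigma support* of that Gaussian, and updates with weight below 0.01
  are skipped. This matters: if the radius were the Gaussian's sigma
  itself, a final radius of 1 would keep adjacent neurons coupled with
  weight ~0.6 forever and small maps would collapse toward the grand mean
  instead of converging, k-means-like, to per-neuron cluster centroids.
  With the 3-sigma reading, late training updates essentially only the
  BMU, which is what the quality-control use of the map requires.
* initialization: codebook vectors are drawn (with replacement) from the
  data itself; presentation order and initialization are driven by one
  seed, so training is bit-reproducible.

Reliability is estimated over `n_runs = 20` independent trainings (run
seeds are `seed + run index`, so runs can be reproduced in isolation). For
each sample, the frequency with which its BMU carries each class label is
recorded; the per-sample frequencies sum to 1. A sample is retained iff
its own label's frequency is at least the threshold (default 0.8). The
frequency is attached to the sample's BMU, not to any coarser grouping of
neurons: the method's description of "cluster" membership is ambiguous on
this point, and BMU-label frequency is the reading that makes the
reliability table well-defined for every sample (a sample's own BMU always
maps at least that sample, hence is always labelled).

## SVM classification

One-vs-one decomposition (the conventional SVM default; the method does
not state a choice): one soft-margin binary SVM per class pair, each
solved *exactly* as the box-constrained dual quadratic program with the
installed `quadprog` solver (a tiny ridge, `1e-8` of the mean kernel
diagonal, keeps the Gram matrix positive definite). `C = 1` and
`gamma = 1/92` are the method's stated parameters and the package
defaults.

Class probabilities are not part of the SVM itself; the contract is only a
valid per-pixel probability vector. The package uses the standard
two-stage construction: a Platt sigmoid per pair, fitted by Newton descent
on *held-out* decision values (an internal stratified 3-fold split within
the pair, falling back to training values when a side has fewer than 3
members), then iterative pairwise coupling of the pairwise probabilities
into a class vector summing to 1. Both stages are seeded. Predicted labels
are the argmax of the coupled probabilities, ties broken toward the lowest
class code.

A numerical consequence of these literal parameters surfaced during
development: with `gamma = 1/92` on the raw feature scale the kernel is
nearly flat (`gamma * d^2` is of order 0.01 for these data), so for many
class pairs *every* dual variable sits at the bound `C` and there are no
free support vectors. The intercept then cannot be read off a free vector
and must be taken as the midpoint of the KKT bracket
(`max` of `y - g` over margin-violating samples vs `min` over
margin-satisfying ones). Getting this bracket exactly right matters: an
approximate midpoint shifts the decision threshold inside a class cloud
and can flip an entire class, seed-dependently. With the exact bracket,
synthetic-data accuracy degrades gracefully with sample size (about 0.89
cross-validated at 15 samples per class, 1.0 at 100).

Cross-validation is stratified k-fold (default 5), pooling held-out
predictions into one confusion matrix; classes with fewer members than
folds trigger a warning and unstratified assignment for those samples.

## Bayesian smoothing

Pixel-wise classification leaves low-confidence noise at borders and in
mixed pixels (confidence = margin between the top two probabilities). The
smoothing model treats, per class, the pixel's class *logit* `x` as a
Gaussian observation whose prior is centred on the neighborhood mean `m`
with the neighbors' sample variance `s2` acting as the observation
variance, giving the conjugate posterior

    (s2 * x + sigma2 * m) / (s2 + sigma2).

The method's source describes this stage only qualitatively; this
logit-scale conjugate form is an interpretation, adopted because it
reproduces every stated property: `sigma2 = 0` changes nothing; larger
`sigma2` increases the neighbors' influence; high neighbor variance
protects the pixel's own value. Numerical choices:

* probabilities are clamped to `[1e-6, 1 - 1e-6]` before the log-odds
  transform so hard 0/1 pixels stay finite;
* the neighborhood is Chebyshev radius 1 (a 3x3 window, default), truncated
  at raster edges, always *excluding* the center pixel; the variance uses
  the `n - 1` denominator;
* unanimous neighbors (`s2 = 0`) with `sigma2 > 0` pull the pixel fully to
  `m` - no variance floor is applied;
* smoothed probabilities are renormalized inverse logits; labels are the
  argmax of posterior logits with ties to the lowest class code.

`sigma2 = 10` is the method's stated global default. Smoothing operates on
the probability cube *before* masks and rules, matching the staging of the
original pipeline.

## Consistency rules

Masks overwrite with precedence water > urban > sugarcane. The base-year
map is fused with the reference layers by five rules evaluated
first-match-wins (the Amazon-layer Forest rule must override the rest).
The ten trajectory rules rewrite per-pixel multi-year sequences over the
letters F (forest), C (cerrado), P (pasture), S (any of the five soy-*
classes) - fallow-cotton contains no soybean cycle and is deliberately
*not* S; it, the auxiliary classes and no-data are opaque to the rules.
Two rules create secondary vegetation (SV): forest signal returning after
a cleared episode.

The matching semantics are not printed in the method's source and were
fixed as follows: rules run in numbered order, one full pass each; within
a pass, each rule's left-hand pattern slides left-to-right over every
contiguous window, and starred positions are replaced immediately, so
later windows see earlier replacements. Two consequences are documented
rather than hidden: (i) under sliding semantics the short rules 1
(`C,F* => C,C*`) and 8 (`F,C* => F,F*`) fire inside the longer patterns of
rules 5-7 and produce the same printed right-hand sides before those rules
are reached - the outputs match the published worked examples either way;
(ii) a second full pass over the rewritten worked examples is a no-op,
which the test suite asserts. Masked pixels are frozen: they neither match
nor change. Rule application is single-pass (no fixed-point iteration),
the reading consistent with "applied sequentially".

## The synthetic world

The generator states the world the tests run in; its defaults are fixed
once and not tuned against outcomes.

* Mean seasonal curves per class are sums of at most two Gaussian bumps
  plus a baseline: forest NDVI high (>= 0.75) and nearly constant; cerrado
  intermediate with mild wet-season seasonality; pasture a stronger swing
  on a lower dry-season baseline; single-crop classes one NDVI peak (soy
  early, cotton late); double-crop classes two peaks with class-specific
  second-cycle amplitude and timing. EVI tracks NDVI at reduced amplitude;
  NIR increases with green biomass with small class-specific reflectance
  offsets; MIR runs anti-phase to NDVI (dry/bare surfaces are MIR-bright).
  Noise is independent Gaussian per observation, sd 0.05 for NDVI/EVI and
  0.03 for NIR/MIR, clipped to physical ranges.
* Mislabels are injected by *relabeling* (the series stays that of the
  true class) - exactly the error model the SOM screening assumes.
* Scenes are rectangular patch mosaics with per-year labels, disjoint
  water/urban/sugarcane mask rectangles, an Amazon-reference sub-rectangle
  (Forest / Non-Forest / Deforestation derived from first-year truth plus
  declared deforestation rectangles) and a Cerrado-reference complement
  (Anthropized / Non-Anthropized). The default demonstration scene is
  30x30 with four years and one forest patch cut to pasture in year 3 and
  regrowing in year 4 - the secondary-vegetation showcase.
* One master seed drives everything; stage seeds are derived by fixed
  offsets so stages can be re-run in isolation.

What the synthetic world does **not** emulate: mixed pixels and spatial
spectral correlation, cloud/gap artifacts (the input product is a
gap-filled composite), class-imbalanced sample tables, inter-annual
phenological drift, and georeferencing. A green test here establishes that
the algorithms implement their stated contracts and recover a separable,
honestly noisy world - not that the real-data accuracy figures of the
original study are reproduced, which would require the deposited
state-scale data.

## Interfaces and artifact formats

Samples travel as tidy tibbles and CSV (fixed wide schema); class maps and
reference/mask layers are integer matrices with plain-text grid I/O plus a
`label,code,color` sidecar table; scenes and probability cubes are dense
arrays with `as_tibble()` converters. There is no shell entry point: the
exported functions (`run_pipeline()` and the per-stage functions it
composes) are the interface, which suits an R-native analysis package.

## Known limitations

* The SVM probability calibration quality depends on per-pair sample
  counts; below ~3 samples per side the sigmoid falls back to training
  decision values.
* The smoothing posterior is an interpretation of a qualitatively
  described procedure (see above); alternative readings (e.g. smoothing
  raw probabilities) would satisfy the identity-at-zero property but not
  the variance-weighting statements as cleanly.
* Trajectory rules are sliding-window and single-pass by decision;
  anchored or fixed-point variants are plausible alternative readings of
  the method and would change behavior only on trajectories longer than
  the printed worked examples.
* Rasters are in-memory matrices; the package does not read or write
  georeferenced formats.
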