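---
title: "Classifying early-glaucoma visual fields from voronoi images"
author: "vorofield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying early-glaucoma visual fields from voronoi images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Standard automated perimetry measures differential light sensitivity (in dB)
at a fixed set of retinal locations — 54 locations for the Humphrey 24-2
pattern, 59 for the OCTOPUS G1 program. After age-normalization each
examination is a vector of *sensitivity deviations* `r`, with losses negative.
Early glaucoma expresses itself as small localized clusters of loss (arcuate
bundles, nasal steps, paracentral scotomas) that global summaries can miss:
the mean defect `MD = -mean(r)` collapses all spatial structure, and the
square-root loss variance `sLV = sd(r)` measures inhomogeneity without
knowing *where* the inhomogeneity sits.

`vorofield` implements a spatial alternative: each examination is rasterized
into a **voronoi image** — a 61x61 pixel grid at one degree per pixel
covering the tested 30-degree radius, where every pixel takes the deviation
of its nearest tested location,

    V(i, j) = r[l*],   l* = argmin_l || (x_l, y_l) - (x, y) ||

— and a compact convolutional neural network (CNN) is trained on these
images to output the probability that the field is early-glaucomatous.
Gradient-based saliency maps (SmoothGrad, and its per-region average, the
piece-wise map) explain which parts of the field drove each decision.

## The voronoi raster

The pixel grid is fixed: row `i`, column `j` (1-based) map to degrees as
`x = j - 31`, `y = 31 - i`, so the field origin sits at image index (31, 31)
and the grid spans `[-30, 30]` degrees on both axes. Seeds are the pattern's
locations; each pixel is assigned to the seed minimizing Euclidean distance
in degree space. Two numerical choices are deliberate:

* **Ties** (a pixel equidistant from several seeds) go to the lowest seed
  index. This makes the assignment deterministic and stable under seed
  order; permuting the seed order relabels regions but never changes the
  rendered image.
* **Blind-spot locations** are excluded from seeding by default (their
  territory falls to neighbouring seeds) and from MD/sLV computation,
  following standard perimetric practice. Both behaviours are configurable.

No smoothing is applied to the raster: learning the appropriate local
averaging is exactly what the convolutional layers are for.

Left-eye (OS) examinations are mirrored about the vertical meridian into
right-eye orientation before rasterization, so one model sees one anatomical
orientation. Mirroring negates the seed x-coordinates, which is equivalent
to mirroring image columns; deviations stay attached to their locations and
the operation is an involution.

## The classifier

The CNN (1,985 trainable parameters) is:

    [conv 4@3x3 - BN - ReLU] x2 -> maxpool/2
    [conv 4@3x3 - BN - ReLU] x2 -> maxpool/2
    conv 4@3x3 - BN - ReLU -> global average pooling
    FC-32 - ReLU - BN -> FC-32 - ReLU - dropout(0.5) -> FC-1 sigmoid

with "same" padding, so the spatial maps shrink 61 -> 31 -> 16 across the
two ceil-mode pools. Batch normalization follows every convolution and the
first fully connected layer; the dropout layer and the output are left
unnormalized. The flat NN baseline reuses the dense head — two FC-32 ReLU
layers with dropout — on the concatenation of the deviation vector with MD
and sLV (`L + 2` features), deliberately discarding spatial structure.

Training minimizes binary cross-entropy with Adam (step size 1e-3, beta1
0.9, beta2 0.999 — standard defaults, as no tuning is required at this model
size) on mini-batches of 32. A subject-grouped, label-stratified 10% of
training subjects is held out as a validation split, and the checkpoint with
the lowest validation loss is the model returned; the epoch cap (default
100, 30 in the packaged experiments, where the small cohorts converge well
before that) is therefore a compute budget rather than a stopping rule. All
randomness — initialization, shuffling, dropout, the validation split — is
derived from explicit seeds, and two runs with the same seeds are
bit-identical. Inference disables dropout and uses batch-norm running
statistics, so scores are a pure function of weights and input, independent
of batching.

The whole engine (convolution, pooling, batch-norm, Adam) is implemented in
the package with small C++ kernels: no deep-learning framework is required,
and the model is small enough that a full cross-validated comparison runs in
minutes on one CPU core.

## Saliency maps

For a trained model and one voronoi image, the gradient map is the
derivative of the output probability with respect to every input pixel,
computed in inference mode. SmoothGrad averages `n` such maps at
Gaussian-perturbed copies of the input, with per-image noise scale
`sigma = sigma_r * (max(VI) - min(VI))`; defaults are `n = 500` and
`sigma_r = 0.05`. The piece-wise map replaces every pixel by the mean of the
SmoothGrad map over its voronoi region, yielding one importance value per
tested location. Three conventions:

* Gradients are kept **signed** through the averaging (an absolute-value
  mode exists but is off by default), and maps are min-max normalized to
  `[0, 1]` per map at the end.
* A constant raw map normalizes to all zeros — "no influence anywhere" —
  rather than dividing by a zero range.
* A constant input image has `sigma = 0`; SmoothGrad then degenerates to the
  plain gradient instead of erroring.

The map is taken for the early-glaucoma output probability; the control
class of a two-class sigmoid model carries the same gradient up to sign, so
no separate class argument is exposed.

## Evaluation protocol

Classifier quality is summarized by **average precision** (AP): the
step-wise area under the precision-recall curve, `sum((R_k - R_{k-1}) *
P_k)` over descending unique score thresholds with ties grouped. It is 1
exactly for a perfect ranking and invariant under monotone transforms of the
scores. A literal threshold-integral of the product `PPV(t) * TPR(t)` over
`t` in `[0, 1]` is also provided (`ap_threshold_integral()`) for comparison;
it is a different functional and is not used for reporting. Operating points
use the F1-style objective `PPV * TPR / (PPV + TPR)` — half the usual F1,
hence the same argmax — scanning observed scores as thresholds with ties
resolved to the smallest.

Cross-validation is grouped at the **subject** level (the stricter reading:
both eyes and all visits of one individual travel together), with folds
balanced by subject count and stratified by label. Deterministic index
methods (MD, sLV, MD+sLV) are scored once per fold; neural methods are
trained 5 times per fold (2 in the packaged scaled-down experiments) with
distinct seeds and each training is scored on the untouched test fold.
Reports aggregate the median and standard deviation over *all* cumulated
entries per method, not over fold means. Subject leakage is asserted inside
the run itself.

The MD+sLV combination has no canonical definition as a single score; the
package fits a two-feature logistic regression on the training fold
(labelled data available in every CV fold) and falls back to a parameter-free
rank-sum of the two indices when no labelled training set is supplied. Both
are interpretations, and the choice is explicit in the API.

## The synthetic cohort generator

Clinical perimetry archives cannot be redistributed with a package, so
`vorofield` ships a generator that emulates the *statistical structure* the
classifier relies on:

* **Controls**: per-eye offset `N(0.31, 0.5^2)` dB plus iid per-location
  noise `N(0, 1.85^2)` dB. The defaults are calibrated so a large control
  cohort has mean MD near -0.31 dB and mean sLV near 1.84 dB, the
  descriptive statistics of a real mixed control population.
* **Early glaucoma**: the same background plus additional loss at one
  defect archetype's locations, `N(-depth, 3^2)` with eye-level depth drawn
  from `N(12, 3^2)` dB. Archetypes are geometric index sets over the
  pattern — superior/inferior arcuate annuli (8-22 degrees), a nasal-step
  wedge, a paracentral cluster, and a diffuse variant applying a quarter of
  the focal depth everywhere — configuration data, not code.
* **Longitudinal structure**: each eye keeps its archetype across visits
  while the depth drifts as a slow random walk (sd 0.5 dB/visit), giving the
  within-subject correlation that makes grouped cross-validation matter.
* **Inclusion cap**: every emitted record satisfies MD < 6 dB, enforced by
  rejection; eye-level depths are truncated at the largest value whose
  expected MD stays a margin below the cap, mirroring how an inclusion
  criterion removes eyes that progressed past "early".
* Deviations are rounded to 0.1 dB, the resolution perimeters report.

What the generator does **not** emulate: fatigue and learning effects,
fixation losses, eccentricity-dependent noise, floor effects at absolute
defects, or realistic covariance between neighbouring locations beyond the
archetype structure. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline is correct and can recover strong localized
signal; they do not certify clinical discrimination performance, which must
be established on real perimetry archives.

## Packaged experiment sizes

The packaged experiments use a cohort of 20 control + 20 early-glaucoma
subjects with 3 visits each (120 examinations) under 10-fold
cross-validation with 2 training repeats and a 30-epoch budget — large
enough that every method's behaviour is measurable, small enough to run
comfortably on one CPU core. On this separable cohort all methods reach
median AP at or near 1.0, and with defect depth set to zero all methods fall
back into the prevalence regime (verified against a Monte-Carlo envelope of
the median-AP statistic under label exchangeability, which is wide here
because each test fold holds only four subjects).

## Known limitations

* The shipped G1 layout is a synthetic 59-location approximation of the
  OCTOPUS G pattern geometry, suitable for simulation and testing but not
  for aligning real G1 exports; the 24-2 chart is the standard published
  grid.
* The CNN's global-average-pooling bottleneck (4 features) is intentionally
  small; on large real cohorts a wider model may be warranted.
* Gradient saliency is piecewise-smooth: maps are well-defined almost
  everywhere, but finite-difference validation must avoid ReLU/max-pool
  kinks (the tests check the difference quotient's self-consistency before
  using it as an oracle).
* `sample()`-based draws depend on R's RNG; all public entry points take
  seeds and restore the caller's RNG state.
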