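---
title: "Binary arithmetic optimization for fundus-image feature selection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary arithmetic optimization for fundus-image feature selection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbscreen)
```

`rbscreen` chains five stages — synthetic data generation, image
preprocessing, optional colour segmentation, texture/filter-bank feature
extraction, and wrapper feature selection by a binary Arithmetic Optimization
Algorithm (AOA) — into a reproducible screening pipeline. This vignette
explains the models behind each stage, the parameters that matter, and the
design decisions taken where the methodology was genuinely open.

## What the synthetic generator emulates — and what it does not

Retinoblastoma screening works from fundus photographs: a bright, vignetted
retinal disc on a dark surround, with the disease presenting as a
yellowish-white lesion. The image generator reproduces exactly these cues: a
circular field with radial falloff and band-limited texture (white noise
box-smoothed at `texture_scale` pixels, default 4), and for the tumour class
a disc-shaped blob with multiplicative brightness gain (default 1.6, with
channel lifts pushing green/blue toward white) and finer internal texture.
Optional saturated discs emulate specular light spots. The tabular generator
plants `n_informative` columns whose class-conditional means differ by
`effect_size × noise_sigma` among class-independent Gaussian noise columns.

Defaults (64–128 px images, n = 200 samples, D = 50 features, 5 informative,
effect size 2σ, balanced classes) are desk-scale conditions under which a
texture-based classifier is learnable but not trivial: at effect 2σ a single
informative column separates classes only weakly, so selection genuinely
matters.

Real fundus photographs differ in ways the generator does not model: vessel
trees and the optic disc, camera-dependent colour balance, focal blur,
heterogeneous lesion shapes. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that selection recovers signal under
known ground truth — not that the feature set is clinically sufficient.

## Preprocessing

Median filtering uses edge-replication padding (window 3 by default); the
choice of padding is invisible away from borders and replication keeps
constant images fixed. Specular spots are removed by dilating the mask with a
3×3 square element — so the saturated rim around each spot is reconstructed
too — and filling the hole with *harmonic* diffusion: Jacobi sweeps replacing
each masked pixel by the mean of its four neighbours until the largest change
per sweep is below `tolerance` (1e−3 on the [0, 1] scale) or `max_iterations`
(500) is reached. Harmonic filling is the transport-free limit of fluid-style
inpainting: it satisfies the same "let the surroundings flow into the hole"
intuition while being analytically testable — the converged solution is
discretely harmonic, so it reproduces affine intensity fields exactly and
obeys the maximum principle (filled values never leave the range of the
boundary ring). A full vorticity-transport solver is deliberately out of
scope.

## Segmentation

The background-removal path converts RGB to HSV, stretches hue linearly to
[0, 1] (the simplest normalisation consistent with subsequent thresholding),
and chooses level thresholds by exhaustive maximisation of the between-class
variance on a 64-bin histogram — multi-level Otsu, tractable for up to four
levels. The hue-posterised image is clustered by K-means (K = 3) on RGB
triples: Lloyd iterations from a deterministic seeded farthest-point
initialisation (ties broken by lowest pixel index), stopping when the largest
centroid shift is below `kmeans_tol`. The "white" cluster is identified
data-drivenly as the centroid nearest (255, 255, 255) and overwritten with
`white_fill`, which makes the discard rule testable rather than nominal.
Segmentation is off by default on the feature path: the texture extractors
operate on the full field, and removing background is only useful when
downstream analysis needs it.

## Features

Gray levels are quantised uniformly to L = 8 bins before co-occurrence
counting; `C(i,j)` counts ordered pairs at each of the four standard offsets
(0,1), (1,0), (1,1), (1,−1), symmetrised and normalised. The four statistics
use the standard Haralick definitions (contrast, correlation with marginal
means/SDs, energy, homogeneity); a co-occurrence matrix with zero marginal
variance (constant image) reports correlation 0 with a `degenerate` flag
rather than erroring, so degenerate inputs stay processable.

The learned-feature analogue is an *untrained* seeded filter bank: valid-mode
convolution with `n_filters` random kernels (N(0, 1/kernel²) weights), bias,
ReLU, and non-overlapping max-pooling, flattened with provenance-bearing
names. Keeping the bank untrained makes the extractor deterministic given its
seed and puts the burden of discrimination on feature *selection*, which is
the package's focus; vector sizes follow from the configuration rather than
from any fixed architecture. Fusion is plain concatenation with disjoint
name spaces, handcrafted entries first.

## The binary Arithmetic Optimization Algorithm

The continuous AOA moves every coordinate of every individual around the best
solution: with probability `1 − MOA(t)` an exploration operator (division
`best/(MOP+ε) × mag` or multiplication `best × MOP × mag`, equal odds) and
otherwise an exploitation operator (subtraction/addition of `MOP × mag`),
where `mag = (ub−lb)·μ + lb`, `MOA(t) = Min + t(Max−Min)/T` rises from 0.2
to 0.9 and `MOP(t) = 1 − (t/T)^{1/α}` decays with α = 5. Updated coordinates
are clipped to the box.

Binarization was the genuinely open design problem, and three decisions
deserve explanation:

1. **The attractor is the elite bit string embedded at its box corner.** In
   a binary search the best-so-far solution *is* a bit vector; its raw
   continuous pre-image carries almost no information about which bits made
   it good (a mid-box coordinate emits either bit with near-even odds). All
   binary metaheuristics that work — binary PSO being the canonical
   example — use the best *bit pattern* as the attractor. Embedding the
   elite at `lb + bits·(ub−lb)` makes the around-best operators sample
   genuine neighbourhoods of the elite subset, with the MOP decay annealing
   the sampling radius.

2. **Transfer arguments are affinely mapped onto the function's effective
   domain.** The transfer functions themselves are the standard
   `S(x) = 1/(1+e^{−x})` and `V(x) = |tanh(x)|`. Fed a raw coordinate from
   the default box [0, 1], the sigmoid could only produce bit-1
   probabilities in [0.50, 0.73]: it could never favour excluding a feature,
   and never saturate enough for a solution to stabilise. The argument is
   therefore the coordinate centred on the box and scaled by a
   `transfer_gain` so the box spans roughly the function's active range —
   the same convention as the classic S/V transfer-function families, whose
   members differ precisely in this argument scaling. Defaults are gain 5
   for S and 8 for V, chosen once from the shapes' saturation behaviour.

3. **The V rule is velocity-style.** A V-shaped flip probability that
   depends only on the coordinate's position is blind to the current bit, so
   bits perform an unbiased random walk and good solutions cannot persist.
   Instead the V argument is the displacement between the proposed
   coordinate and the corner encoding the *current* bit: a coordinate at its
   bit's corner keeps the bit (flip probability 0), a coordinate at the
   opposite corner flips it almost surely — flips are implicitly directed
   toward the attractor, exactly as in V-shaped binary PSO where the flip
   probability is a function of the velocity.

The S rule resamples every bit as 1 with probability `S(arg)`; initial
populations binarize by thresholding at the box centre. Elitism is strict:
the recorded best-so-far fitness never increases, and equal fitness retains
the earlier solution (stable tie-break). The `literal` update mode implements
the alternative hill-climbing reading: each individual proposes a single-bit
flip (S) or an XOR with a random vector of per-bit probability `1/D`, at
least one flip enforced (V), accepting only strict improvements — note the
package minimises a cost, so acceptance is `f_new < f_current`.

## Wrapper fitness

Subsets are scored as `f = w·err + (1−w)·|S|/D` with `w = 0.99` — the
de-facto convention in wrapper feature selection, which weighs accuracy
heavily but breaks ties toward smaller subsets. `err` is the mean
misclassification rate of k-NN (k = 5) over 5-fold seeded *stratified* inner
cross-validation restricted to the selected columns; columns are standardised
with training-fold statistics inside each fold so no test information leaks
into the distances. The empty subset cannot classify and is assigned error 1.
Fitness values are cached per bit string (folds are fixed by the fitness
seed, so the cost is a pure function of the subset), which roughly halves the
wall time of a selection run.

## Evaluation

Metrics follow the defining formulas from the confusion counts; a metric with
a zero denominator is reported as `NA` rather than 0 or an exception, and
fold means are taken over defined folds only, with the contributing count
reported — silently averaging zeros would inflate nothing but deflate means
spuriously. Ten-fold CV uses a plain seeded shuffle (a stratified option
exists behind a flag); the 70/15/15 split rounds the validation and test
fractions and gives the remainder to training.

## Numerical choices and degenerate inputs

* Images are processed as numeric matrices/arrays on [0, 255]; diffusion
  internally rescales to [0, 1] and re-quantises on output.
* Constant-hue images short-circuit the Otsu search (single label,
  thresholds parked at the histogram edge).
* K-means guards against `K` exceeding the number of distinct colours, and
  empty clusters simply keep their previous centroid.
* All seeded operations run inside a scoped RNG context that restores the
  caller's random stream; per-item seeds are derived by a fixed counter
  scheme, so datasets are reproducible element-wise and independent of
  evaluation order.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script study conditions are: OneMax at D = 20
with population 20 and 200 iterations (20 seeded runs per variant); selection
recovery on tables with n = 200, D = 50, 5 informative columns at effect 2σ
(10 seeded tables per variant, population 20, 100 iterations); and an
end-to-end run on 40 synthetic 64×64 images with a reduced selector
(population 10, 30 iterations) over the 144 fused features. These sizes keep
a full verification pass in the minutes range on a single core while leaving
each property far from trivially satisfiable.

## Known limitations

* The filter bank is untrained; it is a fixed random projection, not a
  learned representation, and its features are weaker than a trained CNN's.
* The synthetic lesion model is geometric (discs); shape priors and vessel
  structure are absent, so segmentation quality on real fundus images is
  unvalidated.
* BAOA-V's convergence is slightly less reliable than BAOA-S's on exact
  binary optima (it reaches the OneMax optimum in roughly 19 of 20 seeded
  runs versus 20 of 20 for S at the shipped scale).
* Wrapper selection with k-NN inherits k-NN's sensitivity to feature
  scaling; standardisation is built into the fitness, but exotic feature
  distributions may still favour different inner classifiers.
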