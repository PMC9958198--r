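---
title: "Models and methods in pollenfuse"
author: "pollenfuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pollenfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenfuse)
```

# Overview

`pollenfuse` implements an explainable classification pipeline for airborne
pollen measured one particle at a time by a multi-modal optical detector.
Each particle record holds three signals: an elastic light-scattering image
(24 detection angles by a variable number of laser interactions, reflecting
grain morphology), a laser-induced fluorescence spectrum (32 wavelength
channels spanning 350–800 nm, acquired 8 times at 500 ns intervals,
reflecting grain chemistry), and fluorescence lifetime decays in four
spectral bands (350–400, 420–460, 511–572 and 672–800 nm, sampled at 2 ns
resolution).  The pipeline filters and aligns these signals, trains a
three-branch fusion convolutional network, attributes its decisions to
input coordinates with Integrated Gradients, aggregates attributions into
per-class explanations, and cross-examines spectral explanations against
laboratory reference emission spectra via rectangular-kernel resampling and
PCA.

A synthetic-data module stands in for the instrument and the
spectrofluorometer, so the whole pipeline is testable end-to-end with
known, planted class structure.

# Preprocessing

Raw records are filtered by four predicates, all index conventions 0-based
with inclusive bounds: maximum spectrum intensity above 2500; scattering
image narrower than 450 time columns; the time bin of the global lifetime
maximum inside [10, 44]; and the wavelength argmax of each of the four
retained spectrum acquisitions inside [3, 10].  Surviving records are
reshaped per modality:

* **Scattering** — the two outermost angle rows at each edge are dropped
  (24 to 20 rows, i.e. the angular window narrows to ±37.5° at 3.75°
  spacing), the image is centred on its global maximum and cut to 60
  columns on either side, giving 20 × 120; out-of-range columns are
  zero-filled (particles near the recording edge lose no data silently).
* **Spectrum** — the first four of the eight timed acquisitions are kept
  as a 4 × 32 image.  We keep the *earliest* acquisitions rather than
  averaging adjacent pairs because the signal decays rapidly after
  excitation and the earliest acquisition carries most of the
  class-discriminative energy; averaging would blur it.
* **Lifetime** — all four bands are shifted jointly so the global maximum
  lands at time index 4, then cut/zero-padded to 24 bins.

Two scalar feature sets are derived.  The four *lifetime features* are
noise-corrected band sums normalized by their maximum: the noise level per
band is the mean of the first two (pre-rise) bins of the aligned trace, the
corrected signal is summed with negative residuals clipped at zero, and the
four sums are divided by their largest, so one feature is exactly 1
whenever any band carries signal.  The *size feature* is the natural
logarithm of the total pixel intensity of the preprocessed scattering
image (proportionality constant one); for a convex scatterer the collected
intensity grows with the illuminated cross-section, making the log-sum a
monotone size proxy.  A configuration switch allows deriving it from the
spectrum image instead, for sensitivity analyses.

Ambiguities resolved as package choices: "scattering image size" is read
as the column count (rows are fixed by the detector); the four checked
spectrum maxima are the wavelength argmaxes of the four retained
acquisitions; raw lifetime traces default to 64 bins so that the filter
window [10, 44] is meaningful.

# The fusion network

The classifier has one convolutional branch per modality:

* scattering: two blocks of batch-norm → 3×3 convolution (padding 1) →
  dropout → 2×2 max-pool → ReLU, widening 1→10→20 channels; a 20×120 input
  flattens to 20 · 5 · 30 = **3000** features;
* spectrum: the same two-block design with 1→50→100 channels; a 4×32 input
  flattens to 100 · 1 · 8 = **800** features;
* lifetime: three 1-D convolutions over the 24 time bins with the four
  spectral bands as input channels, kernels 7/5/3 and channels
  4→70→140→200, arranged valid-conv → pool → valid-conv → pool →
  padded-conv, flattening to 200 · 2 = **400** features.

Each branch is reduced to 50 features by a fully-connected layer so that no
modality dominates by feature count alone.  The three 50-vectors are
concatenated with the four lifetime features and the size feature into a
**155**-vector, passed through one fully-connected layer, and classified
with log-softmax.  These four widths (3000/800/400/155) are asserted at
build time; a configuration whose shape arithmetic misses them fails with
an error naming the offending branch.

Kernel sizes and padding for the image branches are not dictated by the
flatten widths alone; we use 3×3 kernels with padding 1 so that only the
pooling determines spatial size — the unique choice under which the stated
flatten widths emerge from the stated channel counts.  Dropout defaults to
0.2.  Two further choices are deliberate:

* **Zero-initialized head.**  The final fully-connected layer starts at
  zero, so an untrained network emits exactly uniform log-probabilities
  and every head weight — hence every model-level attribution — reflects
  accumulated training evidence rather than random initialization.
* **Auxiliary-feature batch-norm.**  The four lifetime features (range
  [0, 1]) and the size feature (a log-sum around 12–14) enter the fusion
  vector through a batch-norm layer.  The convolutional features already
  arrive scale-normalized through their batch-norm stacks; normalizing the
  auxiliary scalars extends the same bias-prevention principle to them.
  Without it, the size feature's large constant offset makes its head
  weight drift track class difficulty rather than class size, and
  attribution signs become initialization artefacts.

Training follows a balanced protocol: 500 samples per class are drawn for
training (tests and examples scale this down), 10% of them held out for
validation; all remaining samples form the test set.  Batches contain 20
randomly chosen samples *per class*.  The loss is the negative
log-likelihood, optimized by stochastic gradient descent with learning
rate 0.001 and momentum 0.9, for up to 800 epochs with early stopping on
the validation loss (patience 50 epochs by default; both are configuration
knobs) and restoration of the best-validation parameters.  A fixed seed
makes initialization, splits, batch order and dropout — and therefore the
whole training history — bit-reproducible.

# Integrated Gradients

For input $x$, baseline $x'$ and target score $f$ (the target class
log-probability), the attribution of coordinate $i$ is

$$IG_i(x, x') = (x_i - x'_i) \cdot \frac{1}{M} \sum_{m=1}^{M}
  \left. \frac{\partial f}{\partial x_i}
  \right|_{x' + \frac{m}{M}(x - x')},$$

a right-endpoint Riemann approximation of the straight-line path integral
of the gradient.  The baseline is zero in every modality, denoting absence
of signal at the detector.  All five input tensors are attributed in one
pass; gradients are exact analytic back-propagated derivatives, evaluated
with dropout off and batch-norm in inference mode.  The default $M = 300$
keeps the completeness residual
$|\sum_i IG_i - (f(x) - f(x'))|$ below 1% of the attributed score
difference on trained models; the residual is recorded per sample.  By
default the *predicted* class is attributed (the question being how the
classifier reached its decision); the true label or any fixed class can be
attributed instead for error analyses.  We differentiate the log-softmax
output rather than the raw logit, matching the convention of reporting
log-probability scores for predictions.

# Model-level aggregation

Instance attributions are pooled per class — by predicted class by
default, since explanations describe decisions; pooling by true label is
available.  For every (class, feature) the signed mean and the mean
absolute attribution are computed; the ratio $s = \text{mean} /
\text{mean-absolute} \in [-1, 1]$ measures sign consistency and is coded
into five levels with symmetric cutoffs at ±0.25 and ±0.75
(strong positive / positive / mixed / negative / strong negative).  The
cutoffs are a package choice, recorded in the summary table.  Features are
ranked within each modality by mean absolute attribution (ties broken by
feature index), which drives the top-$k$ reports and the symbolic
heatmaps (glyph size = importance, colour = sign level); per-class mean
attributions over the scattering image are reshaped to 20 × 120 maps.

# Reference spectra, PCA and the size correlation

Laboratory reference emission spectra (350–800 nm at 1 nm; three
replicates per class) are made comparable with the instrument by filtering
with a rectangular kernel of half-width 14.51 nm — equal to the
instrument's spectral resolution, as stated, although a full-width reading
would also be defensible — and sampling at the 32 grid wavelengths
$\lambda_j = 350 + 14.51\,j$.  The kernel is an unweighted mean and edge
windows are clipped to the domain rather than zero-padded, which would
bias edge means downward.  The transformed spectra enter a mean-centred,
un-standardized PCA; three components are retained and reported with
their explained-variance ratios, per-spectrum scores and the wavelengths
of the local maxima of each component's absolute coefficients.

Finally, the per-class mean attribution of the size feature is correlated
(Pearson) against per-class reference mean grain diameters, pairing by
class name — the quantitative check that the network's use of the size
feature tracks real morphology.

# The synthetic-data generator

The generator plants known structure so that every downstream stage has a
ground truth:

* **Spectra** — each class is a sum of Gaussian emission peaks evaluated
  on the 32-point grid; the eight acquisitions decay geometrically
  (factor 0.5 per 500 ns step); reference spectra use the same peak model
  at 1 nm resolution.
* **Lifetimes** — per band, a sharp rise to a randomly placed peak bin
  (within the filter window) followed by exponential decay with the
  class's band constant; 64 raw bins at 2 ns.
* **Scattering** — a smooth ridge (Gaussian in angle and time) whose peak
  intensity grows with the squared sampled diameter and whose column count
  scales linearly with diameter; surface roughness adds multiplicative
  speckle.
* **Noise** — additive truncated-Gaussian (clipped at zero) on all
  modalities; the instrument's noise statistics are not published, so the
  level is a free parameter (default sd 25, well under 1% of peak
  amplitude).
* **Corruption** — a requested fraction of records per class violates
  exactly one filter predicate (dim spectrum, over-long scattering, early
  lifetime maximum, or an off-window acquisition argmax), so the filter
  pass rate on synthetic data equals one minus the corrupt fraction
  exactly.

The default study conditions (`defaultClassSpecs()`) comprise four classes
organized as two chemically-similar pairs: Alopecurus/Dactylis share the
grass-type 393.5 nm peak and identical lifetime profiles, Platanus/Carex
share a 437.1 nm peak and identical lifetimes, and the members of each
pair differ in grain diameter (25/40 and 18/36 µm medians, log-normal
sdlog 0.15 — a realistic diameter coefficient of variation) and, for
Dactylis, in scattering trace length.  This mirrors the operational
reality that chemically similar taxa are separable only through
morphology, and it is what makes the explanation stage meaningful: if the
planted spectra alone separated all classes, the network would never need
the size feature and its attributions would be noise.  With these
conditions the classifier reaches ≥ 90% held-out accuracy with 200
training samples per class within 10 epochs, recovers each class's
planted peak among its top-10 spectrum attributions, shows the widest
scattering-attribution time window for the long-trace class, and yields a
positive size-attribution/diameter correlation.

What the generator does *not* emulate: physically faithful Mie scattering,
hydration-dependent shrivelling, detector saturation, multi-particle
coincidences, or the heavy class imbalance of field data.  Passing tests
on synthetic data therefore demonstrate the correctness and sensitivity of
the pipeline's machinery, not field-level classification accuracy.

# Problem sizes and numerical choices

The shipped tests train reduced models: 200 training samples per class,
balanced batches of 20 per class and a 10-epoch budget for the end-to-end
recovery checks, and smaller still for unit tests — sizes chosen so the
planted structure is comfortably recoverable while the full suite stays
quick to run.  Convolutions and max-pooling run in compiled code (im2col
plus BLAS GEMM); gradients were verified against central finite
differences through every layer type.  Degenerate inputs are handled
explicitly: all-zero scattering images centre on the first column with a
warning, all-zero lifetime traces are an alignment error, zero-sum images
are a size-feature error (such records cannot pass the filters), and a
class with no pooled attribution records is omitted from summaries with a
warning.  Pooling ties in max-pool route gradients to the first maximum;
top-$k$ ties break by feature index.

# Known limitations

* The network is trained on CPU in R; wall-clock budgets keep the default
  examples at hundreds, not thousands, of samples per class.
* The completeness residual of Integrated Gradients is $O(1/M)$ and not
  exactly zero at finite $M$; it is reported rather than hidden.
* The five-level sign coding and the ±0.25/±0.75 cutoffs are
  interpretive conventions; downstream analyses that need the raw
  statistics should read `mean` and `mean_abs` from the summary table.
* Particle containers serialize to RDS (with CSV for tabular artefacts);
  no HDF5 bindings are used.
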