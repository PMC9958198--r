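# pollenfuse

Explainable multi-modal deep learning for single-particle pollen
classification.

Real-time pollen monitoring instruments record, for every airborne
particle, an optical fingerprint in three modalities: an elastic
light-scattering image (24 angles × N laser interactions, encoding grain
morphology), a laser-induced fluorescence spectrum (32 wavelength channels
over 350–800 nm, acquired 8 times at 500 ns intervals, encoding
chemistry), and fluorescence lifetime decays in four spectral bands.
Convolutional classifiers on such data are accurate but opaque; this
package is for aerobiologists and ML practitioners who need to know *why*
a classifier assigns a particle to a pollen class — which wavelengths,
lifetime bands and scattering regions carry the decision — and whether
those reasons agree with laboratory reference knowledge.

`pollenfuse` provides, as tested R code:

* **Preprocessing** of raw particle records: four quality filters
  (spectrum max > 2500; scattering width < 450 columns; lifetime argmax in
  [10, 44]; acquisition argmaxes in wavelength window [3, 10]),
  max-centred scattering crops to 20 × 120, the first four spectrum
  acquisitions as a 4 × 32 image, lifetime alignment to a common peak at
  time index 4 into 4 × 24, plus four normalized lifetime band features
  and a logarithmic size feature.
* **A three-branch fusion CNN** (channels 1→10→20, 1→50→100 and
  4→70→140→200 with 1-D kernels 7/5/3; branch flatten widths 3000 / 800 /
  400; per-branch reduction to 50; fused 155-vector; log-softmax output)
  trained by SGD (lr 0.001, momentum 0.9) on class-balanced batches with
  negative log-likelihood loss and validation-based early stopping.
* **Integrated Gradients** with a zero baseline: for target score `f`
  (the target-class log-probability),
  `IG_i = (x_i − x'_i) · (1/M) Σ_{m=1..M} ∂f/∂x_i` evaluated at
  `x' + (m/M)(x − x')`, with the completeness residual
  `|Σ IG_i − (f(x) − f(x'))|` reported per sample.
* **Model-level aggregation**: per-class mean / mean-absolute attribution
  statistics, five-level sign-consistency codes, top-k feature rankings,
  symbolic heatmaps and scattering attribution maps.
* **Reference-spectra cross-examination**: rectangular-kernel resampling
  of 1 nm laboratory emission spectra onto the instrument's 32-point grid
  (λ_j = 350 + 14.51·j nm), three-component PCA with coefficient-peak
  reports, and the Pearson correlation between per-class size-feature
  attributions and reference grain diameters.
* **A synthetic-data generator** that emulates the instrument and the
  spectrofluorometer with planted class structure (Gaussian emission
  peaks, band-specific exponential lifetimes, size- and
  roughness-dependent scattering, truncated-Gaussian noise, and an exact
  fraction of filter-violating corrupt records).

## Worked example

Four synthetic classes form two chemically similar pairs
(Alopecurus/Dactylis at 393.5 nm, Platanus/Carex at 437.1 nm) whose
members differ by grain size — so the classifier must combine chemistry
with morphology, as in operational monitoring:

```r
library(pollenfuse)

specs <- defaultClassSpecs()
raw   <- generateParticles(specs, nPerClass = 250,
                           corruptFraction = 0.1, seed = 1)
clean <- preprocessParticles(raw)
attr(clean, "filterReport")
#>              rule rejected
#> 1    spectrum_max       24
#> 2 scattering_cols       26
#> 3 lifetime_argmax       33
#> 4 spectrum_argmax       17
#> 5  total_examined     1000
#> 6      total_kept      900
#> 7  total_rejected      100
```

Exactly the 10% corrupted records are rejected (one record can trip
several rules).  Training the fusion network on 200 samples per class:

```r
cfg <- fusionNetConfig(nClasses = 4, trainPerClass = 200,
                       perClassBatch = 20, maxEpochs = 10,
                       patience = 5, seed = 1)
model <- trainFusionNet(clean, cfg)
ev <- evaluateModel(model, clean[trainTestSplit(model)$test])
ev$accuracy
#> [1] 0.95
ev$confusion
#>              Alopecurus Carex Dactylis Platanus
#>   Alopecurus       0.92  0.00     0.08     0.00
#>   Carex            0.00  1.00     0.00     0.00
#>   Dactylis         0.12  0.00     0.88     0.00
#>   Platanus         0.00  0.00     0.00     1.00
```

Held-out accuracy is 95%, and the residual confusion sits exactly where it
was planted: inside the chemically identical Alopecurus/Dactylis pair.
Explaining the predictions with Integrated Gradients and aggregating per
class:

```r
sp   <- trainTestSplit(model)
test <- clean[sp$test]
pick <- unlist(lapply(classOrder(model), function(cl)
  which(sampleLabels(test) == cl)[1:10]))   # 10 instances per class
att  <- integratedGradients(model, test[pick], steps = 300)
att
#> AttributionSet for 40 samples
#>   max completeness gap: 0.0171
#>   attributed class == predicted class for 100% of samples

su  <- summarizeAttributions(att)
topFeatures(su, "spectrum", 3)[, c("class", "row", "col",
                                   "wavelength_or_bin", "sign_level")]
#>         class row col wavelength_or_bin      sign_level
#> 1  Alopecurus   0   3            393.53 strong_positive
#> 2  Alopecurus   0   2            379.02 strong_positive
#> 3  Alopecurus   1   3            393.53 strong_positive
#> 4       Carex   0   6            437.06 strong_negative
#> ...
```

The top-ranked spectrum features land on the planted emission peaks
(393.5 nm for the grass pair, 437.1 nm for the other), measured at the
earliest acquisitions (rows 0–1) — the model found the planted chemistry.
Checking whether it also uses morphology:

```r
sizes <- data.frame(class = sapply(specs, function(s) s@className),
                    mean_diameter_um = sapply(specs, function(s) s@sizeMu))
sizeCorrelation(su, sizes)
#> [1] 0.897
```

The per-class size-feature attributions correlate strongly and positively
with the planted grain diameters: the network learned to read particle
size.  Finally, the reference spectra transformed to the instrument grid:

```r
ref <- generateReferenceSpectra(specs, replicates = 3, seed = 1)
pcaKnowledge(transformReferenceSpectra(ref))
#> SpectraPCA of transformed reference spectra
#>   explained variance ratios: 1.000, 0.000, 0.000 (total 100.0%)
#>   PC1 |coefficient| peaks at: 393.5, 437.1, ... nm
```

PC1 alone separates the two chemical groups and its coefficient peaks sit
on the two planted emission wavelengths — the same wavelengths the
classifier's attributions single out.

See the methods vignette (`vignettes/pollenfuse-methods.Rmd`) for the
model, its assumptions, all tunable parameters and the design decisions.

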