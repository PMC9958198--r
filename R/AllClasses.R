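#' @useDynLib pollenfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## ---------------------------------------------------------------------------
## ClassSpec
## ---------------------------------------------------------------------------

#' Synthetic pollen class specification
#'
#' A \code{ClassSpec} describes one pollen class for the synthetic particle
#' generator: the Gaussian emission peaks of its fluorescence spectrum, the
#' exponential decay constants of its four fluorescence lifetime bands, the
#' log-normal distribution of its grain diameter, the surface roughness that
#' textures its scattering image, and the mean number of laser interactions
#' (scattering time columns).
#'
#' @slot className class label.
#' @slot peakWavelengths emission peak centres in nm, each within 350--800.
#' @slot peakWidths Gaussian sigma per peak, nm.
#' @slot peakAmplitudes peak amplitudes, arbitrary detector intensity units.
#' @slot bandLifetimes decay constants for the four lifetime spectral bands
#'   (350--400, 420--460, 511--572, 672--800 nm), in ns; all positive.
#' @slot sizeMu median grain diameter in micrometres (log-normal location,
#'   \code{exp(meanlog)}); positive.
#' @slot sizeSigma log-normal shape parameter (sdlog) of the diameter.
#' @slot roughness scalar in [0, 1] controlling multiplicative speckle on the
#'   scattering ridge.
#' @slot nInteractionsMu mean number of scattering time columns for a grain
#'   of diameter \code{sizeMu}.
#' @slot noiseSd standard deviation of the additive truncated-Gaussian
#'   detector noise, intensity units.
#'
#' @seealso [classSpec()], [defaultClassSpecs()], [generateParticles()]
#' @export
setClass("ClassSpec",
  representation(className = "character",
                 peakWavelengths = "numeric",
                 peakWidths = "numeric",
                 peakAmplitudes = "numeric",
                 bandLifetimes = "numeric",
                 sizeMu = "numeric",
                 sizeSigma = "numeric",
                 roughness = "numeric",
                 nInteractionsMu = "numeric",
                 noiseSd = "numeric"))

setValidity("ClassSpec", function(object) {
  msg <- character()
  if (length(object@className) != 1L || !nzchar(object@className))
    msg <- c(msg, "className: must be a single non-empty string")
  np <- length(object@peakWavelengths)
  if (np < 1L)
    msg <- c(msg, "peakWavelengths: at least one peak is required")
  if (any(object@peakWavelengths < 350 | object@peakWavelengths > 800))
    msg <- c(msg, "peakWavelengths: peak centres must lie within [350, 800] nm")
  if (length(object@peakWidths) != np || any(object@peakWidths <= 0))
    msg <- c(msg, "peakWidths: one positive sigma per peak is required")
  if (length(object@peakAmplitudes) != np || any(object@peakAmplitudes <= 0))
    msg <- c(msg, "peakAmplitudes: one positive amplitude per peak is required")
  if (length(object@bandLifetimes) != 4L || any(object@bandLifetimes <= 0))
    msg <- c(msg, "bandLifetimes: four positive decay constants are required")
  if (length(object@sizeMu) != 1L || object@sizeMu <= 0)
    msg <- c(msg, "sizeMu: must be a single positive diameter")
  if (length(object@sizeSigma) != 1L || object@sizeSigma < 0)
    msg <- c(msg, "sizeSigma: must be a single non-negative value")
  if (length(object@roughness) != 1L ||
      object@roughness < 0 || object@roughness > 1)
    msg <- c(msg, "roughness: must be a single value in [0, 1]")
  if (length(object@nInteractionsMu) != 1L || object@nInteractionsMu < 24)
    msg <- c(msg, "nInteractionsMu: must be a single value >= 24")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd: must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RawParticleSet
## ---------------------------------------------------------------------------

#' Set of raw single-particle instrument records
#'
#' Container for unfiltered three-modality particle records as produced by a
#' Rapid-E style detector (or the synthetic generator).  Each record holds a
#' scattering intensity image with 24 angle rows and a variable number of
#' time columns, a fluorescence spectrum matrix with 8 timed acquisitions
#' over 32 wavelength detectors, and a lifetime matrix with 4 spectral bands
#' over a fixed number of 2-ns time bins.
#'
#' @slot records list; each element a list with matrices \code{scattering}
#'   (24 x N), \code{spectrum} (8 x 32) and \code{lifetime} (4 x T).
#' @slot labels character vector of true class labels (\code{NA} if unknown).
#' @slot corrupt logical vector; \code{TRUE} marks records the generator
#'   deliberately corrupted (empty for real data).
#'
#' @seealso [generateParticles()], [filterParticles()], [preprocessParticles()]
#' @export
setClass("RawParticleSet",
  representation(records = "list", labels = "character",
                 corrupt = "logical"))

setValidity("RawParticleSet", function(object) {
  n <- length(object@records)
  if (length(object@labels) != n)
    return("labels must have one entry per record")
  if (length(object@corrupt) && length(object@corrupt) != n)
    return("corrupt must be empty or have one entry per record")
  for (i in seq_len(n)) {
    r <- object@records[[i]]
    if (!is.list(r) ||
        !all(c("scattering", "spectrum", "lifetime") %in% names(r)))
      return(sprintf("record %d: must contain scattering, spectrum, lifetime",
                     i))
    if (nrow(r$scattering) != 24L)
      return(sprintf("record %d: scattering must have 24 angle rows", i))
    if (!all(dim(r$spectrum) == c(8L, 32L)))
      return(sprintf("record %d: spectrum must be 8 x 32", i))
    if (nrow(r$lifetime) != 4L)
      return(sprintf("record %d: lifetime must have 4 band rows", i))
    if (min(r$scattering) < 0 || min(r$spectrum) < 0 || min(r$lifetime) < 0)
      return(sprintf("record %d: intensities must be non-negative", i))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## CleanSampleSet
## ---------------------------------------------------------------------------

#' Set of preprocessed (clean) samples
#'
#' Fixed-shape model inputs produced by [preprocessParticles()]: a centred
#' and cropped 20 x 120 scattering image, the first four spectrum
#' acquisitions as a 4 x 32 image, the aligned 4 x 24 lifetime image whose
#' global maximum sits at time index 4 (0-based), the four normalized
#' lifetime band features and the logarithmic size feature.
#'
#' @slot scattering numeric array (20, 120, n).
#' @slot spectrum numeric array (4, 32, n).
#' @slot lifetime numeric array (4, 24, n).
#' @slot ltFeatures numeric matrix (4, n), each column in [0, 1] with max 1.
#' @slot sizeFeature numeric vector of length n.
#' @slot labels character vector of length n (\code{NA} if unknown).
#'
#' @seealso [preprocessParticles()], [trainFusionNet()]
#' @export
setClass("CleanSampleSet",
  representation(scattering = "array", spectrum = "array",
                 lifetime = "array", ltFeatures = "matrix",
                 sizeFeature = "numeric", labels = "character"))

setValidity("CleanSampleSet", function(object) {
  n <- length(object@labels)
  d <- dim(object@scattering)
  if (length(d) != 3L || d[1L] != 20L || d[2L] != 120L || d[3L] != n)
    return("scattering must be a (20, 120, n) array")
  d <- dim(object@spectrum)
  if (length(d) != 3L || d[1L] != 4L || d[2L] != 32L || d[3L] != n)
    return("spectrum must be a (4, 32, n) array")
  d <- dim(object@lifetime)
  if (length(d) != 3L || d[1L] != 4L || d[2L] != 24L || d[3L] != n)
    return("lifetime must be a (4, 24, n) array")
  if (!all(dim(object@ltFeatures) == c(4L, n)))
    return("ltFeatures must be a (4, n) matrix")
  if (length(object@sizeFeature) != n)
    return("sizeFeature must have one value per sample")
  TRUE
})

## ---------------------------------------------------------------------------
## FusionNet
## ---------------------------------------------------------------------------

#' Three-branch fusion convolutional classifier
#'
#' The multi-modal network: per-modality convolutional branches (scattering
#' 1->10->20 channels flattening to 3000 features, spectrum 1->50->100
#' flattening to 800, lifetime 4->70->140->200 with kernels 7/5/3 flattening
#' to 400), per-branch fully-connected reduction to 50 features each, fusion
#' with the 4 lifetime features and the size feature into a 155-vector, and
#' a final fully-connected layer with log-softmax output.
#'
#' @slot net list of branch modules, reduction and head layers (weights and
#'   batch-norm running statistics); treat as opaque.
#' @slot config configuration list, see [fusionNetConfig()].
#' @slot classOrder character vector fixing the meaning of output indices.
#' @slot history data.frame with per-epoch training and validation loss
#'   (empty until trained).
#' @slot trained logical.
#'
#' @seealso [buildFusionNet()], [trainFusionNet()], [forwardPass()]
#' @export
setClass("FusionNet",
  representation(net = "list", config = "list", classOrder = "character",
                 history = "data.frame", trained = "logical"))

## ---------------------------------------------------------------------------
## AttributionSet
## ---------------------------------------------------------------------------

#' Integrated-gradients attributions for a set of samples
#'
#' Signed per-feature attributions mirroring the shapes of the model inputs,
#' together with prediction metadata: the predicted and attributed (target)
#' class, the target-class log-probability, and the completeness gap
#' \eqn{|\sum_i IG_i - (f(x) - f(x'))|}.
#'
#' @slot scattering numeric array (20, 120, n).
#' @slot spectrum numeric array (4, 32, n).
#' @slot lifetime numeric array (4, 24, n).
#' @slot ltFeatures numeric matrix (4, n).
#' @slot sizeFeature numeric vector of length n.
#' @slot predictedClass character, argmax class of each sample.
#' @slot targetClass character, class attributed for each sample.
#' @slot logProb numeric, target-class log-probability at the input.
#' @slot completenessGap numeric, absolute completeness residual.
#' @slot trueLabel character, true labels when known (else \code{NA}).
#'
#' @seealso [integratedGradients()], [summarizeAttributions()]
#' @export
setClass("AttributionSet",
  representation(scattering = "array", spectrum = "array",
                 lifetime = "array", ltFeatures = "matrix",
                 sizeFeature = "numeric", predictedClass = "character",
                 targetClass = "character", logProb = "numeric",
                 completenessGap = "numeric", trueLabel = "character"))

setValidity("AttributionSet", function(object) {
  n <- length(object@predictedClass)
  ok <- length(dim(object@scattering)) == 3L &&
    dim(object@scattering)[3L] == n &&
    dim(object@spectrum)[3L] == n && dim(object@lifetime)[3L] == n &&
    ncol(object@ltFeatures) == n && length(object@sizeFeature) == n &&
    length(object@targetClass) == n && length(object@logProb) == n &&
    length(object@completenessGap) == n && length(object@trueLabel) == n
  if (!ok) return("attribution tensors and metadata disagree on n")
  if (any(!is.finite(object@completenessGap)))
    return("completenessGap must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## ClassAttributionSummary
## ---------------------------------------------------------------------------

#' Per-class, per-feature attribution summary
#'
#' Model-level explanation table: for every (class, feature) the mean signed
#' attribution, the mean absolute attribution, a five-level sign-consistency
#' code (strong_positive, positive, mixed, negative, strong_negative) and
#' the importance rank of the feature within its modality.
#'
#' @slot table data.frame with columns \code{class}, \code{modality},
#'   \code{feature_id}, \code{row}, \code{col}, \code{wavelength_or_bin},
#'   \code{mean}, \code{mean_abs}, \code{sign_level}, \code{rank}.
#' @slot nPooled named integer, number of pooled instances per class.
#' @slot poolBy \code{"predicted"} or \code{"true"}.
#'
#' @seealso [summarizeAttributions()], [topFeatures()], [scatteringMap()]
#' @export
setClass("ClassAttributionSummary",
  representation(table = "data.frame", nPooled = "integer",
                 poolBy = "character"))

## ---------------------------------------------------------------------------
## SpectraPCA
## ---------------------------------------------------------------------------

#' PCA decomposition of transformed reference spectra
#'
#' Result of [pcaKnowledge()]: the first three principal components of the
#' mean-centred 32-point transformed reference spectra, the fraction of
#' variance each explains, per-spectrum scores, and the wavelengths of the
#' local maxima of each component's absolute coefficients.
#'
#' @slot components numeric matrix (3, 32), mutually orthonormal rows.
#' @slot explainedVarianceRatio numeric length 3, non-increasing, in [0, 1].
#' @slot scores numeric matrix (n spectra, 3).
#' @slot coefficientPeaks list of 3 numeric vectors of peak wavelengths (nm).
#' @slot center numeric length 32, feature means removed before projection.
#' @slot gridWavelengths numeric length 32.
#'
#' @seealso [pcaKnowledge()], [transformSpectrum()]
#' @export
setClass("SpectraPCA",
  representation(components = "matrix",
                 explainedVarianceRatio = "numeric",
                 scores = "matrix", coefficientPeaks = "list",
                 center = "numeric", gridWavelengths = "numeric"))

setValidity("SpectraPCA", function(object) {
  cc <- object@components
  if (nrow(cc) != 3L) return("components must have 3 rows")
  g <- cc %*% t(cc)
  if (max(abs(g - diag(3))) > 1e-8)
    return("component rows must be orthonormal")
  r <- object@explainedVarianceRatio
  if (length(r) != 3L || any(r < -1e-12 | r > 1 + 1e-12) ||
      any(diff(r) > 1e-12))
    return("explainedVarianceRatio must be 3 non-increasing values in [0, 1]")
  TRUE
})
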