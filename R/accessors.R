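## Generics and accessor methods for the package containers.

#' @name accessors
#' @title Accessors for pollenfuse containers
#'
#' @description Slot access for the S4 containers: class labels, raw records,
#' preprocessed tensors, attribution metadata and summary tables.  All slot
#' access should go through these functions.
#'
#' @param x a pollenfuse container object.
#' @param i indices for subsetting.
#' @param j,...,drop ignored; present for generic compatibility.
#' @param object object for \code{show}.
#' @return The requested component; subsetting returns an object of the same
#'   class.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("particleRecords", function(x) standardGeneric("particleRecords"))

#' @rdname accessors
#' @export
setGeneric("corruptFlags", function(x) standardGeneric("corruptFlags"))

#' @rdname accessors
#' @export
setGeneric("scatteringArray", function(x) standardGeneric("scatteringArray"))

#' @rdname accessors
#' @export
setGeneric("spectrumArray", function(x) standardGeneric("spectrumArray"))

#' @rdname accessors
#' @export
setGeneric("lifetimeArray", function(x) standardGeneric("lifetimeArray"))

#' @rdname accessors
#' @export
setGeneric("ltFeatureMatrix", function(x) standardGeneric("ltFeatureMatrix"))

#' @rdname accessors
#' @export
setGeneric("sizeFeatureVector",
           function(x) standardGeneric("sizeFeatureVector"))

#' @rdname accessors
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setGeneric("predictedClasses",
           function(x) standardGeneric("predictedClasses"))

#' @rdname accessors
#' @export
setGeneric("targetClasses", function(x) standardGeneric("targetClasses"))

#' @rdname accessors
#' @export
setGeneric("completenessGap", function(x) standardGeneric("completenessGap"))

#' @rdname accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' @rdname accessors
#' @export
setGeneric("pooledCounts", function(x) standardGeneric("pooledCounts"))

## ---- RawParticleSet --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("length", "RawParticleSet", function(x) length(x@records))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "RawParticleSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("particleRecords", "RawParticleSet", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("corruptFlags", "RawParticleSet", function(x) {
  if (length(x@corrupt)) x@corrupt else rep(FALSE, length(x))
})

#' @rdname accessors
#' @export
setMethod("[", "RawParticleSet", function(x, i, j, ..., drop = FALSE) {
  new("RawParticleSet", records = x@records[i], labels = x@labels[i],
      corrupt = if (length(x@corrupt)) x@corrupt[i] else logical())
})

setMethod("show", "RawParticleSet", function(object) {
  cat(sprintf("RawParticleSet with %d particles\n", length(object)))
  tab <- table(object@labels, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  if (length(object@corrupt))
    cat(sprintf("  generator-corrupted records: %d\n", sum(object@corrupt)))
  ncols <- vapply(object@records, function(r) ncol(r$scattering), 1L)
  cat(sprintf("  scattering columns: %d-%d (median %d)\n",
              min(ncols), max(ncols), as.integer(stats::median(ncols))))
})

## ---- CleanSampleSet --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("length", "CleanSampleSet", function(x) length(x@labels))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "CleanSampleSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("scatteringArray", "CleanSampleSet", function(x) x@scattering)

#' @rdname accessors
#' @export
setMethod("spectrumArray", "CleanSampleSet", function(x) x@spectrum)

#' @rdname accessors
#' @export
setMethod("lifetimeArray", "CleanSampleSet", function(x) x@lifetime)

#' @rdname accessors
#' @export
setMethod("ltFeatureMatrix", "CleanSampleSet", function(x) x@ltFeatures)

#' @rdname accessors
#' @export
setMethod("sizeFeatureVector", "CleanSampleSet", function(x) x@sizeFeature)

#' @rdname accessors
#' @export
setMethod("[", "CleanSampleSet", function(x, i, j, ..., drop = FALSE) {
  new("CleanSampleSet",
      scattering = x@scattering[, , i, drop = FALSE],
      spectrum = x@spectrum[, , i, drop = FALSE],
      lifetime = x@lifetime[, , i, drop = FALSE],
      ltFeatures = x@ltFeatures[, i, drop = FALSE],
      sizeFeature = x@sizeFeature[i],
      labels = x@labels[i])
})

setMethod("show", "CleanSampleSet", function(object) {
  cat(sprintf("CleanSampleSet with %d samples\n", length(object)))
  cat("  scattering 20x120, spectrum 4x32, lifetime 4x24,",
      "4 lifetime features + size feature\n")
  tab <- table(object@labels, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
})

## ---- FusionNet -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("classOrder", "FusionNet", function(x) x@classOrder)

#' @rdname accessors
#' @export
setMethod("modelConfig", "FusionNet", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("trainingHistory", "FusionNet", function(x) x@history)

setMethod("show", "FusionNet", function(object) {
  cfg <- object@config
  cat("FusionNet multi-modal classifier\n")
  cat(sprintf("  classes (%d): %s\n", length(object@classOrder),
              paste(object@classOrder, collapse = ", ")))
  cat(sprintf("  branches: scattering 1->%s (3000), spectrum 1->%s (800), lifetime 4->%s (400)\n",
              paste(cfg$scatteringChannels, collapse = "->"),
              paste(cfg$spectrumChannels, collapse = "->"),
              paste(cfg$lifetimeChannels, collapse = "->")))
  cat(sprintf("  fused feature vector: %d\n",
              3L * cfg$perModalityReduced + 5L))
  if (object@trained)
    cat(sprintf("  trained for %d epochs (best validation loss %.4f)\n",
                nrow(object@history), min(object@history$val_loss)))
  else cat("  untrained (random initialization)\n")
})

## ---- AttributionSet --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("length", "AttributionSet", function(x) length(x@predictedClass))

#' @rdname accessors
#' @export
setMethod("scatteringArray", "AttributionSet", function(x) x@scattering)

#' @rdname accessors
#' @export
setMethod("spectrumArray", "AttributionSet", function(x) x@spectrum)

#' @rdname accessors
#' @export
setMethod("lifetimeArray", "AttributionSet", function(x) x@lifetime)

#' @rdname accessors
#' @export
setMethod("ltFeatureMatrix", "AttributionSet", function(x) x@ltFeatures)

#' @rdname accessors
#' @export
setMethod("sizeFeatureVector", "AttributionSet", function(x) x@sizeFeature)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "AttributionSet", function(x) x@trueLabel)

#' @rdname accessors
#' @export
setMethod("predictedClasses", "AttributionSet", function(x) x@predictedClass)

#' @rdname accessors
#' @export
setMethod("targetClasses", "AttributionSet", function(x) x@targetClass)

#' @rdname accessors
#' @export
setMethod("completenessGap", "AttributionSet", function(x) x@completenessGap)

#' @rdname accessors
#' @export
setMethod("[", "AttributionSet", function(x, i, j, ..., drop = FALSE) {
  new("AttributionSet",
      scattering = x@scattering[, , i, drop = FALSE],
      spectrum = x@spectrum[, , i, drop = FALSE],
      lifetime = x@lifetime[, , i, drop = FALSE],
      ltFeatures = x@ltFeatures[, i, drop = FALSE],
      sizeFeature = x@sizeFeature[i],
      predictedClass = x@predictedClass[i],
      targetClass = x@targetClass[i],
      logProb = x@logProb[i],
      completenessGap = x@completenessGap[i],
      trueLabel = x@trueLabel[i])
})

setMethod("show", "AttributionSet", function(object) {
  cat(sprintf("AttributionSet for %d samples\n", length(object)))
  cat(sprintf("  max completeness gap: %.3g\n",
              max(object@completenessGap)))
  agree <- mean(object@predictedClass == object@targetClass)
  cat(sprintf("  attributed class == predicted class for %.0f%% of samples\n",
              100 * agree))
})

## ---- ClassAttributionSummary ----------------------------------------------

#' @rdname accessors
#' @export
setMethod("summaryTable", "ClassAttributionSummary", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("pooledCounts", "ClassAttributionSummary", function(x) x@nPooled)

setMethod("show", "ClassAttributionSummary", function(object) {
  cat(sprintf("ClassAttributionSummary (pooled by %s class)\n",
              object@poolBy))
  cat(sprintf("  %d classes x %d features per class\n",
              length(object@nPooled),
              nrow(object@table) / max(length(object@nPooled), 1L)))
  cat("  instances pooled:",
      paste(sprintf("%s (%d)", names(object@nPooled), object@nPooled),
            collapse = ", "), "\n")
})

setMethod("show", "SpectraPCA", function(object) {
  cat("SpectraPCA of transformed reference spectra\n")
  cat(sprintf("  explained variance ratios: %s (total %.1f%%)\n",
              paste(sprintf("%.3f", object@explainedVarianceRatio),
                    collapse = ", "),
              100 * sum(object@explainedVarianceRatio)))
  for (k in 1:3)
    cat(sprintf("  PC%d |coefficient| peaks at: %s nm\n", k,
                paste(round(object@coefficientPeaks[[k]], 1),
                      collapse = ", ")))
})

setMethod("show", "ClassSpec", function(object) {
  cat(sprintf("ClassSpec '%s': peaks at %s nm; lifetimes %s ns; diameter %g um\n",
              object@className,
              paste(round(object@peakWavelengths, 1), collapse = ", "),
              paste(object@bandLifetimes, collapse = "/"),
              object@sizeMu))
})
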