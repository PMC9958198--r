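# Integrated Gradients for the multi-input fusion network.
#
# For input x, baseline x' and target-class score f (the target's
# log-probability), the attribution of coordinate i is
#   IG_i = (x_i - x'_i) * (1/M) * sum_{m=1..M} df/dx_i at x' + (m/M)(x - x'),
# i.e. a right-endpoint Riemann approximation of the path integral of the
# gradient along the straight line from baseline to input.  The default
# baseline is zero everywhere, denoting absence of signal at the detector.
# Attributions satisfy the completeness axiom up to the Riemann
# discretization error, which is reported per sample as the completeness
# gap |sum_i IG_i - (f(x) - f(x'))|.

.zeroBaseline <- function() {
  list(scattering = array(0, c(20L, 120L)),
       spectrum = array(0, c(4L, 32L)),
       lifetime = array(0, c(4L, 24L)),
       ltFeatures = numeric(4L),
       sizeFeature = 0)
}

.checkBaseline <- function(baseline) {
  ok <- identical(dim(baseline$scattering), c(20L, 120L)) &&
    identical(dim(baseline$spectrum), c(4L, 32L)) &&
    identical(dim(baseline$lifetime), c(4L, 24L)) &&
    length(baseline$ltFeatures) == 4L &&
    length(baseline$sizeFeature) == 1L
  if (!ok)
    stop("baseline must contain tensors shaped 20x120, 4x32, 4x24, 4, 1")
  baseline
}

## path batch for one sample: columns are x' + (m/M)(x - x'), m = 1..M
.pathBatch <- function(x, baseline, alphas) {
  M <- length(alphas)
  mk <- function(v, b, dm) {
    out <- as.numeric(b) + outer(as.numeric(v) - as.numeric(b), alphas)
    dim(out) <- c(dm, M)
    out
  }
  list(scattering = mk(x$scattering, baseline$scattering, c(1L, 20L, 120L)),
       spectrum = mk(x$spectrum, baseline$spectrum, c(1L, 4L, 32L)),
       lifetime = mk(x$lifetime, baseline$lifetime, c(4L, 1L, 24L)),
       ltFeatures = mk(x$ltFeatures, baseline$ltFeatures, 4L),
       sizeFeature = as.numeric(baseline$sizeFeature) +
         (as.numeric(x$sizeFeature) - as.numeric(baseline$sizeFeature)) *
         alphas)
}

## mean gradient over the path for each modality, as sample-shaped tensors
.gradAlongPath <- function(net, batch, targetIdx) {
  fw <- .netForward(net, batch, train = FALSE)
  M <- ncol(fw$logp)
  dLogp <- matrix(0, nrow(fw$logp), M)
  dLogp[targetIdx, ] <- 1
  bk <- .netBackward(net, fw, dLogp, needParam = FALSE,
                     needInputGrad = TRUE)
  g <- bk$dInputs
  if (any(!vapply(g, function(v) all(is.finite(v)), logical(1L))))
    stop("non-finite gradients encountered along the integration path")
  list(scattering = rowSums(matrix(g$scattering, 2400L, M)),
       spectrum = rowSums(matrix(g$spectrum, 128L, M)),
       lifetime = rowSums(matrix(g$lifetime, 96L, M)),
       ltFeatures = rowSums(matrix(g$ltFeatures, 4L, M)),
       sizeFeature = sum(g$sizeFeature), m = M)
}

## Right-endpoint Riemann core shared by all attribution entry points.
## gradSumFn(alphas) must return, for the path points x' + alpha * (x - x'),
## the per-coordinate gradients SUMMED over those points, as a named list
## matching x.  Returns the attribution vectors (x - x') * mean gradient.
.igRiemann <- function(gradSumFn, x, baseline, steps, chunkSize = 100L) {
  acc <- lapply(x, function(v) numeric(length(v)))
  alphasAll <- seq_len(steps) / steps
  for (ch in split(alphasAll, ceiling(seq_len(steps) / chunkSize))) {
    g <- gradSumFn(ch)
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + as.numeric(g[[nm]])
  }
  out <- lapply(names(acc), function(nm)
    (as.numeric(x[[nm]]) - as.numeric(baseline[[nm]])) * acc[[nm]] / steps)
  names(out) <- names(acc)
  out
}

.sampleInputs <- function(samples, i) {
  list(scattering = samples@scattering[, , i],
       spectrum = samples@spectrum[, , i],
       lifetime = samples@lifetime[, , i],
       ltFeatures = samples@ltFeatures[, i],
       sizeFeature = samples@sizeFeature[i])
}

#' Integrated-gradients attributions
#'
#' Computes signed attributions of every input coordinate (all five input
#' tensors in one pass) towards the target-class log-probability, using the
#' right-endpoint Riemann approximation with \code{steps} points along the
#' straight path from the baseline to the input.
#'
#' @param model a [FusionNet-class] (trained, or at least built).
#' @param samples a [CleanSampleSet-class].
#' @param steps number of Riemann steps M (>= 1; default 300).
#' @param target \code{"predicted"} (default) to attribute each sample's
#'   predicted class, \code{"true"} to attribute its true label, or a
#'   single class name.
#' @param baseline named list of baseline tensors (\code{scattering}
#'   20x120, \code{spectrum} 4x32, \code{lifetime} 4x24, \code{ltFeatures}
#'   length 4, \code{sizeFeature} length 1); default all-zero.
#' @param chunkSize path points evaluated per forward/backward batch.
#' @return an [AttributionSet-class].
#' @examples
#' \donttest{
#' specs <- defaultClassSpecs()
#' clean <- preprocessParticles(generateParticles(specs, 8, seed = 5))
#' net <- buildFusionNet(fusionNetConfig(nClasses = 4),
#'                       classOrder = sort(vapply(specs, slot, "",
#'                                                "className")))
#' attr <- integratedGradients(net, clean[1:2], steps = 20)
#' completenessGap(attr)
#' }
#' @export
integratedGradients <- function(model, samples, steps = 300L,
                                target = "predicted", baseline = NULL,
                                chunkSize = 100L) {
  stopifnot(is(model, "FusionNet"), is(samples, "CleanSampleSet"))
  if (steps < 1L) stop("steps must be >= 1")
  baseline <- if (is.null(baseline)) .zeroBaseline()
              else .checkBaseline(baseline)
  n <- length(samples)
  net <- model@net
  logp <- forwardPass(model, samples)
  predicted <- model@classOrder[apply(logp, 2L, which.max)]
  targetClass <- if (identical(target, "predicted")) {
    predicted
  } else if (identical(target, "true")) {
    if (anyNA(samples@labels))
      stop("target = \"true\" requires labelled samples")
    samples@labels
  } else {
    if (!all(target %in% model@classOrder))
      stop("unknown target class: ",
           paste(setdiff(target, model@classOrder), collapse = ", "))
    rep_len(target, n)
  }
  targetIdx <- match(targetClass, model@classOrder)

  ## baseline score per class, shared across samples
  fwB <- .netForward(net, .pathBatch(baseline, baseline, 1), train = FALSE)
  fBase <- fwB$logp[, 1L]

  scA <- array(0, c(20L, 120L, n))
  spA <- array(0, c(4L, 32L, n))
  ltA <- array(0, c(4L, 24L, n))
  ltfA <- matrix(0, 4L, n)
  szA <- numeric(n)
  gap <- numeric(n)
  for (i in seq_len(n)) {
    x <- .sampleInputs(samples, i)
    ig <- .igRiemann(function(alphas)
      .gradAlongPath(net, .pathBatch(x, baseline, alphas), targetIdx[i]),
      x, baseline, steps, chunkSize)
    scA[, , i] <- ig$scattering
    spA[, , i] <- ig$spectrum
    ltA[, , i] <- ig$lifetime
    ltfA[, i] <- ig$ltFeatures
    szA[i] <- ig$sizeFeature
    total <- sum(unlist(ig))
    gap[i] <- abs(total - (logp[targetIdx[i], i] - fBase[targetIdx[i]]))
  }
  new("AttributionSet", scattering = scA, spectrum = spA, lifetime = ltA,
      ltFeatures = ltfA, sizeFeature = szA,
      predictedClass = predicted, targetClass = targetClass,
      logProb = logp[cbind(targetIdx, seq_len(n))],
      completenessGap = gap, trueLabel = samples@labels)
}

#' Explain one instance: attributions paired with inputs
#'
#' Convenience wrapper around [integratedGradients()] for a single sample,
#' attributing the predicted class and returning plot-ready pairs of each
#' input tensor with its signed attribution tensor (positive values support
#' the predicted class, negative values oppose it).
#'
#' @param model a [FusionNet-class].
#' @param sample a [CleanSampleSet-class] of length 1 (or the sample index
#'   via \code{which}).
#' @param which index of the sample to explain when \code{sample} has more
#'   than one record.
#' @inheritParams integratedGradients
#' @return list with \code{attribution} (an [AttributionSet-class] of
#'   length 1) and \code{pairs}: five elements, each a list with
#'   \code{modality}, \code{input} and \code{attribution}.
#' @export
explainInstance <- function(model, sample, which = 1L, steps = 300L,
                            baseline = NULL, chunkSize = 100L) {
  sample <- sample[which]
  att <- integratedGradients(model, sample, steps = steps,
                             target = "predicted", baseline = baseline,
                             chunkSize = chunkSize)
  x <- .sampleInputs(sample, 1L)
  a <- .sampleInputs(att, 1L)
  pairs <- lapply(names(x), function(nm)
    list(modality = nm, input = x[[nm]], attribution = a[[nm]]))
  list(attribution = att, pairs = pairs)
}
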