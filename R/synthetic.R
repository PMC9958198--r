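# Synthetic particle and reference-spectrum generator.
#
# The generator emulates a Rapid-E style single-particle detector and a
# laboratory spectrofluorometer with known, planted class structure: Gaussian
# emission peaks on the 32-point instrument wavelength grid, band-specific
# exponential lifetime decays, a smooth size- and roughness-dependent
# scattering ridge, additive truncated-Gaussian detector noise, and an exact
# fraction of deliberately corrupted records that the preprocessing filters
# must reject.

#' Construct a synthetic pollen class specification
#'
#' @param className class label.
#' @param peakWavelengths numeric, emission peak centres (nm, in 350--800).
#' @param peakWidths numeric, Gaussian sigma per peak (nm).
#' @param peakAmplitudes numeric, per-peak amplitude (intensity units).
#' @param bandLifetimes numeric(4), lifetime decay constants per spectral
#'   band (ns).
#' @param sizeMu median grain diameter (micrometres).
#' @param sizeSigma log-normal sdlog of the diameter.
#' @param roughness surface roughness in [0, 1]; multiplicative speckle on
#'   the scattering ridge.
#' @param nInteractionsMu mean number of scattering time columns for a grain
#'   of diameter \code{sizeMu}.
#' @param noiseSd sd of additive truncated-Gaussian detector noise on the
#'   spectrum and lifetime modalities; the scattering modality uses
#'   \code{noiseSd / 20} to match its smaller intensity scale.
#' @return A [ClassSpec-class] object.
#' @examples
#' classSpec("Carex", peakWavelengths = 451, peakWidths = 12,
#'           peakAmplitudes = 4000, bandLifetimes = c(3, 4, 8, 2),
#'           sizeMu = 35)
#' @export
classSpec <- function(className, peakWavelengths, peakWidths, peakAmplitudes,
                      bandLifetimes, sizeMu, sizeSigma = 0.15,
                      roughness = 0.3, nInteractionsMu = 130,
                      noiseSd = 25) {
  new("ClassSpec", className = as.character(className),
      peakWavelengths = as.numeric(peakWavelengths),
      peakWidths = as.numeric(peakWidths),
      peakAmplitudes = as.numeric(peakAmplitudes),
      bandLifetimes = as.numeric(bandLifetimes),
      sizeMu = as.numeric(sizeMu), sizeSigma = as.numeric(sizeSigma),
      roughness = as.numeric(roughness),
      nInteractionsMu = as.numeric(nInteractionsMu),
      noiseSd = as.numeric(noiseSd))
}

#' Default four-class study conditions
#'
#' Four synthetic pollen classes used throughout the package examples and
#' tests, organized as two chemically-similar pairs that differ within each
#' pair mainly by grain morphology.  Alopecurus and Dactylis share the
#' grass-type emission peak (393.5 nm, instrument grid index 3) and
#' near-identical lifetime profiles, but Dactylis grains are clearly larger
#' with a much longer scattering trace; Platanus and Carex likewise share a
#' 437.1 nm peak (grid index 6) and similar lifetimes while spanning small
#' versus large grains.  The two pairs are three grid steps apart
#' spectrally and all dominant peaks lie inside the wavelength window that
#' the preprocessing filters retain.  This mirrors the real-world situation
#' where chemically similar pollen can only be told apart through
#' morphology, and forces the classifier to exploit the scattering
#' modality and the derived size feature alongside spectrum and lifetime.
#'
#' @return list of [ClassSpec-class] objects.
#' @export
defaultClassSpecs <- function() {
  list(
    classSpec("Alopecurus", 393.5, 10, 4000,
              bandLifetimes = c(2.0, 6.0, 3.0, 1.5),
              sizeMu = 25, roughness = 0.35, nInteractionsMu = 130),
    classSpec("Dactylis", 393.5, 10, 4000,
              bandLifetimes = c(2.0, 6.0, 3.0, 1.5),
              sizeMu = 40, roughness = 0.35, nInteractionsMu = 230),
    classSpec("Platanus", 437.1, 12, 4200,
              bandLifetimes = c(3.0, 4.0, 8.0, 2.0),
              sizeMu = 18, roughness = 0.30, nInteractionsMu = 110),
    classSpec("Carex", 437.1, 12, 4200,
              bandLifetimes = c(3.0, 4.0, 8.0, 2.0),
              sizeMu = 36, roughness = 0.30, nInteractionsMu = 110))
}

#' Nearest instrument grid indices of a class's planted peaks
#'
#' @param spec a [ClassSpec-class].
#' @return integer vector of 0-based indices into the 32-point wavelength
#'   grid, one per planted peak.
#' @export
plantedPeakIndices <- function(spec) {
  grid <- .rapidEWavelengths()
  vapply(spec@peakWavelengths,
         function(w) which.min(abs(grid - w)) - 1L, integer(1L))
}

## internal: shared wavelength grid of the instrument (32 detectors)
.rapidEWavelengths <- function() 350 + (0:31) * 14.51

.peakModel <- function(spec, wavelengths) {
  out <- numeric(length(wavelengths))
  for (k in seq_along(spec@peakWavelengths)) {
    out <- out + spec@peakAmplitudes[k] *
      exp(-(wavelengths - spec@peakWavelengths[k])^2 /
            (2 * spec@peakWidths[k]^2))
  }
  out
}

## truncated-Gaussian detector noise, clipped at zero
.tnoise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  pmax(stats::rnorm(n, 0, sd), 0)
}

# Spectrum acquisitions decay geometrically (factor 0.5 per 500 ns step)
# so the earliest acquisition dominates.
.spectrumDecay <- 0.5

.makeSpectrum <- function(spec) {
  base <- .peakModel(spec, .rapidEWavelengths())
  sp <- outer(.spectrumDecay^(0:7), base)
  sp + matrix(.tnoise(8L * 32L, spec@noiseSd), 8L, 32L)
}

# Lifetime trace: sharp Gaussian rise to the peak bin, exponential decay
# with the band's constant after it; 2 ns per bin.
.makeLifetime <- function(spec, nBins, peakBin, amplitude = 3000) {
  t <- seq_len(nBins) - 1L
  lt <- matrix(0, 4L, nBins)
  for (b in 1:4) {
    tau <- spec@bandLifetimes[b]
    y <- ifelse(t >= peakBin,
                amplitude * exp(-(t - peakBin) * 2 / tau),
                amplitude * exp(-(peakBin - t)^2 / 2))
    lt[b, ] <- y
  }
  lt + matrix(.tnoise(4L * nBins, spec@noiseSd), 4L, nBins)
}

# Scattering ridge: Gaussian in angle (centre near the middle rows) times
# Gaussian in time; peak intensity grows with the squared diameter and the
# column count scales linearly with diameter.
.makeScattering <- function(spec, diameter, nCols = NULL) {
  if (is.null(nCols)) {
    nCols <- round(spec@nInteractionsMu * diameter / spec@sizeMu +
                     stats::rnorm(1, 0, 3))
    nCols <- max(30L, min(449L, as.integer(nCols)))
  }
  a0 <- 12.5 + stats::runif(1, -2, 2)
  t0 <- nCols * stats::runif(1, 0.4, 0.6)
  ridge <- outer(exp(-(seq_len(24L) - a0)^2 / (2 * 5^2)),
                 exp(-(seq_len(nCols) - t0)^2 / (2 * (nCols / 5)^2)))
  ridge <- 0.5 * diameter^2 * ridge
  if (spec@roughness > 0)
    ridge <- ridge * (1 + spec@roughness *
                        stats::runif(length(ridge), -1, 1))
  ridge + matrix(.tnoise(24L * nCols, spec@noiseSd / 20), 24L, nCols)
}

.corruptModes <- c("dim_spectrum", "long_scattering", "early_lifetime",
                   "spectrum_offpeak")

#' Generate synthetic raw particle records
#'
#' Draws \code{nPerClass} single-particle records for every class
#' specification.  Non-corrupt records are guaranteed (under the default
#' noise levels, and provided every dominant peak lies inside the filter's
#' wavelength window) to pass [filterParticles()]; a fraction
#' \code{round(corruptFraction * nPerClass)} per class is deliberately
#' corrupted so that it violates at least one filtering predicate (too-dim
#' spectrum, over-long scattering image, early lifetime maximum, or an
#' acquisition whose wavelength maximum falls outside the allowed window).
#'
#' @param specs list of [ClassSpec-class] objects.
#' @param nPerClass records per class (>= 1).
#' @param corruptFraction fraction in [0, 1) of records per class to corrupt.
#' @param seed integer seed; identical seeds give identical record sets.
#' @param rawLifetimeBins number of raw lifetime time bins (2 ns each).
#' @return A [RawParticleSet-class] with \code{nPerClass * length(specs)}
#'   records.
#' @examples
#' raw <- generateParticles(defaultClassSpecs(), nPerClass = 5, seed = 1)
#' raw
#' @export
generateParticles <- function(specs, nPerClass, corruptFraction = 0,
                              seed = 1L, rawLifetimeBins = 64L) {
  if (!length(specs)) stop("specs must be a non-empty list of ClassSpec")
  for (s in specs) {
    if (!is(s, "ClassSpec")) stop("specs must contain ClassSpec objects")
    validObject(s)
  }
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  if (corruptFraction < 0 || corruptFraction >= 1)
    stop("corruptFraction must lie in [0, 1)")
  if (rawLifetimeBins < 45L)
    stop("rawLifetimeBins must be >= 45 so the lifetime maximum can fall ",
         "inside the filter window [10, 44]")
  peakSets <- vapply(specs, function(s)
    paste(sort(unique(plantedPeakIndices(s))), collapse = ","), "")
  if (anyDuplicated(peakSets))
    warning("some classes have identical planted peak grid index sets; ",
            "they remain distinguishable only through other modalities")

  set.seed(as.integer(seed))
  records <- vector("list", nPerClass * length(specs))
  labels <- character(length(records))
  corrupt <- logical(length(records))
  k <- 0L
  for (spec in specs) {
    nCorrupt <- round(corruptFraction * nPerClass)
    corruptPos <- if (nCorrupt > 0) sample(nPerClass, nCorrupt) else integer()
    for (i in seq_len(nPerClass)) {
      d <- stats::rlnorm(1, log(spec@sizeMu), spec@sizeSigma)
      sp <- .makeSpectrum(spec)
      lt <- .makeLifetime(spec, rawLifetimeBins, sample(12:36, 1))
      sc <- .makeScattering(spec, d)
      isCorrupt <- i %in% corruptPos
      if (isCorrupt) {
        mode <- sample(.corruptModes, 1)
        if (mode == "dim_spectrum") {
          sp <- sp * (1200 / max(sp))
        } else if (mode == "long_scattering") {
          sc <- .makeScattering(spec, d, nCols = sample(460:520, 1))
        } else if (mode == "early_lifetime") {
          lt <- .makeLifetime(spec, rawLifetimeBins, 4L)
        } else {
          sp[3L, 22L] <- 1.3 * max(sp)  # acquisition 2 peaks at grid index 21
        }
      }
      k <- k + 1L
      records[[k]] <- list(scattering = sc, spectrum = sp, lifetime = lt)
      labels[k] <- spec@className
      corrupt[k] <- isCorrupt
    }
  }
  new("RawParticleSet", records = records, labels = labels,
      corrupt = corrupt)
}

#' Generate synthetic reference fluorescence spectra
#'
#' Emulates bulk spectrofluorometer measurements: the same Gaussian-peak
#' emission model as [generateParticles()] evaluated on the 1 nm grid from
#' 350 to 800 nm (451 points), with each replicate differing only by
#' detector noise.  Three replicates per class mirror typical laboratory
#' practice of measuring each bulk sample three times.
#'
#' @param specs list of [ClassSpec-class] objects.
#' @param replicates measurements per class (>= 1; default 3).
#' @param seed integer seed.
#' @return data.frame with columns \code{class}, \code{replicate},
#'   \code{wavelength_nm}, \code{intensity}.
#' @examples
#' ref <- generateReferenceSpectra(defaultClassSpecs(), seed = 1)
#' nrow(ref)  # 4 classes x 3 replicates x 451 wavelengths
#' @export
generateReferenceSpectra <- function(specs, replicates = 3L, seed = 1L) {
  if (!length(specs)) stop("specs must be a non-empty list of ClassSpec")
  if (replicates < 1) stop("replicates must be >= 1")
  for (s in specs) validObject(s)
  set.seed(as.integer(seed))
  wl <- 350:800
  out <- vector("list", length(specs) * replicates)
  k <- 0L
  for (spec in specs) {
    base <- .peakModel(spec, wl)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      out[[k]] <- data.frame(class = spec@className, replicate = r,
                             wavelength_nm = wl,
                             intensity = base + .tnoise(length(wl),
                                                        spec@noiseSd))
    }
  }
  do.call(rbind, out)
}

## ---- persistence -----------------------------------------------------------

#' Read and write particle containers and class specifications
#'
#' Particle sets (raw or preprocessed) are stored in the package's native
#' serialized container (RDS); class specifications are stored as YAML so
#' study conditions can be edited by hand; reference spectra travel as
#' tidy CSV.
#'
#' @param x object to write.
#' @param path file path.
#' @param specs list of [ClassSpec-class] objects.
#' @param df reference spectra data.frame as returned by
#'   [generateReferenceSpectra()].
#' @return readers return the reconstructed object; writers return
#'   \code{path} invisibly.
#' @name particle-io
NULL

#' @rdname particle-io
#' @export
writeParticles <- function(x, path) {
  stopifnot(is(x, "RawParticleSet") || is(x, "CleanSampleSet") ||
              is(x, "AttributionSet"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname particle-io
#' @export
readParticles <- function(path) {
  x <- readRDS(path)
  if (!(is(x, "RawParticleSet") || is(x, "CleanSampleSet") ||
          is(x, "AttributionSet")))
    stop("file does not contain a particle container")
  validObject(x)
  x
}

#' @rdname particle-io
#' @export
writeClassSpecs <- function(specs, path) {
  lst <- lapply(specs, function(s) list(
    className = s@className, peakWavelengths = s@peakWavelengths,
    peakWidths = s@peakWidths, peakAmplitudes = s@peakAmplitudes,
    bandLifetimes = s@bandLifetimes, sizeMu = s@sizeMu,
    sizeSigma = s@sizeSigma, roughness = s@roughness,
    nInteractionsMu = s@nInteractionsMu, noiseSd = s@noiseSd))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname particle-io
#' @export
readClassSpecs <- function(path) {
  lst <- yaml::read_yaml(path)
  lapply(lst, function(e) do.call(classSpec, e))
}

#' @rdname particle-io
#' @export
writeReferenceSpectra <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname particle-io
#' @export
readReferenceSpectra <- function(path) {
  df <- utils::read.csv(path)
  need <- c("class", "replicate", "wavelength_nm", "intensity")
  if (!all(need %in% names(df)))
    stop("reference spectra CSV must have columns: ",
         paste(need, collapse = ", "))
  df
}
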