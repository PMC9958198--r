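# Preprocessing of raw particle records: quality filters, per-modality
# cropping/alignment and the five derived scalar features.
#
# Index conventions follow the instrument's: indices are 0-based and interval
# bounds are inclusive wherever thresholds are expressed as indices.

#' Filtering thresholds for raw particle records
#'
#' A particle is kept only if all four predicates hold: the global spectrum
#' maximum exceeds \code{minSpectrumMax}; the scattering image has fewer
#' than \code{maxScatteringCols} time columns; the time-bin index (0-based)
#' of the global lifetime maximum lies in \code{lifetimeArgmaxRange}
#' (inclusive); and the wavelength index (0-based) of the maximum of each of
#' the four retained spectrum acquisitions lies in
#' \code{spectrumArgmaxRange} (inclusive).
#'
#' @param minSpectrumMax minimum global spectrum intensity (default 2500).
#' @param maxScatteringCols scattering column-count bound (default 450;
#'   kept records have strictly fewer columns).
#' @param lifetimeArgmaxRange inclusive 0-based index interval, default
#'   \code{c(10, 44)}.
#' @param spectrumArgmaxRange inclusive 0-based wavelength-index interval,
#'   default \code{c(3, 10)}.
#' @param spectrumArgmaxRows 1-based acquisition rows whose maxima are
#'   checked; defaults to the four retained acquisitions \code{1:4}.
#' @return a named list of thresholds.
#' @export
filterThresholds <- function(minSpectrumMax = 2500,
                             maxScatteringCols = 450,
                             lifetimeArgmaxRange = c(10L, 44L),
                             spectrumArgmaxRange = c(3L, 10L),
                             spectrumArgmaxRows = 1:4) {
  stopifnot(minSpectrumMax > 0, maxScatteringCols > 0,
            length(lifetimeArgmaxRange) == 2L,
            lifetimeArgmaxRange[1] <= lifetimeArgmaxRange[2],
            length(spectrumArgmaxRange) == 2L,
            spectrumArgmaxRange[1] <= spectrumArgmaxRange[2],
            all(spectrumArgmaxRows %in% 1:8))
  list(minSpectrumMax = minSpectrumMax,
       maxScatteringCols = maxScatteringCols,
       lifetimeArgmaxRange = as.integer(lifetimeArgmaxRange),
       spectrumArgmaxRange = as.integer(spectrumArgmaxRange),
       spectrumArgmaxRows = as.integer(spectrumArgmaxRows))
}

## 0-based time-bin index of the global maximum of a (bands x bins) matrix
.lifetimeArgmaxBin <- function(lt) {
  (which.max(lt) - 1L) %/% nrow(lt)
}

.passesFilters <- function(r, th) {
  c(spectrum_max = max(r$spectrum) > th$minSpectrumMax,
    scattering_cols = ncol(r$scattering) < th$maxScatteringCols,
    lifetime_argmax = {
      b <- .lifetimeArgmaxBin(r$lifetime)
      b >= th$lifetimeArgmaxRange[1] && b <= th$lifetimeArgmaxRange[2]
    },
    spectrum_argmax = all(vapply(th$spectrumArgmaxRows, function(i) {
      j <- which.max(r$spectrum[i, ]) - 1L
      j >= th$spectrumArgmaxRange[1] && j <= th$spectrumArgmaxRange[2]
    }, logical(1L))))
}

#' Filter raw particle records
#'
#' Applies the four quality predicates described in [filterThresholds()] and
#' returns the surviving records together with a per-rule rejection report
#' (one record may increment several rules).
#'
#' @param x a [RawParticleSet-class]; malformed records are a hard error.
#' @param thresholds output of [filterThresholds()].
#' @return list with elements \code{kept} (a [RawParticleSet-class]) and
#'   \code{report} (data.frame of per-rule rejection counts, plus totals of
#'   examined, kept and rejected records).
#' @examples
#' raw <- generateParticles(defaultClassSpecs(), 10, corruptFraction = 0.2,
#'                          seed = 3)
#' res <- filterParticles(raw)
#' res$report
#' @export
filterParticles <- function(x, thresholds = filterThresholds()) {
  stopifnot(is(x, "RawParticleSet"))
  validObject(x)
  n <- length(x)
  rules <- c("spectrum_max", "scattering_cols", "lifetime_argmax",
             "spectrum_argmax")
  counts <- stats::setNames(integer(4L), rules)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- .passesFilters(x@records[[i]], thresholds)
    keep[i] <- all(ok)
    counts <- counts + !ok
  }
  report <- data.frame(rule = rules, rejected = as.integer(counts))
  report <- rbind(report,
                  data.frame(rule = c("total_examined", "total_kept",
                                      "total_rejected"),
                             rejected = c(n, sum(keep), sum(!keep))))
  list(kept = x[keep], report = report)
}

#' Centre-crop a raw scattering image
#'
#' Drops the two outermost angle rows at each edge (24 to 20 rows, i.e. the
#' angular window narrows to -37.5..37.5 degrees at 3.75-degree spacing),
#' locates the column of the global maximum of the remaining image, and
#' keeps the 60 columns to its left and 60 to its right (120 in total);
#' columns falling outside the recorded range are zero-filled.
#'
#' @param raw numeric matrix with 24 rows and at least one column.
#' @return a 20 x 120 matrix.
#' @export
centerCropScattering <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) == 24L, ncol(raw) >= 1L)
  m <- raw[3:22, , drop = FALSE]
  if (max(m) <= 0) {
    warning("all-zero scattering image; centring on the first column")
    cmax <- 1L
  } else {
    cmax <- (which.max(m) - 1L) %/% 20L + 1L
  }
  out <- matrix(0, 20L, 120L)
  src <- (cmax - 60L):(cmax + 59L)
  ok <- src >= 1L & src <= ncol(m)
  out[, ok] <- m[, src[ok]]
  out
}

#' Align a lifetime trace to the common peak position
#'
#' Shifts all four bands jointly so that the time bin of the global maximum
#' lands at index 4 (0-based), then truncates or zero-pads to 24 bins.
#'
#' @param raw numeric matrix with 4 band rows and at least 24 time bins.
#' @param outBins output bins (default 24).
#' @return a 4 x \code{outBins} matrix whose global maximum is at time
#'   index 4.
#' @export
alignLifetime <- function(raw, outBins = 24L) {
  stopifnot(is.matrix(raw), nrow(raw) == 4L, ncol(raw) >= outBins)
  if (max(raw) <= 0) stop("all-zero lifetime trace cannot be aligned")
  peak <- .lifetimeArgmaxBin(raw)        # 0-based
  shift <- peak - 4L                     # source bin = output bin + shift
  out <- matrix(0, 4L, outBins)
  src <- seq_len(outBins) + shift        # 1-based source columns
  ok <- src >= 1L & src <= ncol(raw)
  out[, ok] <- raw[, src[ok]]
  out
}

#' Stack the retained spectrum acquisitions
#'
#' Keeps the first four of the eight timed fluorescence acquisitions (the
#' earliest after excitation, which carry the strongest signal) as the
#' 4 x 32 spectrum image.
#'
#' @param raw numeric matrix with 8 acquisition rows and 32 wavelengths.
#' @return a 4 x 32 matrix.
#' @export
stackSpectrum <- function(raw) {
  if (!is.matrix(raw) || nrow(raw) != 8L)
    stop("spectrum must have exactly 8 acquisition rows")
  raw[1:4, , drop = FALSE]
}

#' Derive the four normalized lifetime band features
#'
#' For each spectral band the noise level is estimated as the mean of the
#' first two (pre-rise) bins of the aligned trace; the noise-corrected
#' signal is summed (negative residuals clipped at zero) and the four sums
#' are normalized by their maximum, so the largest feature is exactly 1
#' whenever any band carries positive corrected signal.
#'
#' @param lifetime aligned 4 x 24 lifetime image.
#' @return numeric vector of 4 features in [0, 1].
#' @export
deriveLifetimeFeatures <- function(lifetime) {
  stopifnot(is.matrix(lifetime), nrow(lifetime) == 4L)
  noise <- rowMeans(lifetime[, 1:2, drop = FALSE])
  s <- rowSums(pmax(lifetime - noise, 0))
  if (max(s) <= 0) {
    warning("no positive noise-corrected lifetime signal in any band")
    return(numeric(4L))
  }
  s / max(s)
}

#' Derive the logarithmic size feature
#'
#' The particle-size proxy is the natural logarithm of the total pixel
#' intensity of the preprocessed scattering image (proportionality constant
#' one).  A configuration switch allows deriving it from the spectrum image
#' instead.
#'
#' @param img preprocessed 20 x 120 scattering image (or 4 x 32 spectrum
#'   image when \code{from = "spectrum"}).
#' @param from which modality the image belongs to; documentation only.
#' @return a single number, \code{log(sum(img))}.
#' @export
deriveSizeFeature <- function(img, from = c("scattering", "spectrum")) {
  from <- match.arg(from)
  s <- sum(img)
  if (s <= 0)
    stop("size feature undefined for a zero-sum image ",
         "(such records should have been filtered out)")
  log(s)
}

#' Preprocess raw particles into clean model inputs
#'
#' Runs [filterParticles()] and then, per surviving record,
#' [centerCropScattering()], [stackSpectrum()], [alignLifetime()],
#' [deriveLifetimeFeatures()] and [deriveSizeFeature()].
#'
#' @param x a [RawParticleSet-class].
#' @param thresholds output of [filterThresholds()].
#' @param sizeFrom modality for the size feature, \code{"scattering"}
#'   (default) or \code{"spectrum"}.
#' @return a [CleanSampleSet-class] of the kept records; the filtering
#'   report is attached as \code{attr(, "filterReport")}.
#' @examples
#' raw <- generateParticles(defaultClassSpecs(), 5, seed = 2)
#' clean <- preprocessParticles(raw)
#' clean
#' @export
preprocessParticles <- function(x, thresholds = filterThresholds(),
                                sizeFrom = c("scattering", "spectrum")) {
  sizeFrom <- match.arg(sizeFrom)
  res <- filterParticles(x, thresholds)
  kept <- res$kept
  n <- length(kept)
  sc <- array(0, c(20L, 120L, n))
  sp <- array(0, c(4L, 32L, n))
  lt <- array(0, c(4L, 24L, n))
  ltf <- matrix(0, 4L, n)
  sz <- numeric(n)
  for (i in seq_len(n)) {
    r <- kept@records[[i]]
    sc[, , i] <- centerCropScattering(r$scattering)
    sp[, , i] <- stackSpectrum(r$spectrum)
    lt[, , i] <- alignLifetime(r$lifetime)
    ltf[, i] <- deriveLifetimeFeatures(lt[, , i])
    sz[i] <- if (sizeFrom == "scattering")
      deriveSizeFeature(sc[, , i]) else deriveSizeFeature(sp[, , i], "spectrum")
  }
  out <- new("CleanSampleSet", scattering = sc, spectrum = sp, lifetime = lt,
             ltFeatures = ltf, sizeFeature = sz, labels = kept@labels)
  attr(out, "filterReport") <- res$report
  out
}
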