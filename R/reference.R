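# Knowledge extraction from laboratory reference fluorescence spectra:
# rectangular-kernel resampling onto the instrument's 32-point wavelength
# grid, PCA of the transformed spectra, and the correlation of size-feature
# attributions with reference grain diameters.

#' The instrument's 32-point wavelength grid
#'
#' Wavelengths \eqn{\lambda_j = 350 + j \cdot 14.51} nm for
#' \eqn{j = 0, \dots, 31}, matching the 14.51 nm spectral resolution of the
#' detector's 32 wavelength channels over 350--800 nm.
#'
#' @return list with \code{wavelengths} (32 values) and \code{resolution}
#'   (14.51 nm).
#' @examples
#' length(rapidEGrid()$wavelengths)  # 32
#' @export
rapidEGrid <- function() {
  wl <- .rapidEWavelengths()
  stopifnot(length(wl) == 32L, all(wl >= 350), all(wl <= 800))
  list(wavelengths = wl, resolution = 14.51)
}

#' Resample a 1 nm reference spectrum onto the instrument grid
#'
#' Filters the high-resolution spectrum with a rectangular kernel of
#' half-width equal to the instrument's spectral resolution and samples it
#' at the 32 grid wavelengths: output \eqn{j} is the unweighted mean of all
#' reference intensities whose wavelength lies within
#' \eqn{\lambda_j \pm 14.51} nm, with windows clipped at the domain edges.
#'
#' @param intensities numeric vector of reference intensities.
#' @param wavelengths corresponding wavelengths in nm (default the 1 nm
#'   grid 350..800).
#' @param grid output of [rapidEGrid()].
#' @return numeric vector of 32 resampled intensities.
#' @export
transformSpectrum <- function(intensities, wavelengths = 350:800,
                              grid = rapidEGrid()) {
  stopifnot(length(intensities) == length(wavelengths))
  if (any(grid$wavelengths < min(wavelengths) |
          grid$wavelengths > max(wavelengths)))
    stop("grid wavelengths fall outside the reference spectrum domain")
  vapply(grid$wavelengths, function(wj)
    mean(intensities[abs(wavelengths - wj) <= grid$resolution]),
    numeric(1L))
}

#' Transform a tidy set of reference spectra
#'
#' @param df data.frame with columns \code{class}, \code{replicate},
#'   \code{wavelength_nm}, \code{intensity} (one spectrum per
#'   class/replicate pair).
#' @param grid output of [rapidEGrid()].
#' @return matrix (spectra x 32) of transformed intensities, with row
#'   names \code{class_replicate} and the source class per row in
#'   \code{attr(, "class_name")}.
#' @export
transformReferenceSpectra <- function(df, grid = rapidEGrid()) {
  need <- c("class", "replicate", "wavelength_nm", "intensity")
  stopifnot(all(need %in% names(df)))
  keys <- unique(df[, c("class", "replicate")])
  out <- matrix(0, nrow(keys), 32L)
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$class == keys$class[i] & df$replicate == keys$replicate[i],
              , drop = FALSE]
    sub <- sub[order(sub$wavelength_nm), , drop = FALSE]
    out[i, ] <- transformSpectrum(sub$intensity, sub$wavelength_nm, grid)
  }
  rownames(out) <- paste(keys$class, keys$replicate, sep = "_")
  attr(out, "class_name") <- as.character(keys$class)
  out
}

## local maxima (strict interior, plus dominant endpoints) of a vector
.localMaxima <- function(v) {
  n <- length(v)
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
  if (v[1L] > v[2L]) idx <- c(1L, idx)
  if (v[n] > v[n - 1L]) idx <- c(idx, n)
  sort(idx)
}

#' PCA of transformed reference spectra
#'
#' Mean-centred (un-standardized) principal component analysis of the
#' 32-point transformed reference spectra, retaining three components.
#' Reports the explained-variance ratios, the per-spectrum scores in the
#' 3-D latent space, and the wavelengths at which each component's absolute
#' coefficients peak.
#'
#' @param transformed matrix (spectra x 32), e.g. from
#'   [transformReferenceSpectra()]; at least 4 spectra are required.
#' @param grid output of [rapidEGrid()].
#' @return a [SpectraPCA-class].
#' @export
pcaKnowledge <- function(transformed, grid = rapidEGrid()) {
  if (!is.matrix(transformed) || ncol(transformed) != 32L)
    stop("transformed must be a (spectra x 32) matrix")
  if (nrow(transformed) < 4L)
    stop("at least 4 spectra are required for a 3-component PCA")
  pr <- stats::prcomp(transformed, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  comps <- t(pr$rotation[, 1:3, drop = FALSE])
  peaks <- lapply(1:3, function(k)
    grid$wavelengths[.localMaxima(abs(comps[k, ]))])
  new("SpectraPCA", components = unname(comps),
      explainedVarianceRatio = evr[1:3],
      scores = unname(pr$x[, 1:3, drop = FALSE]),
      coefficientPeaks = peaks,
      center = as.numeric(pr$center),
      gridWavelengths = grid$wavelengths)
}

#' Correlation of size-feature attributions with reference diameters
#'
#' Pearson correlation between the per-class mean attribution of the
#' scattering-derived size feature and the per-class reference mean grain
#' diameter, paired by class name.
#'
#' @param summary a [ClassAttributionSummary-class].
#' @param referenceSizes data.frame with columns \code{class} and
#'   \code{mean_diameter_um}.
#' @return the Pearson correlation coefficient.
#' @export
sizeCorrelation <- function(summary, referenceSizes) {
  stopifnot(is(summary, "ClassAttributionSummary"),
            all(c("class", "mean_diameter_um") %in% names(referenceSizes)))
  tab <- summary@table
  sz <- tab[tab$modality == "size_feature", , drop = FALSE]
  a <- setdiff(sz$class, referenceSizes$class)
  b <- setdiff(referenceSizes$class, sz$class)
  if (length(a) || length(b))
    stop("class sets differ; only in summary: ",
         paste(a, collapse = ", "), "; only in reference: ",
         paste(b, collapse = ", "))
  if (nrow(sz) < 3L)
    stop("at least 3 classes are required")
  d <- referenceSizes$mean_diameter_um[match(sz$class,
                                             referenceSizes$class)]
  stats::cor(sz$mean, d)
}
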