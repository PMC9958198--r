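# Model-level explanations: pool instance attributions per class into
# mean / mean-absolute statistics, five-level sign codes, importance ranks,
# and scattering mean-attribution maps.

.modalityMeta <- local({
  meta <- NULL
  function() {
    if (!is.null(meta)) return(meta)
    grid <- .rapidEWavelengths()
    sc <- data.frame(modality = "scattering",
                     row = rep(0:19, times = 120L),
                     col = rep(0:119, each = 20L))
    sc$feature_id <- sc$row * 120L + sc$col
    sc$wavelength_or_bin <- sc$col
    sp <- data.frame(modality = "spectrum",
                     row = rep(0:3, times = 32L),
                     col = rep(0:31, each = 4L))
    sp$feature_id <- sp$row * 32L + sp$col
    sp$wavelength_or_bin <- grid[sp$col + 1L]
    lt <- data.frame(modality = "lifetime",
                     row = rep(0:3, times = 24L),
                     col = rep(0:23, each = 4L))
    lt$feature_id <- lt$row * 24L + lt$col
    lt$wavelength_or_bin <- lt$col
    ltf <- data.frame(modality = "lt_features", row = 0:3, col = NA_integer_,
                      feature_id = 0:3, wavelength_or_bin = NA_real_)
    sz <- data.frame(modality = "size_feature", row = 0L, col = NA_integer_,
                     feature_id = 0L, wavelength_or_bin = NA_real_)
    meta <<- rbind(sc, sp, lt, ltf, sz)
    meta
  }
})

## five-level sign code from the sign-consistency ratio s = mean / mean_abs
.signLevel <- function(m, ma) {
  s <- ifelse(ma > 0, m / ma, 0)
  ifelse(s > 0.75, "strong_positive",
    ifelse(s > 0.25, "positive",
      ifelse(s >= -0.25, "mixed",
        ifelse(s >= -0.75, "negative", "strong_negative"))))
}

#' Aggregate instance attributions into per-class summaries
#'
#' Pools all attribution records of each class (by predicted class by
#' default) and computes, per input feature, the mean signed attribution,
#' the mean absolute attribution, a five-level sign-consistency code
#' (cutoffs at \eqn{\pm 0.25} and \eqn{\pm 0.75} on the ratio
#' mean / mean-absolute) and the feature's importance rank within its
#' modality (descending mean absolute attribution, ties broken by feature
#' index).
#'
#' @param records an [AttributionSet-class].
#' @param poolBy \code{"predicted"} (default) or \code{"true"}: which label
#'   assigns a record to a class.
#' @param onlyCorrect pool only records whose prediction matches the true
#'   label.
#' @return a [ClassAttributionSummary-class]; classes without pooled
#'   records are omitted with a warning.
#' @export
summarizeAttributions <- function(records, poolBy = c("predicted", "true"),
                                  onlyCorrect = FALSE) {
  stopifnot(is(records, "AttributionSet"))
  poolBy <- match.arg(poolBy)
  if (length(records) == 0L) stop("no attribution records to summarize")
  key <- if (poolBy == "predicted") records@predictedClass
         else records@trueLabel
  if (anyNA(key)) stop("pooling labels contain NA")
  use <- rep(TRUE, length(records))
  if (onlyCorrect) {
    if (anyNA(records@trueLabel))
      stop("onlyCorrect requires true labels")
    use <- records@predictedClass == records@trueLabel
  }
  classes <- sort(unique(key))
  meta <- .modalityMeta()
  rows <- list()
  pooled <- integer()
  for (cl in classes) {
    idx <- which(key == cl & use)
    if (!length(idx)) {
      warning("class ", cl, " has no pooled records; omitted")
      next
    }
    A <- rbind(matrix(records@scattering[, , idx], 2400L, length(idx)),
               matrix(records@spectrum[, , idx], 128L, length(idx)),
               matrix(records@lifetime[, , idx], 96L, length(idx)),
               matrix(records@ltFeatures[, idx], 4L, length(idx)),
               matrix(records@sizeFeature[idx], 1L, length(idx)))
    m <- rowMeans(A)
    ma <- rowMeans(abs(A))
    df <- cbind(data.frame(class = cl), meta)
    df$mean <- m
    df$mean_abs <- ma
    df$sign_level <- .signLevel(m, ma)
    df$rank <- NA_integer_
    for (mod in unique(meta$modality)) {
      sel <- which(df$modality == mod)
      o <- order(-df$mean_abs[sel], df$feature_id[sel])
      df$rank[sel[o]] <- seq_along(sel)
    }
    rows[[cl]] <- df
    pooled[cl] <- length(idx)
  }
  if (!length(rows)) stop("no class had pooled records")
  new("ClassAttributionSummary", table = do.call(rbind, c(rows,
        list(make.row.names = FALSE))),
      nPooled = stats::setNames(as.integer(pooled), names(pooled)),
      poolBy = poolBy)
}

#' Top-ranked features of a modality, per class
#'
#' @param summary a [ClassAttributionSummary-class].
#' @param modality one of \code{"scattering"}, \code{"spectrum"},
#'   \code{"lifetime"}, \code{"lt_features"}, \code{"size_feature"}.
#' @param k features per class (default 10); if \code{k} exceeds the
#'   feature count, all features are returned with a warning.
#' @return data.frame of the \code{k} highest mean-absolute-attribution
#'   features per class, ordered by class and rank.
#' @export
topFeatures <- function(summary, modality = "spectrum", k = 10L) {
  stopifnot(is(summary, "ClassAttributionSummary"), k >= 1L)
  tab <- summary@table
  modality <- match.arg(modality, unique(tab$modality))
  sub <- tab[tab$modality == modality, , drop = FALSE]
  nf <- max(sub$rank)
  if (k > nf) {
    warning("k = ", k, " exceeds the ", nf, " features of ", modality,
            "; returning all")
    k <- nf
  }
  out <- sub[sub$rank <= k, , drop = FALSE]
  out <- out[order(out$class, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class mean-attribution maps over the scattering image
#'
#' @param summary a [ClassAttributionSummary-class] covering the
#'   scattering modality.
#' @return named list (one element per class) of 20 x 120 matrices of mean
#'   signed attributions; entry \code{[r, c]} is the mean attribution of
#'   scattering feature index \code{(r-1) * 120 + (c-1)}.
#' @export
scatteringMap <- function(summary) {
  stopifnot(is(summary, "ClassAttributionSummary"))
  tab <- summary@table
  sub <- tab[tab$modality == "scattering", , drop = FALSE]
  if (!nrow(sub)) stop("summary does not cover the scattering modality")
  lapply(stats::setNames(nm = names(summary@nPooled)), function(cl) {
    s <- sub[sub$class == cl, , drop = FALSE]
    img <- matrix(0, 20L, 120L)
    img[cbind(s$row + 1L, s$col + 1L)] <- s$mean
    img
  })
}

#' Write a class summary to CSV
#'
#' @param summary a [ClassAttributionSummary-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSummary <- function(summary, path) {
  utils::write.csv(summaryTable(summary), path, row.names = FALSE)
  invisible(path)
}
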