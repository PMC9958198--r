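# Plotting helpers: symbolic heatmaps of aggregated attributions,
# per-class scattering attribution maps, and paired input/attribution
# panels for single instances.

.signPalette <- c(strong_negative = "#b2182b", negative = "#ef8a62",
                  mixed = "#999999", positive = "#67a9cf",
                  strong_positive = "#2166ac")

#' Symbolic heatmap of aggregated attributions
#'
#' One glyph per (class, feature): glyph size encodes the mean absolute
#' attribution (importance), colour the five-level sign-consistency code.
#'
#' @param summary a [ClassAttributionSummary-class].
#' @param modality modality to display (default \code{"spectrum"}).
#' @param topK show only each class's \code{topK} features (0 = all).
#' @return a ggplot object.
#' @export
plotSymbolicHeatmap <- function(summary, modality = "spectrum",
                                topK = 0L) {
  tab <- summaryTable(summary)
  sub <- tab[tab$modality == modality, , drop = FALSE]
  if (!nrow(sub)) stop("summary does not cover modality ", modality)
  if (topK > 0L) sub <- sub[sub$rank <= topK, , drop = FALSE]
  sub$sign_level <- factor(sub$sign_level, names(.signPalette))
  ggplot2::ggplot(sub,
      ggplot2::aes(x = .data$feature_id, y = .data$class,
                   size = .data$mean_abs, colour = .data$sign_level)) +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::scale_colour_manual(values = .signPalette, drop = FALSE) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = paste(modality, "feature index"), y = NULL,
                  size = "mean |attribution|", colour = "sign") +
    ggplot2::theme_minimal()
}

#' Mean scattering attribution map for one class
#'
#' @param summary a [ClassAttributionSummary-class].
#' @param class class to display.
#' @return a ggplot object (blue positive, red negative contributions).
#' @export
plotScatteringMap <- function(summary, class) {
  maps <- scatteringMap(summary)
  if (!class %in% names(maps)) stop("unknown class: ", class)
  img <- maps[[class]]
  df <- data.frame(angle = rep(seq(-37.5, 37.5, length.out = 20L), 120L),
                   time = rep(0:119, each = 20L),
                   value = as.numeric(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$angle,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(title = class, x = "laser interaction (time)",
                  y = "scattering angle (deg)", fill = "mean attr.") +
    ggplot2::theme_minimal()
}

#' Paired input/attribution panels for one explained instance
#'
#' @param explained output of [explainInstance()].
#' @param modality which modality pair to display.
#' @return a ggplot object with an input panel and an attribution panel.
#' @export
plotInstanceExplanation <- function(explained, modality = "spectrum") {
  pr <- Filter(function(p) p$modality == modality, explained$pairs)
  if (!length(pr)) stop("no such modality: ", modality)
  pr <- pr[[1L]]
  toDf <- function(m, panel) {
    m <- as.matrix(m)
    data.frame(row = rep(seq_len(nrow(m)), ncol(m)),
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.numeric(m), panel = panel)
  }
  df <- rbind(toDf(pr$input, "input"), toDf(pr$attribution, "attribution"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = modality) +
    ggplot2::theme_minimal()
}
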