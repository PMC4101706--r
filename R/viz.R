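## Embedding scatter plots with tangent arrows, and group-median profiles.

#' Plot an embedding with optional tangent fields
#'
#' Scatter plot of a two-dimensional embedding with one marker per sample
#' (colour from one factor, glyph from another), one arrow per sample and
#' tangent field anchored at the sample's coordinates, and an optional
#' global reference arrow from the grand centroid. Arrows are by default
#' unit-normalized and scaled to a fraction of the axis range so direction,
#' not magnitude, is read off the plot; \code{arrowScale = "raw"} keeps
#' the tangent norms.
#'
#' @param embedding an \linkS4class{Embedding} with r = 2.
#' @param colorBy,symbolBy optional factors, one value per sample.
#' @param fields list of \linkS4class{TangentField} objects from the same
#'   model.
#' @param w optional reference r-vector drawn from the grand centroid.
#' @param arrowScale \code{"normalized"} or \code{"raw"}.
#' @param arrowFrac arrow length as a fraction of the axis range in
#'   normalized mode (default 0.08).
#' @param file optional output path (.png/.svg/.pdf); when given the plot
#'   is also written there.
#' @returns a ggplot object, invisibly when \code{file} is given.
#' @export
plotEmbedding <- function(embedding, colorBy = NULL, symbolBy = NULL,
                          fields = list(), w = NULL,
                          arrowScale = c("normalized", "raw"),
                          arrowFrac = 0.08, file = NULL) {
    arrowScale <- match.arg(arrowScale)
    co <- embedding@coords
    if (ncol(co) != 2L)
        stop("plotEmbedding needs a two-dimensional embedding (r = 2)")
    vs <- embedding@varianceShare
    df <- data.frame(comp_1 = co[, 1L], comp_2 = co[, 2L])
    n <- nrow(df)
    aesArgs <- list(x = quote(comp_1), y = quote(comp_2))
    if (!is.null(colorBy)) {
        stopifnot(length(colorBy) == n)
        df$colour <- factor(colorBy)
        aesArgs$colour <- quote(colour)
    }
    if (!is.null(symbolBy)) {
        stopifnot(length(symbolBy) == n)
        df$shape <- factor(symbolBy)
        aesArgs$shape <- quote(shape)
    }
    p <- ggplot2::ggplot(df, do.call(ggplot2::aes, aesArgs)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::labs(
            x = sprintf("Component 1 (%.1f%%)", 100 * vs[1L]),
            y = sprintf("Component 2 (%.1f%%)", 100 * vs[2L]),
            colour = NULL, shape = NULL) +
        ggplot2::theme_bw()
    rng <- max(apply(co, 2L, function(v) diff(range(v))))
    scaleField <- function(V) {
        if (arrowScale == "raw") return(V)
        nv <- sqrt(rowSums(V^2))
        nv[nv < .DEGENERATE_NORM] <- 1
        V / nv * (arrowFrac * rng)
    }
    fieldCols <- grDevices::hcl.colors(max(1L, length(fields)), "Dark 3")
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (!all(dim(f@anchors) == dim(co)))
            stop("tangent field does not match the embedding")
        V <- scaleField(f@vectors)
        seg <- data.frame(x = f@anchors[, 1L], y = f@anchors[, 2L],
                          xend = f@anchors[, 1L] + V[, 1L],
                          yend = f@anchors[, 2L] + V[, 2L])
        p <- p + ggplot2::geom_segment(
            data = seg,
            ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
            inherit.aes = FALSE, colour = fieldCols[i],
            arrow = grid::arrow(length = grid::unit(0.12, "cm")))
    }
    if (!is.null(w)) {
        base <- colMeans(co)
        wv <- w / sqrt(sum(w^2)) * (2 * arrowFrac * rng)
        seg <- data.frame(x = base[1L], y = base[2L],
                          xend = base[1L] + wv[1L], yend = base[2L] + wv[2L])
        p <- p + ggplot2::geom_segment(
            data = seg,
            ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
            inherit.aes = FALSE, colour = "darkgreen", linewidth = 1,
            arrow = grid::arrow(length = grid::unit(0.2, "cm")))
    }
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 6, height = 5)
        return(invisible(p))
    }
    p
}

#' Plot a group-median profile
#'
#' Line-and-point profile of per-group medians (for example of one gene's
#' expression across genotypes or diets), in the given group order.
#'
#' @param medians named numeric vector, as returned by
#'   \code{\link{groupMedianProfile}}.
#' @param title optional plot title.
#' @param file optional output path.
#' @returns a ggplot object, invisibly when \code{file} is given.
#' @export
plotProfile <- function(medians, title = NULL, file = NULL) {
    if (length(medians) < 1L) stop("at least one group required")
    df <- data.frame(group = factor(names(medians), levels = names(medians)),
                     median = as.numeric(medians))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = median, group = 1)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
        ggplot2::labs(x = NULL, y = "median", title = title) +
        ggplot2::theme_bw()
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 5, height = 4)
        return(invisible(p))
    }
    p
}
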