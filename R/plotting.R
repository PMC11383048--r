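## Cluster plots: Theta on x, R on y, points colored by genotype, with an
## optional semi-transparent background layer from a second genotype source.

#' Plot the genotype clusters of one SNP
#'
#' Scatter of the SNP's per-sample probe measurements — Theta (allelic
#' ratio) on the x axis, R (normalized intensity) on the y axis — colored by
#' genotype with the fixed palette of \code{\link{genotypePalette}}. Several
#' genotype sources (e.g. Gencall, predicted, imputed) can be shown as one
#' panel each, and a further source can be drawn as a semi-transparent
#' background layer behind every panel.
#'
#' The homozygote for Illumina allele A (AA) falls at low theta (left), the
#' other homozygote (BB) at high theta (right), heterozygotes in the middle.
#'
#' @param x a \linkS4class{SnpMetrics}.
#' @param snpId the snpID to plot (must be present in \code{x}).
#' @param layers named list of genotype vectors (over AA/AB/BB/NC), each
#'   aligned with the SNP's records in \code{x}; default is the metrics'
#'   own genotype column, labelled "gencall". At most 3 layers.
#' @param background optional genotype vector (aligned likewise) drawn as a
#'   transparent background layer in every panel.
#' @param pointSize point size.
#' @return A ggplot object (one panel per layer).
#' @export
plotSnpClusters <- function(x, snpId, layers = NULL, background = NULL,
                            pointSize = 1.5) {
    df <- x@records
    sel <- df$snpID == snpId
    if (!any(sel))
        stop("unknown SNP '", snpId, "'; available: ",
             paste(head(sort(unique(df$snpID)), 10L), collapse = ", "),
             if (length(unique(df$snpID)) > 10L) ", ...", call. = FALSE)
    df <- df[sel, , drop = FALSE]
    if (is.null(layers)) layers <- list(gencall = df$genotype)
    stopIfNot(length(layers) <= 3L, "at most 3 genotype layers")
    stopIfNot(!is.null(names(layers)) && all(nzchar(names(layers))),
              "layers must be named")
    for (nm in names(layers))
        stopIfNot(length(layers[[nm]]) == nrow(df),
                  paste0("layer '", nm, "' must align with the SNP's records"))

    long <- do.call(rbind, lapply(names(layers), function(nm)
        data.frame(theta = df$theta, r = df$r,
                   genotype = factor(layers[[nm]], levels = GT_LEVELS),
                   source = nm, stringsAsFactors = FALSE)))
    long$source <- factor(long$source, levels = names(layers))

    p <- ggplot2::ggplot(long, ggplot2::aes(x = theta, y = r))
    if (!is.null(background)) {
        stopIfNot(length(background) == nrow(df),
                  "background must align with the SNP's records")
        bg <- do.call(rbind, lapply(names(layers), function(nm)
            data.frame(theta = df$theta, r = df$r,
                       genotype = factor(background, levels = GT_LEVELS),
                       source = factor(nm, levels = names(layers)))))
        p <- p + ggplot2::geom_point(
            data = bg, ggplot2::aes(color = genotype),
            alpha = 0.25, size = pointSize * 1.6, shape = 16)
    }
    p + ggplot2::geom_point(ggplot2::aes(color = genotype),
                            size = pointSize, shape = 16) +
        ggplot2::scale_color_manual(values = genotypePalette(),
                                    drop = FALSE, name = "genotype") +
        ggplot2::facet_wrap(~source) +
        ggplot2::coord_cartesian(xlim = c(0, 1)) +
        ggplot2::labs(title = snpId, x = "Theta (allelic ratio)",
                      y = "R (normalized intensity)") +
        ggplot2::theme_bw()
}
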