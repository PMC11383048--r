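## Per-genotype cluster geometry in (theta, r) space and flagging of SNPs
## whose raw data do not exhibit genotype clustering.

#' Compute per-genotype cluster geometry for one SNP
#'
#' For each genotype class present among the labels, computes the point
#' count, the mean centroid in (theta, r), and the cluster width — the
#' root-mean-square Euclidean distance of the class's points to its centroid
#' (optionally per-axis standard deviations combined in quadrature behave
#' identically up to the n vs n-1 divisor; RMS is the default and the one
#' used for flagging). Also records the absolute theta separation of every
#' present centroid pair and the minimum centroid R.
#'
#' Labels may come from any genotype source — imputed genotypes (the
#' intended use for QC), Gencall calls, or predictions.
#'
#' @param theta,r numeric vectors of probe measurements.
#' @param labels genotype per point, over AA/AB/BB.
#' @return A \linkS4class{ClusterGeometry}.
#' @export
#' @examples
#' computeGeometry(c(0.1, 0.3), c(1, 1), c("AA", "AA"))
computeGeometry <- function(theta, r, labels) {
    stopIfNot(length(theta) > 0L, "empty input")
    stopIfNot(length(theta) == length(r) && length(r) == length(labels),
              "theta, r and labels must have equal length")
    stopIfNot(all(labels %in% GT_CLASSES), "labels must be AA/AB/BB")
    classes <- GT_CLASSES[GT_CLASSES %in% labels]
    k <- length(classes)
    centroids <- matrix(NA_real_, k, 2L,
                        dimnames = list(classes, c("theta", "r")))
    n <- setNames(integer(k), classes)
    widths <- setNames(numeric(k), classes)
    for (i in seq_len(k)) {
        sel <- labels == classes[i]
        n[i] <- sum(sel)
        centroids[i, ] <- c(mean(theta[sel]), mean(r[sel]))
        widths[i] <- sqrt(mean((theta[sel] - centroids[i, 1L])^2 +
                               (r[sel] - centroids[i, 2L])^2))
    }
    seps <- numeric(0)
    if (k >= 2L) {
        pairs <- combn(k, 2L)
        seps <- abs(centroids[pairs[1L, ], 1L] - centroids[pairs[2L, ], 1L])
        names(seps) <- paste(classes[pairs[1L, ]], classes[pairs[2L, ]],
                             sep = "-")
    }
    new("ClusterGeometry", classes = classes, n = n, centroids = centroids,
        widths = widths, thetaSeparations = seps,
        minCentroidR = min(centroids[, 2L]))
}

#' Flag a SNP for non-clustering behavior
#'
#' A SNP is unsuitable for array genotyping when its genotype clusters are
#' too wide, its cluster centroids sit too close together along theta, or
#' its centroids have very low R coordinates (weak signal). Flags:
#' \itemize{
#'   \item \code{too_wide}: any present class width exceeds \code{wMax};
#'   \item \code{centroids_too_close}: any present centroid pair closer than
#'     \code{dMin} in theta (set \code{jointDistance = TRUE} to measure
#'     Euclidean distance in (theta, r) instead);
#'   \item \code{low_r_centroid}: the minimum centroid R is below \code{rMin};
#'   \item \code{insufficient_data}: every present class has fewer than
#'     \code{nMin} points (informational; does not by itself flag the SNP).
#' }
#'
#' Default thresholds (wMax 0.10, dMin 0.10 theta units, rMin 0.20, nMin 3)
#' reflect the usual geometry of well-behaved SNPs — homozygote clusters near
#' theta 0 and 1, heterozygotes near 0.5 — and are configurable.
#'
#' @param geometry a \linkS4class{ClusterGeometry}.
#' @param wMax,dMin,rMin,nMin thresholds as above.
#' @param jointDistance measure centroid closeness in (theta, r) jointly.
#' @return list with \code{flags} (character subset of the four flag names)
#'   and \code{flagged} (TRUE when any geometric flag is set).
#' @export
flagSnp <- function(geometry, wMax = 0.10, dMin = 0.10, rMin = 0.20,
                    nMin = 3L, jointDistance = FALSE) {
    flags <- character()
    if (any(geometry@widths > wMax)) flags <- c(flags, "too_wide")
    seps <- geometry@thetaSeparations
    if (jointDistance && length(geometry@classes) >= 2L) {
        pairs <- combn(length(geometry@classes), 2L)
        seps <- sqrt(colSums((geometry@centroids[pairs[1L, ], , drop = FALSE] -
                              geometry@centroids[pairs[2L, ], , drop = FALSE])^2))
    }
    if (length(seps) && any(seps < dMin))
        flags <- c(flags, "centroids_too_close")
    if (geometry@minCentroidR < rMin) flags <- c(flags, "low_r_centroid")
    if (all(geometry@n < nMin)) flags <- c(flags, "insufficient_data")
    list(flags = flags,
         flagged = length(setdiff(flags, "insufficient_data")) > 0L)
}

#' Flag every SNP in a metrics panel
#'
#' Convenience wrapper running \code{\link{computeGeometry}} and
#' \code{\link{flagSnp}} per SNP over a metrics table, using a chosen
#' genotype source for the labels.
#'
#' @param x a \linkS4class{SnpMetrics}; records with NC or missing genotype,
#'   theta or r are ignored.
#' @param labels optional character vector overriding the genotype column
#'   (same length as \code{nRecords(x)}), e.g. imputed genotypes.
#' @param ... thresholds passed to \code{\link{flagSnp}}.
#' @return data.frame with one row per SNP: snpID, variant key, per-class
#'   counts and widths, minimum theta separation, minimum centroid R, flags
#'   (comma-separated) and flagged.
#' @export
flagPanel <- function(x, labels = NULL, ...) {
    df <- x@records
    gt <- if (is.null(labels)) df$genotype else as.character(labels)
    stopIfNot(length(gt) == nrow(df), "labels length must match records")
    use <- !is.na(gt) & gt %in% GT_CLASSES & !is.na(df$theta) & !is.na(df$r)
    df <- df[use, , drop = FALSE]
    gt <- gt[use]
    out <- lapply(split(seq_len(nrow(df)), df$snpID), function(i) {
        geo <- computeGeometry(df$theta[i], df$r[i], gt[i])
        fl <- flagSnp(geo, ...)
        nByClass <- setNames(rep(0L, 3L), GT_CLASSES)
        nByClass[geo@classes] <- geo@n
        wByClass <- setNames(rep(NA_real_, 3L), GT_CLASSES)
        wByClass[geo@classes] <- geo@widths
        data.frame(snpID = df$snpID[i[1L]], chromosome = df$chromosome[i[1L]],
                   position = df$position[i[1L]], ref = df$ref[i[1L]],
                   alt = df$alt[i[1L]],
                   n_AA = nByClass[["AA"]], n_AB = nByClass[["AB"]],
                   n_BB = nByClass[["BB"]],
                   width_AA = wByClass[["AA"]], width_AB = wByClass[["AB"]],
                   width_BB = wByClass[["BB"]],
                   min_theta_separation = if (length(geo@thetaSeparations))
                       min(geo@thetaSeparations) else NA_real_,
                   min_centroid_r = geo@minCentroidR,
                   flags = paste(fl$flags, collapse = ","),
                   flagged = fl$flagged, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- out[order(out$chromosome, out$position), , drop = FALSE]
    rownames(out) <- NULL
    out
}
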