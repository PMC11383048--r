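#' @rdname SnpMetrics-class
#' @param x,object a \linkS4class{SnpMetrics} (or other class as documented).
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname SnpMetrics-class
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname TrainedGenotyper-class
#' @param x a \linkS4class{TrainedGenotyper} or \linkS4class{EncodedDataset}.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname TrainedGenotyper-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname DosageCallset-class
#' @param x a \linkS4class{DosageCallset}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname PredictionResult-class
#' @param x a \linkS4class{PredictionResult}.
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname PredictionResult-class
#' @export
setGeneric("predictedGenotype", function(x) standardGeneric("predictedGenotype"))

setMethod("metricsTable", "SnpMetrics", function(x) x@records)
setMethod("nRecords", "SnpMetrics", function(x) nrow(x@records))
setMethod("vocabulary", "TrainedGenotyper", function(x) x@vocabulary)
setMethod("vocabulary", "EncodedDataset", function(x) x@vocabulary)
setMethod("trainingHistory", "TrainedGenotyper", function(x) x@history)
setMethod("dosages", "DosageCallset", function(x) x@dosages)
setMethod("probabilities", "PredictionResult", function(x) x@probabilities)
setMethod("predictedGenotype", "PredictionResult", function(x) x@predicted)

#' @rdname SnpMetrics-class
#' @param i row indices (any base subscript form).
#' @export
setMethod("[", "SnpMetrics", function(x, i) {
    initialize(x, records = {
        df <- x@records[i, , drop = FALSE]
        rownames(df) <- NULL
        df
    })
})

#' @rdname SnpMetrics-class
#' @export
setMethod("length", "SnpMetrics", function(x) nrow(x@records))

setMethod("show", "SnpMetrics", function(object) {
    df <- object@records
    cat("SnpMetrics with", nrow(df), "records:",
        length(unique(df$snpID)), "SNPs x",
        length(unique(df$sampleID)), "samples\n")
    gt <- table(factor(df$genotype, levels = GT_LEVELS), useNA = "ifany")
    cat("  genotypes:", paste(names(gt), gt, sep = "=", collapse = " "), "\n")
    if (nrow(df)) {
        cat("  head:\n")
        print(head(df, 3L))
    }
})

setMethod("show", "TrainedGenotyper", function(object) {
    cfg <- object@config
    cat("TrainedGenotyper:", length(object@vocabulary), "SNPs, embedding dim",
        cfg@embeddingDim, "\n")
    cat("  dense layers:", paste(cfg@hiddenUnits, collapse = " -> "),
        "-> 3 (softmax)\n")
    if (nrow(object@history)) {
        last <- object@history[nrow(object@history), ]
        cat(sprintf("  trained %d epochs; final val loss %.6g, val accuracy %.4f\n",
                    nrow(object@history), last$val_loss, last$val_accuracy))
    }
})

setMethod("show", "DosageCallset", function(object) {
    cat("DosageCallset [", object@technology, "]: ",
        length(object@samples), " samples x ", nrow(object@variants),
        " variants\n", sep = "")
})

setMethod("show", "ClusterGeometry", function(object) {
    cat("ClusterGeometry over classes:",
        paste(object@classes, collapse = ", "), "\n")
    for (k in seq_along(object@classes))
        cat(sprintf("  %s: n=%d centroid=(%.3f, %.3f) width=%.4f\n",
                    object@classes[k], object@n[k],
                    object@centroids[k, 1L], object@centroids[k, 2L],
                    object@widths[k]))
    cat("  min centroid R:", format(object@minCentroidR), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSnps, "SNPs x",
        .simNSamples(object), "samples (",
        object@nStrata, "strata ), seed", object@seed, "\n")
    cat(sprintf("  theta template %s, noise sd %.3f, NC %.3f, missing %.3f, non-clustering %.2f\n",
                paste(format(object@centroidTemplate), collapse = "/"),
                object@thetaNoiseSd, object@ncProbability,
                object@missingness, object@nonClusteringFraction))
})

setMethod("show", "PredictionResult", function(object) {
    cat("PredictionResult:", nrow(object@probabilities), "records predicted")
    if (length(object@excludedSnpIds))
        cat(",", length(object@excludedSnpIds), "excluded (unknown snpID)")
    cat("\n")
    if (nrow(object@probabilities)) {
        gt <- table(factor(object@predicted, levels = GT_CLASSES))
        cat("  calls:", paste(names(gt), gt, sep = "=", collapse = " "), "\n")
    }
})
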