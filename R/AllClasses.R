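## S4 containers for the genotype-rescue pipeline.

.METRICS_COLS <- c("sampleID", "snpID", "chromosome", "position", "ref", "alt",
                   "r", "theta", "gentrain", "genotype", "aIsRef")

#' SnpMetrics: per-sample, per-SNP array measurements
#'
#' One row per sample x SNP observation from an Illumina array export:
#' identifiers, the variant key (chromosome, 1-based position, ref and alt
#' alleles), normalized intensity R, allelic ratio Theta, the per-SNP GenTrain
#' cluster-quality score, the Gencall genotype (AA/AB/BB/NC), and whether
#' Illumina allele "A" corresponds to the reference allele (\code{aIsRef}).
#'
#' @slot records data.frame with columns sampleID, snpID, chromosome,
#'   position, ref, alt, r, theta, gentrain, genotype, aIsRef.
#' @export
setClass("SnpMetrics", representation(records = "data.frame"))

setValidity("SnpMetrics", function(object) {
    df <- object@records
    missing_cols <- setdiff(.METRICS_COLS, names(df))
    if (length(missing_cols))
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    msgs <- character()
    if (any(!is.na(df$position) & df$position < 1L))
        msgs <- c(msgs, "position must be >= 1")
    if (any(!is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt))
        msgs <- c(msgs, "ref and alt alleles must differ")
    if (any(!is.na(df$r) & df$r < 0))
        msgs <- c(msgs, "r must be non-negative")
    if (any(!is.na(df$theta) & (df$theta < 0 | df$theta > 1)))
        msgs <- c(msgs, "theta must lie in [0, 1]")
    if (any(!is.na(df$gentrain) & (df$gentrain < 0 | df$gentrain > 1)))
        msgs <- c(msgs, "gentrain must lie in [0, 1]")
    if (any(!is.na(df$genotype) & !df$genotype %in% GT_LEVELS))
        msgs <- c(msgs, "genotype must be one of AA, AB, BB, NC")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SnpMetrics object from a data.frame
#'
#' @param records data.frame with the columns documented in
#'   \linkS4class{SnpMetrics}. Column types are coerced (position to integer,
#'   r/theta/gentrain to numeric, aIsRef to logical).
#' @return A \linkS4class{SnpMetrics} object.
#' @export
#' @examples
#' SnpMetrics(data.frame(sampleID = "s1", snpID = "snp1", chromosome = "1",
#'   position = 100L, ref = "A", alt = "G", r = 1.2, theta = 0.04,
#'   gentrain = 0.8, genotype = "AA", aIsRef = TRUE))
SnpMetrics <- function(records) {
    records <- as.data.frame(records)
    records$sampleID <- as.character(records$sampleID)
    records$snpID <- as.character(records$snpID)
    records$chromosome <- as.character(records$chromosome)
    records$position <- as.integer(records$position)
    records$ref <- as.character(records$ref)
    records$alt <- as.character(records$alt)
    records$r <- as.numeric(records$r)
    records$theta <- as.numeric(records$theta)
    records$gentrain <- as.numeric(records$gentrain)
    records$genotype <- as.character(records$genotype)
    if (is.null(records$aIsRef)) records$aIsRef <- NA
    records$aIsRef <- as.logical(records$aIsRef)
    rownames(records) <- NULL
    new("SnpMetrics", records = records[, .METRICS_COLS])
}

#' EncodedDataset: records encoded for the neural network
#'
#' Records mapped onto the network's input space: an integer SNP index into a
#' fixed vocabulary, the (r, theta) feature pair, and (when genotypes are
#' available) one-hot targets over the class order AA, AB, BB.
#'
#' @slot snpIndex integer vector, 1-based index into \code{vocabulary}.
#' @slot features numeric matrix, one row per record, columns r and theta.
#' @slot targets numeric matrix with 3 columns (AA, AB, BB); zero rows when
#'   targets were not requested.
#' @slot vocabulary character vector; position i is the snpID with index i.
#' @export
setClass("EncodedDataset", representation(
    snpIndex = "integer", features = "matrix", targets = "matrix",
    vocabulary = "character"))

setValidity("EncodedDataset", function(object) {
    n <- length(object@snpIndex)
    if (nrow(object@features) != n) return("features/snpIndex length mismatch")
    if (ncol(object@features) != 2L) return("features must have 2 columns")
    if (n && (min(object@snpIndex) < 1L ||
              max(object@snpIndex) > length(object@vocabulary)))
        return("snpIndex out of vocabulary range")
    if (nrow(object@targets)) {
        if (nrow(object@targets) != n) return("targets length mismatch")
        if (ncol(object@targets) != 3L) return("targets must have 3 columns")
        ok <- rowSums(object@targets == 1) == 1 & rowSums(object@targets == 0) == 2
        if (!all(ok)) return("each target row must be one-hot")
    }
    TRUE
})

#' ModelConfig: genotyping-network hyperparameters
#'
#' Defaults follow the production recipe: a 50-dimensional SNP embedding,
#' dense layers of 64 and 160 rectifier units, a 3-class softmax output,
#' focal cross-entropy, and an adaptive-moment optimizer at learning rate
#' 1e-4 run for at most 11 epochs with early stopping (patience 5) on
#' validation loss.
#'
#' @slot embeddingDim integer, embedding width per SNP.
#' @slot hiddenUnits integer vector of dense-layer widths.
#' @slot nClasses integer, fixed at 3.
#' @slot learningRate numeric.
#' @slot maxEpochs integer.
#' @slot earlyStopPatience integer; epochs without validation-loss improvement
#'   tolerated before stopping.
#' @slot focalGamma numeric, focusing exponent of the focal loss.
#' @slot focalAlpha numeric in (0, 1], focal-loss scale.
#' @slot batchSize integer.
#' @slot seed integer used for weight initialization and batch shuffling.
#' @export
setClass("ModelConfig", representation(
    embeddingDim = "integer", hiddenUnits = "integer", nClasses = "integer",
    learningRate = "numeric", maxEpochs = "integer",
    earlyStopPatience = "integer", focalGamma = "numeric",
    focalAlpha = "numeric", batchSize = "integer", seed = "integer"))

setValidity("ModelConfig", function(object) {
    if (object@nClasses != 3L) return("nClasses is fixed at 3")
    if (object@embeddingDim < 1L) return("embeddingDim must be positive")
    if (any(object@hiddenUnits < 1L)) return("hiddenUnits must be positive")
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@maxEpochs < 1L) return("maxEpochs must be positive")
    if (object@earlyStopPatience < 0L) return("earlyStopPatience must be >= 0")
    if (object@focalGamma < 0) return("focalGamma must be >= 0")
    if (object@focalAlpha <= 0 || object@focalAlpha > 1)
        return("focalAlpha must lie in (0, 1]")
    if (object@batchSize < 1L) return("batchSize must be positive")
    TRUE
})

#' @rdname ModelConfig-class
#' @param embeddingDim,hiddenUnits,learningRate,maxEpochs,earlyStopPatience,focalGamma,focalAlpha,batchSize,seed
#'   see the class slots.
#' @return A \linkS4class{ModelConfig}.
#' @export
#' @examples
#' modelConfig(seed = 1L)
modelConfig <- function(embeddingDim = 50L, hiddenUnits = c(64L, 160L),
                        learningRate = 1e-4, maxEpochs = 11L,
                        earlyStopPatience = 5L, focalGamma = 2,
                        focalAlpha = 0.25, batchSize = 512L, seed = 42L) {
    new("ModelConfig", embeddingDim = as.integer(embeddingDim),
        hiddenUnits = as.integer(hiddenUnits), nClasses = 3L,
        learningRate = as.numeric(learningRate),
        maxEpochs = as.integer(maxEpochs),
        earlyStopPatience = as.integer(earlyStopPatience),
        focalGamma = as.numeric(focalGamma),
        focalAlpha = as.numeric(focalAlpha),
        batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' TrainedGenotyper: a fitted genotyping network
#'
#' @slot vocabulary character; snpID for each embedding row.
#' @slot embedding numeric matrix, vocabulary size x embeddingDim.
#' @slot weights list of dense-layer weight matrices and bias vectors
#'   (W1, b1, ..., Wout, bout).
#' @slot config the \linkS4class{ModelConfig} used.
#' @slot history data.frame with per-epoch train/validation loss and accuracy.
#' @export
setClass("TrainedGenotyper", representation(
    vocabulary = "character", embedding = "matrix", weights = "list",
    config = "ModelConfig", history = "data.frame"))

setValidity("TrainedGenotyper", function(object) {
    if (nrow(object@embedding) != length(object@vocabulary))
        return("embedding rows must equal vocabulary size")
    nw <- length(object@weights)
    if (nw < 2L || nw %% 2L != 0L) return("weights must pair matrices/biases")
    out_w <- object@weights[[nw - 1L]]
    if (ncol(out_w) != 3L) return("output layer must have 3 units")
    TRUE
})

#' PredictionResult: class probabilities and calls for a set of records
#'
#' @slot probabilities numeric matrix (rows = predicted records, columns AA,
#'   AB, BB); each row is a probability simplex.
#' @slot predicted character vector of argmax genotypes (never NC); ties are
#'   broken toward the earlier class in the order AA < AB < BB.
#' @slot maxProbability numeric vector of per-record winning probabilities.
#' @slot keptRows integer indices of the input records that were predictable.
#' @slot excludedSnpIds character; snpIDs absent from the model vocabulary,
#'   one entry per excluded record.
#' @export
setClass("PredictionResult", representation(
    probabilities = "matrix", predicted = "character",
    maxProbability = "numeric", keptRows = "integer",
    excludedSnpIds = "character"))

setValidity("PredictionResult", function(object) {
    n <- nrow(object@probabilities)
    if (length(object@predicted) != n || length(object@maxProbability) != n ||
        length(object@keptRows) != n)
        return("slot lengths disagree")
    if (n) {
        if (any(object@probabilities < 0)) return("negative probability")
        if (any(abs(rowSums(object@probabilities) - 1) > 1e-6))
            return("probability rows must sum to 1")
        if (any(!object@predicted %in% GT_CLASSES))
            return("predicted classes must be AA/AB/BB")
    }
    TRUE
})

#' DosageCallset: a reference genotype callset as additive dosages
#'
#' Hard allele-count dosages (0/1/2, NA for missing) for one genotyping
#' technology, as exported in the PLINK .raw text layout.
#'
#' @slot technology character, e.g. "imputed" or "wgs".
#' @slot samples character vector of sample IDs (from IID).
#' @slot variants data.frame with columns id, chromosome, position, ref, alt,
#'   countedAllele; the dosage counts copies of countedAllele.
#' @slot dosages integer matrix, samples x variants, values 0/1/2/NA.
#' @export
setClass("DosageCallset", representation(
    technology = "character", samples = "character", variants = "data.frame",
    dosages = "matrix"))

setValidity("DosageCallset", function(object) {
    if (nrow(object@dosages) != length(object@samples))
        return("dosage rows must match samples")
    if (ncol(object@dosages) != nrow(object@variants))
        return("dosage columns must match variants")
    vals <- object@dosages[!is.na(object@dosages)]
    if (length(vals) && !all(vals %in% 0:2))
        return("dosages must be 0, 1, 2 or NA")
    bad <- !(object@variants$countedAllele == object@variants$ref |
             object@variants$countedAllele == object@variants$alt)
    if (any(bad)) return("countedAllele must be the ref or alt allele")
    TRUE
})

#' ClusterGeometry: per-genotype cluster centroids and widths for one SNP
#'
#' Geometry of the AA/AB/BB point clouds in (theta, r) space: per-class
#' counts, mean centroids, root-mean-square widths, pairwise centroid
#' separations along theta, and the lowest centroid R coordinate.
#'
#' @slot classes character; genotype classes present (subset of AA, AB, BB).
#' @slot n named integer, points per present class.
#' @slot centroids numeric matrix, present classes x (theta, r).
#' @slot widths named numeric; RMS Euclidean distance to the class centroid.
#' @slot thetaSeparations named numeric; |delta theta| for each present pair,
#'   named like "AA-AB".
#' @slot minCentroidR numeric; minimum centroid r over present classes.
#' @export
setClass("ClusterGeometry", representation(
    classes = "character", n = "integer", centroids = "matrix",
    widths = "numeric", thetaSeparations = "numeric", minCentroidR = "numeric"))

setValidity("ClusterGeometry", function(object) {
    k <- length(object@classes)
    if (length(object@n) != k || nrow(object@centroids) != k ||
        length(object@widths) != k)
        return("per-class slots must align with classes")
    if (any(object@widths < 0)) return("widths must be non-negative")
    TRUE
})

#' SimulationConfig: parameters of the synthetic panel generator
#'
#' The generator emulates a multi-ancestry array study: samples drawn in
#' ancestry strata (default eleven strata of 44 samples each), per-SNP minor
#' allele frequencies, Hardy-Weinberg genotypes, per-genotype (theta, r)
#' clusters around a 0.05/0.50/0.95 theta template, gamma-distributed
#' intensities, a GenTrain-like cluster-quality score, a no-call mechanism
#' concentrated on low-intensity and boundary-theta points, planted
#' non-clustering SNPs, and field missingness.
#'
#' @slot nSnps,nStrata,samplesPerStratum integers; the sample count is
#'   nStrata * samplesPerStratum unless nSamples overrides it.
#' @slot nSamples integer or NA to derive from the strata.
#' @slot mafRange numeric length-2; per-SNP MAF drawn uniformly from it.
#' @slot centroidTemplate numeric length-3; theta centroids for AA/AB/BB.
#' @slot centroidJitterSd numeric; per-SNP jitter of the theta centroids.
#' @slot thetaNoiseSd numeric; within-cluster theta standard deviation.
#' @slot rMeans numeric length-3; mean intensity per genotype class.
#' @slot rShape numeric; gamma shape of the intensity distribution.
#' @slot strataShiftSd numeric; per-stratum theta centroid offset (0 = off).
#' @slot ncProbability numeric; marginal no-call rate.
#' @slot ncSharpness,ncRFloor numeric; how strongly no-calls concentrate on
#'   ambiguous-theta and low-r points.
#' @slot nonClusteringFraction numeric; fraction of SNPs planted as a single
#'   overlapping cloud.
#' @slot missingness numeric; probability a gentrain/r/theta/genotype cell is
#'   missing.
#' @slot seed integer.
#' @export
setClass("SimulationConfig", representation(
    nSnps = "integer", nStrata = "integer", samplesPerStratum = "integer",
    nSamples = "integer", mafRange = "numeric", centroidTemplate = "numeric",
    centroidJitterSd = "numeric", thetaNoiseSd = "numeric", rMeans = "numeric",
    rShape = "numeric", strataShiftSd = "numeric", ncProbability = "numeric",
    ncSharpness = "numeric", ncRFloor = "numeric",
    nonClusteringFraction = "numeric", missingness = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    probs <- c(object@ncProbability, object@nonClusteringFraction,
               object@missingness)
    if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
    if (any(c(object@centroidJitterSd, object@thetaNoiseSd,
              object@strataShiftSd) < 0))
        return("standard deviations must be >= 0")
    if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
        any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
        return("mafRange must be increasing within (0, 0.5]")
    if (length(object@centroidTemplate) != 3L ||
        any(object@centroidTemplate < 0 | object@centroidTemplate > 1))
        return("centroidTemplate must be 3 theta values in [0, 1]")
    if (length(object@rMeans) != 3L || any(object@rMeans <= 0))
        return("rMeans must be 3 positive values")
    if (object@nSnps < 1L) return("nSnps must be positive")
    TRUE
})
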