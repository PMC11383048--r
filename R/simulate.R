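## Synthetic SNP-array panel generator with known ground truth. Emulates a
## multi-ancestry array study: stratified samples, per-SNP minor allele
## frequencies, Hardy-Weinberg genotypes, per-genotype (theta, r) intensity
## clusters, a GenTrain-like cluster-quality score, a no-call mechanism
## concentrated on ambiguous points, planted non-clustering SNPs, and
## matched reference callsets with injectable error.

.simNSamples <- function(config) {
    if (!is.na(config@nSamples)) config@nSamples
    else config@nStrata * config@samplesPerStratum
}

#' Build a simulation configuration
#'
#' Defaults emulate the sampling design of a multi-ancestry array study:
#' eleven ancestry strata of 44 samples each (484 samples), per-SNP minor
#' allele frequency uniform on [0.05, 0.5], Hardy-Weinberg genotypes, theta
#' clusters at 0.05/0.50/0.95 for AA/AB/BB with within-cluster standard
#' deviation 0.03 and per-SNP centroid jitter 0.02, gamma-distributed
#' intensities with unit mean, a 3\% no-call rate concentrated on low-r and
#' boundary-theta points, and no planted non-clustering SNPs or field
#' missingness unless requested.
#'
#' @param nSnps number of SNPs.
#' @param nStrata,samplesPerStratum ancestry-stratum layout.
#' @param nSamples override the total sample count (NA = derive from strata).
#' @param mafRange,centroidTemplate,centroidJitterSd,thetaNoiseSd,rMeans,rShape,strataShiftSd,ncProbability,ncSharpness,ncRFloor,nonClusteringFraction,missingness
#'   see \linkS4class{SimulationConfig}.
#' @param seed integer.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSnps = 100L, nStrata = 11L,
                             samplesPerStratum = 44L, nSamples = NA_integer_,
                             mafRange = c(0.05, 0.5),
                             centroidTemplate = c(0.05, 0.50, 0.95),
                             centroidJitterSd = 0.02, thetaNoiseSd = 0.03,
                             rMeans = c(1, 1, 1), rShape = 200,
                             strataShiftSd = 0, ncProbability = 0.03,
                             ncSharpness = 4, ncRFloor = 0.5,
                             nonClusteringFraction = 0, missingness = 0,
                             seed = 42L) {
    new("SimulationConfig", nSnps = as.integer(nSnps),
        nStrata = as.integer(nStrata),
        samplesPerStratum = as.integer(samplesPerStratum),
        nSamples = as.integer(nSamples), mafRange = as.numeric(mafRange),
        centroidTemplate = as.numeric(centroidTemplate),
        centroidJitterSd = as.numeric(centroidJitterSd),
        thetaNoiseSd = as.numeric(thetaNoiseSd), rMeans = as.numeric(rMeans),
        rShape = as.numeric(rShape), strataShiftSd = as.numeric(strataShiftSd),
        ncProbability = as.numeric(ncProbability),
        ncSharpness = as.numeric(ncSharpness), ncRFloor = as.numeric(ncRFloor),
        nonClusteringFraction = as.numeric(nonClusteringFraction),
        missingness = as.numeric(missingness), seed = as.integer(seed))
}

#' Simulate a SNP-array metrics panel with known truth
#'
#' Per SNP: an alternate-allele frequency is drawn from \code{mafRange} and
#' genotypes follow Hardy-Weinberg proportions. Each genotype class has a
#' (theta, r) cluster — theta centered on the (jittered) class template with
#' Gaussian noise, r gamma-distributed — and the Gencall genotype equals the
#' truth except where the no-call mechanism fires, with probability raised
#' for low-intensity and boundary-theta points while preserving the marginal
#' rate \code{ncProbability}. A GenTrain-like score decreases with cluster
#' overlap. Planted non-clustering SNPs draw all genotypes from a single
#' overlapping cloud. Whether Illumina allele A is the reference allele is
#' randomized per SNP. With probability \code{missingness} a record has one
#' of its four required fields (GenTrain, r, theta, genotype) knocked out.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{metrics} (a \linkS4class{SnpMetrics}),
#'   \code{truth} (data.frame: sampleID, snpID, chromosome, position, ref,
#'   alt, altDosage, genotype — the true calls, never NC), and
#'   \code{snpParams} (per-SNP generating parameters: maf, class centroids,
#'   gentrain, aIsRef, nonClustering).
#' @export
simulatePanel <- function(config) {
    validObject(config)
    nS <- .simNSamples(config)
    nV <- config@nSnps
    withSeed(config@seed, {
        sampleID <- sprintf("SAMPLE_%04d", seq_len(nS))
        stratum <- rep_len(seq_len(config@nStrata), nS)
        strataShift <- rnorm(config@nStrata, 0, config@strataShiftSd)

        snpID <- sprintf("snp%05d", seq_len(nV))
        chromosome <- as.character(sample(1:22, nV, replace = TRUE))
        position <- sample.int(2e8, nV)
        ref <- sample(c("A", "C", "G", "T"), nV, replace = TRUE)
        alt <- vapply(ref, function(a)
            sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1L))
        maf <- runif(nV, config@mafRange[1L], config@mafRange[2L])
        aIsRef <- sample(c(TRUE, FALSE), nV, replace = TRUE)
        nonClustering <- rep(FALSE, nV)
        nNC <- round(config@nonClusteringFraction * nV)
        if (nNC > 0L) nonClustering[sample.int(nV, nNC)] <- TRUE

        ## per-SNP, per-class theta centroids (class order AA, AB, BB in
        ## Illumina A/B allele space)
        centroids <- matrix(rep(config@centroidTemplate, each = nV), nV, 3L) +
            matrix(rnorm(nV * 3L, 0, config@centroidJitterSd), nV, 3L)
        centroids <- clamp(centroids, 0.01, 0.99)

        adjSep <- pmin(abs(centroids[, 2L] - centroids[, 1L]),
                       abs(centroids[, 3L] - centroids[, 2L]))
        effSep <- ifelse(nonClustering, 0, adjSep)
        gentrain <- clamp(1 - exp(-effSep / (4 * config@thetaNoiseSd)) +
                          rnorm(nV, 0, 0.01), 0, 1)

        ## long-format panel
        sIdx <- rep(seq_len(nS), times = nV)
        vIdx <- rep(seq_len(nV), each = nS)
        q <- maf[vIdx]                       # alt-allele frequency
        u <- runif(nS * nV)
        altDosage <- ifelse(u < (1 - q)^2, 0L,
                     ifelse(u < (1 - q)^2 + 2 * q * (1 - q), 1L, 2L))
        bCopies <- ifelse(aIsRef[vIdx], altDosage, 2L - altDosage)
        label <- GT_CLASSES[bCopies + 1L]

        mu <- centroids[cbind(vIdx, bCopies + 1L)]
        theta <- mu + rnorm(nS * nV, 0, config@thetaNoiseSd) +
            strataShift[stratum[sIdx]]
        rMean <- config@rMeans[bCopies + 1L]
        nc <- nonClustering[vIdx]
        if (any(nc)) {
            theta[nc] <- rnorm(sum(nc), 0.5, 0.15)
            rMean[nc] <- rMean[nc] * 0.6
        }
        theta <- clamp(theta, 0, 1)
        r <- rgamma(nS * nV, shape = config@rShape,
                    scale = rMean / config@rShape)

        ## no-call mechanism: marginal rate ncProbability, risk concentrated
        ## on boundary-theta and low-r points
        genotype <- label
        if (config@ncProbability > 0) {
            z <- abs(theta - mu) / max(config@thetaNoiseSd, 1e-9)
            riskTheta <- plogis(config@ncSharpness * (z - 2))
            riskR <- plogis(config@ncSharpness *
                            (config@ncRFloor - r) / max(config@ncRFloor, 1e-9))
            s <- 0.5 + riskTheta + riskR
            p <- clamp(config@ncProbability * s / mean(s), 0, 1)
            genotype[runif(nS * nV) < p] <- "NC"
        }

        gentrainCol <- gentrain[vIdx]
        rCol <- r; thetaCol <- theta
        if (config@missingness > 0) {
            hit <- which(runif(nS * nV) < config@missingness)
            field <- sample.int(4L, length(hit), replace = TRUE)
            gentrainCol[hit[field == 1L]] <- NA
            rCol[hit[field == 2L]] <- NA
            thetaCol[hit[field == 3L]] <- NA
            genotype[hit[field == 4L]] <- NA
        }

        metrics <- SnpMetrics(data.frame(
            sampleID = sampleID[sIdx], snpID = snpID[vIdx],
            chromosome = chromosome[vIdx], position = position[vIdx],
            ref = ref[vIdx], alt = alt[vIdx], r = rCol, theta = thetaCol,
            gentrain = gentrainCol, genotype = genotype,
            aIsRef = aIsRef[vIdx], stringsAsFactors = FALSE))
        truth <- data.frame(
            sampleID = sampleID[sIdx], snpID = snpID[vIdx],
            chromosome = chromosome[vIdx], position = position[vIdx],
            ref = ref[vIdx], alt = alt[vIdx], altDosage = altDosage,
            genotype = label, stringsAsFactors = FALSE)
        snpParams <- data.frame(
            snpID = snpID, chromosome = chromosome, position = position,
            ref = ref, alt = alt, maf = maf, centroid_AA = centroids[, 1L],
            centroid_AB = centroids[, 2L], centroid_BB = centroids[, 3L],
            gentrain = gentrain, aIsRef = aIsRef,
            nonClustering = nonClustering, stringsAsFactors = FALSE)
        list(metrics = metrics, truth = truth, snpParams = snpParams)
    })
}

#' Simulate imputed/WGS reference callsets from truth genotypes
#'
#' Each technology's dosage equals the true alternate-allele dosage, flipped
#' to a uniformly chosen different dosage with that technology's error rate.
#' Sample and variant overlap with the array can be thinned; the counted
#' allele of each variant column is randomized between ref and alt to
#' exercise allele-convention handling.
#'
#' @param truth the \code{truth} data.frame from \code{\link{simulatePanel}}.
#' @param errorRates named numeric vector; one callset per name (e.g.
#'   \code{c(imputed = 0.01, wgs = 0)}).
#' @param sampleOverlap,variantOverlap fraction of array samples / variants
#'   present in each callset.
#' @param seed integer.
#' @return named list of \linkS4class{DosageCallset}s.
#' @export
simulateReferenceCallsets <- function(truth,
                                      errorRates = c(imputed = 0, wgs = 0),
                                      sampleOverlap = 1, variantOverlap = 1,
                                      seed = 42L) {
    stopIfNot(all(errorRates >= 0 & errorRates <= 1),
              "error rates must lie in [0, 1]")
    stopIfNot(!is.null(names(errorRates)) && all(nzchar(names(errorRates))),
              "errorRates must be named by technology")
    samples <- unique(truth$sampleID)
    vKey <- unique(truth[c("snpID", "chromosome", "position", "ref", "alt")])
    withSeed(seed, {
        out <- list()
        for (tech in names(errorRates)) {
            keepS <- sort(sample.int(length(samples),
                                     round(sampleOverlap * length(samples))))
            keepV <- sort(sample.int(nrow(vKey),
                                     round(variantOverlap * nrow(vKey))))
            sIDs <- samples[keepS]
            v <- vKey[keepV, , drop = FALSE]
            counted <- ifelse(runif(nrow(v)) < 0.5, v$ref, v$alt)
            variants <- data.frame(
                id = .variantId(v$chromosome, v$position, v$ref, v$alt),
                chromosome = v$chromosome, position = v$position,
                ref = v$ref, alt = v$alt, countedAllele = counted,
                stringsAsFactors = FALSE)
            ## truth alt dosage matrix for the kept samples x variants
            si <- match(truth$sampleID, sIDs)
            vi <- match(truth$snpID, v$snpID)
            ok <- !is.na(si) & !is.na(vi)
            alt <- matrix(NA_integer_, length(sIDs), nrow(v))
            alt[cbind(si[ok], vi[ok])] <- truth$altDosage[ok]
            e <- errorRates[[tech]]
            if (e > 0) {
                flip <- !is.na(alt) & runif(length(alt)) < e
                shift <- sample(1:2, sum(flip), replace = TRUE)
                alt[flip] <- (alt[flip] + shift) %% 3L
            }
            countedIsAlt <- variants$countedAllele == variants$alt
            dos <- alt
            if (any(!countedIsAlt))
                dos[, !countedIsAlt] <- 2L - alt[, !countedIsAlt, drop = FALSE]
            out[[tech]] <- new("DosageCallset", technology = tech,
                               samples = sIDs, variants = variants,
                               dosages = dos)
        }
        out
    })
}
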