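## Matching array genotype calls against reference dosage callsets and all
## per-SNP concordance statistics.

.variantId <- function(chromosome, position, ref, alt) {
    paste(chromosome, position, ref, alt, sep = ":")
}

#' Match array genotype calls to reference dosage callsets
#'
#' A call is matched only when the sample ID agrees exactly and the variant
#' key agrees exactly on all four fields (chromosome, position, ref allele,
#' alt allele) — no strand or allele flipping is attempted. Array genotypes
#' are converted to alternate-allele dosages via
#' \code{\link{dosageFromGenotype}}; reference dosages are re-expressed on the
#' alternate allele so all technologies are compared on one scale. Array NC
#' calls are not matchable and are dropped. Variants with no emitted match are
#' reported (with a reason) in the \code{unmatchedVariants} attribute rather
#' than raising an error.
#'
#' When a record's \code{aIsRef} is missing, allele A is assumed to be the
#' reference allele and the result carries
#' \code{attr(, "alleleConventionUnverified") = TRUE}.
#'
#' @param x a \linkS4class{SnpMetrics} whose genotype column holds the calls
#'   to validate (Gencall or predicted).
#' @param callsets list of \linkS4class{DosageCallset}s (distinct technology
#'   labels).
#' @return data.frame with one row per matched call: sampleID, variantId,
#'   chromosome, position, ref, alt, arrayDosage, and one
#'   \code{dosage_<technology>} column per callset (NA where that technology
#'   has no call). Attributes: \code{unmatchedVariants} (variantId, reason in
#'   no variant match / allele mismatch / no sample overlap),
#'   \code{alleleConventionUnverified}.
#' @export
matchCalls <- function(x, callsets) {
    if (is(callsets, "DosageCallset")) callsets <- list(callsets)
    techs <- vapply(callsets, function(cs) cs@technology, character(1L))
    stopIfNot(!anyDuplicated(techs), "duplicate technology labels")

    df <- x@records
    df <- df[!is.na(df$genotype) & df$genotype != "NC", , drop = FALSE]
    unverified <- anyNA(df$aIsRef)
    aIsRef <- ifelse(is.na(df$aIsRef), TRUE, df$aIsRef)
    vid <- .variantId(df$chromosome, df$position, df$ref, df$alt)
    ## alt-allele dosage of every array call
    altDosage <- if (nrow(df))
        dosageFromGenotype(df$genotype, aIsRef, countedIsAlt = TRUE)
        else integer()

    out <- data.frame(sampleID = df$sampleID, variantId = vid,
                      chromosome = df$chromosome, position = df$position,
                      ref = df$ref, alt = df$alt, arrayDosage = altDosage,
                      stringsAsFactors = FALSE)
    ## per-variant bookkeeping for unmatched-reason reporting
    keyMatched <- rep(FALSE, nrow(df))   # variant key present in a callset
    posMatched <- rep(FALSE, nrow(df))   # chrom:pos present (alleles differ)

    for (cs in callsets) {
        v <- cs@variants
        csVid <- .variantId(v$chromosome, v$position, v$ref, v$alt)
        vmatch <- match(vid, csVid)
        smatch <- match(df$sampleID, cs@samples)
        keyMatched <- keyMatched | !is.na(vmatch)
        posMatched <- posMatched |
            paste(df$chromosome, df$position, sep = ":") %in%
                paste(v$chromosome, v$position, sep = ":")
        dos <- rep(NA_integer_, nrow(df))
        ok <- !is.na(vmatch) & !is.na(smatch)
        if (any(ok)) {
            raw <- cs@dosages[cbind(smatch[ok], vmatch[ok])]
            countedIsAlt <- v$countedAllele[vmatch[ok]] == v$alt[vmatch[ok]]
            dos[ok] <- ifelse(countedIsAlt, raw, 2L - raw)
        }
        out[[paste0("dosage_", cs@technology)]] <- dos
    }

    refCols <- paste0("dosage_", techs)
    hasRef <- rowSums(!is.na(as.matrix(out[refCols]))) > 0L
    matched <- out[hasRef, , drop = FALSE]
    rownames(matched) <- NULL

    unVid <- unique(vid[!vid %in% matched$variantId])
    if (length(unVid)) {
        first <- match(unVid, vid)
        reason <- ifelse(keyMatched[first], "no sample overlap",
                         ifelse(posMatched[first], "allele mismatch",
                                "no variant match"))
        unmatched <- data.frame(variantId = unVid, reason = unname(reason),
                                stringsAsFactors = FALSE)
    } else {
        unmatched <- data.frame(variantId = character(), reason = character(),
                                stringsAsFactors = FALSE)
    }
    attr(matched, "technologies") <- techs
    attr(matched, "unmatchedVariants") <- unmatched
    attr(matched, "alleleConventionUnverified") <- unverified
    matched
}

#' Per-SNP concordance rates against each reference technology
#'
#' For each variant and technology, the concordance rate is the fraction of
#' matched calls (calls where that technology has a dosage) whose array
#' dosage equals the reference dosage. The summary rate counts a call
#' concordant when it equals at least one available reference dosage
#' (agreement with either imputation or WGS). Rates with an empty
#' denominator are reported as NA, never 0.
#'
#' @param matched the data.frame returned by \code{\link{matchCalls}}.
#' @return data.frame with one row per variant, sorted by chromosome then
#'   position: the variant key, then per technology \code{n_<tech>},
#'   \code{concordant_<tech>}, \code{rate_<tech>}, and \code{n_summary},
#'   \code{concordant_summary}, \code{summary_rate}.
#' @export
snpConcordance <- function(matched) {
    techs <- attr(matched, "technologies")
    if (is.null(techs))
        techs <- sub("^dosage_", "",
                     grep("^dosage_", names(matched), value = TRUE))
    refCols <- paste0("dosage_", techs)
    key <- unique(matched[c("variantId", "chromosome", "position",
                            "ref", "alt")])
    key <- key[order(key$chromosome, key$position, key$ref, key$alt), ,
               drop = FALSE]
    rownames(key) <- NULL
    g <- factor(matched$variantId, levels = key$variantId)

    out <- key
    anyConc <- rep(FALSE, nrow(matched))
    anyPresent <- rep(FALSE, nrow(matched))
    for (i in seq_along(techs)) {
        ref <- matched[[refCols[i]]]
        present <- !is.na(ref)
        conc <- present & ref == matched$arrayDosage
        nm <- as.integer(tapply(present, g, sum, default = 0L))
        nc <- as.integer(tapply(conc, g, sum, default = 0L))
        out[[paste0("n_", techs[i])]] <- nm
        out[[paste0("concordant_", techs[i])]] <- nc
        out[[paste0("rate_", techs[i])]] <- ifelse(nm > 0L, nc / nm, NA_real_)
        anyConc <- anyConc | conc
        anyPresent <- anyPresent | present
    }
    ns <- as.integer(tapply(anyPresent, g, sum, default = 0L))
    cs <- as.integer(tapply(anyConc, g, sum, default = 0L))
    out$n_summary <- ns
    out$concordant_summary <- cs
    out$summary_rate <- ifelse(ns > 0L, cs / ns, NA_real_)
    attr(out, "technologies") <- techs
    out
}

#' Classify SNPs as high-performing
#'
#' A SNP is high-performing when its concordance rate with every reference
#' technology for which matched calls exist is at or above the threshold; a
#' technology with no matched calls (NA rate) does not veto. SNPs with no
#' available rate at all are not classified high-performing (they are
#' unvalidated).
#'
#' @param report the data.frame from \code{\link{snpConcordance}}.
#' @param threshold minimum per-technology concordance rate (default 0.90).
#' @return \code{report} with a logical \code{high_performing} column added.
#' @export
classifyHighPerforming <- function(report, threshold = 0.90) {
    techs <- attr(report, "technologies")
    if (is.null(techs))
        techs <- sub("^rate_", "",
                     grep("^rate_", names(report), value = TRUE))
    rates <- as.matrix(report[paste0("rate_", techs)])
    nAvail <- rowSums(!is.na(rates))
    allPass <- rowSums(!is.na(rates) & rates >= threshold) == nAvail
    report$high_performing <- nAvail > 0L & allPass
    report
}

#' Recalculate a SNP's call rate after no-call recovery
#'
#' Recovered genotypes that agree with at least one reference technology are
#' added to the SNP's original call count.
#'
#' @param originalCalls integer; samples with a valid (non-NC) Gencall
#'   genotype at the SNP.
#' @param originalTotal integer; all samples assayed at the SNP.
#' @param recoveredConcordant integer; recovered no-calls concordant with a
#'   reference.
#' @return \code{(originalCalls + recoveredConcordant) / originalTotal}.
#' @export
#' @examples
#' recalculateCallRate(95, 100, 4)  # 0.99
recalculateCallRate <- function(originalCalls, originalTotal,
                                recoveredConcordant) {
    stopIfNot(all(originalCalls <= originalTotal),
              "originalCalls must not exceed originalTotal")
    stopIfNot(all(recoveredConcordant <= originalTotal - originalCalls),
              "recoveredConcordant must not exceed the no-call count")
    stopIfNot(all(c(originalCalls, originalTotal, recoveredConcordant) >= 0),
              "counts must be non-negative")
    (originalCalls + recoveredConcordant) / originalTotal
}

#' Pearson correlation between GenTrain score and concordance
#'
#' @param gentrain,rate numeric vectors (paired); incomplete pairs are
#'   dropped.
#' @return list with \code{r} (Pearson coefficient, NA when fewer than 3
#'   complete pairs or a variance is zero) and \code{n} (pairs used).
#' @export
gentrainCorrelation <- function(gentrain, rate) {
    stopIfNot(length(gentrain) == length(rate),
              "gentrain and rate must have equal length")
    ok <- !is.na(gentrain) & !is.na(rate)
    n <- sum(ok)
    if (n < 3L || stats::var(gentrain[ok]) == 0 || stats::var(rate[ok]) == 0) {
        warning("correlation undefined: fewer than 3 complete pairs or zero variance",
                call. = FALSE)
        return(list(r = NA_real_, n = n))
    }
    list(r = stats::cor(gentrain[ok], rate[ok]), n = n)
}

## U statistic of the first group, with midranks for ties.
.ustat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U comparison of two groups of concordance rates
#'
#' Computes the rank-sum U statistic of the first group (midranks for ties)
#' and a two-sided p-value: by full enumeration of all group assignments of
#' the pooled values when both groups have at most 8 observations (exact
#' even under ties), and by the normal approximation with tie correction (no
#' continuity correction) otherwise. The two-sided exact p doubles the
#' smaller tail probability, capped at 1.
#'
#' @param x,y numeric vectors (e.g. summary concordance rates of included
#'   and excluded SNPs); both non-empty.
#' @param exact force ("TRUE"/"FALSE") or auto-select (NULL, the default:
#'   exact when both groups have <= 8 values).
#' @return list with \code{U} (first-group statistic), \code{p} (two-sided)
#'   and \code{method}.
#' @export
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
compareGroups <- function(x, y, exact = NULL) {
    stopIfNot(length(x) > 0L && length(y) > 0L, "both groups must be non-empty")
    n1 <- length(x); n2 <- length(y)
    if (is.null(exact)) exact <- n1 <= 8L && n2 <= 8L
    U <- .ustat(x, y)
    if (exact) {
        pooled <- c(x, y)
        picks <- combn(n1 + n2, n1)
        us <- apply(picks, 2L, function(i)
            .ustat(pooled[i], pooled[-i]))
        pLo <- mean(us <= U + 1e-9)
        pHi <- mean(us >= U - 1e-9)
        p <- min(1, 2 * min(pLo, pHi))
        method <- "exact enumeration"
    } else {
        N <- n1 + n2
        ties <- table(c(x, y))
        tieTerm <- sum(ties^3 - ties)
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
        z <- (U - n1 * n2 / 2) / sqrt(sigma2)
        p <- 2 * stats::pnorm(-abs(z))
        method <- "normal approximation with tie correction"
    }
    list(U = U, p = p, method = method)
}
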