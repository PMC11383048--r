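## PLINK additive-dosage (.raw) text ingestion: whitespace-delimited, header
## FID IID PAT MAT SEX PHENOTYPE followed by one column per variant named
## <id>_<countedAllele>, cells counting copies of the counted allele (0/1/2,
## NA for missing).

.RAW_FIXED <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

.parseVariantColumns <- function(cols, variantAnnotation = NULL) {
    us <- regexpr("_[^_]*$", cols)
    if (any(us < 1L))
        stop("variant column without _countedAllele suffix: ",
             cols[which(us < 1L)[1L]], call. = FALSE)
    id <- substr(cols, 1L, us - 1L)
    counted <- substring(cols, us + 1L)
    if (!is.null(variantAnnotation)) {
        m <- match(id, variantAnnotation$id)
        if (anyNA(m))
            stop("variant id not in the annotation file: ",
                 id[which(is.na(m))[1L]], call. = FALSE)
        ann <- variantAnnotation[m, ]
        return(data.frame(id = id, chromosome = as.character(ann$chromosome),
                          position = as.integer(ann$position),
                          ref = as.character(ann$ref),
                          alt = as.character(ann$alt),
                          countedAllele = counted, stringsAsFactors = FALSE))
    }
    parts <- strsplit(id, ":", fixed = TRUE)
    bad <- lengths(parts) != 4L
    if (any(bad))
        stop("variant column id does not parse as chrom:pos:ref:alt: ",
             cols[which(bad)[1L]],
             " (supply variantAnnotation for opaque ids)", call. = FALSE)
    parts <- do.call(rbind, parts)
    pos <- suppressWarnings(as.integer(parts[, 2L]))
    if (anyNA(pos))
        stop("non-integer position in variant column: ",
             cols[which(is.na(pos))[1L]], call. = FALSE)
    data.frame(id = id, chromosome = parts[, 1L], position = pos,
               ref = parts[, 3L], alt = parts[, 4L],
               countedAllele = counted, stringsAsFactors = FALSE)
}

#' Read a PLINK .raw additive-dosage export
#'
#' Parses the whitespace-delimited .raw text layout: six fixed columns
#' (FID IID PAT MAT SEX PHENOTYPE, of which only IID is kept) followed by one
#' column per variant, named \code{<id>_<countedAllele>} with \code{id}
#' encoding \code{chrom:pos:ref:alt}. Cells must be 0, 1, 2 or NA — these are
#' hard genotype dosages; fractional imputed dosages must be hard-called by
#' the producer.
#'
#' @param path path to the .raw file.
#' @param technology label stored on the callset (e.g. "imputed", "wgs").
#' @param variantAnnotation optional data.frame (columns id, chromosome,
#'   position, ref, alt) mapping opaque variant ids (e.g. rs numbers) to
#'   variant keys.
#' @return A \linkS4class{DosageCallset}.
#' @export
readPlinkRaw <- function(path, technology = "imputed",
                         variantAnnotation = NULL) {
    stopIfNot(file.exists(path), paste("file not found:", path))
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", na.strings = character())
    if (ncol(df) < 6L || !identical(names(df)[1:6], .RAW_FIXED))
        stop("malformed .raw header: must begin 'FID IID PAT MAT SEX PHENOTYPE'",
             call. = FALSE)
    variants <- .parseVariantColumns(names(df)[-(1:6)], variantAnnotation)
    n <- nrow(df)
    dosages <- matrix(NA_integer_, n, nrow(variants))
    for (j in seq_len(nrow(variants))) {
        cell <- df[[j + 6L]]
        cell[cell == "NA"] <- NA_character_
        ok <- is.na(cell) | cell %in% c("0", "1", "2")
        if (!all(ok))
            stop(sprintf("invalid dosage '%s' at row %d, column %s (must be 0/1/2/NA)",
                         cell[which(!ok)[1L]], which(!ok)[1L],
                         names(df)[j + 6L]), call. = FALSE)
        dosages[, j] <- as.integer(cell)
    }
    new("DosageCallset", technology = technology, samples = df$IID,
        variants = variants, dosages = dosages)
}

#' Write a callset in the PLINK .raw text layout
#'
#' @param callset a \linkS4class{DosageCallset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePlinkRaw <- function(callset, path) {
    v <- callset@variants
    header <- c(.RAW_FIXED, paste0(v$id, "_", v$countedAllele))
    body <- cbind(callset@samples, callset@samples, "0", "0", "0", "-9",
                  ifelse(is.na(callset@dosages), "NA", callset@dosages))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = " "), con)
    writeLines(apply(body, 1L, paste, collapse = " "), con)
    invisible(path)
}

#' Convert an array genotype to an additive dosage
#'
#' Maps an Illumina AA/AB/BB genotype to the count of a designated
#' ("counted") allele. The genotype counts copies of Illumina allele B;
#' \code{aIsRef} says whether allele A is the reference allele (so B is the
#' alternate), and \code{countedIsAlt} whether the counted allele is the
#' alternate.
#'
#' @param genotype character vector over AA/AB/BB (NC is an error).
#' @param aIsRef logical vector (recycled).
#' @param countedIsAlt logical vector (recycled).
#' @return integer vector of dosages in 0/1/2.
#' @export
#' @examples
#' dosageFromGenotype("BB", aIsRef = TRUE, countedIsAlt = TRUE)  # 2
#' dosageFromGenotype("AB", aIsRef = FALSE, countedIsAlt = TRUE) # 1
dosageFromGenotype <- function(genotype, aIsRef, countedIsAlt) {
    if (any(is.na(genotype)) || any(!genotype %in% GT_CLASSES))
        stop("genotype must be AA, AB or BB (no NC, no missing)",
             call. = FALSE)
    bCopies <- match(genotype, GT_CLASSES) - 1L
    altCopies <- ifelse(rep_len(aIsRef, length(genotype)), bCopies,
                        2L - bCopies)
    as.integer(ifelse(rep_len(countedIsAlt, length(genotype)), altCopies,
                      2L - altCopies))
}
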