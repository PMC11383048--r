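## Reading, validation, filtering, partitioning and encoding of per-sample
## SNP metrics tables.

.EXTERNAL_COLS <- c(sampleID = "sampleID", snpID = "snpID",
                    chromosome = "chromosome", position = "position",
                    ref = "Ref", alt = "Alt", r = "R", theta = "Theta",
                    gentrain = "GenTrain_Score", genotype = "GT")

.parseNumericColumn <- function(x, col) {
    if (is.numeric(x)) return(as.numeric(x))
    x[x %in% c("", "NA")] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
        stop(sprintf("column '%s': unparseable numeric value '%s' at row %d",
                     col, x[bad[1L]], bad[1L]), call. = FALSE)
    out
}

#' Read a per-sample SNP metrics table
#'
#' Reads a columnar metrics export with one row per sample x SNP observation.
#' Required columns: sampleID, snpID, chromosome, position, Ref, Alt, R,
#' Theta, GenTrain_Score, GT; optional a_is_ref. CSV and TSV dialects are
#' auto-detected from the header line; empty cells and "NA" are treated as
#' missing. Parquet files are read through the arrow package.
#'
#' When the a_is_ref column is absent, Illumina allele "A" is assumed to be
#' the reference allele (with a warning); downstream concordance results
#' carry an allele-convention-unverified flag in that case.
#'
#' @param path path to the metrics file.
#' @param format one of "auto", "csv", "tsv", "parquet". "auto" picks
#'   parquet for a .parquet extension and delimited text otherwise.
#' @return A \linkS4class{SnpMetrics} with row order preserved.
#' @export
#' @examples
#' cfg <- simulationConfig(nSnps = 3, nSamples = 8, seed = 1)
#' panel <- simulatePanel(cfg)
#' f <- tempfile(fileext = ".csv")
#' writeSnpMetrics(panel$metrics, f)
#' readSnpMetrics(f)
readSnpMetrics <- function(path, format = c("auto", "csv", "tsv", "parquet")) {
    format <- match.arg(format)
    stopIfNot(file.exists(path), paste("file not found:", path))
    if (format == "auto")
        format <- if (grepl("\\.parquet$", path)) "parquet" else "csv"
    if (format == "parquet") {
        if (!requireNamespace("arrow", quietly = TRUE))
            stop("reading parquet requires the 'arrow' package", call. = FALSE)
        ## typed columns come through natively; numeric validation is a
        ## pass-through for already-numeric columns
        df <- as.data.frame(arrow::read_parquet(path))
    } else {
        sep <- if (format == "tsv") "\t" else {
            header <- readLines(path, n = 1L)
            if (grepl("\t", header)) "\t" else ","
        }
        df <- as.data.frame(data.table::fread(
            path, sep = sep, header = TRUE, colClasses = "character",
            na.strings = NULL, data.table = FALSE, showProgress = FALSE))
    }
    missing_cols <- setdiff(unname(.EXTERNAL_COLS), names(df))
    if (length(missing_cols))
        stop("metrics file is missing required column(s): ",
             paste(missing_cols, collapse = ", "), call. = FALSE)

    blank <- function(x) {
        x <- as.character(x)
        replace(x, x %in% c("", "NA"), NA_character_)
    }
    gt <- blank(df[[.EXTERNAL_COLS[["genotype"]]]])
    badGt <- which(!is.na(gt) & !gt %in% GT_LEVELS)
    if (length(badGt))
        stop(sprintf("column 'GT': invalid genotype '%s' at row %d",
                     gt[badGt[1L]], badGt[1L]), call. = FALSE)

    if ("a_is_ref" %in% names(df)) {
        v <- toupper(blank(df$a_is_ref))
        aIsRef <- ifelse(is.na(v), NA, v %in% c("TRUE", "T", "1"))
    } else {
        warning("no a_is_ref column: assuming Illumina allele A = ref allele; ",
                "concordance results will be allele-convention-unverified",
                call. = FALSE)
        aIsRef <- rep(NA, nrow(df))
    }

    SnpMetrics(data.frame(
        sampleID = blank(df$sampleID),
        snpID = blank(df$snpID),
        chromosome = blank(df$chromosome),
        position = as.integer(.parseNumericColumn(df$position, "position")),
        ref = blank(df$Ref),
        alt = blank(df$Alt),
        r = .parseNumericColumn(df$R, "R"),
        theta = .parseNumericColumn(df$Theta, "Theta"),
        gentrain = .parseNumericColumn(df$GenTrain_Score, "GenTrain_Score"),
        genotype = gt,
        aIsRef = aIsRef,
        stringsAsFactors = FALSE))
}

#' Write a SnpMetrics table
#'
#' Writes the external columnar layout read back by
#' \code{\link{readSnpMetrics}} (columns sampleID, snpID, chromosome,
#' position, Ref, Alt, R, Theta, GenTrain_Score, GT, a_is_ref).
#'
#' @param x a \linkS4class{SnpMetrics}.
#' @param path output path.
#' @param format "auto" (by extension), "csv", "tsv" or "parquet".
#' @return \code{path}, invisibly.
#' @export
writeSnpMetrics <- function(x, path,
                            format = c("auto", "csv", "tsv", "parquet")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.parquet$", path)) "parquet"
                  else if (grepl("\\.tsv$", path)) "tsv" else "csv"
    df <- x@records
    out <- data.frame(sampleID = df$sampleID, snpID = df$snpID,
                      chromosome = df$chromosome, position = df$position,
                      Ref = df$ref, Alt = df$alt, R = df$r, Theta = df$theta,
                      GenTrain_Score = df$gentrain, GT = df$genotype,
                      a_is_ref = df$aIsRef, stringsAsFactors = FALSE)
    if (format == "parquet") {
        if (!requireNamespace("arrow", quietly = TRUE))
            stop("writing parquet requires the 'arrow' package", call. = FALSE)
        arrow::write_parquet(out, path)
    } else {
        data.table::fwrite(out, path, sep = if (format == "tsv") "\t" else ",",
                           na = "NA", quote = FALSE)
    }
    invisible(path)
}

#' Drop records with missing core measurements
#'
#' A record is complete when all four of GenTrain score, R, Theta and
#' genotype are present; incomplete records are removed before training.
#'
#' @param x a \linkS4class{SnpMetrics}.
#' @return list with elements \code{kept} and \code{dropped}, both
#'   \linkS4class{SnpMetrics}; together they partition the input with order
#'   preserved.
#' @export
filterCompleteRecords <- function(x) {
    df <- x@records
    complete <- !is.na(df$gentrain) & !is.na(df$r) & !is.na(df$theta) &
        !is.na(df$genotype)
    list(kept = x[complete], dropped = x[!complete])
}

#' Separate no-call records from valid genotype calls
#'
#' @param x a \linkS4class{SnpMetrics}, already completeness-filtered.
#' @return list with elements \code{valid} (genotype AA/AB/BB) and
#'   \code{noCalls} (genotype NC), order preserved.
#' @export
partitionNoCalls <- function(x) {
    nc <- !is.na(x@records$genotype) & x@records$genotype == "NC"
    list(valid = x[!nc], noCalls = x[nc])
}

#' Randomly split records into training, validation and test sets
#'
#' Splitting is by record (sample x SNP observation); the same sample may
#' appear in different partitions at different SNPs.
#'
#' @param x a \linkS4class{SnpMetrics}.
#' @param fractions length-3 positive numeric summing to 1 (train, val,
#'   test); default \code{c(0.90, 0.05, 0.05)}.
#' @param seed integer; the same seed yields the identical split.
#' @return list with \linkS4class{SnpMetrics} elements \code{train},
#'   \code{val}, \code{test}; disjoint, jointly exhaustive, sizes matching
#'   the fractions to within one record.
#' @export
splitTrainValTest <- function(x, fractions = c(0.90, 0.05, 0.05), seed = 42L) {
    stopIfNot(length(fractions) == 3L && all(fractions > 0),
              "fractions must be 3 positive numbers")
    stopIfNot(abs(sum(fractions) - 1) <= 1e-9, "fractions must sum to 1")
    n <- nRecords(x)
    perm <- withSeed(seed, sample.int(n))
    bounds <- round(cumsum(fractions) * n)
    bounds[3L] <- n
    idx <- list(train = perm[seq_len(bounds[1L])],
                val = perm[seq_len(bounds[2L])[-seq_len(bounds[1L])]],
                test = perm[setdiff(seq_len(n), seq_len(bounds[2L]))])
    lapply(idx, function(i) x[sort(i)])
}

#' Encode records for the neural network
#'
#' Maps each record's snpID to an integer index into a vocabulary, collects
#' the (r, theta) feature pair, and (optionally) one-hot encodes the Gencall
#' genotype over the fixed class order AA, AB, BB.
#'
#' @param x a \linkS4class{SnpMetrics}; must contain no NC genotypes when
#'   \code{withTargets = TRUE}.
#' @param vocab optional existing vocabulary (character vector). When
#'   absent, one is built from the sorted distinct snpIDs. A record whose
#'   snpID is absent from a supplied vocabulary is an error.
#' @param withTargets logical; encode one-hot genotype targets.
#' @return An \linkS4class{EncodedDataset}.
#' @export
encodeDataset <- function(x, vocab = NULL, withTargets = TRUE) {
    df <- x@records
    if (is.null(vocab)) {
        vocab <- sort(unique(df$snpID))
    } else {
        unknown <- setdiff(unique(df$snpID), vocab)
        if (length(unknown))
            stop("snpID(s) absent from the supplied vocabulary: ",
                 paste(head(unknown, 10L), collapse = ", "),
                 if (length(unknown) > 10L) ", ...", call. = FALSE)
    }
    idx <- match(df$snpID, vocab)
    features <- cbind(r = df$r, theta = df$theta)
    if (withTargets) {
        if (any(is.na(df$genotype)) || any(df$genotype == "NC"))
            stop("targets requested but records contain NC or missing genotypes",
                 call. = FALSE)
        cls <- match(df$genotype, GT_CLASSES)
        targets <- matrix(0, nrow(df), 3L, dimnames = list(NULL, GT_CLASSES))
        if (nrow(df)) targets[cbind(seq_len(nrow(df)), cls)] <- 1
    } else {
        targets <- matrix(0, 0L, 3L, dimnames = list(NULL, GT_CLASSES))
    }
    new("EncodedDataset", snpIndex = as.integer(idx), features = features,
        targets = targets, vocabulary = as.character(vocab))
}

#' Recover snpIDs from an encoded dataset
#'
#' @param x an \linkS4class{EncodedDataset}.
#' @return character vector of snpIDs, one per record.
#' @export
decodeSnpIds <- function(x) x@vocabulary[x@snpIndex]
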