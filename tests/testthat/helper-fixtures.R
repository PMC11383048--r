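## Shared fixture builders for the test suite. Everything is generated in
## code; no data files.

## A small hand-written metrics table; `...` overrides columns.
makeMetrics <- function(n = 4L, ...) {
    df <- data.frame(
        sampleID = sprintf("S%02d", seq_len(n)),
        snpID = rep_len(c("snpA", "snpB"), n),
        chromosome = rep_len(c("1", "2"), n),
        position = rep_len(c(100L, 200L), n),
        ref = rep_len(c("A", "G"), n),
        alt = rep_len(c("G", "T"), n),
        r = rep_len(c(1.0, 1.1), n),
        theta = rep_len(c(0.05, 0.95), n),
        gentrain = rep_len(0.8, n),
        genotype = rep_len(c("AA", "BB"), n),
        aIsRef = TRUE,
        stringsAsFactors = FALSE)
    over <- list(...)
    for (nm in names(over)) df[[nm]] <- over[[nm]]
    SnpMetrics(df)
}

## 99% two-sided binomial interval for a count at rate p over n trials.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)

## Independent brute-force per-SNP concordance recount: plain double loop
## over matched calls, no vectorized bookkeeping shared with the engine.
bruteConcordance <- function(matched, techs) {
    vids <- sort(unique(matched$variantId))
    out <- list()
    for (vid in vids) {
        row <- list(variantId = vid)
        anyC <- 0L; anyN <- 0L
        for (tech in techs) {
            nm <- 0L; nc <- 0L
            for (i in seq_len(nrow(matched))) {
                if (matched$variantId[i] != vid) next
                ref <- matched[[paste0("dosage_", tech)]][i]
                if (is.na(ref)) next
                nm <- nm + 1L
                if (ref == matched$arrayDosage[i]) nc <- nc + 1L
            }
            row[[paste0("rate_", tech)]] <- if (nm > 0L) nc / nm else NA_real_
        }
        for (i in seq_len(nrow(matched))) {
            if (matched$variantId[i] != vid) next
            present <- FALSE; conc <- FALSE
            for (tech in techs) {
                ref <- matched[[paste0("dosage_", tech)]][i]
                if (!is.na(ref)) {
                    present <- TRUE
                    if (ref == matched$arrayDosage[i]) conc <- TRUE
                }
            }
            if (present) anyN <- anyN + 1L
            if (conc) anyC <- anyC + 1L
        }
        row$summary_rate <- if (anyN > 0L) anyC / anyN else NA_real_
        out[[vid]] <- row
    }
    out
}

## Train a small model quickly (higher learning rate than the production
## recipe so tests converge in a couple of epochs).
quickTrain <- function(split, lr = 5e-3, epochs = 4L, batch = 256L,
                       seed = 7L) {
    tr <- encodeDataset(split$train)
    va <- encodeDataset(split$val, vocab = tr@vocabulary)
    trainGenotyper(tr, va, modelConfig(learningRate = lr, maxEpochs = epochs,
                                       batchSize = batch, seed = seed))
}

## Drive the full CLI chain (simulate -> train -> predict -> validate ->
## flag) into `root`.
runPipeline <- function(root, seed = 5) {
    fix <- file.path(root, "fix")
    status <- runCli(c("simulate", "--out", fix, "--seed", seed,
                       "--n-snps", "12", "--n-samples", "80",
                       "--nc-prob", "0.05", "--error-imputed", "0.02",
                       "--error-wgs", "0"))
    stopifnot(status == 0)
    mdir <- file.path(root, "model")
    status <- runCli(c("train", "--metrics", file.path(fix, "metrics.csv"),
                       "--out", mdir, "--seed", seed, "--epochs", "3",
                       "--lr", "0.005", "--batch-size", "256"))
    stopifnot(status == 0)
    status <- runCli(c("predict", "--model", file.path(mdir, "model.json"),
                       "--metrics", file.path(fix, "metrics.csv"),
                       "--out", file.path(root, "predictions.tsv")))
    stopifnot(status == 0)
    vdir <- file.path(root, "validate")
    status <- runCli(c("validate", "--model", file.path(mdir, "model.json"),
                       "--metrics", file.path(fix, "metrics.csv"),
                       "--imputed", file.path(fix, "imputed.raw"),
                       "--wgs", file.path(fix, "wgs.raw"),
                       "--out", vdir))
    stopifnot(status == 0)
    status <- runCli(c("flag", "--metrics", file.path(fix, "metrics.csv"),
                       "--out", file.path(root, "flags.tsv")))
    stopifnot(status == 0)
    invisible(root)
}
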