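Package: GenoRescue
Title: Recovery of No-Call SNP Array Genotypes with a Per-SNP Embedding
    Neural Network
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recovers "no-call" genotypes on Illumina SNP arrays from raw
    probe intensity measurements (normalized intensity R and allelic ratio
    Theta) using a neural network with a per-SNP categorical embedding,
    trained with focal cross-entropy on the array's valid Gencall genotypes.
    Includes readers for per-sample SNP metrics tables (CSV/TSV/parquet) and
    PLINK additive-dosage (.raw) reference callsets, a concordance engine
    validating predicted genotypes against imputed and whole-genome-sequencing
    genotypes (per-SNP and summary concordance, high-performing SNP selection,
    call-rate recalculation, GenTrain correlation, group comparisons), a
    cluster-geometry module flagging SNPs whose (Theta, R) data do not exhibit
    genotype clustering, a synthetic-panel simulator with known ground truth,
    cluster plotting, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    ggplot2
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SNP, Genetics, Classification, QualityControl, Microarray
RoxygenNote: 7.3.3
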