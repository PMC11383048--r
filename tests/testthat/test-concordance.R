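## A small deterministic cross-technology fixture: 3 samples x 2 variants,
## all dosages present.
smallMatchFixture <- function() {
    m <- SnpMetrics(data.frame(
        sampleID = rep(c("s1", "s2", "s3"), 2),
        snpID = rep(c("v1", "v2"), each = 3),
        chromosome = rep(c("1", "2"), each = 3),
        position = rep(c(100L, 200L), each = 3),
        ref = rep(c("A", "C"), each = 3), alt = rep(c("G", "T"), each = 3),
        r = 1, theta = 0.5, gentrain = 0.9,
        genotype = c("AA", "AB", "BB", "AB", "AB", "AA"),
        aIsRef = TRUE, stringsAsFactors = FALSE))
    cs <- new("DosageCallset", technology = "imputed",
              samples = c("s1", "s2", "s3"),
              variants = data.frame(
                  id = c("1:100:A:G", "2:200:C:T"),
                  chromosome = c("1", "2"), position = c(100L, 200L),
                  ref = c("A", "C"), alt = c("G", "T"),
                  countedAllele = c("G", "C"), stringsAsFactors = FALSE),
              dosages = matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 3, 2))
    list(metrics = m, callset = cs)
}

test_that("calls match only on exact sample and full variant key", {
    fx <- smallMatchFixture()
    matched <- matchCalls(fx$metrics, list(fx$callset))
    expect_equal(nrow(matched), 6)
    ## counted allele C = ref at v2: raw dosages 1,0,2 -> alt dosages 1,2,0
    v2 <- matched[matched$variantId == "2:200:C:T", ]
    expect_equal(v2$dosage_imputed, c(1L, 2L, 0L))

    ## ref/alt swapped -> no match, reason "allele mismatch"
    swapped <- fx$metrics
    df <- metricsTable(swapped)
    df$ref <- rep(c("G", "C"), each = 3); df$alt <- rep(c("A", "T"), each = 3)
    m2 <- matchCalls(SnpMetrics(df), list(fx$callset))
    un <- attr(m2, "unmatchedVariants")
    expect_equal(un$reason[un$variantId == "1:100:G:A"], "allele mismatch")

    ## disjoint samples -> "no sample overlap"
    cs3 <- fx$callset
    cs3@samples <- c("x1", "x2", "x3")
    m3 <- matchCalls(fx$metrics, list(cs3))
    expect_equal(nrow(m3), 0)
    expect_true(all(attr(m3, "unmatchedVariants")$reason ==
                    "no sample overlap"))

    ## absent variant -> "no variant match"
    cs4 <- fx$callset
    cs4@variants$position <- c(999L, 888L)
    cs4@variants$id <- c("1:999:A:G", "2:888:C:T")
    m4 <- matchCalls(fx$metrics, list(cs4))
    expect_true(all(attr(m4, "unmatchedVariants")$reason ==
                    "no variant match"))
})

test_that("per-SNP concordance and the either-technology summary rule", {
    fx <- smallMatchFixture()
    ## array alt dosages: v1 (aIsRef, AA/AB/BB) -> 0,1,2; imputed identical
    matched <- matchCalls(fx$metrics, list(fx$callset))
    rep1 <- snpConcordance(matched)
    expect_equal(rep1$rate_imputed[rep1$variantId == "1:100:A:G"], 1)

    ## craft a second technology that disagrees where imputed agrees
    wgs <- fx$callset
    wgs@technology <- "wgs"
    wgs@dosages <- matrix(c(2L, 1L, 0L, 1L, 0L, 2L), 3, 2)
    matched2 <- matchCalls(fx$metrics, list(fx$callset, wgs))
    rep2 <- snpConcordance(matched2)
    v1 <- rep2[rep2$variantId == "1:100:A:G", ]
    ## imputed all concordant, wgs only the heterozygote
    expect_equal(v1$rate_imputed, 1)
    expect_equal(v1$rate_wgs, 1 / 3)
    ## summary counts a call concordant with either technology
    expect_equal(v1$summary_rate, 1)
    expect_gte(v1$summary_rate, max(v1$rate_imputed, v1$rate_wgs))

    ## 9 of 10 concordant -> 0.9
    m10 <- SnpMetrics(data.frame(
        sampleID = sprintf("s%02d", 1:10), snpID = "v", chromosome = "3",
        position = 7L, ref = "A", alt = "T", r = 1, theta = 0.5,
        gentrain = 0.9, genotype = c(rep("AB", 9), "AA"), aIsRef = TRUE,
        stringsAsFactors = FALSE))
    cs10 <- new("DosageCallset", technology = "imputed",
                samples = sprintf("s%02d", 1:10),
                variants = data.frame(id = "3:7:A:T", chromosome = "3",
                                      position = 7L, ref = "A", alt = "T",
                                      countedAllele = "T",
                                      stringsAsFactors = FALSE),
                dosages = matrix(1L, 10, 1))
    rep10 <- snpConcordance(matchCalls(m10, list(cs10)))
    expect_equal(rep10$rate_imputed, 0.9)
})

test_that("engine concordance equals a brute-force recount on random fixtures", {
    for (seed in 1:8) {
        panel <- simulatePanel(simulationConfig(
            nSnps = 6, nSamples = 25, ncProbability = 0.05,
            seed = 1000 + seed))
        css <- simulateReferenceCallsets(
            panel$truth, errorRates = c(imputed = 0.15, wgs = 0.05),
            sampleOverlap = 0.7, variantOverlap = 0.8,
            seed = 2000 + seed)
        matched <- matchCalls(partitionNoCalls(panel$metrics)$valid, css)
        engine <- snpConcordance(matched)
        brute <- bruteConcordance(matched, c("imputed", "wgs"))
        for (vid in engine$variantId) {
            e <- engine[engine$variantId == vid, ]
            b <- brute[[vid]]
            expect_identical(e$rate_imputed, b$rate_imputed)
            expect_identical(e$rate_wgs, b$rate_wgs)
            expect_identical(e$summary_rate, b$summary_rate)
        }
    }
})

test_that("concordance is invariant to record order and perfect against itself", {
    panel <- simulatePanel(simulationConfig(nSnps = 5, nSamples = 30,
                                            ncProbability = 0, seed = 51))
    css <- simulateReferenceCallsets(panel$truth,
                                     errorRates = c(imputed = 0), seed = 52)
    valid <- partitionNoCalls(panel$metrics)$valid
    matched <- matchCalls(valid, css)
    rep1 <- snpConcordance(matched)
    ## error-free reference -> every SNP fully concordant
    expect_true(all(rep1$rate_imputed == 1))

    perm <- withr::with_seed(53, sample(nrow(matched)))
    shuffled <- matched[perm, ]
    attr(shuffled, "technologies") <- attr(matched, "technologies")
    rep2 <- snpConcordance(shuffled)
    expect_equal(rep1, rep2, ignore_attr = TRUE)
})

test_that("high-performing classification honors available technologies only", {
    rep <- data.frame(variantId = c("a", "b", "c"),
                      chromosome = "1", position = 1:3, ref = "A", alt = "G",
                      rate_imputed = c(0.95, 0.95, 0.95),
                      rate_wgs = c(0.92, 0.70, NA))
    attr(rep, "technologies") <- c("imputed", "wgs")
    out <- classifyHighPerforming(rep)
    expect_identical(out$high_performing, c(TRUE, FALSE, TRUE))
    ## no available rate at all -> unvalidated, not high-performing
    rep$rate_imputed <- NA
    rep$rate_wgs <- NA
    attr(rep, "technologies") <- c("imputed", "wgs")
    expect_false(any(classifyHighPerforming(rep)$high_performing))
    ## threshold is a parameter
    rep2 <- data.frame(variantId = "a", chromosome = "1", position = 1L,
                       ref = "A", alt = "G", rate_imputed = 0.8, rate_wgs = NA)
    attr(rep2, "technologies") <- c("imputed", "wgs")
    expect_true(classifyHighPerforming(rep2, threshold = 0.75)$high_performing)
})

test_that("call-rate recalculation is monotone arithmetic with guarded inputs", {
    expect_equal(recalculateCallRate(95, 100, 4), 0.99)
    expect_equal(recalculateCallRate(95, 100, 0), 0.95)
    expect_equal(recalculateCallRate(95, 100, 5), 1.0)
    expect_error(recalculateCallRate(101, 100, 0), "exceed")
    expect_error(recalculateCallRate(95, 100, 6), "no-call")
})

test_that("GenTrain correlation matches the textbook covariance formula", {
    expect_equal(gentrainCorrelation(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))$r, 1)
    expect_equal(gentrainCorrelation(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1))$r, -1)
    set.seed(61)
    g <- runif(40); c0 <- g * 0.3 + runif(40, 0, 0.7)
    g[c(3, 8)] <- NA
    got <- gentrainCorrelation(g, c0)
    ok <- !is.na(g)
    x <- g[ok]; y <- c0[ok]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, oracle, tolerance = 1e-12)
    expect_equal(got$n, 38)
    expect_warning(out <- gentrainCorrelation(c(1, 2), c(1, 2)), "undefined")
    expect_true(is.na(out$r))
})

test_that("Mann-Whitney comparison: exact enumeration and normal approximation", {
    ## {1,2,3} vs {4,5,6}: U = 0 and exact two-sided p = 0.1 (2 of the 20
    ## assignments are as extreme)
    out <- compareGroups(c(1, 2, 3), c(4, 5, 6))
    expect_equal(out$U, 0)
    expect_equal(out$p, 0.1)
    expect_match(out$method, "exact")
    ## agreement with the reference implementation in the exact case
    wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
    expect_equal(out$p, wt$p.value)

    ## identical groups -> p near 1
    expect_gt(compareGroups(c(1, 2, 3), c(1, 2, 3))$p, 0.9)

    ## large samples: normal approximation with tie correction agrees with
    ## the reference implementation without continuity correction
    set.seed(71)
    x <- round(runif(30), 1); y <- round(runif(25) + 0.2, 1)
    out2 <- compareGroups(x, y)
    wt2 <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(out2$U, unname(wt2$statistic))
    expect_equal(out2$p, wt2$p.value, tolerance = 1e-6)
    expect_error(compareGroups(numeric(0), 1), "non-empty")
})

test_that("injected reference error shows up as the measured discordance", {
    panel <- simulatePanel(simulationConfig(nSnps = 40, nSamples = 400,
                                            ncProbability = 0, seed = 81))
    css <- simulateReferenceCallsets(panel$truth,
                                     errorRates = c(imputed = 0.1), seed = 82)
    matched <- matchCalls(partitionNoCalls(panel$metrics)$valid, css)
    n <- sum(!is.na(matched$dosage_imputed))
    expect_gte(n, 10000)
    disc <- sum(matched$dosage_imputed != matched$arrayDosage, na.rm = TRUE)
    iv <- binom99(n, 0.1)
    expect_gte(disc, iv[1])
    expect_lte(disc, iv[2])
})
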