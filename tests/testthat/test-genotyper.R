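## Hand-buildable model for forward-pass arithmetic checks.
handModel <- function(W1, b1, Wout, bout, emb = matrix(0.2, 1, 1)) {
    new("TrainedGenotyper", vocabulary = "s1", embedding = emb,
        weights = list(W1, b1, Wout, bout),
        config = modelConfig(embeddingDim = ncol(emb), hiddenUnits = nrow(Wout),
                             seed = 1),
        history = data.frame())
}

test_that("forward pass matches a pencil-and-paper computation", {
    ## 1 SNP, embedding dim 1 (value 0.2), one hidden unit, known weights
    W1 <- matrix(c(0.5, -0.3, 0.8), 3, 1)   # input order: embedding, r, theta
    b1 <- 0.1
    Wout <- matrix(c(1.0, -2.0, 0.5), 1, 3)
    bout <- c(0.05, 0, -0.05)
    m <- handModel(W1, b1, Wout, bout)
    p <- forwardPass(m, 1L, r = 1.1, theta = 0.4)

    ## independent arithmetic: affine -> rectifier -> affine -> softmax
    h <- max(0.2 * 0.5 + 1.1 * -0.3 + 0.4 * 0.8 + 0.1, 0)
    z <- c(h * 1.0 + 0.05, h * -2.0 + 0, h * 0.5 - 0.05)
    expected <- exp(z - max(z)) / sum(exp(z - max(z)))
    expect_equal(unname(p[1, ]), expected, tolerance = 1e-9)

    ## negative pre-activation is rectified to zero
    p2 <- forwardPass(m, 1L, r = 10, theta = 0)   # z1 = -2.8 -> h = 0
    z2 <- bout
    expect_equal(unname(p2[1, ]), exp(z2 - max(z2)) / sum(exp(z2 - max(z2))),
                 tolerance = 1e-9)
})

test_that("all-zero weights yield the uniform distribution and outputs stay on the simplex", {
    m <- handModel(matrix(0, 3, 1), 0, matrix(0, 1, 3), c(0, 0, 0),
                   emb = matrix(0, 1, 1))
    expect_equal(unname(forwardPass(m, 1L, 0.7, 0.3)[1, ]), rep(1 / 3, 3))

    set.seed(1)
    W1 <- matrix(rnorm(3 * 4), 3, 4)
    m2 <- handModel(W1, rnorm(4), matrix(rnorm(12), 4, 3), rnorm(3))
    P <- forwardPass(m2, rep(1L, 50), runif(50, 0, 3), runif(50))
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-6)
    expect_error(forwardPass(m2, 2L, 1, 0.5), "vocabulary")
})

test_that("focal loss matches its closed form and limiting cases", {
    ## p_t = 0.5, gamma 2, alpha 0.25 -> 0.25 * 0.25 * ln 2
    expect_equal(focalLoss(c(0.5, 0.3, 0.2), c(1, 0, 0), 2, 0.25),
                 0.25 * 0.25 * log(2), tolerance = 1e-9)
    ## gamma 0, alpha 1 is plain cross-entropy over random simplex points
    set.seed(42)
    for (i in 1:200) {
        p <- rgamma(3, 1); p <- p / sum(p)
        t <- diag(3)[sample(3, 1), ]
        expect_equal(focalLoss(p, t, gamma = 0, alpha = 1),
                     -log(max(min(sum(p * t), 1 - 1e-7), 1e-7)),
                     tolerance = 1e-9)
    }
    ## perfectly confident correct prediction -> loss ~ 0
    expect_lt(focalLoss(c(1, 0, 0), c(1, 0, 0)), 1e-10)
    ## strictly decreasing in p_t for gamma > 0
    pt <- seq(0.01, 0.99, by = 0.01)
    losses <- vapply(pt, function(p)
        focalLoss(c(p, (1 - p) / 2, (1 - p) / 2), c(1, 0, 0), 2, 0.25),
        numeric(1))
    expect_true(all(diff(losses) < 0))
})

test_that("training separates well-clustered synthetic genotypes", {
    cfg <- simulationConfig(nSnps = 8, nSamples = 250, ncProbability = 0,
                            seed = 13)
    sp <- splitTrainValTest(simulatePanel(cfg)$metrics, seed = 13)
    m <- quickTrain(sp)
    expect_gte(m@history$val_accuracy[nrow(m@history)], 0.99)
    expect_lte(nrow(m@history), 4)

    pred <- predictGenotypes(m, sp$test)
    agg <- evaluateAgreement(pred, metricsTable(sp$test)$genotype)
    expect_gte(agg$accuracy, 0.98)
    expect_equal(sum(agg$confusion), nRecords(sp$test))
})

test_that("early stopping restores the best weights and respects patience", {
    cfg <- simulationConfig(nSnps = 4, nSamples = 120, ncProbability = 0,
                            seed = 17, thetaNoiseSd = 0.15)
    sp <- splitTrainValTest(simulatePanel(cfg)$metrics,
                            fractions = c(0.6, 0.2, 0.2), seed = 17)
    tr <- encodeDataset(sp$train)
    va <- encodeDataset(sp$val, vocab = tr@vocabulary)
    ## a destabilizing learning rate makes the validation loss rise
    m <- trainGenotyper(tr, va, modelConfig(learningRate = 2, maxEpochs = 8,
                                            earlyStopPatience = 0,
                                            batchSize = 64, seed = 17))
    h <- m@history
    expect_lte(nrow(h), 8)
    if (nrow(h) > 1 && nrow(h) < 8) {
        ## stopped early: the final epoch failed to improve on the best
        expect_gte(h$val_loss[nrow(h)], min(h$val_loss[-nrow(h)]))
        ## every earlier epoch was a strict improvement (patience 0)
        expect_true(all(h$val_loss[2:(nrow(h) - 1)] <
                        cummin(h$val_loss)[1:(nrow(h) - 2)]))
    }
    ## restored weights reproduce the best epoch's validation loss
    va_probs <- forwardPass(m, va@snpIndex, va@features[, 1], va@features[, 2])
    expect_equal(mean(focalLoss(va_probs, va@targets)), min(h$val_loss),
                 tolerance = 1e-9)
})

test_that("training is reproducible under a fixed seed and refuses empty input", {
    cfg <- simulationConfig(nSnps = 3, nSamples = 60, ncProbability = 0,
                            seed = 19)
    sp <- splitTrainValTest(simulatePanel(cfg)$metrics, seed = 19)
    m1 <- quickTrain(sp, epochs = 2)
    m2 <- quickTrain(sp, epochs = 2)
    expect_identical(m1@history, m2@history)
    expect_identical(m1@embedding, m2@embedding)

    tr <- encodeDataset(sp$train)
    empty <- encodeDataset(sp$train[integer(0)], vocab = tr@vocabulary)
    expect_error(trainGenotyper(empty, empty, modelConfig(seed = 1)), "empty")
})

test_that("grid search enumerates the grid and returns the best pair", {
    cfg <- simulationConfig(nSnps = 2, nSamples = 60, ncProbability = 0,
                            seed = 23)
    sp <- splitTrainValTest(simulatePanel(cfg)$metrics,
                            fractions = c(0.7, 0.15, 0.15), seed = 23)
    tr <- encodeDataset(sp$train)
    va <- encodeDataset(sp$val, vocab = tr@vocabulary)
    base <- modelConfig(embeddingDim = 4, batchSize = 64, learningRate = 1e-3,
                        seed = 23)
    gs <- gridSearchHiddenUnits(tr, va, sizes = c(32, 64), epochs = 1,
                                config = base)
    expect_equal(nrow(gs$results), 4)
    expect_true(all(gs$hiddenUnits %in% c(32, 64)))
    expect_equal(min(gs$results$val_loss),
                 gs$results$val_loss[gs$results$h1 == gs$hiddenUnits[1] &
                                     gs$results$h2 == gs$hiddenUnits[2]])
    ## the production grid enumerates 25 pairs
    expect_equal(nrow(expand.grid(seq(32, 160, by = 32),
                                  seq(32, 160, by = 32))), 25)
    gs1 <- gridSearchHiddenUnits(tr, va, sizes = 48, epochs = 1,
                                 config = base)
    expect_equal(gs1$hiddenUnits, c(48L, 48L))
})

test_that("prediction applies argmax with fixed tie order and excludes unknown SNPs", {
    ## argmax picks AB for (0.2, 0.5, 0.3); ties break toward earlier class
    W <- matrix(0, 1, 3)
    m <- handModel(matrix(0, 3, 1), 0, W, log(c(0.2, 0.5, 0.3)))
    rec <- makeMetrics(1, snpID = "s1")
    pred <- predictGenotypes(m, rec)
    expect_equal(predictedGenotype(pred), "AB")
    expect_equal(pred@maxProbability, 0.5, tolerance = 1e-9)

    mTie <- handModel(matrix(0, 3, 1), 0, W, c(0, 0, 0))
    expect_equal(predictedGenotype(predictGenotypes(mTie, rec)), "AA")

    ## unknown snpID is excluded with a message, never NC-called
    recs <- makeMetrics(2, snpID = c("s1", "zz"))
    expect_message(p2 <- predictGenotypes(mTie, recs), "excluded")
    expect_equal(nrow(probabilities(p2)), 1)
    expect_equal(p2@excludedSnpIds, "zz")
    ## empty input -> empty result
    p3 <- suppressMessages(predictGenotypes(mTie, recs[integer(0)]))
    expect_equal(nrow(probabilities(p3)), 0)
})

test_that("agreement evaluation counts matches and fills the confusion matrix", {
    out <- evaluateAgreement(c("AA", "BB"), c("AA", "AA"))
    expect_equal(out$accuracy, 0.5)
    expect_equal(out$confusion["AA", "AA"], 1L)
    expect_equal(out$confusion["AA", "BB"], 1L)
    ident <- evaluateAgreement(c("AA", "AB", "BB"), c("AA", "AB", "BB"))
    expect_equal(ident$accuracy, 1)
    expect_equal(unname(diag(ident$confusion)), c(1L, 1L, 1L))
    expect_error(evaluateAgreement(c("AA"), c("AA", "AB")), "length")
})

test_that("model archives round-trip through save/load", {
    cfg <- simulationConfig(nSnps = 3, nSamples = 80, ncProbability = 0,
                            seed = 29)
    sp <- splitTrainValTest(simulatePanel(cfg)$metrics, seed = 29)
    m <- quickTrain(sp, epochs = 2)
    f <- withr::local_tempfile(fileext = ".json")
    saveGenotyper(m, f)
    m2 <- loadGenotyper(f)
    expect_identical(vocabulary(m2), vocabulary(m))
    te <- encodeDataset(sp$test, vocab = vocabulary(m))
    p1 <- forwardPass(m, te@snpIndex, te@features[, 1], te@features[, 2])
    p2 <- forwardPass(m2, te@snpIndex, te@features[, 1], te@features[, 2])
    expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("trained model tracks the Bayes classifier on overlapping clusters", {
    ## moderately overlapping clusters: Bayes error is non-trivial, and the
    ## network should come within one percentage point of the Bayes rule
    cfg <- simulationConfig(nSnps = 20, nSamples = 400, ncProbability = 0,
                            thetaNoiseSd = 0.1, centroidJitterSd = 0,
                            seed = 37)
    panel <- simulatePanel(cfg)
    sp <- splitTrainValTest(panel$metrics, seed = 37)
    m <- quickTrain(sp, lr = 3e-3, epochs = 8, seed = 37)

    test_df <- metricsTable(sp$test)
    pred <- predictGenotypes(m, sp$test)
    accNN <- mean(predictedGenotype(pred) == test_df$genotype)

    ## Bayes rule from the generating model: per-SNP HWE priors in B-allele
    ## space and Gaussian theta likelihoods around the planted centroids
    pars <- panel$snpParams
    i <- match(test_df$snpID, pars$snpID)
    q <- pars$maf[i]
    pB <- ifelse(pars$aIsRef[i], q, 1 - q)   # frequency of Illumina allele B
    priors <- cbind((1 - pB)^2, 2 * pB * (1 - pB), pB^2)
    centroids <- as.matrix(pars[i, c("centroid_AA", "centroid_AB",
                                     "centroid_BB")])
    lik <- stats::dnorm(test_df$theta, centroids, cfg@thetaNoiseSd)
    post <- priors * matrix(lik, ncol = 3)
    bayesCall <- c("AA", "AB", "BB")[max.col(post, ties.method = "first")]
    accBayes <- mean(bayesCall == test_df$genotype)
    expect_gte(accNN, accBayes - 0.01)
    expect_lt(accBayes, 1)
})

test_that("accuracy collapses to the class prior when clusters coincide", {
    cfg <- simulationConfig(nSnps = 10, nSamples = 300, ncProbability = 0,
                            centroidTemplate = c(0.5, 0.5, 0.5),
                            centroidJitterSd = 0, mafRange = c(0.5, 0.5),
                            seed = 41)
    sp <- splitTrainValTest(simulatePanel(cfg)$metrics, seed = 41)
    m <- quickTrain(sp, epochs = 8, seed = 41)
    pred <- predictGenotypes(m, sp$test)
    testGt <- metricsTable(sp$test)$genotype
    acc <- mean(predictedGenotype(pred) == testGt)
    ## with MAF 0.5 the majority class (AB) has prior 0.5: accuracy should
    ## approach the majority-class rate of the held-out split, nothing more
    majority <- max(table(factor(testGt, levels = c("AA", "AB", "BB")))) /
        length(testGt)
    expect_gte(acc, majority - 0.05)
    expect_lte(acc, majority + 0.05)
})
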