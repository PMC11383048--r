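## The genotyping network: a per-SNP embedding concatenated with the (r,
## theta) probe measurements, two rectifier dense layers, and a 3-class
## softmax output, trained with focal cross-entropy and an adaptive-moment
## (Adam) optimizer. All linear algebra is plain R matrix code; the network
## is small enough that BLAS-backed matrix products dominate.

.glorotUniform <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
}

.initParams <- function(vocabSize, config) {
    dims <- c(config@embeddingDim + 2L, config@hiddenUnits, 3L)
    weights <- list()
    for (l in seq_len(length(dims) - 1L)) {
        weights[[2L * l - 1L]] <- .glorotUniform(dims[l], dims[l + 1L])
        weights[[2L * l]] <- numeric(dims[l + 1L])
    }
    list(E = matrix(runif(vocabSize * config@embeddingDim, -0.05, 0.05),
                    vocabSize, config@embeddingDim),
         W = weights)
}

.softmax <- function(z) {
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    e / rowSums(e)
}

## Forward pass returning all layer activations (for backprop).
.forwardFull <- function(E, W, idx, feats) {
    x <- cbind(E[idx, , drop = FALSE], feats)
    nlayers <- length(W) / 2L
    Z <- A <- vector("list", nlayers)
    a <- x
    for (l in seq_len(nlayers)) {
        z <- sweep(a %*% W[[2L * l - 1L]], 2L, W[[2L * l]], "+")
        if (l < nlayers) a <- pmax(z, 0) else a <- .softmax(z)
        Z[[l]] <- z
        A[[l]] <- a
    }
    list(x = x, Z = Z, A = A, P = A[[nlayers]])
}

.forwardProbs <- function(E, W, idx, feats, chunk = 8192L) {
    n <- length(idx)
    if (n <= chunk)
        return(.forwardFull(E, W, idx, feats)$P)
    out <- matrix(NA_real_, n, 3L)
    starts <- seq(1L, n, by = chunk)
    for (s in starts) {
        e <- min(s + chunk - 1L, n)
        out[s:e, ] <- .forwardFull(E, W, idx[s:e],
                                   feats[s:e, , drop = FALSE])$P
    }
    out
}

#' Forward pass of the genotyping network
#'
#' Looks up the embedding row for each SNP index, concatenates it with the
#' (r, theta) features, applies each hidden layer (affine map then rectifier)
#' and the output layer (affine map then numerically stable softmax).
#'
#' @param model a \linkS4class{TrainedGenotyper}.
#' @param snpIndex integer vector of 1-based vocabulary indices.
#' @param r,theta numeric vectors of probe measurements.
#' @return numeric matrix, one probability simplex row (AA, AB, BB) per input.
#' @export
forwardPass <- function(model, snpIndex, r, theta) {
    snpIndex <- as.integer(snpIndex)
    if (any(snpIndex < 1L | snpIndex > length(model@vocabulary)))
        stop("snpIndex out of vocabulary range", call. = FALSE)
    P <- .forwardProbs(model@embedding, model@weights, snpIndex,
                       cbind(r = r, theta = theta))
    colnames(P) <- GT_CLASSES
    P
}

#' Focal cross-entropy loss
#'
#' For true-class probability p_t, returns
#' \code{-alpha * (1 - p_t)^gamma * log(p_t)}, with p_t clipped to
#' [1e-7, 1 - 1e-7] before the logarithm. With \code{gamma = 0, alpha = 1}
#' this reduces to ordinary categorical cross-entropy; for
#' \code{gamma > 0} well-classified examples (p_t near 1) are down-weighted.
#'
#' @param prob numeric matrix of probability rows (or a single 3-vector).
#' @param target one-hot matrix (or 3-vector) of the same shape.
#' @param gamma focusing exponent (>= 0).
#' @param alpha scale in (0, 1].
#' @return numeric vector of per-record losses.
#' @export
#' @examples
#' focalLoss(c(0.5, 0.3, 0.2), c(1, 0, 0), gamma = 2, alpha = 0.25)
focalLoss <- function(prob, target, gamma = 2, alpha = 0.25) {
    if (is.null(dim(prob))) prob <- matrix(prob, 1L)
    if (is.null(dim(target))) target <- matrix(target, 1L)
    pt <- clamp(rowSums(prob * target), 1e-7, 1 - 1e-7)
    -alpha * (1 - pt)^gamma * log(pt)
}

## Gradient of the mean focal loss w.r.t. the output-layer logits.
## dL/dz_j = dL/dp_t * p_t * (t_j - p_j), with p_t = probability of the true
## class (clipped as in the loss).
.focalLogitGrad <- function(P, Y, gamma, alpha) {
    pt <- clamp(rowSums(P * Y), 1e-7, 1 - 1e-7)
    if (gamma == 0) {
        dLdpt <- -alpha / pt
    } else {
        ## pt is clipped away from 1, so (1 - pt)^(gamma - 1) stays finite
        dLdpt <- alpha * (gamma * (1 - pt)^(gamma - 1) * log(pt) -
                          (1 - pt)^gamma / pt)
    }
    (dLdpt * pt) * (Y - P)
}

.evalDataset <- function(E, W, data, gamma, alpha) {
    P <- .forwardProbs(E, W, data@snpIndex, data@features)
    loss <- mean(focalLoss(P, data@targets, gamma, alpha))
    acc <- mean(max.col(P, ties.method = "first") ==
                max.col(data@targets, ties.method = "first"))
    list(loss = loss, accuracy = acc)
}

#' Train the genotyping network
#'
#' Minimizes the mean focal cross-entropy with an adaptive-moment optimizer
#' (moment decays 0.9/0.999, epsilon 1e-7) over shuffled mini-batches.
#' Training runs for at most \code{maxEpochs} epochs and stops early when
#' the validation loss has failed to improve for \code{earlyStopPatience}
#' consecutive epochs (for patience 0, the first non-improving epoch stops
#' training); the weights from the best-validation-loss epoch are restored.
#'
#' @param train,val \linkS4class{EncodedDataset}s encoded against the same
#'   vocabulary.
#' @param config a \linkS4class{ModelConfig}.
#' @param verbose logical; print per-epoch metrics.
#' @return A \linkS4class{TrainedGenotyper} whose \code{history} records
#'   per-epoch train/validation loss and accuracy.
#' @export
trainGenotyper <- function(train, val, config = modelConfig(),
                           verbose = FALSE) {
    stopIfNot(length(train@snpIndex) > 0L, "training set is empty")
    stopIfNot(identical(train@vocabulary, val@vocabulary),
              "train and val must share one vocabulary")
    stopIfNot(nrow(train@targets) > 0L && nrow(val@targets) > 0L,
              "train and val must carry targets")
    gamma <- config@focalGamma
    alpha <- config@focalAlpha
    lr <- config@learningRate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
    n <- length(train@snpIndex)

    withSeed(config@seed, {
        params <- .initParams(length(train@vocabulary), config)
        E <- params$E; W <- params$W
        mE <- E * 0; vE <- E * 0
        mW <- lapply(W, function(w) w * 0)
        vW <- lapply(W, function(w) w * 0)
        t_step <- 0L
        nlayers <- length(W) / 2L
        embDim <- config@embeddingDim

        best <- list(loss = Inf, E = E, W = W, epoch = 0L)
        wait <- 0L
        hist <- data.frame()

        for (epoch in seq_len(config@maxEpochs)) {
            perm <- sample.int(n)
            starts <- seq(1L, n, by = config@batchSize)
            epochLoss <- 0; epochAcc <- 0; seen <- 0L
            for (s in starts) {
                rows <- perm[s:min(s + config@batchSize - 1L, n)]
                nb <- length(rows)
                idx <- train@snpIndex[rows]
                Y <- train@targets[rows, , drop = FALSE]
                fw <- .forwardFull(E, W, idx,
                                   train@features[rows, , drop = FALSE])
                P <- fw$P
                epochLoss <- epochLoss + sum(focalLoss(P, Y, gamma, alpha))
                epochAcc <- epochAcc +
                    sum(max.col(P, ties.method = "first") ==
                        max.col(Y, ties.method = "first"))
                seen <- seen + nb

                ## backprop
                grads <- vector("list", length(W))
                ## per-record dL/dz at the output logits; /nb gives the
                ## gradient of the mean batch loss
                delta <- .focalLogitGrad(P, Y, gamma, alpha) / nb
                for (l in rev(seq_len(nlayers))) {
                    a_prev <- if (l == 1L) fw$x else fw$A[[l - 1L]]
                    grads[[2L * l - 1L]] <- crossprod(a_prev, delta)
                    grads[[2L * l]] <- colSums(delta)
                    if (l > 1L) {
                        delta <- (delta %*% t(W[[2L * l - 1L]])) *
                            (fw$Z[[l - 1L]] > 0)
                    } else {
                        dX <- delta %*% t(W[[1L]])
                    }
                }
                gE <- matrix(0, nrow(E), embDim)
                acc_rows <- rowsum(dX[, seq_len(embDim), drop = FALSE],
                                   group = idx)
                gE[as.integer(rownames(acc_rows)), ] <- acc_rows

                ## Adam update
                t_step <- t_step + 1L
                c1 <- 1 - b1^t_step; c2 <- 1 - b2^t_step
                for (k in seq_along(W)) {
                    mW[[k]] <- b1 * mW[[k]] + (1 - b1) * grads[[k]]
                    vW[[k]] <- b2 * vW[[k]] + (1 - b2) * grads[[k]]^2
                    W[[k]] <- W[[k]] - lr * (mW[[k]] / c1) /
                        (sqrt(vW[[k]] / c2) + eps)
                }
                mE <- b1 * mE + (1 - b1) * gE
                vE <- b2 * vE + (1 - b2) * gE^2
                E <- E - lr * (mE / c1) / (sqrt(vE / c2) + eps)
            }
            valStats <- .evalDataset(E, W, val, gamma, alpha)
            hist <- rbind(hist, data.frame(
                epoch = epoch, loss = epochLoss / seen,
                accuracy = epochAcc / seen, val_loss = valStats$loss,
                val_accuracy = valStats$accuracy))
            if (verbose)
                message(sprintf(
                    "epoch %d: loss %.6g acc %.4f | val loss %.6g acc %.4f",
                    epoch, epochLoss / seen, epochAcc / seen,
                    valStats$loss, valStats$accuracy))
            if (valStats$loss < best$loss) {
                best <- list(loss = valStats$loss, E = E, W = W,
                             epoch = epoch)
                wait <- 0L
            } else {
                wait <- wait + 1L
                if (wait >= max(config@earlyStopPatience, 1L)) break
            }
        }
    })

    new("TrainedGenotyper", vocabulary = train@vocabulary,
        embedding = best$E, weights = best$W, config = config,
        history = hist)
}

#' Grid search over the two dense-layer widths
#'
#' Trains one reduced-epoch model per (first width, second width) pair and
#' returns the pair minimizing the best validation loss; ties are broken
#' toward the smaller total parameter count. The default grid spans widths
#' 32 to 160 in steps of 32 (25 pairs).
#'
#' @param train,val \linkS4class{EncodedDataset}s sharing a vocabulary.
#' @param sizes integer vector of candidate layer widths.
#' @param epochs epochs per candidate (kept small; this is a search, not a
#'   final fit).
#' @param config base \linkS4class{ModelConfig}; hiddenUnits and maxEpochs
#'   are overridden per candidate.
#' @return list with \code{hiddenUnits} (the winning pair) and
#'   \code{results} (one row per candidate with its validation loss).
#' @export
gridSearchHiddenUnits <- function(train, val, sizes = seq(32L, 160L, by = 32L),
                                  epochs = 2L, config = modelConfig()) {
    stopIfNot(length(sizes) > 0L, "size grid must be non-empty")
    grid <- expand.grid(h1 = as.integer(sizes), h2 = as.integer(sizes))
    res <- data.frame(grid, val_loss = NA_real_, n_params = NA_integer_)
    for (i in seq_len(nrow(grid))) {
        cfg <- config
        cfg@hiddenUnits <- c(grid$h1[i], grid$h2[i])
        cfg@maxEpochs <- as.integer(epochs)
        fit <- trainGenotyper(train, val, cfg)
        res$val_loss[i] <- min(fit@history$val_loss)
        d <- c(cfg@embeddingDim + 2L, cfg@hiddenUnits, 3L)
        res$n_params[i] <- length(train@vocabulary) * cfg@embeddingDim +
            sum(d[-length(d)] * d[-1L] + d[-1L])
    }
    ord <- order(res$val_loss, res$n_params)
    list(hiddenUnits = c(res$h1[ord[1L]], res$h2[ord[1L]]), results = res)
}

#' Predict genotypes for metrics records
#'
#' Applies the trained network to each record's (snpID, r, theta). Records
#' whose snpID is not in the model vocabulary cannot be predicted (their
#' embedding was never trained); they are excluded from the output and their
#' count is reported with a message. NC is never a predicted class; the
#' maximum class probability is returned so a downstream confidence
#' threshold can be applied.
#'
#' @param model a \linkS4class{TrainedGenotyper}.
#' @param x a \linkS4class{SnpMetrics} with non-missing r and theta.
#' @return A \linkS4class{PredictionResult}.
#' @export
predictGenotypes <- function(model, x) {
    df <- x@records
    idx <- match(df$snpID, model@vocabulary)
    known <- !is.na(idx)
    if (any(!known))
        message(sum(!known), " record(s) excluded: snpID not in model ",
                "vocabulary")
    keep <- which(known)
    if (length(keep) && anyNA(df$r[keep] + df$theta[keep]))
        stop("records with missing r/theta cannot be predicted", call. = FALSE)
    if (!length(keep)) {
        return(new("PredictionResult",
                   probabilities = matrix(0, 0L, 3L,
                                          dimnames = list(NULL, GT_CLASSES)),
                   predicted = character(), maxProbability = numeric(),
                   keptRows = integer(),
                   excludedSnpIds = df$snpID[!known]))
    }
    P <- forwardPass(model, idx[keep], df$r[keep], df$theta[keep])
    cls <- max.col(P, ties.method = "first")
    new("PredictionResult", probabilities = P,
        predicted = GT_CLASSES[cls],
        maxProbability = P[cbind(seq_len(nrow(P)), cls)],
        keptRows = keep, excludedSnpIds = df$snpID[!known])
}

#' Agreement between predicted and reference genotypes
#'
#' @param predictions a \linkS4class{PredictionResult} or a character vector
#'   of AA/AB/BB calls.
#' @param reference character vector of AA/AB/BB genotypes, same length as
#'   the predictions.
#' @return list with \code{accuracy} (fraction of exact matches) and
#'   \code{confusion}, a 3x3 count matrix with reference classes as rows and
#'   predicted classes as columns.
#' @export
evaluateAgreement <- function(predictions, reference) {
    pred <- if (is(predictions, "PredictionResult")) predictions@predicted
            else as.character(predictions)
    stopIfNot(length(pred) == length(reference),
              "predictions and reference must have equal length")
    stopIfNot(all(reference %in% GT_CLASSES),
              "reference must contain only AA/AB/BB")
    confusion <- table(factor(reference, levels = GT_CLASSES),
                       factor(pred, levels = GT_CLASSES))
    confusion <- matrix(as.integer(confusion), 3L, 3L,
                        dimnames = list(reference = GT_CLASSES,
                                        predicted = GT_CLASSES))
    list(accuracy = mean(pred == reference), confusion = confusion)
}

#' Save / load a trained genotyper
#'
#' The model archive is a single self-describing JSON file holding the
#' format version, the configuration, the snpID vocabulary, the embedding
#' table and all dense-layer weights at full precision.
#'
#' @param model a \linkS4class{TrainedGenotyper}.
#' @param path archive path (conventionally .json).
#' @return \code{saveGenotyper}: \code{path}, invisibly.
#' @export
saveGenotyper <- function(model, path) {
    cfg <- model@config
    obj <- list(
        format = "genorescue-model", version = 1L,
        config = list(embeddingDim = cfg@embeddingDim,
                      hiddenUnits = cfg@hiddenUnits, nClasses = cfg@nClasses,
                      learningRate = cfg@learningRate,
                      maxEpochs = cfg@maxEpochs,
                      earlyStopPatience = cfg@earlyStopPatience,
                      focalGamma = cfg@focalGamma, focalAlpha = cfg@focalAlpha,
                      batchSize = cfg@batchSize, seed = cfg@seed),
        vocabulary = model@vocabulary,
        embedding = model@embedding,
        weights = model@weights,
        history = model@history)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
    invisible(path)
}

#' @rdname saveGenotyper
#' @param path archive path written by \code{saveGenotyper}.
#' @return \code{loadGenotyper}: a \linkS4class{TrainedGenotyper}.
#' @export
loadGenotyper <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    stopIfNot(identical(obj$format, "genorescue-model"),
              "not a genotyper model archive")
    cfg <- modelConfig(embeddingDim = obj$config$embeddingDim,
                       hiddenUnits = obj$config$hiddenUnits,
                       learningRate = obj$config$learningRate,
                       maxEpochs = obj$config$maxEpochs,
                       earlyStopPatience = obj$config$earlyStopPatience,
                       focalGamma = obj$config$focalGamma,
                       focalAlpha = obj$config$focalAlpha,
                       batchSize = obj$config$batchSize,
                       seed = obj$config$seed)
    weights <- lapply(obj$weights, function(w) {
        if (is.matrix(w)) w else as.numeric(w)
    })
    new("TrainedGenotyper", vocabulary = as.character(obj$vocabulary),
        embedding = as.matrix(obj$embedding), weights = weights,
        config = cfg, history = as.data.frame(obj$history))
}
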