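#' Training-harness configuration
#'
#' See [TrainConfig-class] for the meaning and provenance of the defaults.
#'
#' @param lossKind `"ce"`, `"ce+triplet"` or `"ce+bst"`.
#' @param margin,lambda triplet-loss parameters.
#' @param batchSize batch size Nb (default 36).
#' @param initLr initial learning rate (default 0.001).
#' @param lrFactor plateau multiplier (default 0.3).
#' @param lrPatience epochs of non-improving training loss before the
#'   learning rate is reduced (default 20).
#' @param lrMinDelta improvement below this does not count (default 1e-4,
#'   mirroring the early-stopping delta).
#' @param minLr learning-rate floor (default 1e-8).
#' @param maxEpochs maximum epochs (default 400).
#' @param earlyStopPatience epochs of non-improving validation loss before
#'   stopping (default 30).
#' @param earlyStopMinDelta minimum improvement (default 1e-4).
#' @param seed integer seed; the run is fully reproducible given it.
#' @param embeddingDim embedding length l of the built-in network
#'   (default 16).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(lossKind = "ce+bst", margin = 0.9, lambda = 1,
                        batchSize = 36L, initLr = 0.001, lrFactor = 0.3,
                        lrPatience = 20L, lrMinDelta = 1e-4, minLr = 1e-8,
                        maxEpochs = 400L, earlyStopPatience = 30L,
                        earlyStopMinDelta = 1e-4, seed = 1L,
                        embeddingDim = 16L) {
    new("TrainConfig", lossKind = lossKind, margin = as.numeric(margin),
        lambda = as.numeric(lambda), batchSize = as.integer(batchSize),
        initLr = as.numeric(initLr), lrFactor = as.numeric(lrFactor),
        lrPatience = as.integer(lrPatience),
        lrMinDelta = as.numeric(lrMinDelta), minLr = as.numeric(minLr),
        maxEpochs = as.integer(maxEpochs),
        earlyStopPatience = as.integer(earlyStopPatience),
        earlyStopMinDelta = as.numeric(earlyStopMinDelta),
        seed = as.integer(seed), embeddingDim = as.integer(embeddingDim))
}

#' Read a TrainConfig from a YAML/JSON key-value file
#'
#' Keys mirror the [trainConfig()] arguments; missing keys keep their
#' defaults.
#'
#' @param path config file path.
#' @return a [TrainConfig-class].
#' @export
trainConfigFromFile <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(trainConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(trainConfig, vals)
}

## draw one training batch of indices into the training subset
.drawBatch <- function(nTrain, Nb, plan = NULL, quotas = NULL) {
    if (is.null(plan))
        return(sample.int(nTrain, Nb, replace = Nb > nTrain))
    out <- integer(0)
    for (g in seq_len(plan@nGroups)) {
        q <- quotas[g]
        if (q == 0L) next
        members <- which(plan@groupOfSample == g)
        take <- if (length(members) == 1L) members
                else sample(members, min(q, length(members)),
                            replace = q > length(members))
        out <- c(out, take)
    }
    out
}

## whole-set validation loss under the configured objective (BST evaluated
## on the full set as one batch; the random-pairing triplet term is left out
## of the monitored quantity)
.evalLoss <- function(net, X, labels, cfg, bstCfg, ctx) {
    fwd <- .netForward(net, X, keepActs = FALSE, ctx = ctx)
    ce <- crossEntropyLoss(fwd$probs, labels)
    if (cfg@lossKind == "ce+bst" && nrow(fwd$emb) >= 2L &&
        all(rowSums(fwd$emb^2) > 1e-12)) {
        ce + cfg@lambda * bstLoss(fwd$emb, labels, bstCfg)@batchMean
    } else ce
}

#' Train the built-in classifier on an image dataset
#'
#' Trains a small convolutional classifier (two 3x3 convolution blocks with
#' 8 and `embeddingDim` filters, ReLU and 2x2 max-pooling, global average
#' pooling as the embedding, then a linear softmax head) under one of three
#' objectives: plain cross-entropy (`"ce"`), cross-entropy plus the regular
#' similarity triplet loss with random positive/negative pairing
#' (`"ce+triplet"`), or cross-entropy plus the BSTriplet batch loss
#' (`"ce+bst"`).  Optimization is Adam under a reduce-on-plateau learning
#' rate schedule with early stopping on the validation loss (see
#' [trainConfig()]).  Batches are drawn uniformly at random ("RS"), or by
#' the mining strategy's per-group quotas when a [MiningPlan-class] over the
#' training subset is supplied ("DM").
#'
#' @param dataset an image-bearing [SyntheticDataset-class] (or the return
#'   of [readImageDataset()]).
#' @param config a [TrainConfig-class].
#' @param plan optional [MiningPlan-class] built over the training-subset
#'   samples in order (see [miningPlanForDataset()]).
#' @param verbose print one line per epoch.
#' @return a [TrainHistory-class].
#' @export
trainClassifier <- function(dataset, config = trainConfig(), plan = NULL,
                            verbose = FALSE) {
    stopifnot(is(dataset, "SyntheticDataset"), is(config, "TrainConfig"))
    if (length(dataset@images) == 0L)
        stop("the training harness needs an image dataset")
    validObject(config)
    cls <- dataset@classLabels
    C <- max(cls) + 1L
    trIdx <- which(dataset@split == "train")
    vaIdx <- which(dataset@split == "validation")
    teIdx <- which(dataset@split == "test")
    if (!length(vaIdx)) vaIdx <- teIdx
    if (!is.null(plan) &&
        length(plan@groupOfSample) != length(trIdx))
        stop("mining plan must cover exactly the training-subset samples")
    Xtr <- dataset@images[trIdx, , , drop = FALSE]
    ytr <- cls[trIdx]
    Xva <- dataset@images[vaIdx, , , drop = FALSE]
    yva <- cls[vaIdx]
    H <- dim(Xtr)[2L]; W <- dim(Xtr)[3L]
    ctx <- .netContext(H, W, 8L, config@batchSize)
    ctxVal <- .netContext(H, W, 8L, length(vaIdx))
    bstCfg <- bstConfig(margin = config@margin, lambda = config@lambda)
    quotas <- if (!is.null(plan))
        batchQuotas(plan, config@batchSize)@quotaOfGroup else NULL
    nTrain <- length(trIdx)
    iters <- max(1L, nTrain %/% config@batchSize)

    withr::with_seed(config@seed, {
        net <- .initNet(C, config@embeddingDim)
        adam <- .adamInit(net)
        lr <- config@initLr
        trainLoss <- valLoss <- lrTrace <- bstTrace <- numeric(0)
        bestTrain <- Inf; lrWait <- 0L
        bestVal <- Inf; esWait <- 0L
        stopped <- FALSE
        for (epoch in seq_len(config@maxEpochs)) {
            epochLosses <- epochBst <- numeric(iters)
            for (it in seq_len(iters)) {
                bi <- .drawBatch(nTrain, config@batchSize, plan, quotas)
                Xb <- Xtr[bi, , , drop = FALSE]
                yb <- ytr[bi]
                fwd <- .netForward(net, Xb, keepActs = TRUE, ctx = ctx)
                nb <- length(bi)
                Y <- matrix(0, nb, C)
                Y[cbind(seq_len(nb), yb + 1L)] <- 1
                dLogits <- (fwd$probs - Y) / nb
                ce <- crossEntropyLoss(fwd$probs, yb)
                dEmbExtra <- matrix(0, nb, ncol(fwd$emb))
                tripVal <- 0
                embOk <- all(rowSums(fwd$emb^2) > 1e-12)
                if (config@lossKind == "ce+bst" && embOk) {
                    res <- bstLoss(fwd$emb, yb, bstCfg, gradient = TRUE)
                    tripVal <- res@batchMean
                    dEmbExtra <- config@lambda * res@gradient
                } else if (config@lossKind == "ce+triplet" && embOk) {
                    tb <- .tripletBatch(fwd$emb, yb)
                    tripVal <- tb$loss
                    dEmbExtra <- config@lambda * tb$grad
                }
                grads <- .netBackward(net, fwd, dLogits, dEmbExtra)
                st <- .adamStep(net, grads, adam, lr)
                net <- st$net; adam <- st$state
                epochLosses[it] <- ce + config@lambda * tripVal
                epochBst[it] <- tripVal
            }
            trainLoss <- c(trainLoss, mean(epochLosses))
            bstTrace <- c(bstTrace, mean(epochBst))
            vl <- .evalLoss(net, Xva, yva, config, bstCfg, ctxVal)
            valLoss <- c(valLoss, vl)
            lrTrace <- c(lrTrace, lr)
            if (verbose)
                message(sprintf(
                    "epoch %3d  train %.5f  val %.5f  lr %.2g",
                    epoch, mean(epochLosses), vl, lr))
            ## reduce-on-plateau on the training loss
            if (mean(epochLosses) < bestTrain - config@lrMinDelta) {
                bestTrain <- mean(epochLosses); lrWait <- 0L
            } else {
                lrWait <- lrWait + 1L
                if (lrWait >= config@lrPatience) {
                    lr <- max(config@minLr, lr * config@lrFactor)
                    lrWait <- 0L
                }
            }
            ## early stopping on the validation loss
            if (vl < bestVal - config@earlyStopMinDelta) {
                bestVal <- vl; esWait <- 0L
            } else {
                esWait <- esWait + 1L
                if (esWait >= config@earlyStopPatience) {
                    stopped <- TRUE
                    break
                }
            }
        }
        ## final evaluation on the test split
        Xte <- dataset@images[teIdx, , , drop = FALSE]
        yte <- cls[teIdx]
        fwdTe <- .netForward(net, Xte, keepActs = FALSE,
                             ctx = .netContext(H, W, 8L, length(teIdx)))
        metrics <- classMetrics(yte, scores = fwdTe$probs, nClasses = C)
        new("TrainHistory", epochs = length(trainLoss),
            trainLoss = trainLoss, valLoss = valLoss, trainBst = bstTrace,
            learningRate = lrTrace, stoppedEarly = stopped,
            metrics = metrics, testScores = fwdTe$probs,
            testLabels = as.integer(yte), testEmbeddings = fwdTe$emb,
            config = config)
    })
}

#' Build a mining plan for a dataset's training subset
#'
#' Computes the default clustering features ([imageFeatures()] for images,
#' the raw embeddings otherwise) on the training-split samples and builds
#' the [MiningPlan-class] over them, in training-subset order, ready to pass
#' to [trainClassifier()].
#'
#' @param dataset a [SyntheticDataset-class].
#' @param groupsPerClass subgroups per class (default 2).
#' @param seed clustering seed.
#' @return a [MiningPlan-class].
#' @export
miningPlanForDataset <- function(dataset, groupsPerClass = 2L, seed = 1L) {
    stopifnot(is(dataset, "SyntheticDataset"))
    trIdx <- which(dataset@split == "train")
    feats <- if (length(dataset@images) > 0L)
        imageFeatures(dataset@images[trIdx, , , drop = FALSE])
    else dataset@embeddings[trIdx, , drop = FALSE]
    miningPlan(feats, dataset@classLabels[trIdx],
               groupsPerClass = groupsPerClass, seed = seed)
}

setMethod("show", "TrainHistory", function(object) {
    cat(sprintf(
        "TrainHistory: %s, %d epochs%s, final train %.4f / val %.4f\n",
        object@config@lossKind, object@epochs,
        if (object@stoppedEarly) " (early stop)" else "",
        utils::tail(object@trainLoss, 1L), utils::tail(object@valLoss, 1L)))
    cat(sprintf("test accuracy %.4f\n", object@metrics@acc))
})

#' Save a training run to a directory
#'
#' Writes `history.json` (per-epoch traces and config), `metrics.json`,
#' `confusion.csv`, `roc.csv` (one-vs-rest ROC points per class),
#' `pca.csv` (2-d PCA of the test embeddings with true labels) and
#' `scores.csv`.
#'
#' @param history a [TrainHistory-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
saveRun <- function(history, dir) {
    stopifnot(is(history, "TrainHistory"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- history@config
    jsonlite::write_json(
        list(loss_kind = cfg@lossKind, margin = cfg@margin,
             lambda = cfg@lambda, batch_size = cfg@batchSize,
             seed = cfg@seed, epochs = history@epochs,
             stopped_early = history@stoppedEarly,
             train_loss = history@trainLoss, val_loss = history@valLoss,
             train_bst = history@trainBst,
             learning_rate = history@learningRate),
        file.path(dir, "history.json"), auto_unbox = TRUE, digits = NA)
    writeMetrics(history@metrics, file.path(dir, "metrics.json"))
    utils::write.csv(history@metrics@counts,
                     file.path(dir, "confusion.csv"))
    C <- ncol(history@testScores)
    roc <- do.call(rbind, lapply(seq_len(C), function(j) {
        pos <- history@testLabels == (j - 1L)
        if (!any(pos) || all(pos)) return(NULL)
        cbind(class = j - 1L,
              rocCurve(history@testScores[, j], pos))
    }))
    utils::write.csv(roc, file.path(dir, "roc.csv"), row.names = FALSE)
    pc <- pcaProjection(history@testEmbeddings,
                        min(2L, ncol(history@testEmbeddings)))
    utils::write.csv(data.frame(pc1 = pc[, 1L],
                                pc2 = if (ncol(pc) > 1L) pc[, 2L] else 0,
                                label = history@testLabels),
                     file.path(dir, "pca.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(history@testScores),
                     file.path(dir, "scores.csv"), row.names = FALSE)
    invisible(dir)
}
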