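test_that("L2 normalization rescales rows and rejects degenerate ones", {
    expect_equal(as.numeric(l2Normalize(rbind(c(3, 4)))), c(0.6, 0.8))
    expect_equal(as.numeric(l2Normalize(rbind(c(1, 0, 0)))), c(1, 0, 0))
    expect_error(l2Normalize(rbind(c(1, 1), c(0, 0))), "row 2")
    # rescaling any row leaves the normalized batch unchanged
    X <- matrix(rnorm(12), 4, 3)
    Xs <- X; Xs[2, ] <- 7 * Xs[2, ]
    expect_equal(l2Normalize(X), l2Normalize(Xs))
})

test_that("similarity matrix holds all pairwise cosines with unit diagonal", {
    e1 <- c(1, 0); e2 <- c(0, 1)
    expect_equal(similarityMatrix(rbind(e1, e1)),
                 matrix(1, 2, 2), ignore_attr = TRUE)
    expect_equal(similarityMatrix(rbind(e1, e2)),
                 diag(2), ignore_attr = TRUE)
    expect_equal(similarityMatrix(rbind(e1, -e1)),
                 matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
    expect_error(similarityMatrix(rbind(c(2, 0))), "unit-norm")
})

test_that("binary pair matrix marks same-class pairs", {
    expect_equal(binaryPairMatrix(c(0, 0, 1), 2),
                 rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
                 ignore_attr = TRUE)
    expect_equal(binaryPairMatrix(rep(2, 4), 3), matrix(1, 4, 4),
                 ignore_attr = TRUE)
    expect_equal(binaryPairMatrix(0:3, 4), diag(4), ignore_attr = TRUE)
    expect_error(binaryPairMatrix(c(0, 5), 3), "invalid label")
    # equals the outer product of one-hot rows
    lab <- c(0L, 2L, 1L, 2L, 0L)
    oneHot <- diag(3)[lab + 1L, ]
    expect_equal(binaryPairMatrix(lab, 3), oneHot %*% t(oneHot),
                 ignore_attr = TRUE)
})

test_that("discriminative matrix signs pairs and zeroes the diagonal", {
    S <- matrix(1, 2, 2)
    D <- discriminativeMatrix(S, binaryPairMatrix(c(0, 0), 1))
    expect_equal(dmValues(D), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
    S2 <- rbind(c(1, 0.5), c(0.5, 1))
    D2 <- discriminativeMatrix(S2, binaryPairMatrix(c(0, 1), 2))
    expect_equal(dmValues(D2), rbind(c(0, -0.5), c(-0.5, 0)),
                 ignore_attr = TRUE)
    expect_error(discriminativeMatrix(matrix(0, 2, 2), matrix(0, 3, 3)),
                 "same shape")
    # matches elementwise evaluation of the expanded form on mixed batches
    for (seed in 1:5) {
        b <- randomBatch(6, 4, 3, seed)
        S <- similarityMatrix(l2Normalize(b$values))
        B <- binaryPairMatrix(b$labels, b$C)
        expect_equal(dmValues(discriminativeMatrix(S, B, b$labels)),
                     oracleDiscriminative(S, B), tolerance = 1e-15)
    }
})

test_that("per-sample loss reproduces hand-worked cases", {
    e1 <- c(1, 0); e2 <- c(0, 1)
    mk <- function(values, labels) {
        S <- similarityMatrix(l2Normalize(values))
        discriminativeMatrix(S, binaryPairMatrix(labels, max(labels) + 1),
                             labels)
    }
    # ideal clustering: positives identical, negatives orthogonal
    expect_equal(bstLossPerSample(mk(rbind(e1, e1, e2), c(0, 0, 1)), 1, 0.9),
                 0)
    # worst case attains the upper bound 1 + m
    expect_equal(bstLossPerSample(mk(rbind(e1, e2, e1), c(0, 0, 1)), 1, 0.9),
                 1.9)
    # mixed geometry: pos^2 = 0.36, neg^2 = 0 -> 0.9 - 0.36 = 0.54
    expect_equal(bstLossPerSample(
        mk(rbind(c(1, 0), c(0.6, 0.8), c(0, 1)), c(0, 0, 1)), 1, 0.9), 0.54)
    # a single-sample batch is the one unavailable case
    D1 <- new("DiscriminativeMatrix", values = matrix(0, 1, 1), labels = 0L)
    expect_error(bstLossPerSample(D1, 1, 0.9), "Nb = 1")
})

test_that("batch loss averages per-sample losses and matches the oracle", {
    # identical same-class pair: no negatives, fill 0 -> hinge inactive
    res <- bstLoss(rbind(c(1, 0), c(1, 0)), c(0, 0))
    expect_equal(res@batchMean, 0)
    # the 3-vector worked batch against the scalar-loop oracle
    X <- rbind(c(1, 0), c(0.6, 0.8), c(0, 1)); lab <- c(0, 0, 1)
    res <- bstLoss(X, lab)
    expect_equal(res@perSample, oracleBstBatch(X, lab), tolerance = 1e-12)
    expect_equal(res@batchMean, mean(oracleBstBatch(X, lab)),
                 tolerance = 1e-12)
    expect_error(bstLoss(rbind(c(1, 0)), 0), "Nb = 1")
})

test_that("matrix implementation equals the pair-loop oracle on random batches", {
    for (seed in 1:40) {
        nb <- 2 + (seed %% 7)
        b <- randomBatch(nb, 1 + (seed %% 5), min(4, 1 + seed %% 4 + 1),
                         seed = 1000 + seed)
        got <- bstLoss(b$values, b$labels)
        expect_equal(got@perSample, oracleBstBatch(b$values, b$labels),
                     tolerance = 1e-12)
    }
})

test_that("batch loss is permutation-equivariant and row-scale invariant", {
    b <- randomBatch(8, 5, 3, seed = 7)
    base <- bstLoss(b$values, b$labels)
    for (seed in 1:5) {
        perm <- withr::with_seed(seed, sample(8))
        permuted <- bstLoss(b$values[perm, ], b$labels[perm])
        expect_equal(permuted@perSample, base@perSample[perm],
                     tolerance = 1e-12)
        expect_equal(permuted@batchMean, base@batchMean, tolerance = 1e-12)
    }
    scaled <- b$values
    scaled[3, ] <- 100 * scaled[3, ]
    scaled[5, ] <- 1e-3 * scaled[5, ]
    expect_equal(bstLoss(scaled, b$labels)@perSample, base@perSample,
                 tolerance = 1e-9)
})

test_that("loss decreases with same-class similarity and increases with cross-class", {
    # anchor + one positive at controllable angle, plus one fixed negative
    lossAt <- function(posAngle, negAngle) {
        X <- rbind(c(1, 0),
                   c(cos(posAngle), sin(posAngle)),
                   c(cos(negAngle), sin(negAngle)))
        bstLossPerSample(discriminativeMatrix(
            similarityMatrix(l2Normalize(X)),
            binaryPairMatrix(c(0, 0, 1), 2), c(0, 0, 1)), 1, 0.9)
    }
    posAngles <- seq(0.1, pi / 2, length.out = 8)
    vals <- vapply(posAngles, lossAt, numeric(1), negAngle = pi / 2)
    expect_true(all(diff(vals) >= -1e-12))  # closer positive, lower loss
    negAngles <- seq(pi / 2, 0.1, length.out = 8)
    vals <- vapply(negAngles, lossAt, numeric(1), posAngle = 0.4)
    expect_true(all(diff(vals) >= -1e-12))  # closer negative, higher loss
})

test_that("missing-pair fills reduce the loss to the remaining constraint", {
    # all same class: no negatives anywhere
    res <- bstLoss(rbind(c(1, 0), c(1, 0), c(0.6, 0.8)), c(0, 0, 0))
    ora <- vapply(1:3, function(i)
        oracleBstPerSample(rbind(c(1, 0), c(1, 0), c(0.6, 0.8)),
                           c(0, 0, 0), i), numeric(1))
    expect_equal(res@perSample, ora)
    # all distinct classes: no positives anywhere; fill 1 means only the
    # cross-class term can activate the hinge
    resD <- bstLoss(diag(3), 0:2)
    expect_equal(resD@perSample, rep(0, 3) + pmax(0, 0.9 - 1 + 0))
    # non-default fills shift the inactive term
    resF <- bstLoss(diag(3), 0:2,
                    bstConfig(missingPositiveFill = 0))
    expect_equal(resF@perSample, rep(0.9, 3))
})

test_that("pairwise triplet loss follows max(0, 1 - sPos + sNeg)", {
    expect_equal(pairwiseTripletLoss(1, 0), 0)
    expect_equal(pairwiseTripletLoss(0, 1), 2)
    expect_equal(pairwiseTripletLoss(0.5, 0.2), 0.7)
    expect_error(pairwiseTripletLoss(1.5, 0), "\\[-1, 1\\]")
})

test_that("softmax is stable, normalized and shift-invariant", {
    expect_equal(softmaxProbs(c(0, 0, 0)), rep(1 / 3, 3))
    p <- softmaxProbs(c(1000, 0))
    expect_true(all(is.finite(p)))
    expect_equal(p[1], 1, tolerance = 1e-12)
    x <- rnorm(5)
    expect_equal(softmaxProbs(x), softmaxProbs(x + 123.4),
                 tolerance = 1e-12)
    m <- matrix(rnorm(12), 3, 4)
    expect_equal(rowSums(softmaxProbs(m)), rep(1, 3), tolerance = 1e-12)
    expect_error(softmaxProbs(c(1, NA)), "finite")
})

test_that("cross entropy matches closed forms and validates its input", {
    perfect <- diag(3)[c(1, 2, 3), ]
    expect_equal(crossEntropyLoss(perfect, 0:2), 0)
    expect_equal(crossEntropyLoss(matrix(1 / 3, 4, 3),
                                  c(0, 1, 2, 0)), log(3))
    expect_equal(crossEntropyLoss(rbind(c(0.5, 0.5)), 0), log(2))
    expect_error(crossEntropyLoss(rbind(c(0.7, 0.6)), 0), "sum to 1")
})

test_that("combined loss adds the weighted triplet term to cross entropy", {
    X <- rbind(c(1, 0), c(0.6, 0.8), c(0, 1)); lab <- c(0, 0, 1)
    logits <- rbind(c(2, 0), c(1.5, 0.2), c(0, 2))
    ce <- crossEntropyLoss(softmaxProbs(logits), lab)
    bst <- bstLoss(X, lab)@batchMean
    out <- combinedLoss(X, logits, lab)
    expect_equal(out$total, ce + bst)
    out0 <- combinedLoss(X, logits, lab, bstConfig(lambda = 0))
    expect_equal(out0$total, ce)
    # zero-triplet batch: combined equals cross entropy at lambda = 1
    Xz <- rbind(c(1, 0), c(1, 0), c(0, 1)); labz <- c(0, 0, 1)
    expect_equal(combinedLoss(Xz, logits, labz)$total,
                 crossEntropyLoss(softmaxProbs(logits), labz))
})

test_that("EmbeddingBatch validates labels and round-trips through CSV", {
    eb <- EmbeddingBatch(rbind(c(1, 0), c(0, 1)), c(0, 1))
    expect_equal(nSamples(eb), 2L)
    expect_equal(embeddingDim(eb), 2L)
    expect_equal(nClasses(eb), 2L)
    expect_error(EmbeddingBatch(rbind(c(1, 0)), 2, nClasses = 2),
                 "\\[0, 1\\]")
    expect_error(EmbeddingBatch(rbind(c(1, NA)), 0), "finite")
    vf <- tempfile(fileext = ".csv"); lf <- tempfile(fileext = ".csv")
    write.table(rbind(c(1, 0), c(0.6, 0.8)), vf, sep = ",",
                row.names = FALSE, col.names = FALSE)
    write.table(c(1, 2), lf, row.names = FALSE, col.names = FALSE)
    eb2 <- readEmbeddingBatch(vf, lf, oneBased = TRUE)
    expect_equal(sampleLabels(eb2), c(0L, 1L))
    expect_equal(embeddingMatrix(eb2)[2, ], c(0.6, 0.8))
    # loss result serialization keeps full precision
    res <- bstLoss(eb2)
    out <- tempfile(fileext = ".json")
    writeLossResult(res, out)
    back <- jsonlite::read_json(out, simplifyVector = TRUE)
    expect_equal(back$batch_mean, res@batchMean)
})
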