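test_that("confusion matrix counts true/predicted pairs", {
    expect_equal(confusionMatrix(c(0, 0, 1), c(0, 1, 1), 2),
                 rbind(c(1, 1), c(0, 1)), ignore_attr = TRUE)
    perfect <- confusionMatrix(c(0, 1, 2, 1), c(0, 1, 2, 1), 3)
    expect_equal(diag(perfect), c(1, 2, 1), ignore_attr = TRUE)
    expect_equal(sum(perfect) - sum(diag(perfect)), 0)
    expect_error(confusionMatrix(integer(0), integer(0)), "empty")
    expect_error(confusionMatrix(c(0, 1), c(0)), "equal length")
})

test_that("accuracy is the fraction of the diagonal", {
    # two-class counts reconstructed from published per-class rates at
    # test sizes 390/234: (370 + 198) / 624
    cm <- rbind(c(370, 20), c(36, 198))
    expect_equal(round(100 * accuracy(cm), 2), 91.03)
    expect_equal(accuracy(diag(5) * 7), 1)
    expect_equal(accuracy(rbind(c(0, 3), c(4, 0))), 0)
})

test_that("one-vs-rest sensitivity and specificity match hand reductions", {
    # reconstructed two-class counts at test sizes 36/51:
    # TP = 28 of 36 -> SEN 77.78%, TN = 42 of 51 -> SPE 82.35%
    cm <- rbind(c(42, 9), c(8, 28))
    ss <- sensitivitySpecificity(cm)
    expect_equal(round(100 * ss$senPerClass[2], 2), 77.78)
    expect_equal(round(100 * ss$spePerClass[2], 2), 82.35)
    # binary symmetry: SEN of one class is SPE of the other
    expect_equal(ss$senPerClass[1], ss$spePerClass[2])
    expect_equal(ss$senPerClass[2], ss$spePerClass[1])
    perfect <- diag(c(5, 6, 7))
    ssp <- sensitivitySpecificity(perfect)
    expect_equal(ssp$senMean, 1)
    expect_equal(ssp$speMean, 1)
    # undefined rows are flagged and excluded from the mean
    cmNA <- rbind(c(2, 0, 0), c(1, 3, 0), c(0, 0, 0))
    expect_warning(ssNA <- sensitivitySpecificity(cmNA), "no true members")
    expect_true(is.na(ssNA$senPerClass[3]))
    expect_equal(ssNA$senMean, mean(ssNA$senPerClass[1:2]))
})

test_that("matrix metrics equal a naive per-sample loop on random labelings", {
    withr::with_seed(17, {
        for (rep in 1:100) {
            C <- sample(2:4, 1); n <- sample(10:40, 1)
            yt <- sample.int(C, n, replace = TRUE) - 1L
            yp <- sample.int(C, n, replace = TRUE) - 1L
            cm <- confusionMatrix(yt, yp, C)
            expect_equal(accuracy(cm), mean(yt == yp))
            present <- sort(unique(yt))
            if (length(present) < C) next
            ss <- sensitivitySpecificity(cm)
            senLoop <- vapply(0:(C - 1), function(cl)
                sum(yp == cl & yt == cl) / sum(yt == cl), numeric(1))
            speLoop <- vapply(0:(C - 1), function(cl)
                sum(yp != cl & yt != cl) / sum(yt != cl), numeric(1))
            expect_equal(ss$senPerClass, senLoop)
            expect_equal(ss$spePerClass, speLoop)
        }
    })
})

test_that("AUC matches pair counting, pROC, and the midrank tie convention", {
    # perfectly separated scores
    expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
    # all-tied scores sit at chance under midranks
    expect_equal(rocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
    # six-sample toy with one inversion equals U / (n1 n0)
    score <- c(0.9, 0.8, 0.35, 0.4, 0.2, 0.1)
    truth <- c(1, 1, 1, 0, 0, 0)
    expect_equal(rocAuc(score, truth)$auc,
                 oraclePairCountAuc(score, truth == 1))
    # random scores against both oracles
    withr::with_seed(23, {
        for (rep in 1:20) {
            n <- sample(8:30, 1)
            sc <- round(runif(n), 2)  # rounding forces ties
            yt <- sample(0:1, n, replace = TRUE)
            if (length(unique(yt)) < 2) next
            ours <- rocAuc(sc, yt)$auc
            expect_equal(ours, oraclePairCountAuc(sc, yt == 1))
            expect_equal(ours,
                         as.numeric(suppressMessages(
                             pROC::auc(yt, sc, direction = "<"))))
        }
    })
    expect_error(rocAuc(c(0.1, 0.9), c(1, 1)), "single class")
})

test_that("AUC is invariant to strictly increasing score transforms", {
    withr::with_seed(31, {
        sc <- runif(20); yt <- sample(0:1, 20, replace = TRUE)
        base <- rocAuc(sc, yt)$auc
        expect_equal(rocAuc(exp(3 * sc), yt)$auc, base)
        expect_equal(rocAuc(rank(sc), yt)$auc, base)
    })
})

test_that("multiclass AUC macro-averages one-vs-rest columns", {
    withr::with_seed(37, {
        probs <- softmaxProbs(matrix(rnorm(60), 20, 3))
        yt <- sample(0:2, 20, replace = TRUE)
        r <- rocAuc(probs, yt)
        per <- vapply(1:3, function(j)
            oraclePairCountAuc(probs[, j], yt == (j - 1)), numeric(1))
        expect_equal(r$perClass, per)
        expect_equal(r$auc, mean(per))
    })
})

test_that("ROC curve starts at the origin and ends at (1, 1)", {
    sc <- c(0.9, 0.7, 0.7, 0.3, 0.2)
    pos <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
    rc <- rocCurve(sc, pos)
    expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1)
    expect_equal(rc$tpr[nrow(rc)], 1)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("PCA projection preserves 2-d geometry and orders variance", {
    withr::with_seed(41, {
        X <- matrix(rnorm(40), 20, 2) %*% rbind(c(2, 0.5), c(0, 1))
        P <- pcaProjection(X, 2)
        expect_equal(as.numeric(dist(P)), as.numeric(dist(X)),
                     tolerance = 1e-9)
        expect_gte(var(P[, 1]), var(P[, 2]))
        # collinear points have a vanishing second component
        line <- cbind(1:10, 2 * (1:10) + 3)
        P2 <- pcaProjection(line, 2)
        expect_lt(max(abs(P2[, 2])), 1e-9)
        expect_error(pcaProjection(X, 5), "outDim")
        # deterministic sign convention
        expect_equal(pcaProjection(X, 2), pcaProjection(X, 2))
    })
})

test_that("clustering gap separates tight orthogonal classes from noise", {
    X <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
    expect_equal(clusteringGap(X, c(0, 0, 1, 1)), 1)
    expect_equal(clusteringGap(matrix(1, 4, 3), c(0, 0, 1, 1)), 0)
    expect_error(clusteringGap(X, rep(0, 4)), "two classes")
    # permutation null: shuffled labels give near-zero expected gap
    withr::with_seed(43, {
        emb <- matrix(rnorm(200), 40, 5)
        lab <- rep(0:1, each = 20)
        gaps <- replicate(1000, clusteringGap(emb, sample(lab)))
        expect_lt(abs(mean(gaps)), 0.02)
    })
})

test_that("classMetrics bundles counts, rates and AUC consistently", {
    withr::with_seed(47, {
        probs <- softmaxProbs(matrix(rnorm(90), 30, 3))
        yt <- sample(0:2, 30, replace = TRUE)
        m <- classMetrics(yt, scores = probs)
        expect_equal(m@acc, accuracy(m@counts))
        expect_equal(m@senMean, mean(m@senPerClass))
        expect_equal(m@auc, rocAuc(probs, yt)$auc)
        out <- tempfile(fileext = ".json")
        writeMetrics(m, out)
        back <- jsonlite::read_json(out, simplifyVector = TRUE)
        expect_equal(back$acc, m@acc)
        expect_equal(back$sen_per_class, m@senPerClass)
    })
})
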