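# trainer tests use a deliberately small dataset so each run takes seconds
smallImageSet <- function(seed = 1) {
    makeSyntheticImages(c(40, 40), groupsPerClass = 2, size = 16,
                        noise = 0.05, seed = seed)
}

test_that("training runs to completion and records consistent traces", {
    ds <- smallImageSet()
    cfg <- trainConfig(lossKind = "ce+bst", batchSize = 12, maxEpochs = 5,
                       seed = 1)
    h <- trainClassifier(ds, cfg)
    expect_lte(h@epochs, 5L)
    expect_length(h@trainLoss, h@epochs)
    expect_length(h@valLoss, h@epochs)
    expect_true(all(h@trainLoss >= 0))
    # the triplet component is bounded by 1 + m at every logged step
    expect_true(all(h@trainBst <= 1 + cfg@margin + 1e-9))
    # learning-rate trace never increases and respects the floor
    expect_true(all(diff(h@learningRate) <= 0))
    expect_true(all(h@learningRate >= cfg@minLr))
    expect_equal(dim(h@testScores), c(sum(ds@split == "test"), 2L))
})

test_that("identical config and seed reproduce the run exactly", {
    ds <- smallImageSet()
    cfg <- trainConfig(lossKind = "ce+bst", batchSize = 12, maxEpochs = 3,
                       seed = 11)
    h1 <- trainClassifier(ds, cfg)
    h2 <- trainClassifier(ds, cfg)
    expect_identical(h1@trainLoss, h2@trainLoss)
    expect_identical(h1@testScores, h2@testScores)
    h3 <- trainClassifier(ds, trainConfig(lossKind = "ce+bst",
                                          batchSize = 12, maxEpochs = 3,
                                          seed = 12))
    expect_false(identical(h1@trainLoss, h3@trainLoss))
})

test_that("learning rate drops by the plateau factor after the patience window", {
    ds <- smallImageSet()
    # an lrMinDelta so large that no epoch ever counts as an improvement:
    # the plateau rule must fire exactly every lrPatience epochs
    cfg <- trainConfig(lossKind = "ce", batchSize = 12, maxEpochs = 5,
                       lrPatience = 2L, lrMinDelta = 1e6,
                       earlyStopPatience = 50L, seed = 2)
    h <- trainClassifier(ds, cfg)
    expect_equal(h@learningRate,
                 0.001 * c(1, 1, 1, 0.3, 0.3))
})

test_that("early stopping halts after the configured patience", {
    ds <- smallImageSet()
    # learning rate ~0 freezes the network, so the validation loss cannot
    # improve and the early-stop counter runs straight through
    cfg <- trainConfig(lossKind = "ce", batchSize = 12, maxEpochs = 50,
                       initLr = 1e-12, earlyStopPatience = 4L, seed = 3)
    h <- trainClassifier(ds, cfg)
    expect_true(h@stoppedEarly)
    # first epoch sets the baseline; the next four fail to improve
    expect_equal(h@epochs, 5L)
})

test_that("triplet losses refuse a batch size of one", {
    expect_error(trainConfig(lossKind = "ce+bst", batchSize = 1L),
                 "Nb = 1")
    expect_error(trainConfig(lossKind = "ce+triplet", batchSize = 1L),
                 "Nb = 1")
    cfgOk <- trainConfig(lossKind = "ce", batchSize = 1L)
    expect_s4_class(cfgOk, "TrainConfig")
})

test_that("all three objectives train and the combined ones use their term", {
    ds <- smallImageSet()
    for (kind in c("ce", "ce+triplet", "ce+bst")) {
        h <- trainClassifier(ds, trainConfig(lossKind = kind,
                                             batchSize = 12,
                                             maxEpochs = 2, seed = 5))
        expect_equal(h@epochs, 2L)
        if (kind == "ce") expect_equal(h@trainBst, rep(0, 2))
    }
})

test_that("mined batches follow the plan quotas during training", {
    ds <- smallImageSet()
    plan <- miningPlanForDataset(ds, groupsPerClass = 2, seed = 1)
    expect_equal(plan@nGroups, 4L)
    cfg <- trainConfig(lossKind = "ce+bst", batchSize = 12, maxEpochs = 2,
                       seed = 6)
    h <- trainClassifier(ds, cfg, plan = plan)
    expect_equal(h@epochs, 2L)
    # plan must match the training subset
    badPlan <- miningPlan(matrix(rnorm(20), 10, 2), rep(0:1, 5), 1)
    expect_error(trainClassifier(ds, cfg, plan = badPlan),
                 "training-subset")
})

test_that("mined batches balance class proportions better than random ones", {
    ds <- smallImageSet(seed = 21)
    trIdx <- which(ds@split == "train")
    plan <- miningPlanForDataset(ds, groupsPerClass = 2, seed = 1)
    quotas <- batchQuotas(plan, 12L)@quotaOfGroup
    labels <- ds@classLabels[trIdx]
    withr::with_seed(31, {
        share <- function(idx) mean(labels[idx] == 0)
        dm <- replicate(200, {
            idx <- unlist(lapply(seq_len(plan@nGroups), function(g) {
                members <- which(plan@groupOfSample == g)
                sample(members, quotas[g])
            }))
            share(idx)
        })
        rs <- replicate(200, share(sample(length(labels), 12)))
        expect_lt(var(dm), var(rs))
    })
})

test_that("training history serializes to a run directory", {
    ds <- smallImageSet()
    h <- trainClassifier(ds, trainConfig(lossKind = "ce+bst",
                                         batchSize = 12, maxEpochs = 2,
                                         seed = 7))
    dir <- tempfile("run")
    saveRun(h, dir)
    for (f in c("history.json", "metrics.json", "confusion.csv",
                "roc.csv", "pca.csv", "scores.csv"))
        expect_true(file.exists(file.path(dir, f)))
    hist <- jsonlite::read_json(file.path(dir, "history.json"),
                                simplifyVector = TRUE)
    expect_equal(hist$epochs, 2L)
    expect_equal(hist$train_loss, h@trainLoss)
})

test_that("config files round-trip through YAML", {
    path <- tempfile(fileext = ".yaml")
    writeLines(c("lossKind: ce+triplet", "margin: 0.8", "batchSize: 24",
                 "maxEpochs: 10"), path)
    cfg <- trainConfigFromFile(path)
    expect_equal(cfg@lossKind, "ce+triplet")
    expect_equal(cfg@margin, 0.8)
    expect_equal(cfg@batchSize, 24L)
    expect_equal(cfg@maxEpochs, 10L)
    expect_equal(cfg@initLr, 0.001)  # untouched default
    writeLines("nonsense: 1", path)
    expect_error(trainConfigFromFile(path), "unknown config keys")
})

test_that("clustering gap is high for trained-like embeddings, zero at chance", {
    d0 <- makeBlobEmbeddings(2, 1, 10, 8, spread = 0, seed = 2,
                             groupSpread = 0)
    expect_equal(clusteringGap(d0@embeddings, d0@classLabels), 1)
})
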