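#' @importFrom methods setClass setValidity new validObject is slot show
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' EmbeddingBatch: a batch of embedding vectors with class labels
#'
#' An `EmbeddingBatch` holds the raw (not yet normalized) embedding vectors a
#' network produced for one batch of `Nb` samples, together with the integer
#' class label of each sample.  It extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' the single assay `"embeddings"` stores the vectors as an `l x Nb` matrix
#' (features in rows, samples in columns, following the container's
#' convention), the `colData` column `label` stores 0-based class labels, and
#' `metadata(x)$nClasses` records the number of classes `C`.
#'
#' Labels are 0-based throughout the package; 1-based labels in input files
#' are converted at the I/O boundary.
#'
#' @seealso [EmbeddingBatch()] for construction, [embeddingMatrix()],
#'   [sampleLabels()], [nClasses()] for access, [bstLoss()] for the loss.
#' @name EmbeddingBatch-class
#' @exportClass EmbeddingBatch
setClass("EmbeddingBatch", contains = "SummarizedExperiment")

setValidity("EmbeddingBatch", function(object) {
    msg <- character()
    anm <- SummarizedExperiment::assayNames(object)
    if (!identical(anm, "embeddings"))
        msg <- c(msg, "assays must be a single matrix named 'embeddings'")
    if (nrow(object) < 1L || ncol(object) < 1L)
        msg <- c(msg, "need at least one sample and one embedding dimension")
    if (length(msg) == 0L) {
        vals <- SummarizedExperiment::assay(object, "embeddings")
        if (!is.numeric(vals) || !all(is.finite(vals)))
            msg <- c(msg, "all embedding values must be finite numbers")
        cd <- SummarizedExperiment::colData(object)
        if (!("label" %in% colnames(cd))) {
            msg <- c(msg, "colData must contain a 'label' column")
        } else {
            lab <- cd$label
            C <- S4Vectors::metadata(object)$nClasses
            if (is.null(C) || length(C) != 1L || is.na(C) || C < 1L)
                msg <- c(msg, "metadata$nClasses must be a single integer >= 1")
            else if (any(lab < 0L) || any(lab >= C))
                msg <- c(msg, sprintf(
                    "labels must be 0-based class indices in [0, %d]", C - 1L))
        }
    }
    if (length(msg)) msg else TRUE
})

#' DiscriminativeMatrix: signed batch similarity matrix
#'
#' The working structure of the BSTriplet loss: the cosine-similarity matrix
#' S of a batch with same-class entries kept positive, different-class
#' entries negated, and the diagonal zeroed (elementwise
#' `S * (2B - 1 - I)` with B the binary same-class pair matrix).  Carries the
#' label vector used to build it so per-sample positive/negative partners can
#' be recovered.
#'
#' @slot values numeric `Nb x Nb` matrix, zero diagonal, symmetric.
#' @slot labels integer vector of length `Nb`, 0-based class labels.
#' @seealso [discriminativeMatrix()], [bstLossPerSample()]
#' @exportClass DiscriminativeMatrix
setClass("DiscriminativeMatrix",
    representation(values = "matrix", labels = "integer"))

setValidity("DiscriminativeMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (length(object@labels) != nrow(v))
        msg <- c(msg, "labels length must equal matrix order")
    if (nrow(v) > 0L) {
        if (any(abs(diag(v)) > 0))
            msg <- c(msg, "diagonal must be exactly zero")
        if (max(abs(v - t(v))) > 1e-9)
            msg <- c(msg, "matrix must be symmetric (tolerance 1e-9)")
    }
    if (length(msg)) msg else TRUE
})

#' BSTConfig: parameters of the BSTriplet / combined objective
#'
#' @slot margin hinge margin m in \[0, 1\]; controls how strictly same-class
#'   squared similarities must exceed cross-class ones (default 0.9 — the
#'   margin should sit near 1, but exactly 1 would demand identical
#'   embeddings within a class).
#' @slot lambda nonnegative trade-off weight of the triplet term in the
#'   combined loss (default 1).
#' @slot missingPositiveFill value substituted for the positive-pair mean when
#'   a sample has no same-class partner in the batch (default 1, the ideal
#'   value, so the loss reduces to the remaining constraint with no bias).
#' @slot missingNegativeFill value substituted for the negative-pair mean when
#'   a sample has no different-class partner (default 0).
#' @seealso [bstConfig()]
#' @exportClass BSTConfig
setClass("BSTConfig", representation(
    margin = "numeric", lambda = "numeric",
    missingPositiveFill = "numeric", missingNegativeFill = "numeric"))

setValidity("BSTConfig", function(object) {
    msg <- character()
    m <- object@margin
    if (length(m) != 1L || is.na(m) || m < 0 || m > 1)
        msg <- c(msg, "margin must be a single value in [0, 1]")
    if (length(object@lambda) != 1L || is.na(object@lambda) ||
        object@lambda < 0)
        msg <- c(msg, "lambda must be a single nonnegative value")
    if (length(object@missingPositiveFill) != 1L ||
        length(object@missingNegativeFill) != 1L)
        msg <- c(msg, "fill values must be single numbers")
    if (length(msg)) msg else TRUE
})

#' BSTLossResult: per-sample and batch BSTriplet loss values
#'
#' @slot perSample nonnegative per-sample hinge losses, length `Nb`; each
#'   value lies in \[0, 1 + m\].
#' @slot batchMean mean of `perSample`.
#' @slot gradient `Nb x l` matrix d(batchMean)/d(raw embeddings), or a 0x0
#'   matrix when the gradient was not requested.
#' @slot margin,lambda the configuration the loss was evaluated under.
#' @seealso [bstLoss()], [writeLossResult()]
#' @exportClass BSTLossResult
setClass("BSTLossResult", representation(
    perSample = "numeric", batchMean = "numeric", gradient = "matrix",
    margin = "numeric", lambda = "numeric"))

setValidity("BSTLossResult", function(object) {
    msg <- character()
    if (any(object@perSample < 0))
        msg <- c(msg, "per-sample losses must be nonnegative")
    if (length(object@batchMean) != 1L)
        msg <- c(msg, "batchMean must be a single value")
    else if (length(object@perSample) &&
             abs(object@batchMean - mean(object@perSample)) > 1e-12)
        msg <- c(msg, "batchMean must equal mean(perSample) within 1e-12")
    if (length(msg)) msg else TRUE
})

#' MiningPlan: per-class subgroup structure of a training set
#'
#' Result of the batch-mining setup: every training sample is assigned to one
#' subgroup (obtained by clustering within its class), and each subgroup
#' carries its share of the training set.  Batch quotas are derived from the
#' shares so that mined batches mirror the training distribution.
#'
#' @slot groupOfSample integer vector, 1-based global group id per sample.
#' @slot classOfGroup integer vector mapping group id to 0-based class label.
#' @slot ratioOfGroup numeric vector of group shares; nonnegative, sums to 1.
#' @slot nGroups total number of groups g.
#' @seealso [miningPlan()], [batchQuotas()], [sampleBatch()]
#' @exportClass MiningPlan
setClass("MiningPlan", representation(
    groupOfSample = "integer", classOfGroup = "integer",
    ratioOfGroup = "numeric", nGroups = "integer"))

setValidity("MiningPlan", function(object) {
    msg <- character()
    g <- object@nGroups
    if (length(object@classOfGroup) != g || length(object@ratioOfGroup) != g)
        msg <- c(msg, "classOfGroup and ratioOfGroup must have length nGroups")
    if (any(object@ratioOfGroup < 0))
        msg <- c(msg, "group ratios must be nonnegative")
    if (abs(sum(object@ratioOfGroup) - 1) > 1e-9)
        msg <- c(msg, "group ratios must sum to 1 within 1e-9")
    if (length(object@groupOfSample) &&
        (min(object@groupOfSample) < 1L || max(object@groupOfSample) > g))
        msg <- c(msg, "group ids must lie in 1..nGroups")
    if (length(msg)) msg else TRUE
})

#' BatchSpec: per-group sample quotas for one mined batch
#'
#' @slot quotaOfGroup nonnegative integer quota per group; sums to `batchSize`.
#' @slot batchSize the batch size Nb.
#' @seealso [batchQuotas()], [sampleBatch()]
#' @exportClass BatchSpec
setClass("BatchSpec", representation(
    quotaOfGroup = "integer", batchSize = "integer"))

setValidity("BatchSpec", function(object) {
    msg <- character()
    if (any(object@quotaOfGroup < 0L))
        msg <- c(msg, "quotas must be nonnegative")
    if (sum(object@quotaOfGroup) != object@batchSize)
        msg <- c(msg, "quotas must sum to batchSize")
    if (length(msg)) msg else TRUE
})

#' FlopEstimate: itemized floating-point operation count
#'
#' @slot total total FLOPs (stored as numeric to allow counts beyond the
#'   integer range; always a whole number).
#' @slot breakdown named numeric vector of per-step costs; sums to `total`.
#' @seealso [bstFlops()], [miningSetupFlops()]
#' @exportClass FlopEstimate
setClass("FlopEstimate", representation(
    total = "numeric", breakdown = "numeric"))

setValidity("FlopEstimate", function(object) {
    msg <- character()
    if (object@total < 0) msg <- c(msg, "total must be nonnegative")
    if (abs(sum(object@breakdown) - object@total) > 0)
        msg <- c(msg, "breakdown must sum exactly to total")
    if (length(msg)) msg else TRUE
})

#' ClassMetrics: classification performance report
#'
#' Holds the confusion matrix of a classifier together with derived metrics:
#' fraction-correct accuracy, one-vs-rest per-class sensitivity and
#' specificity with their macro means, and (when scores are available)
#' per-class one-vs-rest AUC with its macro mean.
#'
#' @slot counts `C x C` confusion counts, rows = true class, cols = predicted.
#' @slot acc fraction correct in \[0, 1\].
#' @slot senPerClass,spePerClass per-class one-vs-rest rates (may contain NA
#'   when a class has no true members / no true non-members).
#' @slot senMean,speMean macro means over defined classes.
#' @slot aucPerClass per-class one-vs-rest AUC (length 0 when unavailable).
#' @slot auc macro-average AUC (NA when unavailable).
#' @seealso [classMetrics()], [confusionMatrix()], [rocAuc()]
#' @exportClass ClassMetrics
setClass("ClassMetrics", representation(
    counts = "matrix", acc = "numeric",
    senPerClass = "numeric", spePerClass = "numeric",
    senMean = "numeric", speMean = "numeric",
    aucPerClass = "numeric", auc = "numeric"))

#' SyntheticDataset: generated embeddings or images with known structure
#'
#' Synthetic data with known class labels *and* known within-class subgroup
#' labels, so both the loss (which sees classes) and the mining strategy
#' (which must rediscover subgroups) can be tested without external data.
#' Exactly one of `embeddings` (`n x l` matrix) or `images`
#' (`n x H x W` array, grayscale in \[0, 1\]) is populated.
#'
#' @slot embeddings numeric matrix (0x0 when the dataset holds images).
#' @slot images numeric 3-d array (dim `c(0,0,0)` when the dataset holds
#'   embeddings).
#' @slot classLabels 0-based class label per item.
#' @slot groupLabels 1-based true subgroup id per item (global across classes;
#'   subgroups nest within classes).
#' @slot split factor with levels train/validation/test, one entry per item.
#' @slot seed the seed the generator was called with.
#' @seealso [makeBlobEmbeddings()], [makeSyntheticImages()],
#'   [syntheticPreset()]
#' @exportClass SyntheticDataset
setClass("SyntheticDataset", representation(
    embeddings = "matrix", images = "array",
    classLabels = "integer", groupLabels = "integer",
    split = "factor", seed = "integer"))

setValidity("SyntheticDataset", function(object) {
    msg <- character()
    n <- length(object@classLabels)
    hasEmb <- nrow(object@embeddings) > 0L
    hasImg <- length(object@images) > 0L
    if (hasEmb == hasImg)
        msg <- c(msg, "exactly one of embeddings or images must be populated")
    nItems <- if (hasEmb) nrow(object@embeddings) else dim(object@images)[1L]
    if (!hasEmb && !hasImg) nItems <- 0L
    if (n != nItems || length(object@groupLabels) != n ||
        length(object@split) != n)
        msg <- c(msg, "labels, groups and split must match the item count")
    if (!all(levels(object@split) %in% c("train", "validation", "test")))
        msg <- c(msg, "split levels must be train/validation/test")
    # subgroups must nest within classes
    if (n > 0L) {
        byGroup <- split(object@classLabels, object@groupLabels)
        if (any(vapply(byGroup, function(z) length(unique(z)), 1L) > 1L))
            msg <- c(msg, "each subgroup must belong to a single class")
    }
    if (length(msg)) msg else TRUE
})

#' TrainConfig: training-harness hyperparameters
#'
#' Defaults follow the training protocol used throughout the package's
#' experiments: initial learning rate 0.001, multiplied by 0.3 when the
#' training loss has not improved by more than `lrMinDelta` for
#' `lrPatience` consecutive epochs, floored at `minLr` 1e-8; at most
#' `maxEpochs` 400 epochs with early stopping once the validation loss has
#' failed to improve by `earlyStopMinDelta` 1e-4 for `earlyStopPatience` 30
#' consecutive epochs; batch size Nb = 36; combined-loss weight lambda = 1.
#'
#' @slot lossKind one of `"ce"`, `"ce+triplet"`, `"ce+bst"`.
#' @slot margin,lambda BSTriplet parameters (see [bstConfig()]).
#' @slot batchSize batch size Nb (>= 2 for the triplet losses).
#' @slot initLr,lrFactor,lrPatience,lrMinDelta,minLr learning-rate schedule.
#' @slot maxEpochs,earlyStopPatience,earlyStopMinDelta stopping rules.
#' @slot seed integer seed controlling initialization and all sampling.
#' @slot embeddingDim length l of the embedding the built-in network produces.
#' @seealso [trainConfig()], [trainClassifier()]
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
    lossKind = "character", margin = "numeric", lambda = "numeric",
    batchSize = "integer", initLr = "numeric", lrFactor = "numeric",
    lrPatience = "integer", lrMinDelta = "numeric", minLr = "numeric",
    maxEpochs = "integer", earlyStopPatience = "integer",
    earlyStopMinDelta = "numeric", seed = "integer",
    embeddingDim = "integer"))

setValidity("TrainConfig", function(object) {
    msg <- character()
    if (!object@lossKind %in% c("ce", "ce+triplet", "ce+bst"))
        msg <- c(msg, "lossKind must be 'ce', 'ce+triplet' or 'ce+bst'")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@lossKind != "ce" && object@batchSize < 2L)
        msg <- c(msg, "triplet losses need batchSize >= 2 (Nb = 1 is the one unavailable case)")
    if (object@initLr <= 0 || object@minLr <= 0 ||
        object@lrFactor <= 0 || object@lrFactor >= 1)
        msg <- c(msg, "learning-rate parameters out of range")
    if (length(msg)) msg else TRUE
})

#' TrainHistory: record of one training run
#'
#' @slot epochs number of epochs actually run.
#' @slot trainLoss,valLoss,learningRate per-epoch traces (learning rate is
#'   non-increasing and never below the configured floor).
#' @slot trainBst per-epoch mean triplet-loss component (all zero for plain
#'   cross-entropy training).
#' @slot stoppedEarly whether the early-stopping rule fired.
#' @slot metrics final test-set [ClassMetrics-class].
#' @slot testScores test-set predicted probability matrix.
#' @slot testLabels 0-based true test labels.
#' @slot testEmbeddings final-model embeddings of the test set.
#' @slot config the [TrainConfig-class] used.
#' @seealso [trainClassifier()], [saveRun()]
#' @exportClass TrainHistory
setClass("TrainHistory", representation(
    epochs = "integer", trainLoss = "numeric", valLoss = "numeric",
    trainBst = "numeric", learningRate = "numeric", stoppedEarly = "logical",
    metrics = "ClassMetrics", testScores = "matrix", testLabels = "integer",
    testEmbeddings = "matrix", config = "TrainConfig"))
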