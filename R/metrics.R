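#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns).
#'
#' @param yTrue,yPred 0-based label vectors of equal, nonzero length.
#' @param nClasses number of classes C; defaults to the largest observed
#'   label + 1.
#' @return `C x C` integer matrix with dimnames `"0" ... "C-1"`.
#' @examples
#' confusionMatrix(c(0, 0, 1), c(0, 1, 1), 2)
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses = NULL) {
    yTrue <- .asLabels(yTrue); yPred <- .asLabels(yPred)
    if (length(yTrue) == 0L) stop("empty input: no samples to tabulate")
    if (length(yTrue) != length(yPred))
        stop("yTrue and yPred must have equal length")
    if (is.null(nClasses)) nClasses <- max(yTrue, yPred) + 1L
    nClasses <- as.integer(nClasses)
    .checkLabels(yTrue, nClasses); .checkLabels(yPred, nClasses)
    counts <- matrix(tabulate(yTrue * nClasses + yPred + 1L,
                              nClasses * nClasses),
                     nClasses, nClasses, byrow = TRUE)
    dimnames(counts) <- rep(list(as.character(seq_len(nClasses) - 1L)), 2L)
    counts
}

#' Classification accuracy (fraction correct)
#'
#' `sum(diag(cm)) / N`, the fraction of correctly classified samples.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
    cm <- as.matrix(cm)
    n <- sum(cm)
    if (n == 0) stop("confusion matrix is empty")
    sum(diag(cm)) / n
}

#' One-vs-rest sensitivity and specificity
#'
#' For each class i taken as positive against the rest:
#' `SEN_i = TP_i / (TP_i + FN_i)` and `SPE_i = TN_i / (TN_i + FP_i)`, with
#' `TP_i` the diagonal entry, `FN_i` the rest of row i, `FP_i` the rest of
#' column i, and `TN_i` the remainder.  A class with no true members (SEN)
#' or no true non-members (SPE) yields `NA` with a warning, and is excluded
#' from the corresponding macro mean.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @return list with `senPerClass`, `spePerClass`, `senMean`, `speMean`.
#' @export
sensitivitySpecificity <- function(cm) {
    cm <- as.matrix(cm)
    n <- sum(cm)
    tp <- diag(cm)
    fn <- rowSums(cm) - tp
    fp <- colSums(cm) - tp
    tn <- n - tp - fn - fp
    sen <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
    spe <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
    if (anyNA(sen))
        warning("sensitivity undefined for classes with no true members; excluded from the mean")
    if (anyNA(spe))
        warning("specificity undefined for classes with no true non-members; excluded from the mean")
    list(senPerClass = as.numeric(sen), spePerClass = as.numeric(spe),
         senMean = mean(sen, na.rm = TRUE), speMean = mean(spe, na.rm = TRUE))
}

## midrank (Mann-Whitney) AUC of a score vector against a binary truth
.binaryAuc <- function(score, positive) {
    n1 <- sum(positive); n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L)
        stop("AUC undefined: truth contains a single class")
    r <- rank(score)  # midranks handle ties
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC (binary or macro one-vs-rest)
#'
#' Binary truth: trapezoidal/Mann-Whitney AUC of the positive-class score
#' with the midrank tie convention (equivalent to U / (n1 n0)).  Multiclass
#' truth: one-vs-rest AUC per class using that class's score column,
#' macro-averaged; classes absent from the truth give `NA` with a warning
#' and are excluded from the average.
#'
#' @param scores `N x C` matrix of class scores/probabilities (a vector is
#'   taken as the positive-class score of a binary problem).
#' @param yTrue 0-based true labels.
#' @return list with `auc` (macro or binary) and `perClass`.
#' @export
rocAuc <- function(scores, yTrue) {
    yTrue <- .asLabels(yTrue)
    if (is.null(dim(scores))) {
        if (length(unique(yTrue)) < 2L)
            stop("AUC undefined: truth contains a single class")
        auc <- .binaryAuc(as.numeric(scores), yTrue == 1L)
        return(list(auc = auc, perClass = auc))
    }
    scores <- as.matrix(scores)
    C <- ncol(scores)
    .checkLabels(yTrue, C)
    if (length(unique(yTrue)) < 2L)
        stop("AUC undefined: truth contains a single class")
    if (C == 2L) {
        auc <- .binaryAuc(scores[, 2L], yTrue == 1L)
        return(list(auc = auc, perClass = c(.binaryAuc(scores[, 1L],
                                                       yTrue == 0L), auc)))
    }
    per <- vapply(seq_len(C), function(j) {
        pos <- yTrue == (j - 1L)
        if (!any(pos) || all(pos)) return(NA_real_)
        .binaryAuc(scores[, j], pos)
    }, numeric(1))
    if (anyNA(per))
        warning("one-vs-rest AUC undefined for classes absent from the truth; excluded from the macro average")
    list(auc = mean(per, na.rm = TRUE), perClass = per)
}

#' ROC curve points
#'
#' One-vs-rest ROC curve of a score vector: false-positive rate and
#' true-positive rate at every distinct threshold.
#'
#' @param score numeric score vector (higher = more positive).
#' @param positive logical vector of true positivity.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocCurve <- function(score, positive) {
    positive <- as.logical(positive)
    n1 <- sum(positive); n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L)
        stop("ROC undefined: truth contains a single class")
    thr <- c(Inf, sort(unique(score), decreasing = TRUE))
    tpr <- vapply(thr, function(t) sum(score >= t & positive) / n1, 1)
    fpr <- vapply(thr, function(t) sum(score >= t & !positive) / n0, 1)
    data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Full classification report
#'
#' Bundles confusion counts, accuracy, one-vs-rest sensitivity/specificity
#' and (when scores are given) AUC into a [ClassMetrics-class].
#'
#' @param yTrue 0-based true labels.
#' @param yPred 0-based predicted labels; defaults to the arg-max of
#'   `scores` when those are given.
#' @param scores optional `N x C` probability matrix for AUC.
#' @param nClasses number of classes.
#' @return a [ClassMetrics-class].
#' @export
classMetrics <- function(yTrue, yPred = NULL, scores = NULL,
                         nClasses = NULL) {
    yTrue <- .asLabels(yTrue)
    if (is.null(yPred)) {
        if (is.null(scores)) stop("need yPred or scores")
        yPred <- max.col(as.matrix(scores), ties.method = "first") - 1L
    }
    if (is.null(nClasses))
        nClasses <- if (!is.null(scores)) ncol(as.matrix(scores)) else
            max(yTrue, yPred) + 1L
    cm <- confusionMatrix(yTrue, yPred, nClasses)
    ss <- sensitivitySpecificity(cm)
    aucPer <- numeric(0); auc <- NA_real_
    if (!is.null(scores)) {
        r <- rocAuc(as.matrix(scores), yTrue)
        auc <- r$auc; aucPer <- r$perClass
    }
    new("ClassMetrics", counts = cm, acc = accuracy(cm),
        senPerClass = ss$senPerClass, spePerClass = ss$spePerClass,
        senMean = ss$senMean, speMean = ss$speMean,
        aucPerClass = aucPer, auc = auc)
}

setMethod("show", "ClassMetrics", function(object) {
    cat(sprintf("ClassMetrics: %d classes, N = %d\n",
                nrow(object@counts), sum(object@counts)))
    cat(sprintf("  ACC  %.4f\n", object@acc))
    cat(sprintf("  SEN  mean %.4f (%s)\n", object@senMean,
                paste(sprintf("%.4f", object@senPerClass), collapse = " ")))
    cat(sprintf("  SPE  mean %.4f (%s)\n", object@speMean,
                paste(sprintf("%.4f", object@spePerClass), collapse = " ")))
    if (!is.na(object@auc))
        cat(sprintf("  AUC  %.4f\n", object@auc))
})

#' Serialize a ClassMetrics report to JSON
#'
#' @param metrics a [ClassMetrics-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMetrics <- function(metrics, path) {
    stopifnot(is(metrics, "ClassMetrics"))
    jsonlite::write_json(
        list(acc = metrics@acc,
             sen_per_class = metrics@senPerClass,
             spe_per_class = metrics@spePerClass,
             sen_mean = metrics@senMean, spe_mean = metrics@speMean,
             auc = if (is.na(metrics@auc)) NULL else metrics@auc,
             auc_per_class = if (length(metrics@aucPerClass))
                 metrics@aucPerClass else NULL,
             confusion = apply(metrics@counts, 1L, as.integer,
                               simplify = FALSE)),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' PCA projection of embeddings
#'
#' Mean-centered projection onto the leading principal components, ordered
#' by decreasing variance, used to visualize how well embeddings cluster.
#' Component signs are fixed by requiring the largest-magnitude loading of
#' each component to be positive, so projections are reproducible.
#'
#' @param embeddings `N x l` matrix.
#' @param outDim number of components (<= min(N, l)).
#' @return `N x outDim` matrix of component scores.
#' @export
pcaProjection <- function(embeddings, outDim = 2L) {
    embeddings <- as.matrix(embeddings)
    outDim <- as.integer(outDim)
    if (outDim > min(dim(embeddings)))
        stop("outDim exceeds min(N, l)")
    pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(outDim), drop = FALSE]
    flip <- vapply(seq_len(outDim), function(j) {
        v <- rot[, j]
        sign(v[which.max(abs(v))])
    }, numeric(1))
    flip[flip == 0] <- 1
    scores <- pc$x[, seq_len(outDim), drop = FALSE]
    sweep(scores, 2L, flip, "*")
}

#' Clustering gap of labeled embeddings
#'
#' Mean same-class cosine similarity minus mean cross-class cosine
#' similarity over all unordered sample pairs — a scalar measure of how
#' strongly the embedding space separates the classes (higher is better;
#' perfectly clustered orthogonal classes give 1).
#'
#' @param x an [EmbeddingBatch-class] or embedding matrix.
#' @param labels 0-based labels (ignored for an `EmbeddingBatch`).
#' @return single numeric value.
#' @export
clusteringGap <- function(x, labels = NULL) {
    p <- .batchParts(x, labels)
    if (length(unique(p$labels)) < 2L)
        stop("clustering gap needs at least two classes")
    S <- similarityMatrix(l2Normalize(p$values))
    same <- outer(p$labels, p$labels, "==")
    diag(same) <- NA  # exclude self-pairs
    up <- upper.tri(S)
    mean(S[up][same[up]], na.rm = TRUE) - mean(S[up][!same[up]], na.rm = TRUE)
}
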