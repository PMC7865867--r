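#' BSTriplet loss configuration
#'
#' @param margin hinge margin m in \[0, 1\] (default 0.9; it should sit near
#'   1, but exactly 1 would demand identical same-class embeddings).
#' @param lambda nonnegative weight of the triplet term in [combinedLoss()]
#'   (default 1).
#' @param missingPositiveFill substitute for the positive-pair mean when a
#'   sample has no same-class partner in the batch; default 1, the ideal
#'   value, so the loss reduces to the cross-class constraint alone.
#' @param missingNegativeFill substitute for the negative-pair mean when a
#'   sample has no different-class partner; default 0.
#' @return a [BSTConfig-class].
#' @examples
#' bstConfig(margin = 0.9)
#' @export
bstConfig <- function(margin = 0.9, lambda = 1,
                      missingPositiveFill = 1, missingNegativeFill = 0) {
    new("BSTConfig", margin = as.numeric(margin), lambda = as.numeric(lambda),
        missingPositiveFill = as.numeric(missingPositiveFill),
        missingNegativeFill = as.numeric(missingNegativeFill))
}

#' L2-normalize embedding rows
#'
#' Divides each row by its Euclidean norm so cosine similarities become plain
#' dot products.  Rows with norm below 1e-12 are degenerate (direction
#' undefined) and raise an error naming the offending row.
#'
#' @param values numeric matrix, one embedding per row, or an
#'   [EmbeddingBatch-class].
#' @return matrix of the same shape with unit-norm rows.
#' @examples
#' l2Normalize(rbind(c(3, 4)))  # -> c(0.6, 0.8)
#' @export
l2Normalize <- function(values) {
    if (is(values, "EmbeddingBatch")) values <- embeddingMatrix(values)
    values <- as.matrix(values)
    nrm <- sqrt(rowSums(values^2))
    bad <- which(nrm <= 1e-12)
    if (length(bad))
        stop(sprintf(
            "degenerate input: embedding row %d has norm <= 1e-12 and cannot be normalized",
            bad[1L]))
    values / nrm
}

#' Pairwise cosine-similarity matrix of a normalized batch
#'
#' `S = fhat %*% t(fhat)`: entry (i, j) is the cosine similarity of samples i
#' and j.  Input rows must be unit-norm (use [l2Normalize()]); the result is
#' symmetric with unit diagonal and entries in \[-1, 1\].
#'
#' @param normed matrix of unit-norm rows.
#' @return `Nb x Nb` similarity matrix.
#' @export
similarityMatrix <- function(normed) {
    normed <- as.matrix(normed)
    nrm <- sqrt(rowSums(normed^2))
    if (any(abs(nrm - 1) > 1e-9))
        stop("similarityMatrix expects unit-norm rows; call l2Normalize first")
    S <- tcrossprod(normed)
    ## clamp tiny numerical excursions beyond [-1, 1]
    S[S > 1] <- 1
    S[S < -1] <- -1
    S
}

#' Binary same-class pair matrix
#'
#' `B = yhat %*% t(yhat)` for one-hot label rows `yhat`: entry (i, j) is 1
#' when samples i and j share a class and 0 otherwise (diagonal all 1).
#'
#' @param labels integer vector of 0-based class labels.
#' @param nClasses number of classes C.
#' @return `Nb x Nb` 0/1 matrix.
#' @examples
#' binaryPairMatrix(c(0, 0, 1), 2)
#' @export
binaryPairMatrix <- function(labels, nClasses) {
    labels <- .asLabels(labels)
    .checkLabels(labels, as.integer(nClasses))
    B <- outer(labels, labels, "==") + 0
    B
}

#' Discriminative similarity matrix
#'
#' Combines the similarity matrix S and the binary pair matrix B into the
#' signed matrix `D = S * (2B - 1 - I)` (elementwise): same-class
#' off-diagonal entries keep their similarity, different-class entries are
#' negated, and the diagonal (each sample against itself, always similarity
#' 1 and uninformative) is zeroed.
#'
#' @param S similarity matrix from [similarityMatrix()].
#' @param B binary pair matrix from [binaryPairMatrix()].
#' @param labels optional 0-based labels to store alongside D; when omitted,
#'   pseudo-labels are derived from the equivalence classes of B (which is
#'   all the loss needs).
#' @return a [DiscriminativeMatrix-class].
#' @export
discriminativeMatrix <- function(S, B, labels = NULL) {
    S <- as.matrix(S); B <- as.matrix(B)
    if (!all(dim(S) == dim(B)))
        stop("S and B must have the same shape")
    n <- nrow(S)
    D <- S * (2 * B - 1)
    diag(D) <- 0
    if (is.null(labels)) {
        ## rows of B index the same-class equivalence classes
        labels <- as.integer(match(
            apply(B, 1L, paste, collapse = ""),
            unique(apply(B, 1L, paste, collapse = "")))) - 1L
    } else {
        labels <- .asLabels(labels)
    }
    new("DiscriminativeMatrix", values = D, labels = labels)
}

#' @describeIn discriminativeMatrix matrix of D values.
#' @param x a `DiscriminativeMatrix`.
#' @export
dmValues <- function(x) {
    stopifnot(is(x, "DiscriminativeMatrix"))
    x@values
}

setMethod("show", "DiscriminativeMatrix", function(object) {
    cat(sprintf("DiscriminativeMatrix: %d x %d, %d classes\n",
                nrow(object@values), ncol(object@values),
                length(unique(object@labels))))
})

## core per-row hinge terms, vectorized over rows.
## returns list(perSample, posTerm, negTerm, posMask, negMask, nPos, nNeg, h)
.bstTerms <- function(D, labels, cfg) {
    n <- nrow(D)
    same <- outer(labels, labels, "==")
    diag(same) <- FALSE           # positives exclude the diagonal
    diff <- outer(labels, labels, "!=")
    nPos <- rowSums(same)
    nNeg <- rowSums(diff)
    Dsq <- D * D
    posTerm <- ifelse(nPos > 0, rowSums(Dsq * same) / pmax(nPos, 1),
                      cfg@missingPositiveFill)
    negTerm <- ifelse(nNeg > 0, rowSums(Dsq * diff) / pmax(nNeg, 1),
                      cfg@missingNegativeFill)
    h <- cfg@margin - posTerm + negTerm
    list(perSample = pmax(0, h), posMask = same, negMask = diff,
         nPos = nPos, nNeg = nNeg, h = h)
}

#' Per-sample BSTriplet loss from a discriminative matrix
#'
#' For row i of D, the loss is
#' `max(0, m - mean(D[i, positives]^2) + mean(D[i, negatives]^2))`: the
#' hinge activates while the average squared same-class similarity fails to
#' exceed the average squared cross-class similarity by the margin m.
#' Squares (rather than the raw similarities) give a smoother gradient near
#' the optimum.  When row i has no positive (or no negative) partners the
#' corresponding mean is replaced by the configured fill value, so the loss
#' reduces to the remaining constraint.  The value always lies in
#' \[0, 1 + m\].
#'
#' @param D a [DiscriminativeMatrix-class].
#' @param i row index (1-based).
#' @param margin hinge margin m.
#' @param config optional [BSTConfig-class] overriding `margin` and the fill
#'   values.
#' @return single nonnegative loss value.
#' @export
bstLossPerSample <- function(D, i, margin = 0.9, config = NULL) {
    stopifnot(is(D, "DiscriminativeMatrix"))
    n <- nrow(D@values)
    if (n < 2L)
        stop("BSTriplet loss is unavailable for a batch of one sample (Nb = 1)")
    if (i < 1L || i > n) stop("row index out of range")
    cfg <- if (is.null(config)) bstConfig(margin = margin) else config
    terms <- .bstTerms(D@values, D@labels, cfg)
    terms$perSample[i]
}

#' BSTriplet batch loss
#'
#' Evaluates the batch similarity-based triplet loss on a batch of raw
#' embeddings: rows are L2-normalized, the cosine-similarity and binary pair
#' matrices are combined into the discriminative matrix D, the per-sample
#' hinge losses are computed (see [bstLossPerSample()]), and the batch loss
#' is their arithmetic mean.  Optionally also returns the analytic gradient
#' of the batch mean with respect to the *raw* embeddings, chained through
#' the normalization Jacobian; the hinge subgradient at the kink is taken as
#' 0.
#'
#' @param x an [EmbeddingBatch-class], or a numeric matrix of raw embeddings
#'   (rows = samples).
#' @param labels 0-based class labels (ignored when `x` is an
#'   `EmbeddingBatch`).
#' @param config a [BSTConfig-class]; see [bstConfig()].
#' @param gradient whether to compute the analytic gradient.
#' @return a [BSTLossResult-class].
#' @examples
#' res <- bstLoss(rbind(c(1, 0), c(0.6, 0.8), c(0, 1)), labels = c(0, 0, 1))
#' res@perSample
#' res@batchMean
#' @export
bstLoss <- function(x, labels = NULL, config = bstConfig(),
                    gradient = FALSE) {
    p <- .batchParts(x, labels)
    values <- p$values; labels <- p$labels
    n <- nrow(values)
    if (n < 2L)
        stop("BSTriplet loss is unavailable for a batch of one sample (Nb = 1)")
    fhat <- l2Normalize(values)
    S <- similarityMatrix(fhat)
    D <- S * (2 * outer(labels, labels, "==") - 1)
    diag(D) <- 0
    terms <- .bstTerms(D, labels, config)
    grad <- matrix(numeric(0), 0L, 0L)
    if (gradient)
        grad <- .bstGradientCore(values, fhat, S, labels, config, terms)
    new("BSTLossResult", perSample = as.numeric(terms$perSample),
        batchMean = mean(terms$perSample), gradient = grad,
        margin = config@margin, lambda = config@lambda)
}

## gradient of mean per-sample hinge w.r.t. raw embeddings.
## dL/dS has, for each active row i, entries -2*S[i,j]/(Nb*nPos[i]) at
## positives and +2*S[i,j]/(Nb*nNeg[i]) at negatives (D^2 = S^2 regardless of
## sign); fill-valued terms contribute nothing.  Then dL/dfhat = (G + G^T) fhat
## and each row is pushed through the normalization Jacobian
## (I - fhat fhat^T)/||f||.
.bstGradientCore <- function(values, fhat, S, labels, cfg, terms) {
    n <- nrow(values)
    active <- terms$h > 0
    G <- matrix(0, n, n)
    if (any(active)) {
        posW <- ifelse(terms$nPos > 0, -2 / (n * pmax(terms$nPos, 1)), 0)
        negW <- ifelse(terms$nNeg > 0,  2 / (n * pmax(terms$nNeg, 1)), 0)
        W <- matrix(0, n, n)
        W[terms$posMask] <- (posW * active)[row(S)[terms$posMask]]
        W[terms$negMask] <- (negW * active)[row(S)[terms$negMask]]
        G <- W * S
    }
    gHat <- (G + t(G)) %*% fhat
    nrm <- sqrt(rowSums(values^2))
    radial <- rowSums(gHat * fhat)
    (gHat - radial * fhat) / nrm
}

#' Analytic gradient of the BSTriplet batch loss
#'
#' Convenience wrapper around `bstLoss(..., gradient = TRUE)` returning only
#' the `Nb x l` matrix d(batch mean)/d(raw embeddings).
#'
#' @inheritParams bstLoss
#' @return numeric `Nb x l` matrix.
#' @export
bstGradient <- function(x, labels = NULL, config = bstConfig()) {
    bstLoss(x, labels, config, gradient = TRUE)@gradient
}

#' Regular similarity-based triplet loss for one triplet
#'
#' `max(0, 1 - sPos + sNeg)` for the cosine similarity of an anchor with one
#' positive and one negative partner.  Both similarities must lie in
#' \[-1, 1\].
#'
#' @param sPos anchor-positive cosine similarity.
#' @param sNeg anchor-negative cosine similarity.
#' @return nonnegative loss value.
#' @examples
#' pairwiseTripletLoss(0.5, 0.2)  # 0.7
#' @export
pairwiseTripletLoss <- function(sPos, sNeg) {
    if (any(!is.finite(c(sPos, sNeg))) ||
        any(abs(c(sPos, sNeg)) > 1 + 1e-9))
        stop("similarities must be finite values in [-1, 1]")
    pmax(0, 1 - sPos + sNeg)
}

#' Numerically stable softmax
#'
#' Row-wise softmax with max-shift, so large logits do not overflow.  Accepts
#' a vector (one sample) or a matrix (rows = samples).
#'
#' @param logits finite numeric vector or matrix.
#' @return probabilities of the same shape; rows are positive and sum to 1.
#' @export
softmaxProbs <- function(logits) {
    vec <- is.null(dim(logits))
    x <- if (vec) matrix(logits, nrow = 1L) else as.matrix(logits)
    if (!all(is.finite(x))) stop("logits must be finite")
    x <- x - apply(x, 1L, max)
    e <- exp(x)
    p <- e / rowSums(e)
    if (vec) as.numeric(p) else p
}

#' Mean cross-entropy loss
#'
#' Mean over samples of `-log p(true class)`.  Probabilities are clipped
#' below at 1e-12 before the log; rows must sum to 1 within 1e-6.
#'
#' @param probs `Nb x C` matrix of predicted class probabilities.
#' @param labels 0-based true class labels.
#' @return nonnegative mean cross-entropy.
#' @examples
#' crossEntropyLoss(rbind(c(0.5, 0.5)), 0)  # log(2)
#' @export
crossEntropyLoss <- function(probs, labels) {
    probs <- as.matrix(probs)
    labels <- .asLabels(labels)
    if (length(labels) != nrow(probs))
        stop("labels length must equal the number of probability rows")
    .checkLabels(labels, ncol(probs))
    if (any(abs(rowSums(probs) - 1) > 1e-6))
        stop("each probability row must sum to 1 (tolerance 1e-6)")
    pTrue <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
    mean(-log(pmax(pTrue, 1e-12)))
}

#' Combined cross-entropy + BSTriplet objective
#'
#' `L = Lce + lambda * Ltrip`, the training objective that pairs the
#' classification loss with the clustering loss; lambda defaults to 1, which
#' balances the two terms since they live on comparable scales.
#'
#' @param x an [EmbeddingBatch-class] or raw embedding matrix.
#' @param logits `Nb x C` matrix of classifier outputs (pre-softmax).
#' @param labels 0-based labels (ignored for an `EmbeddingBatch`).
#' @param config a [BSTConfig-class].
#' @return list with components `total`, `crossEntropy`, `bstriplet`.
#' @export
combinedLoss <- function(x, logits, labels = NULL, config = bstConfig()) {
    p <- .batchParts(x, labels)
    logits <- as.matrix(logits)
    if (nrow(logits) != nrow(p$values))
        stop("logits and embeddings must agree on the number of samples")
    ce <- crossEntropyLoss(softmaxProbs(logits), p$labels)
    bst <- bstLoss(p$values, p$labels, config)@batchMean
    list(total = ce + config@lambda * bst, crossEntropy = ce, bstriplet = bst)
}

#' Serialize a loss result to JSON
#'
#' Writes `perSample`, `batchMean`, `margin` and `lambda` as a JSON object.
#'
#' @param result a [BSTLossResult-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeLossResult <- function(result, path) {
    stopifnot(is(result, "BSTLossResult"))
    jsonlite::write_json(
        list(per_sample = result@perSample, batch_mean = result@batchMean,
             margin = result@margin, lambda = result@lambda),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

setMethod("show", "BSTLossResult", function(object) {
    cat(sprintf(
        "BSTLossResult: Nb = %d, batch mean = %.6g (margin %.3g, lambda %.3g)\n",
        length(object@perSample), object@batchMean, object@margin,
        object@lambda))
    if (nrow(object@gradient) > 0L)
        cat(sprintf("gradient: %d x %d matrix, max |entry| = %.3g\n",
                    nrow(object@gradient), ncol(object@gradient),
                    max(abs(object@gradient))))
})
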