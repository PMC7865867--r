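# Independent reference implementations used to cross-check the vectorized
# package code.  Everything here is deliberately written as plain scalar
# loops over pairs, sharing no code path with the package internals.

# naive per-sample BSTriplet loss: explicit loops over positive and
# negative partners of row i
oracleBstPerSample <- function(values, labels, i, margin = 0.9,
                               fillPos = 1, fillNeg = 0) {
    n <- nrow(values)
    fhat <- values
    for (r in seq_len(n))
        fhat[r, ] <- values[r, ] / sqrt(sum(values[r, ]^2))
    pos <- c(); neg <- c()
    for (j in seq_len(n)) {
        if (j == i) next
        s <- sum(fhat[i, ] * fhat[j, ])
        if (labels[j] == labels[i]) pos <- c(pos, s) else neg <- c(neg, s)
    }
    posTerm <- if (length(pos)) mean(pos^2) else fillPos
    negTerm <- if (length(neg)) mean(neg^2) else fillNeg
    max(0, margin - posTerm + negTerm)
}

oracleBstBatch <- function(values, labels, margin = 0.9) {
    vapply(seq_len(nrow(values)),
           function(i) oracleBstPerSample(values, labels, i, margin),
           numeric(1))
}

# elementwise evaluation of the expanded discriminative-matrix form
# S*B + S*(B - 1) - S*I, one entry at a time
oracleDiscriminative <- function(S, B) {
    n <- nrow(S)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        I <- as.numeric(i == j)
        D[i, j] <- S[i, j] * B[i, j] + S[i, j] * (B[i, j] - 1) -
            S[i, j] * I
    }
    D
}

# central finite differences of the batch-mean BSTriplet loss
oracleFiniteDiffGrad <- function(values, labels, margin = 0.9, h = 1e-6) {
    fd <- matrix(0, nrow(values), ncol(values))
    cfg <- bstConfig(margin = margin)
    for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
        up <- values; up[i, j] <- up[i, j] + h
        dn <- values; dn[i, j] <- dn[i, j] - h
        fd[i, j] <- (bstLoss(up, labels, cfg)@batchMean -
                     bstLoss(dn, labels, cfg)@batchMean) / (2 * h)
    }
    fd
}

# minimum distance of any per-sample hinge argument from its kink
hingeMarginGap <- function(values, labels, margin = 0.9) {
    n <- nrow(values)
    fhat <- values / sqrt(rowSums(values^2))
    S <- tcrossprod(fhat)
    gaps <- vapply(seq_len(n), function(i) {
        pos <- neg <- c()
        for (j in seq_len(n)) {
            if (j == i) next
            if (labels[j] == labels[i]) pos <- c(pos, S[i, j])
            else neg <- c(neg, S[i, j])
        }
        posTerm <- if (length(pos)) mean(pos^2) else 1
        negTerm <- if (length(neg)) mean(neg^2) else 0
        abs(margin - posTerm + negTerm)
    }, numeric(1))
    min(gaps)
}

# AUC by brute-force pair counting (ties count half)
oraclePairCountAuc <- function(score, positive) {
    posIdx <- which(positive); negIdx <- which(!positive)
    tot <- 0
    for (p in posIdx) for (q in negIdx) {
        if (score[p] > score[q]) tot <- tot + 1
        else if (score[p] == score[q]) tot <- tot + 0.5
    }
    tot / (length(posIdx) * length(negIdx))
}

# random batch generator for property tests
randomBatch <- function(nb, l, C, seed) {
    withr::with_seed(seed, {
        values <- matrix(stats::rnorm(nb * l), nb, l)
        labels <- sample.int(C, nb, replace = TRUE) - 1L
        list(values = values, labels = labels, C = C)
    })
}
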