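## Minimal convolutional classifier used by the training harness:
## conv 3x3 (8 filters) -> ReLU -> maxpool 2x2 ->
## conv 3x3 (embeddingDim filters) -> ReLU -> maxpool 2x2 ->
## global average pool (= the embedding) -> linear -> softmax.
## Convolutions are same-padded, implemented via im2col so forward and
## backward are matrix products; training uses Adam.  All internal.

## linear indices from output positions into a zero-padded
## (H+2) x (W+2) x Cin array, column-major; one column per (dr, dc, ch)
.convIdx <- function(H, W, Cin) {
    Hp <- H + 2L; Wp <- W + 2L
    r <- rep(seq_len(H), times = W)
    c <- rep(seq_len(W), each = H)
    cols <- vector("list", 9L * Cin)
    j <- 0L
    for (ch in seq_len(Cin)) {
        off <- (ch - 1L) * Hp * Wp
        for (dc in 0:2) for (dr in 0:2) {
            j <- j + 1L
            cols[[j]] <- off + (c + dc - 1L) * Hp + (r + dr)
        }
    }
    matrix(unlist(cols), nrow = H * W)
}

.initNet <- function(C, embeddingDim = 16L, filters1 = 8L) {
    list(
        W1 = matrix(stats::rnorm(9L * filters1, sd = 0.2), 9L, filters1),
        b1 = rep(0.1, filters1),
        W2 = matrix(stats::rnorm(9L * filters1 * embeddingDim, sd = 0.1),
                    9L * filters1, embeddingDim),
        b2 = rep(0.1, embeddingDim),
        Wf = matrix(stats::rnorm(embeddingDim * C, sd = 0.1),
                    embeddingDim, C),
        bf = rep(0, C))
}

## expand per-sample patch indices to the whole batch: rows ordered sample-
## fastest then output position, matching the column-major layout of an
## (nb, H, W, Cout) array, so conv output reshapes without copying logic
.bigIdx <- function(idx, nb) {
    HW <- nrow(idx)
    base <- idx[rep(seq_len(HW), each = nb), , drop = FALSE]
    matrix(rep(seq_len(nb), times = HW), nb * HW, ncol(idx)) +
        nb * (base - 1L)
}

## per-batch precomputed geometry: patch indices for both conv layers,
## expanded for a given batch size
.netContext <- function(H, W, filters1, nb) {
    idx1 <- .convIdx(H, W, 1L)
    idx2 <- .convIdx(H %/% 2L, W %/% 2L, filters1)
    list(H = H, W = W, filters1 = filters1, nb = nb,
         idx1 = idx1, idx2 = idx2,
         bi1 = .bigIdx(idx1, nb), bi2 = .bigIdx(idx2, nb))
}

.ctxFor <- function(ctx, nb) {
    if (nb == ctx$nb) return(ctx)
    ctx$nb <- nb
    ctx$bi1 <- .bigIdx(ctx$idx1, nb)
    ctx$bi2 <- .bigIdx(ctx$idx2, nb)
    ctx
}

## X: nb x H x W x Cin array -> one im2col matrix and one matmul for the
## whole batch
.convForward <- function(X, W, b, bi) {
    d <- dim(X)
    nb <- d[1L]; H <- d[2L]; Wd <- d[3L]; Cin <- d[4L]
    Hp <- H + 2L; Wp <- Wd + 2L
    pad <- array(0, c(nb, Hp, Wp, Cin))
    pad[, 2:(H + 1L), 2:(Wd + 1L), ] <- X
    v <- matrix(pad[bi], nrow = nb * H * Wd)
    o <- v %*% W
    o <- sweep(o, 2L, b, "+")
    list(out = array(o, c(nb, H, Wd, ncol(W))), cols = v)
}

## backward through one conv layer; returns dW, db and (optionally) dX.
## the scatter-add into the padded input runs per patch offset: for a fixed
## (dr, dc, channel) offset the map from output positions to padded
## positions is injective, so each column is a plain vectorized add
.convBackward <- function(dOut, cols, bi, W, inDim, needInput = TRUE) {
    d <- dim(dOut)
    nb <- d[1L]; H <- d[2L]; Wd <- d[3L]
    Hp <- inDim[1L] + 2L; Wp <- inDim[2L] + 2L; Cin <- inDim[3L]
    g <- matrix(dOut, nrow = nb * H * Wd)
    dW <- crossprod(cols, g)
    db <- colSums(g)
    dX <- NULL
    if (needInput) {
        dv <- g %*% t(W)
        dPad <- numeric(nb * Hp * Wp * Cin)
        for (j in seq_len(ncol(bi))) {
            bj <- bi[, j]
            dPad[bj] <- dPad[bj] + dv[, j]
        }
        dPad <- array(dPad, c(nb, Hp, Wp, Cin))
        dX <- dPad[, 2:(inDim[1L] + 1L), 2:(inDim[2L] + 1L), ,
                   drop = FALSE]
    }
    list(dW = dW, db = db, dX = dX)
}

.pool2Forward <- function(X) {
    d <- dim(X)
    H2 <- d[2L] %/% 2L; W2 <- d[3L] %/% 2L
    ro <- seq_len(H2) * 2L - 1L; co <- seq_len(W2) * 2L - 1L
    a11 <- X[, ro, co, , drop = FALSE]
    a21 <- X[, ro + 1L, co, , drop = FALSE]
    a12 <- X[, ro, co + 1L, , drop = FALSE]
    a22 <- X[, ro + 1L, co + 1L, , drop = FALSE]
    out <- pmax(a11, a21, a12, a22)
    list(out = out, corners = list(a11, a21, a12, a22))
}

.pool2Backward <- function(dOut, pooled, corners, inDim) {
    d <- dim(dOut)
    H2 <- d[2L]; W2 <- d[3L]
    ro <- seq_len(H2) * 2L - 1L; co <- seq_len(W2) * 2L - 1L
    dX <- array(0, inDim)
    taken <- array(FALSE, dim(dOut))  # route ties to the first corner
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (k in 1:4) {
        m <- (corners[[k]] == pooled) & !taken
        taken <- taken | m
        dX[, ro + offs[[k]][1L], co + offs[[k]][2L], ] <-
            dX[, ro + offs[[k]][1L], co + offs[[k]][2L], , drop = FALSE] +
            dOut * m
    }
    dX
}

## full forward pass; keepActs retains intermediates for backprop
.netForward <- function(net, X, keepActs = FALSE, ctx) {
    nb <- dim(X)[1L]
    ctx <- .ctxFor(ctx, nb)
    X4 <- array(X, c(dim(X), 1L))
    c1 <- .convForward(X4, net$W1, net$b1, ctx$bi1)
    r1 <- pmax(c1$out, 0)
    p1 <- .pool2Forward(r1)
    c2 <- .convForward(p1$out, net$W2, net$b2, ctx$bi2)
    r2 <- pmax(c2$out, 0)
    p2 <- .pool2Forward(r2)
    d2 <- dim(p2$out)
    emb <- matrix(0, nb, d2[4L])
    spatial <- d2[2L] * d2[3L]
    for (ch in seq_len(d2[4L]))
        emb[, ch] <- rowSums(matrix(p2$out[, , , ch], nb)) / spatial
    logits <- sweep(emb %*% net$Wf, 2L, net$bf, "+")
    res <- list(emb = emb, logits = logits, probs = softmaxProbs(logits))
    if (keepActs)
        res$acts <- list(X4 = X4, c1 = c1, r1 = r1, p1 = p1, c2 = c2,
                         r2 = r2, p2 = p2, ctx = ctx)
    res
}

## backward from (dLogits, dEmb) to parameter gradients
.netBackward <- function(net, fwd, dLogits, dEmbExtra) {
    a <- fwd$acts
    ctx <- a$ctx
    nb <- nrow(fwd$emb)
    dWf <- crossprod(fwd$emb, dLogits)
    dbf <- colSums(dLogits)
    dEmb <- dLogits %*% t(net$Wf) + dEmbExtra
    d2 <- dim(a$p2$out)
    spatial <- d2[2L] * d2[3L]
    dP2 <- array(0, d2)
    for (h in seq_len(d2[2L])) for (w in seq_len(d2[3L]))
        dP2[, h, w, ] <- dEmb / spatial
    dR2 <- .pool2Backward(dP2, a$p2$out, a$p2$corners, dim(a$r2))
    dC2 <- dR2 * (a$c2$out > 0)
    inDim2 <- dim(a$p1$out)[-1L]
    cb2 <- .convBackward(dC2, a$c2$cols, ctx$bi2, net$W2, inDim2,
                         needInput = TRUE)
    dP1 <- array(cb2$dX, dim(a$p1$out))
    dR1 <- .pool2Backward(dP1, a$p1$out, a$p1$corners, dim(a$r1))
    dC1 <- dR1 * (a$c1$out > 0)
    inDim1 <- dim(a$X4)[-1L]
    cb1 <- .convBackward(dC1, a$c1$cols, ctx$bi1, net$W1, inDim1,
                         needInput = FALSE)
    list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db,
         Wf = dWf, bf = dbf)
}

.adamInit <- function(net) {
    list(m = lapply(net, function(p) p * 0),
         v = lapply(net, function(p) p * 0), t = 0L)
}

.adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    for (nm in names(net)) {
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- state$m[[nm]] / (1 - beta1^state$t)
        vhat <- state$v[[nm]] / (1 - beta2^state$t)
        net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(net = net, state = state)
}

## regular triplet loss over a batch: for each anchor one random positive
## and one random negative (drawn from the current RNG stream); anchors
## lacking either partner are skipped.  Returns mean loss and gradient
## w.r.t. the raw embeddings.
.tripletBatch <- function(emb, labels) {
    n <- nrow(emb)
    fhat <- l2Normalize(emb)
    S <- tcrossprod(fhat)
    G <- matrix(0, n, n)
    losses <- numeric(0)
    for (i in seq_len(n)) {
        pos <- which(labels == labels[i]); pos <- pos[pos != i]
        neg <- which(labels != labels[i])
        if (!length(pos) || !length(neg)) next
        p <- if (length(pos) == 1L) pos else sample(pos, 1L)
        ng <- if (length(neg) == 1L) neg else sample(neg, 1L)
        li <- 1 - S[i, p] + S[i, ng]
        losses <- c(losses, max(0, li))
        if (li > 0) {
            G[i, p] <- G[i, p] - 1
            G[i, ng] <- G[i, ng] + 1
        }
    }
    if (!length(losses))
        return(list(loss = 0, grad = matrix(0, n, ncol(emb))))
    G <- G / length(losses)
    gHat <- (G + t(G)) %*% fhat
    nrm <- sqrt(rowSums(emb^2))
    radial <- rowSums(gHat * fhat)
    list(loss = mean(losses), grad = (gHat - radial * fhat) / nrm)
}
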