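#' Partition sample indices by class
#'
#' Step 1 of the batch-mining strategy: group the training samples by their
#' ground-truth class.
#'
#' @param labels 0-based class labels.
#' @param nClasses number of classes C; classes with no observed samples get
#'   an empty index list.
#' @return list of length C (named `"0" ... "C-1"`) of 1-based sample index
#'   vectors; disjoint and jointly covering all samples.
#' @examples
#' partitionByClass(c(0, 1, 0, 2), 3)
#' @export
partitionByClass <- function(labels, nClasses) {
    labels <- .asLabels(labels)
    nClasses <- as.integer(nClasses)
    .checkLabels(labels, nClasses)
    out <- lapply(seq_len(nClasses) - 1L,
                  function(cl) which(labels == cl))
    names(out) <- as.character(seq_len(nClasses) - 1L)
    out
}

## k-means++ style seeding: first center uniform, then proportional to
## squared distance from the nearest chosen center.
.kmeansPPCenters <- function(x, k) {
    n <- nrow(x)
    centers <- numeric(0)
    idx <- sample.int(n, 1L)
    centers <- x[idx, , drop = FALSE]
    minD2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x),
                                 byrow = TRUE))^2)
    while (nrow(centers) < k) {
        if (all(minD2 <= 0)) {
            ## duplicated points: fall back to distinct rows where possible
            idx <- sample.int(n, 1L)
        } else {
            idx <- sample.int(n, 1L, prob = minD2 / sum(minD2))
        }
        cand <- x[idx, , drop = FALSE]
        centers <- rbind(centers, cand)
        d2 <- rowSums((x - matrix(cand, n, ncol(x), byrow = TRUE))^2)
        minD2 <- pmin(minD2, d2)
    }
    centers
}

#' Cluster the samples of one class into subgroups
#'
#' Step 2 of the batch-mining strategy: split a class into `k` subgroups so
#' that batch quotas can follow the within-class structure.  The default
#' algorithm is Lloyd's K-means started from k-means++-style seeds; any
#' other clustering can be plugged in via `assignFun`.
#'
#' @param features numeric matrix, one row per sample of the class.
#' @param k number of subgroups (1 <= k <= number of samples).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @param assignFun optional replacement clustering: a
#'   `function(features, k)` returning an integer assignment in `1..k`.
#' @return integer vector of subgroup assignments in `1..k`.
#' @export
clusterWithinClass <- function(features, k, seed = 1L, assignFun = NULL) {
    features <- as.matrix(features)
    n <- nrow(features)
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > n)
        stop(sprintf("k = %d exceeds the class size %d", k, n))
    if (!is.null(assignFun)) {
        a <- as.integer(assignFun(features, k))
        if (length(a) != n || any(a < 1L) || any(a > k))
            stop("assignFun must return one group id in 1..k per sample")
        return(a)
    }
    if (k == 1L) return(rep(1L, n))
    if (k == n) return(seq_len(n))
    withr::with_seed(as.integer(seed), {
        centers <- .kmeansPPCenters(features, k)
        ## duplicate seed centers would make kmeans fail; jitter is not
        ## acceptable (determinism), so fall back to distinct rows
        if (anyDuplicated(centers)) {
            ord <- unique(as.data.frame(features))
            take <- min(k, nrow(ord))
            centers <- as.matrix(ord[seq_len(take), , drop = FALSE])
            if (take < k)
                return(.kmeansFallbackAssign(features, centers))
        }
        km <- suppressWarnings(
            stats::kmeans(features, centers = centers, iter.max = 100L,
                          algorithm = "Lloyd"))
        as.integer(km$cluster)
    })
}

## fewer distinct points than k: assign by nearest available center
.kmeansFallbackAssign <- function(features, centers) {
    d <- as.matrix(stats::dist(rbind(centers, features)))
    k <- nrow(centers)
    d <- d[-seq_len(k), seq_len(k), drop = FALSE]
    as.integer(apply(d, 1L, which.min))
}

#' Build a mining plan: per-class subgroups and their training-set shares
#'
#' Steps 1-3 of the batch-mining strategy: partition the training samples by
#' class, cluster each class into subgroups, count each subgroup and record
#' its share of the training set.  Group ids are global, ordered by class
#' and then by within-class group.
#'
#' @param features `Ntrn x d` feature matrix used for clustering (for raw
#'   images see [imageFeatures()]).
#' @param labels 0-based class labels, length `Ntrn`.
#' @param groupsPerClass integer vector with one entry per class (recycled
#'   from length 1); default 2 subgroups per class.
#' @param seed integer seed for the clustering.
#' @param nClasses number of classes; defaults to `max(labels) + 1`.
#' @param assignFun optional clustering override, see [clusterWithinClass()].
#' @return a [MiningPlan-class].
#' @export
miningPlan <- function(features, labels, groupsPerClass = 2L, seed = 1L,
                       nClasses = NULL, assignFun = NULL) {
    features <- as.matrix(features)
    labels <- .asLabels(labels)
    if (is.null(nClasses)) nClasses <- max(labels) + 1L
    nClasses <- as.integer(nClasses)
    .checkLabels(labels, nClasses)
    if (nrow(features) != length(labels))
        stop("features and labels must agree on the number of samples")
    groupsPerClass <- rep(as.integer(groupsPerClass), length.out = nClasses)
    byClass <- partitionByClass(labels, nClasses)
    n <- length(labels)
    groupOfSample <- integer(n)
    classOfGroup <- integer(0)
    offset <- 0L
    for (cl in seq_len(nClasses)) {
        idx <- byClass[[cl]]
        k <- groupsPerClass[cl]
        if (length(idx) == 0L) {
            if (k > 0L) next  # empty class contributes no groups
        } else {
            a <- clusterWithinClass(features[idx, , drop = FALSE], k,
                                    seed = seed + cl, assignFun = assignFun)
            groupOfSample[idx] <- offset + a
            classOfGroup <- c(classOfGroup, rep(cl - 1L, k))
            offset <- offset + k
        }
    }
    g <- offset
    sizes <- tabulate(groupOfSample, g)
    new("MiningPlan", groupOfSample = groupOfSample,
        classOfGroup = as.integer(classOfGroup),
        ratioOfGroup = sizes / n, nGroups = g)
}

setMethod("show", "MiningPlan", function(object) {
    cat(sprintf("MiningPlan: %d samples in %d groups over %d classes\n",
                length(object@groupOfSample), object@nGroups,
                length(unique(object@classOfGroup))))
    cat("group shares:",
        paste(sprintf("%.3f", object@ratioOfGroup), collapse = " "), "\n")
})

#' Per-group batch quotas from a mining plan
#'
#' Step 4 (sizing): each group's quota is its share of the batch,
#' `ratio * Nb`, rounded by the largest-remainder method so the quotas sum
#' exactly to Nb; remainder ties are broken by ascending group id.
#'
#' @param plan a [MiningPlan-class].
#' @param batchSize batch size Nb (>= 1).
#' @return a [BatchSpec-class].
#' @examples
#' plan <- new("MiningPlan", groupOfSample = rep(1:3, c(4, 4, 2)),
#'             classOfGroup = c(0L, 1L, 2L),
#'             ratioOfGroup = c(0.4, 0.4, 0.2), nGroups = 3L)
#' batchQuotas(plan, 10)@quotaOfGroup
#' @export
batchQuotas <- function(plan, batchSize) {
    stopifnot(is(plan, "MiningPlan"))
    batchSize <- as.integer(batchSize)
    if (batchSize < 1L) stop("batch size must be >= 1")
    exact <- plan@ratioOfGroup * batchSize
    base <- floor(exact)
    rem <- exact - base
    short <- batchSize - sum(base)
    quota <- as.integer(base)
    if (short > 0L) {
        ## largest remainders win; ties by ascending group id
        ord <- order(-rem, seq_along(rem))
        quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1L
    }
    new("BatchSpec", quotaOfGroup = quota, batchSize = batchSize)
}

#' Draw one mined batch
#'
#' Step 4 (sampling): draws each group's quota uniformly without replacement
#' from the group's samples.  Deterministic given the seed.
#'
#' @param plan a [MiningPlan-class].
#' @param spec a [BatchSpec-class] (from [batchQuotas()]).
#' @param seed integer seed.
#' @return integer vector of Nb 1-based sample indices, ordered by group.
#' @export
sampleBatch <- function(plan, spec, seed = 1L) {
    stopifnot(is(plan, "MiningPlan"), is(spec, "BatchSpec"))
    if (length(spec@quotaOfGroup) != plan@nGroups)
        stop("spec and plan disagree on the number of groups")
    sizes <- tabulate(plan@groupOfSample, plan@nGroups)
    over <- which(spec@quotaOfGroup > sizes)
    if (length(over))
        stop(sprintf(
            "infeasible quota: group %d has %d samples but quota %d",
            over[1L], sizes[over[1L]], spec@quotaOfGroup[over[1L]]))
    withr::with_seed(as.integer(seed), {
        out <- integer(0)
        for (g in seq_len(plan@nGroups)) {
            q <- spec@quotaOfGroup[g]
            if (q == 0L) next
            members <- which(plan@groupOfSample == g)
            take <- if (length(members) == 1L) members else
                sample(members, q)
            out <- c(out, take)
        }
        out
    })
}

#' Flattened, standardized image features for clustering
#'
#' The default feature representation the mining strategy clusters on:
#' images are downsampled to `side x side` grayscale by block averaging,
#' flattened, and standardized per feature (constant features are left
#' centered).
#'
#' @param images `n x H x W` array of grayscale images.
#' @param side output side length (default 16).
#' @return `n x side^2` feature matrix.
#' @export
imageFeatures <- function(images, side = 16L) {
    d <- dim(images)
    if (length(d) != 3L) stop("images must be an n x H x W array")
    n <- d[1L]; H <- d[2L]; W <- d[3L]
    side <- as.integer(side)
    rIdx <- pmin(H, floor(seq(0, H - 1e-9, length.out = H)) + 1L)
    ## map each output cell to a block of input pixels (area average)
    rowBin <- cut(seq_len(H), breaks = side, labels = FALSE)
    colBin <- cut(seq_len(W), breaks = side, labels = FALSE)
    feats <- matrix(0, n, side * side)
    for (i in seq_len(n)) {
        img <- images[i, , ]
        pooled <- rowsum(img, rowBin)                 # side x W
        pooled <- t(rowsum(t(pooled), colBin))        # side x side sums
        cnt <- tabulate(rowBin, side) %o% tabulate(colBin, side)
        feats[i, ] <- as.numeric(pooled / cnt)
    }
    mu <- colMeans(feats)
    sdv <- apply(feats, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    sweep(sweep(feats, 2L, mu), 2L, sdv, "/")
}
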