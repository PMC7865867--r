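#' FLOP cost of one BSTriplet loss evaluation
#'
#' Closed-form operation count for evaluating the batch loss once on a batch
#' of Nb embeddings of length l over C classes:
#' `(l^2 + C^2 + l + C + 3) * Nb^2 + (2l + 5) * Nb`.
#' The itemized breakdown (normalization `(2l-1)Nb`, similarity matrix
#' `(l^2+l-1)Nb^2`, one-hot encoding `2Nb`, binary pair matrix
#' `(C^2+C-1)Nb^2`, discriminative matrix `3Nb^2+Nb`, per-sample losses
#' `2Nb^2+2Nb`, batch averaging `Nb`) sums exactly to the closed form.
#' The counting convention is one FLOP per multiply, add, index or
#' assignment; no fused multiply-add.
#'
#' @param l embedding length (>= 1).
#' @param nClasses number of classes C (>= 1).
#' @param batchSize batch size Nb (>= 1).
#' @return a [FlopEstimate-class].
#' @examples
#' bstFlops(1280, 3, 36)@total  # 2125137060
#' @export
bstFlops <- function(l, nClasses, batchSize) {
    l <- as.numeric(l); C <- as.numeric(nClasses)
    Nb <- as.numeric(batchSize)
    if (any(c(l, C, Nb) < 1) || any(c(l, C, Nb) != round(c(l, C, Nb))))
        stop("l, nClasses and batchSize must be positive integers")
    breakdown <- c(
        normalization = (2 * l - 1) * Nb,
        similarity = (l^2 + l - 1) * Nb^2,
        one_hot = 2 * Nb,
        binary_matrix = (C^2 + C - 1) * Nb^2,
        discriminative_matrix = 3 * Nb^2 + Nb,
        per_sample_losses = 2 * Nb^2 + 2 * Nb,
        averaging = Nb)
    total <- (l^2 + C^2 + l + C + 3) * Nb^2 + (2 * l + 5) * Nb
    new("FlopEstimate", total = total, breakdown = breakdown)
}

#' One-off setup cost of the mining strategy
#'
#' The first three mining steps run once before training: indexing the Ntrn
#' training samples (Ntrn FLOPs), clustering (algorithm-dependent, supplied
#' as an abstract count), and computing the g group ratios (g FLOPs).  The
#' per-iteration batch construction costs Nb FLOPs and is reported
#' separately by [bstFlops()] callers.
#'
#' @param nTrain training-set size Ntrn (>= 0).
#' @param nGroups total number of groups g (>= 0).
#' @param clusteringCost abstract FLOP count of the clustering step (>= 0).
#' @return total setup FLOPs, `clusteringCost + nTrain + nGroups`.
#' @examples
#' miningSetupFlops(5604, 6, 1000)  # 6610
#' @export
miningSetupFlops <- function(nTrain, nGroups, clusteringCost) {
    v <- c(nTrain, nGroups, clusteringCost)
    if (any(v < 0)) stop("arguments must be nonnegative")
    sum(as.numeric(v))
}

setMethod("show", "FlopEstimate", function(object) {
    cat(sprintf("FlopEstimate: %s FLOPs\n",
                format(object@total, big.mark = ",", scientific = FALSE)))
    for (nm in names(object@breakdown))
        cat(sprintf("  %-22s %s\n", nm,
                    format(object@breakdown[[nm]], big.mark = ",",
                           scientific = FALSE)))
})
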