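## internal helpers

.asLabels <- function(labels) {
    if (is.factor(labels)) labels <- as.integer(labels) - 1L
    lab <- as.integer(round(labels))
    if (any(is.na(lab)) || any(abs(labels - lab) > 0))
        stop("labels must be integers")
    lab
}

.checkLabels <- function(labels, C) {
    if (length(C) != 1L || is.na(C) || C < 1L)
        stop("number of classes must be a single integer >= 1")
    bad <- which(labels < 0L | labels >= C)
    if (length(bad))
        stop(sprintf(
            "invalid label %d at position %d: labels must lie in [0, %d]",
            labels[bad[1L]], bad[1L], C - 1L))
    invisible(TRUE)
}

## coerce (matrix, labels) or EmbeddingBatch into a (values, labels, C) list
.batchParts <- function(x, labels = NULL, nClasses = NULL) {
    if (is(x, "EmbeddingBatch")) {
        list(values = embeddingMatrix(x), labels = sampleLabels(x),
             C = nClasses(x))
    } else {
        values <- as.matrix(x)
        labels <- .asLabels(labels)
        if (length(labels) != nrow(values))
            stop("labels length must equal the number of embedding rows")
        if (is.null(nClasses)) nClasses <- max(labels) + 1L
        .checkLabels(labels, as.integer(nClasses))
        list(values = values, labels = labels, C = as.integer(nClasses))
    }
}
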