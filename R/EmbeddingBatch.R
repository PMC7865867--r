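#' Construct an EmbeddingBatch
#'
#' @param values numeric matrix with `Nb` rows (samples) and `l` columns
#'   (embedding dimensions), all values finite.  Note the transpose relative
#'   to the underlying container: user-facing embeddings are row-per-sample,
#'   matching the delimited-text interchange format.
#' @param labels integer vector of length `Nb`; 0-based class labels.
#' @param nClasses number of classes `C`; defaults to `max(labels) + 1`.
#' @return an [EmbeddingBatch-class] object.
#' @examples
#' eb <- EmbeddingBatch(rbind(c(1, 0), c(0.6, 0.8), c(0, 1)),
#'                      labels = c(0, 0, 1))
#' embeddingMatrix(eb)
#' sampleLabels(eb)
#' @export
EmbeddingBatch <- function(values, labels, nClasses = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("embedding values must be numeric")
    storage.mode(values) <- "double"
    labels <- .asLabels(labels)
    if (length(labels) != nrow(values))
        stop(sprintf("got %d labels for %d embedding rows",
                     length(labels), nrow(values)))
    if (is.null(nClasses)) nClasses <- max(labels) + 1L
    nClasses <- as.integer(nClasses)
    .checkLabels(labels, nClasses)
    assay <- t(values)
    dimnames(assay) <- list(NULL, NULL)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(embeddings = assay),
        colData = S4Vectors::DataFrame(label = labels),
        metadata = list(nClasses = nClasses))
    new("EmbeddingBatch", se)
}

#' Accessors for EmbeddingBatch
#'
#' `embeddingMatrix()` returns the raw embeddings as an `Nb x l` matrix
#' (samples in rows), `sampleLabels()` the 0-based class labels,
#' `nClasses()` the number of classes, `nSamples()` the batch size `Nb`, and
#' `embeddingDim()` the embedding length `l`.
#'
#' @param x an [EmbeddingBatch-class].
#' @return see description.
#' @name EmbeddingBatch-accessors
NULL

#' @rdname EmbeddingBatch-accessors
#' @export
embeddingMatrix <- function(x) {
    stopifnot(is(x, "EmbeddingBatch"))
    t(SummarizedExperiment::assay(x, "embeddings"))
}

#' @rdname EmbeddingBatch-accessors
#' @export
sampleLabels <- function(x) {
    stopifnot(is(x, "EmbeddingBatch"))
    SummarizedExperiment::colData(x)$label
}

#' @rdname EmbeddingBatch-accessors
#' @export
nClasses <- function(x) {
    stopifnot(is(x, "EmbeddingBatch"))
    S4Vectors::metadata(x)$nClasses
}

#' @rdname EmbeddingBatch-accessors
#' @export
nSamples <- function(x) {
    stopifnot(is(x, "EmbeddingBatch"))
    ncol(x)
}

#' @rdname EmbeddingBatch-accessors
#' @export
embeddingDim <- function(x) {
    stopifnot(is(x, "EmbeddingBatch"))
    nrow(x)
}

setMethod("show", "EmbeddingBatch", function(object) {
    lab <- sampleLabels(object)
    cat(sprintf("EmbeddingBatch: %d samples x %d dims, %d classes\n",
                ncol(object), nrow(object), nClasses(object)))
    cat("class counts:",
        paste(sprintf("%d:%d", seq_len(nClasses(object)) - 1L,
                      tabulate(lab + 1L, nClasses(object))), collapse = " "),
        "\n")
})

#' Read an EmbeddingBatch from delimited text
#'
#' Embeddings are read from a headerless delimited file with one sample per
#' row; labels from a single-column file of integers aligned by row.  Labels
#' may be 0- or 1-based: by default they are used as-is (0-based); set
#' `oneBased = TRUE` to convert.
#'
#' @param valuesFile path to the embeddings CSV.
#' @param labelsFile path to the labels CSV.
#' @param sep field separator (default comma).
#' @param oneBased whether labels in the file are 1-based.
#' @param nClasses number of classes; defaults to the maximum label + 1.
#' @return an [EmbeddingBatch-class].
#' @export
readEmbeddingBatch <- function(valuesFile, labelsFile, sep = ",",
                               oneBased = FALSE, nClasses = NULL) {
    values <- as.matrix(utils::read.table(valuesFile, sep = sep,
                                          header = FALSE))
    labels <- utils::read.table(labelsFile, sep = sep, header = FALSE)[[1L]]
    labels <- as.integer(labels)
    if (oneBased) labels <- labels - 1L
    EmbeddingBatch(values, labels, nClasses = nClasses)
}
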