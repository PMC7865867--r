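## split items into train/validation/test, stratified by class.
## valFromTrain = FALSE mimics protocols that carve validation out of the
## test set instead (leakage-prone; off by default).
.makeSplit <- function(classLabels, trainFrac = 0.8, valFrac = 0.1,
                       valFromTrain = TRUE) {
    n <- length(classLabels)
    split <- factor(rep("train", n),
                    levels = c("train", "validation", "test"))
    for (cl in unique(classLabels)) {
        idx <- which(classLabels == cl)
        nTest <- max(1L, round(length(idx) * (1 - trainFrac)))
        test <- idx[seq_len(nTest)]  # deterministic: leading block per class
        split[test] <- "test"
        pool <- if (valFromTrain) setdiff(idx, test) else test
        nVal <- max(1L, round(length(idx) * valFrac))
        nVal <- min(nVal, length(pool) - 1L)
        if (nVal > 0L) split[pool[seq_len(nVal)]] <- "validation"
    }
    split
}

#' Generate class/subgroup-structured embeddings on the unit sphere
#'
#' Draws each subgroup's rows around a distinct unit-norm center with
#' isotropic Gaussian noise.  Class centers are mutually orthogonal when the
#' embedding length allows (`l >= C`), so classes are well separated; each
#' subgroup center is a perturbation of its class center
#' (`groupSpread` controls how far subgroups sit from the class center,
#' re-normalized to the sphere).  With `spread = 0` all rows of a subgroup
#' equal its center exactly.
#'
#' @param nClasses number of classes C.
#' @param groupsPerClass subgroups per class.
#' @param nPerGroup rows per subgroup.
#' @param l embedding length.
#' @param spread isotropic noise scale around each subgroup center.
#' @param seed integer seed; regeneration is byte-identical.
#' @param groupSpread perturbation scale of subgroup centers around their
#'   class center (default 0.3; 0 collapses subgroups onto the class
#'   center).
#' @param trainFrac,valFrac,valFromTrain split parameters, see Details in
#'   [makeSyntheticImages()].
#' @return a [SyntheticDataset-class] holding embeddings.
#' @examples
#' d <- makeBlobEmbeddings(2, 2, 10, 8, spread = 0.05, seed = 1)
#' table(d@classLabels, d@groupLabels)
#' @export
makeBlobEmbeddings <- function(nClasses, groupsPerClass, nPerGroup, l,
                               spread = 0.1, seed = 1L, groupSpread = 0.3,
                               trainFrac = 0.8, valFrac = 0.1,
                               valFromTrain = TRUE) {
    nClasses <- as.integer(nClasses)
    groupsPerClass <- as.integer(groupsPerClass)
    nPerGroup <- as.integer(nPerGroup); l <- as.integer(l)
    if (any(c(nClasses, groupsPerClass, nPerGroup, l) < 1L))
        stop("all counts must be >= 1")
    if (spread < 0) stop("spread must be nonnegative")
    n <- nClasses * groupsPerClass * nPerGroup
    withr::with_seed(as.integer(seed), {
        ## orthonormal class centers when possible (QR of a Gaussian matrix)
        if (l >= nClasses) {
            M <- matrix(stats::rnorm(l * nClasses), l, nClasses)
            classCenters <- t(qr.Q(qr(M))[, seq_len(nClasses), drop = FALSE])
        } else {
            M <- matrix(stats::rnorm(nClasses * l), nClasses, l)
            classCenters <- M / sqrt(rowSums(M^2))
        }
        values <- matrix(0, n, l)
        classLabels <- integer(n); groupLabels <- integer(n)
        row <- 0L; gid <- 0L
        for (cl in seq_len(nClasses)) {
            for (g in seq_len(groupsPerClass)) {
                gid <- gid + 1L
                gc <- classCenters[cl, ] +
                    groupSpread * stats::rnorm(l)
                gc <- gc / sqrt(sum(gc^2))
                noise <- matrix(stats::rnorm(nPerGroup * l), nPerGroup, l)
                values[row + seq_len(nPerGroup), ] <-
                    matrix(gc, nPerGroup, l, byrow = TRUE) + spread * noise
                classLabels[row + seq_len(nPerGroup)] <- cl - 1L
                groupLabels[row + seq_len(nPerGroup)] <- gid
                row <- row + nPerGroup
            }
        }
        split <- .makeSplit(classLabels, trainFrac, valFrac, valFromTrain)
        new("SyntheticDataset", embeddings = values,
            images = array(0, c(0, 0, 0)),
            classLabels = classLabels, groupLabels = groupLabels,
            split = split, seed = as.integer(seed))
    })
}

## deterministic grating pattern for one (class, subgroup) cell.
## orientation follows the class, frequency and phase follow the subgroup,
## plus a class-specific radial component so classes differ in structure,
## not just orientation.
.subgroupPattern <- function(size, classId, subId, nClasses) {
    xs <- matrix(seq(0, 1, length.out = size), size, size)
    ys <- t(xs)
    theta <- pi * (classId - 1L) / max(nClasses, 2L)
    freq <- 2 + 3 * subId
    phase <- subId * pi / 4
    u <- cos(theta) * xs + sin(theta) * ys
    r <- sqrt((xs - 0.5)^2 + (ys - 0.5)^2)
    0.5 + 0.25 * sin(2 * pi * freq * u + phase) +
        0.15 * cos(2 * pi * (classId + 1) * r)
}

#' Generate synthetic grayscale images with class and subgroup structure
#'
#' Each (class, subgroup) cell renders a distinct parametric texture — a
#' sinusoidal grating whose orientation follows the class and whose
#' frequency/phase follow the subgroup, plus a class-dependent radial
#' component — with additive Gaussian pixel noise.  Class sizes are taken
#' exactly as requested, so imbalanced multi-class compositions can be
#' emulated (e.g. `classSizes = c(1266, 3418, 920)`).  With `noise = 0` all
#' images of a subgroup are identical.
#'
#' Splits are stratified by class: `1 - trainFrac` of each class goes to
#' test, and by default the validation fraction is carved out of the
#' training portion (avoiding test leakage); `valFromTrain = FALSE` carves
#' it from the test portion instead.
#'
#' @param classSizes integer vector, items per class.
#' @param groupsPerClass subgroups per class (recycled; each >= 1, <= class
#'   size).
#' @param size image side length (>= 16).
#' @param noise pixel noise standard deviation.
#' @param seed integer seed.
#' @param trainFrac,valFrac,valFromTrain split parameters (defaults 0.8 /
#'   0.1 / TRUE).
#' @return a [SyntheticDataset-class] holding images.
#' @export
makeSyntheticImages <- function(classSizes, groupsPerClass = 2L, size = 32L,
                                noise = 0.05, seed = 1L, trainFrac = 0.8,
                                valFrac = 0.1, valFromTrain = TRUE) {
    classSizes <- as.integer(classSizes)
    nClasses <- length(classSizes)
    groupsPerClass <- rep(as.integer(groupsPerClass), length.out = nClasses)
    size <- as.integer(size)
    if (any(classSizes < 1L)) stop("class sizes must be >= 1")
    if (any(groupsPerClass < 1L) || any(groupsPerClass > classSizes))
        stop("groups per class must be >= 1 and <= the class size")
    if (size < 16L) stop("image side must be >= 16")
    n <- sum(classSizes)
    withr::with_seed(as.integer(seed), {
        images <- array(0, c(n, size, size))
        classLabels <- integer(n); groupLabels <- integer(n)
        row <- 0L; gid <- 0L
        for (cl in seq_len(nClasses)) {
            ## distribute the class over its subgroups as evenly as possible
            sizes <- diff(round(seq(0, classSizes[cl],
                                    length.out = groupsPerClass[cl] + 1L)))
            for (g in seq_len(groupsPerClass[cl])) {
                gid <- gid + 1L
                pat <- .subgroupPattern(size, cl, g, nClasses)
                for (k in seq_len(sizes[g])) {
                    row <- row + 1L
                    img <- pat
                    if (noise > 0)
                        img <- img + noise * matrix(stats::rnorm(size * size),
                                                    size, size)
                    images[row, , ] <- pmin(pmax(img, 0), 1)
                    classLabels[row] <- cl - 1L
                    groupLabels[row] <- gid
                }
            }
        }
        split <- .makeSplit(classLabels, trainFrac, valFrac, valFromTrain)
        new("SyntheticDataset", embeddings = matrix(numeric(0), 0L, 0L),
            images = images, classLabels = classLabels,
            groupLabels = groupLabels, split = split,
            seed = as.integer(seed))
    })
}

#' Named synthetic dataset presets
#'
#' * `"chest-like"`: three imbalanced classes sized 1266/3418/920 with two
#'   subgroups each, emulating a multi-class chest X-ray composition.
#' * `"rash-like"`: two classes sized 257/187 with two subgroups each,
#'   emulating a small two-class optical-image set.
#' * `"blobs"`: the desk-scale training preset — 2 classes x 2 subgroups,
#'   200 images per class at side 24.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param noise pixel noise level (default 0.05).
#' @return a [SyntheticDataset-class].
#' @export
syntheticPreset <- function(name = c("blobs", "chest-like", "rash-like"),
                            seed = 1L, noise = 0.05) {
    name <- match.arg(name)
    switch(name,
        "chest-like" = makeSyntheticImages(c(1266L, 3418L, 920L), 2L,
                                           size = 32L, noise = noise,
                                           seed = seed),
        "rash-like" = makeSyntheticImages(c(257L, 187L), 2L, size = 32L,
                                          noise = noise, seed = seed),
        "blobs" = makeSyntheticImages(c(200L, 200L), 2L, size = 24L,
                                      noise = noise, seed = seed))
}

setMethod("show", "SyntheticDataset", function(object) {
    kind <- if (nrow(object@embeddings) > 0L) {
        sprintf("embeddings (%d x %d)", nrow(object@embeddings),
                ncol(object@embeddings))
    } else {
        d <- dim(object@images)
        sprintf("images (%d x %d x %d)", d[1L], d[2L], d[3L])
    }
    cat(sprintf("SyntheticDataset: %s, %d classes, %d subgroups, seed %d\n",
                kind, length(unique(object@classLabels)),
                length(unique(object@groupLabels)), object@seed))
    print(table(split = object@split))
})

## single-image transforms (matrices); rotations are counterclockwise
.rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
.rot180 <- function(m) .rot90(.rot90(m))
.rot270 <- function(m) .rot90(.rot180(m))
.flipH <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
.flipV <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
.translate <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))  # zero padding
    srcR <- seq_len(nrow(m)) - dr
    srcC <- seq_len(ncol(m)) - dc
    okR <- srcR >= 1L & srcR <= nrow(m)
    okC <- srcC >= 1L & srcC <= ncol(m)
    out[okR, okC] <- m[srcR[okR], srcC[okC], drop = FALSE]
    out
}

#' Seven-transform image augmentation
#'
#' For each input image emits the original plus seven transformed copies —
#' rotations by 90, 180 and 270 degrees, horizontal and vertical flips, and
#' horizontal and vertical translations by `translationPx` pixels
#' (zero-padded) — enlarging the set eightfold (seven added copies per
#' original).  Rotations require square images.
#'
#' @param images `n x H x W` array of grayscale images.
#' @param labels optional label vector to replicate alongside the images.
#' @param translationPx translation magnitude in pixels (default 5).
#' @return list with `images` (`8n x H x W` array, originals first, then
#'   the seven transforms in the order above, grouped by transform) and
#'   `labels` (replicated, or NULL).
#' @export
augmentImages <- function(images, labels = NULL, translationPx = 5L) {
    d <- dim(images)
    if (length(d) != 3L) stop("images must be an n x H x W array")
    n <- d[1L]; H <- d[2L]; W <- d[3L]
    if (H != W)
        stop("rotations require square images; got non-square input")
    tp <- as.integer(translationPx)
    transforms <- list(
        identity,
        .rot90, .rot180, .rot270, .flipH, .flipV,
        function(m) .translate(m, 0L, tp),
        function(m) .translate(m, tp, 0L))
    out <- array(0, c(8L * n, H, W))
    for (t in seq_along(transforms)) {
        for (i in seq_len(n)) {
            out[(t - 1L) * n + i, , ] <- transforms[[t]](images[i, , ])
        }
    }
    list(images = out,
         labels = if (is.null(labels)) NULL else rep(labels, 8L))
}

#' Write a SyntheticDataset of images to PNG files with a manifest
#'
#' @param dataset an image-bearing [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return the manifest path (`manifest.csv` with columns path, label,
#'   group, split), invisibly.
#' @export
writeImageDataset <- function(dataset, dir) {
    stopifnot(is(dataset, "SyntheticDataset"))
    if (length(dataset@images) == 0L)
        stop("dataset holds embeddings, not images")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    n <- dim(dataset@images)[1L]
    paths <- file.path(dir, sprintf("img%05d.png", seq_len(n)))
    for (i in seq_len(n))
        png::writePNG(dataset@images[i, , ], paths[i])
    manifest <- data.frame(path = basename(paths),
                           label = dataset@classLabels,
                           group = dataset@groupLabels,
                           split = as.character(dataset@split))
    mPath <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, mPath, row.names = FALSE)
    invisible(mPath)
}

#' Read an image dataset written by [writeImageDataset()]
#'
#' @param dir directory containing `manifest.csv` and PNG files.
#' @return a [SyntheticDataset-class].
#' @export
readImageDataset <- function(dir) {
    manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
    n <- nrow(manifest)
    first <- png::readPNG(file.path(dir, manifest$path[1L]))
    if (length(dim(first)) == 3L) first <- first[, , 1L]
    images <- array(0, c(n, nrow(first), ncol(first)))
    for (i in seq_len(n)) {
        img <- png::readPNG(file.path(dir, manifest$path[i]))
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        images[i, , ] <- img
    }
    grp <- if ("group" %in% names(manifest)) as.integer(manifest$group)
           else as.integer(manifest$label) + 1L  # one group per class
    spl <- if ("split" %in% names(manifest))
        factor(manifest$split, levels = c("train", "validation", "test"))
    else .makeSplit(as.integer(manifest$label))
    new("SyntheticDataset", embeddings = matrix(numeric(0), 0L, 0L),
        images = images, classLabels = as.integer(manifest$label),
        groupLabels = grp, split = spl, seed = NA_integer_)
}
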