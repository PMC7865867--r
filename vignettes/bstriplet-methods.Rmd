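---
title: "Batch similarity-based triplet loss: model, mining strategy and design notes"
author: "BSTriplet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch similarity-based triplet loss: model, mining strategy and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BSTriplet)
```

## The problem

Small medical-image collections are too thin to train heavy classifiers,
and light-weight convolutional networks trained with plain cross-entropy
(CE) tend to overfit them.  Deep metric learning offers a remedy: add a
loss term that pulls same-class embeddings together and pushes
different-class embeddings apart, so the embedding space itself becomes
discriminative.  Classical triplet losses do this one (anchor, positive,
negative) triple at a time, which makes the gradient signal noisy and
requires a pairing rule that is awkward to combine with ordinary CE
training.

The *batch similarity-based triplet* (BSTriplet) loss implemented here
works on the whole batch at once.  It needs no pairing rule, attaches to
any network that exposes an embedding vector, and is combined additively
with CE.

## The loss

For a batch of $N_b$ raw embedding rows $f_i \in \mathbb{R}^l$ with class
labels $y_i \in \{0, \dots, C-1\}$:

1. Each row is L2-normalized, $\hat f_i = f_i / \lVert f_i \rVert_2$, so
   dot products are cosine similarities.
2. The similarity matrix $S = \hat f \hat f^{\mathsf T}$ collects all
   pairwise cosines (`similarityMatrix()`).
3. The binary pair matrix $B$, the outer product of one-hot label rows,
   marks same-class pairs (`binaryPairMatrix()`).
4. The discriminative matrix
   $D = S \circ (2B - \mathbf{1} - I)$
   keeps same-class similarities positive, negates cross-class ones, and
   zeroes the uninformative diagonal (`discriminativeMatrix()`).

The per-sample loss reads row $i$ of $D$:

$$
L_i \;=\; \max\!\Big(0,\; m
  \;-\; \tfrac{1}{N^+}\textstyle\sum_{j \in P_i} D_{ij}^2
  \;+\; \tfrac{1}{N^-}\textstyle\sum_{k \in N_i} D_{ik}^2\Big),
$$

where $P_i$/$N_i$ are the same-/different-class partners of sample $i$
and $m \in [0,1]$ is the margin.  The batch loss is the mean of the
$L_i$.  Squared similarities (rather than raw ones) give a smoother
gradient near the optimum; since every $|D_{ij}| \le 1$ each $L_i$ lies
in $[0, 1+m]$, with both bounds attained (identical positives and
orthogonal negatives give 0; the inverted arrangement gives exactly
$1+m$).  The combined training objective is
$L = L_{\mathrm{ce}} + \lambda \bar L_{\mathrm{trip}}$ with
$\lambda = 1$ by default, a weighting that works because both terms live
on comparable scales.

### Sign conventions and degenerate rows

Two printed forms of this construction circulating in the literature are
mutually inconsistent; the package implements the variant that actually
has the stated $[0, 1+m]$ range and the intended monotonicity (loss
non-increasing in same-class similarity, non-decreasing in cross-class
similarity — both property-tested):

* the cross-class term is *added* inside the hinge, not subtracted;
* the compact form of $D$ is $S \circ (2B - 1 - I)$, which zeroes the
  diagonal, rather than a Hadamard product *with* $I$, which would zero
  everything else.

A sample can lack positive partners ($N^+ = 0$) or negative partners
($N^- = 0$) in a batch; the loss is still well defined by substituting
the *ideal* value for the missing term (1 for the positive mean, 0 for
the negative mean), so the remaining constraint is enforced with no
constant bias.  Both fills are configurable via `bstConfig()`.  The only
genuinely unavailable case is $N_b = 1$, which errors.

Numerical guards: rows with norm $\le 10^{-12}$ cannot be normalized and
raise a degenerate-input error naming the row; cross-entropy clips
probabilities at $10^{-12}$ before the log; the hinge subgradient exactly
at the kink is taken as 0 (the inactive side).

One ambiguity is accepted as-is: squaring makes the positive-pair term
sign-blind (a similarity of $-1$ also gives squared value 1).  The loss
is implemented per the formula; in practice CE breaks this symmetry.

### Gradient

Training needs $\partial \bar L / \partial f$ with respect to the *raw*
embeddings.  Writing $G = \partial \bar L / \partial S$ (nonzero only in
rows with an active hinge, with entries $\mp 2 S_{ij} / (N_b N^{\pm}_i)$
on positive/negative partners), the chain rule through
$S = \hat f \hat f^{\mathsf T}$ gives
$\partial \bar L / \partial \hat f = (G + G^{\mathsf T})\hat f$, and the
normalization Jacobian $(I - \hat f_i \hat f_i^{\mathsf T}) / \lVert f_i
\rVert$ maps this to raw rows.  A direct consequence is that the gradient
of each row is orthogonal to that row — scaling a row leaves the loss
unchanged, so there is no radial component.  The implementation is
verified against central finite differences (step $10^{-6}$, relative
error below $10^{-5}$) on seeded random batches away from hinge kinks,
and the whole matrix pipeline against a scalar pair-loop oracle at
$10^{-12}$.

## The batch-mining strategy

Batches that mirror the training-set distribution stabilize the estimate
of the data distribution that the loss relies on.  The four-step mining
strategy:

1. partition training samples by class (`partitionByClass()`);
2. cluster each class into subgroups (`clusterWithinClass()`; default 2
   per class, configurable per class);
3. record each subgroup's share of the training set
   (`miningPlan()`);
4. fill each batch with per-group quotas proportional to those shares,
   sampling uniformly without replacement within groups
   (`batchQuotas()`, `sampleBatch()`).

Design choices where the procedure is underdetermined:

* **Clustering features.** Raw images are clustered after downsampling to
  16×16 grayscale by block averaging, flattening and per-feature
  standardization (`imageFeatures()`); any precomputed feature matrix or
  assignment function can be plugged in instead.
* **Clustering algorithm.** Lloyd's K-means started from
  k-means++-style seeds, deterministic given the seed; `stats::kmeans`
  does the iterations.
* **Quota rounding.** `ratio * Nb` is rounded by the largest-remainder
  method (ties by ascending group id): totals are preserved exactly and
  the deviation from proportionality is minimal.  If `Nb` is smaller than
  the number of groups, some groups legitimately receive quota 0.
* **Replacement.** Sampling is without replacement within a batch and
  with replacement across batches of an epoch; small groups would
  otherwise be exhausted mid-epoch.

## Cost model

`bstFlops()` gives the closed-form operation count of one batch-loss
evaluation,
$(l^2 + C^2 + l + C + 3)N_b^2 + (2l + 5)N_b$,
itemized into normalization, similarity, one-hot encoding, binary matrix,
discriminative matrix, per-sample losses and averaging; the breakdown
summing exactly to the closed form is kept as a tested invariant.  The
counting convention is one FLOP per multiply, add, index or assignment,
with no fused operations.  `miningSetupFlops()` prices the one-off
mining setup as `clustering + Ntrn + g`; the clustering cost stays an
abstract caller-supplied integer since it depends entirely on the chosen
algorithm.

## Metrics

Accuracy is implemented as fraction correct, $\sum_i TP_i / N'$.  (A
printed formula that adds the per-class true negatives into the numerator
would exceed 1 for $C \ge 3$; the published percentages are consistent
with fraction-correct, so that is what the package computes.)
Sensitivity and specificity are one-vs-rest per class with macro means;
classes with no true members (or non-members) yield `NA` with a warning
and are excluded from the mean.  AUC uses the midrank (Mann–Whitney)
convention, macro-averaged one-vs-rest for multiclass problems — the
multiclass averaging method is a package choice, documented as such, and
is cross-checked in the tests against brute-force pair counting and an
independent ROC implementation.  `pcaProjection()` provides the usual
2-d embedding view with a deterministic sign convention
(largest-magnitude loading positive).  `clusteringGap()` condenses the
PCA picture into a scalar: mean same-class minus mean cross-class cosine
similarity over all pairs.

## Synthetic data

Because the loss's natural habitat is multi-thousand-image clinical
collections that cannot ship with a package, testability rests on
generators whose structure is known exactly:

* `makeBlobEmbeddings()` draws each subgroup around a distinct
  unit-norm center (class centers orthogonal when the dimension allows;
  subgroup centers perturbed from them by `groupSpread`, default 0.3)
  with isotropic noise `spread`.  With `spread = 0` the within-group
  cosine similarity is exactly 1 — the ideal-clustering limit where the
  loss must vanish for any margin.
* `makeSyntheticImages()` renders one parametric texture per
  (class, subgroup) cell — grating orientation follows the class,
  frequency/phase the subgroup, plus a class-dependent radial component —
  with additive Gaussian pixel noise.  Class sizes are taken exactly as
  requested, so imbalanced compositions (the `chest-like` preset uses
  1266/3418/920 with two subgroups per class) are reproduced.
* `augmentImages()` applies the seven standard transforms (rotations by
  90/180/270 degrees, horizontal/vertical flips, horizontal/vertical
  translations by 5 pixels, zero-padded) and keeps the original, i.e.
  seven added copies per image.  The "enlarged seven-fold" recipe is
  ambiguous between 7 added copies and ×7 total; seven *added* copies is
  implemented because exactly seven transforms are enumerated.

These generators emulate class imbalance, within-class subgroup
structure, and controllable separation-to-noise ratios.  They do **not**
emulate the content of real radiographs or histology: backgrounds,
acquisition artifacts, label noise and inter-observer variability are
absent, and subgroups are cleanly parametric.  Passing tests therefore
demonstrate that the implementation is correct and that the loss behaves
as designed on data with this structure — not that the published clinical
accuracies are reproduced.  Replicating those would require the original
Kaggle/TCIA datasets and GPU-scale training of the published backbones,
which is outside this package's scope; only arithmetic identities that
depend purely on printed table values are checked exactly.

## The training harness

`trainClassifier()` exists so the three objectives (CE, CE + regular
triplet, CE + BSTriplet) can be compared end to end on a CPU in minutes.
The reference model is a deliberately small convolutional network — two
3×3 blocks of 8 and 16 filters with ReLU and 2×2 max-pooling, global
average pooling as the embedding ($l = 16$), then a linear softmax head —
implemented directly in R (im2col convolutions, so forward and backward
are matrix products).  Choices the protocol leaves open:

* **Optimizer:** Adam, with the schedule applied to its learning rate.
* **Schedule:** initial rate 0.001, multiplied by 0.3 when the training
  loss has not improved by more than $10^{-4}$ for 20 consecutive epochs
  (the improvement threshold mirrors the early-stopping delta, which is
  the only delta the protocol states), floored at $10^{-8}$; at most 400
  epochs; early stop after 30 consecutive epochs without $10^{-4}$
  validation improvement.
* **Validation split:** carved from the *training* portion by default.
  Drawing validation images from the test set — as small-sample protocols
  sometimes do — leaks information; a `valFromTrain = FALSE` flag in the
  generators mimics that protocol for comparison.
* **Triplet baseline pairing:** one random positive and one random
  negative per anchor, drawn from the seeded stream; anchors lacking
  either partner are skipped.
* **Monitored validation loss:** CE plus the BST term for `ce+bst` (the
  full set treated as one batch), CE alone otherwise — the random-pairing
  triplet term would add noise to the early-stopping signal.

Runs are fully reproducible from the seed.  The desk-scale experiment
shipped in the tests and the acceptance script uses the `blobs` preset
(2 classes × 2 subgroups, 200 images per class at side 24, pixel noise
0.05), 5 seeds × 30 epochs, batch size 36: a size chosen so the full
comparison finishes in minutes on one CPU while still showing the effect.
Under it, the median clustering gap of the test-set embeddings is
consistently higher with the BST term than with CE alone — the package's
testable restatement of the published PCA clustering-effect figure.

## Known limitations

* The built-in network is a reference implementation for correctness and
  small-scale comparison, not a performance model; no GPU path exists.
* Multiclass AUC is macro one-vs-rest by choice; other conventions
  (pairwise, prevalence-weighted) would give different numbers.
* K-means subgroup discovery inherits K-means' limitations (isotropic
  clusters, fixed k per class); the assignment hook exists precisely so
  better structure finders can be substituted.
* The FLOP model counts the loss's arithmetic only; it says nothing about
  memory traffic or the network's own cost.

## A worked session

```{r worked}
X <- rbind(c(1, 0), c(0.6, 0.8), c(0, 1))
labels <- c(0, 0, 1)
res <- bstLoss(X, labels, bstConfig(margin = 0.9))
res@perSample
res@batchMean

est <- bstFlops(l = 1280, nClasses = 3, batchSize = 36)
est@total

d <- makeBlobEmbeddings(2, 2, 20, 8, spread = 0.05, seed = 1)
clusteringGap(d@embeddings, d@classLabels)
```
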