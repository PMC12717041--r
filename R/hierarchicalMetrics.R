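#' @useDynLib salt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.volData <- function(x) if (is(x, "LabelVolume") || is(x, "ImageVolume")) x@data else x

#' Hierarchical Dice evaluation in encoded space
#'
#' Computes, for every tree node, the Dice coefficient between prediction and
#' reference where a voxel belongs to node `n` whenever `n` is an
#' ancestor-or-self of the voxel's label — so a correctly placed parent earns
#' credit even when the child is wrong, and on a flat tree the scores equal
#' conventional per-class Dice. The comparison runs entirely in the bitwise
#' encoded space: the two volumes are reduced to joint label counts once, and
#' per-node membership is resolved by masked code comparisons on the label
#' table, never by materializing per-node masks at full resolution.
#'
#' Nodes absent from both volumes are reported `NA` (not applicable) and
#' excluded from summary means.
#'
#' @param pred,ref [LabelVolume-class] objects (or integer arrays) on the
#'   same grid; 0 = unlabeled, counted as belonging to no node.
#' @param tree the [LabelTree-class].
#' @param encoding optional precomputed [PathEncoding-class].
#' @return data.frame with columns `node`, `dice`, `n_pred`, `n_ref`, plus
#'   attribute `"meanDice"` (mean over applicable non-root nodes).
#' @export
hierarchicalDice <- function(pred, ref, tree, encoding = encodePaths(tree)) {
  pv <- .volData(pred); rv <- .volData(ref)
  if (!identical(dim(pv), dim(rv))) stop("prediction and reference grids differ")
  if (is(pred, "LabelVolume") && is(ref, "LabelVolume") &&
      length(pred@spacing) && length(ref@spacing) &&
      !isTRUE(all.equal(pred@spacing, ref@spacing)))
    stop("prediction and reference voxel spacings differ")
  n <- nNodes(tree)

  # joint counts over (pred label, ref label) pairs; labels 0..N
  joint <- table(factor(as.vector(pv), levels = 0:n),
                 factor(as.vector(rv), levels = 0:n))
  joint <- matrix(as.numeric(joint), n + 1L, n + 1L)
  cntP <- rowSums(joint); cntR <- colSums(joint)

  # membership[l, n]: does label l belong to node n?  (masked code test)
  member <- matrix(FALSE, n + 1L, n)
  for (node in seq_len(n)) {
    member[1L + seq_len(n), node] <-
      isAncestorEncoded(encoding, node, seq_len(n))
  }

  dice <- rep(NA_real_, n)
  nP <- nR <- numeric(n)
  for (node in seq_len(n)) {
    mem <- member[, node]
    nP[node] <- sum(cntP[mem]); nR[node] <- sum(cntR[mem])
    if (nP[node] + nR[node] == 0) next   # not applicable
    inter <- sum(joint[mem, mem])
    dice[node] <- 2 * inter / (nP[node] + nR[node])
  }
  out <- data.frame(node = tree@name, dice = dice, n_pred = nP, n_ref = nR,
                    stringsAsFactors = FALSE)
  nonRoot <- setdiff(seq_len(n), rootIndex(tree))
  attr(out, "meanDice") <- mean(dice[nonRoot], na.rm = TRUE)
  out
}

# 6-connected boundary: mask voxels with at least one face-neighbour outside
.boundary6 <- function(mask) {
  d <- dim(mask)
  inside <- mask
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
    out
  }
  erod <- mask
  for (ax in 1:3) for (by in c(-1L, 1L)) erod <- erod & shift(mask, ax, by)
  mask & !erod
}

#' Euclidean distance transform with anisotropic spacing
#'
#' Exact physical distance (mm) from every voxel to the nearest `TRUE` voxel
#' of `mask`, computed by the separable lower-envelope algorithm; all-`FALSE`
#' masks give `Inf` everywhere.
#'
#' @param mask logical 3-D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return numeric array of distances in mm.
#' @export
distanceTransform <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3-D array")
  sq <- .edt3d(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(sqrt(sq), dim = d)
}

#' Normalized surface Dice (NSD)
#'
#' The fraction of boundary voxels of each segmentation lying within a
#' physical tolerance of the other segmentation's boundary, symmetrized:
#' `(|{p in bP : d(p, bR) <= tol}| + |{r in bR : d(r, bP) <= tol}|) /
#' (|bP| + |bR|)`. Boundaries are 6-connected (voxels of the mask with a
#' face-neighbour outside); distances are exact Euclidean distances between
#' voxel centers respecting anisotropic spacing. Default tolerance 3 mm.
#' If exactly one mask has an empty surface the score is 0; if both are
#' empty it is 1 (identical nothing).
#'
#' @param pred,ref logical/0-1 3-D arrays on the same grid.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param tolerance surface tolerance in mm (default 3).
#' @return score in \[0, 1\].
#' @export
nsd <- function(pred, ref, spacing = c(1, 1, 1), tolerance = 3) {
  pred <- .volData(pred) > 0; ref <- .volData(ref) > 0
  if (!identical(dim(pred), dim(ref))) stop("grids differ")
  bP <- .boundary6(pred); bR <- .boundary6(ref)
  nP <- sum(bP); nR <- sum(bR)
  if (nP == 0L && nR == 0L) return(1)
  if (nP == 0L || nR == 0L) return(0)
  dToR <- distanceTransform(bR, spacing)
  dToP <- distanceTransform(bP, spacing)
  (sum(dToR[bP] <= tolerance) + sum(dToP[bR] <= tolerance)) / (nP + nR)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples per-case scores with replacement `nRounds` times, takes the mean
#' of each resample, and returns the empirical 2.5 and 97.5 percentiles
#' (95% interval by default) of those means. Seed-reproducible.
#'
#' @param scores numeric vector of per-case scores.
#' @param nRounds bootstrap rounds (default 1000).
#' @param seed optional integer seed.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrapCI <- function(scores, nRounds = 1000, seed = NULL, level = 0.95) {
  if (!length(scores)) stop("empty score vector")
  if (!is.null(seed)) set.seed(seed)
  k <- length(scores)
  means <- vapply(seq_len(nRounds), function(i)
    mean(scores[sample.int(k, k, replace = TRUE)]), numeric(1))
  a <- (1 - level) / 2
  q <- quantile(means, probs = c(a, 1 - a), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Full evaluation report for a predicted labeling
#'
#' Per-node hierarchical Dice and NSD (the NSD of each node's
#' ancestor-or-self membership mask) plus summary means; the workhorse behind
#' the `salt eval` command line.
#'
#' @inheritParams hierarchicalDice
#' @param spacing voxel spacing in mm (taken from `pred` if a
#'   [LabelVolume-class] with spacing).
#' @param tolerance NSD tolerance in mm.
#' @param nsdNodes optional node subset (indices or names) for the NSD
#'   column; defaults to all non-root nodes present in either volume.
#' @return data.frame `(node, dice, nsd, n_pred, n_ref)` with attribute
#'   `"summary"` (mean dice, mean nsd).
#' @export
evaluationReport <- function(pred, ref, tree, spacing = NULL, tolerance = 3,
                             nsdNodes = NULL) {
  if (is.null(spacing)) {
    spacing <- if (is(pred, "LabelVolume") && length(pred@spacing))
      pred@spacing else c(1, 1, 1)
  }
  enc <- encodePaths(tree)
  rep <- hierarchicalDice(pred, ref, tree, enc)
  pv <- .volData(pred); rv <- .volData(ref)
  reach <- treeMatrices(tree)@reachability
  if (is.null(nsdNodes)) {
    nsdNodes <- which(!is.na(rep$dice))
  } else if (is.character(nsdNodes)) nsdNodes <- match(nsdNodes, tree@name)
  nsdNodes <- setdiff(nsdNodes, rootIndex(tree))
  rep$nsd <- NA_real_
  lut0 <- function(node) c(FALSE, reach[node, ] == 1L)  # label 0..N lookup
  for (node in nsdNodes) {
    mem <- lut0(node)
    rep$nsd[node] <- nsd(array(mem[pv + 1L], dim(pv)),
                         array(mem[rv + 1L], dim(rv)),
                         spacing = spacing, tolerance = tolerance)
  }
  rep <- rep[, c("node", "dice", "nsd", "n_pred", "n_ref")]
  attr(rep, "summary") <- c(meanDice = mean(rep$dice[-rootIndex(tree)], na.rm = TRUE),
                            meanNSD = mean(rep$nsd, na.rm = TRUE))
  rep
}
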