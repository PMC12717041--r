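#' Encode a label map into hierarchical supervision targets
#'
#' Maps each voxel's node label to its reachability vector: the multi-hot
#' target activates not only the labeled node but every ancestor up to the
#' root, so fine-grained predictions are supervised conditionally on their
#' coarser context. Labels may be internal nodes (partial-depth supervision,
#' as in mixed sparse/dense datasets); voxels with `mask == 0` or label 0 are
#' left unsupervised.
#'
#' @param labels a [LabelVolume-class] or integer array of node indices
#'   (0 = unlabeled).
#' @param tree the [LabelTree-class].
#' @param mask optional 0/1 array of the same shape; defaults to
#'   `labels > 0`.
#' @return a [TargetField-class].
#' @export
encodeTargets <- function(labels, tree, mask = NULL) {
  lab <- if (is(labels, "LabelVolume")) labels@data else labels
  if (is.null(dim(lab))) dim(lab) <- length(lab)
  if (is.null(mask)) mask <- array(as.integer(lab > 0L), dim = dim(lab))
  else {
    mask <- array(as.integer((if (is(mask, "LabelVolume")) mask@data else mask) > 0L),
                  dim = dim(lab))
    mask[lab <= 0L] <- 0L
  }
  bad <- lab[mask > 0L]
  if (length(bad) && (any(bad < 1L) || any(bad > nNodes(tree))))
    stop("unknown label index in supervised voxels")
  lab2 <- lab
  lab2[mask == 0L] <- rootIndex(tree)   # placeholder, never read
  new("TargetField", label = array(as.integer(lab2), dim = dim(lab)),
      mask = mask, tree = tree)
}

#' Multi-hot reachability encoding of a target field
#'
#' @param targets a [TargetField-class].
#' @return V x N 0/1 matrix; row v is the reachability column of voxel v's
#'   deepest label (all-zero for unsupervised voxels).
#' @export
multiHot <- function(targets) {
  tree <- targets@tree
  reach <- treeMatrices(tree)@reachability
  m <- t(reach)[as.vector(targets@label), , drop = FALSE]
  m[as.vector(targets@mask) == 0L, ] <- 0L
  storage.mode(m) <- "integer"
  m
}

.lossPrep <- function(field, targets) {
  tree <- field@tree
  n <- nNodes(tree)
  p <- .flattenField(field@data, n)$mat
  lab <- as.vector(targets@label)
  msk <- as.vector(targets@mask) > 0L
  if (length(lab) != nrow(p)) stop("field and target shapes differ")
  list(tree = tree, p = p, lab = lab, msk = msk)
}

#' Path cross-entropy over supervised voxels
#'
#' The cross-entropy of the chained probability of each voxel's deepest
#' target node: `-log p[deepest]`, averaged over supervised voxels. Because
#' the chained probability is the product of sibling-softmax conditionals
#' along the target path, this equals the sum of per-sibling-group
#' cross-entropies along that path, and reduces to the standard categorical
#' cross-entropy on a flat tree. Internal-node targets penalize only the path
#' down to that node. An empty supervision mask yields 0 with a warning.
#'
#' @param field a [ProbabilityField-class] from [saltActivation()].
#' @param targets a [TargetField-class] from [encodeTargets()].
#' @return scalar loss.
#' @export
pathCrossEntropy <- function(field, targets) {
  x <- .lossPrep(field, targets)
  if (!any(x$msk)) {
    warning("empty supervision mask; cross-entropy defined as 0")
    return(0)
  }
  v <- which(x$msk)
  pt <- x$p[cbind(v, x$lab[v])]
  mean(-log(pmax(pt, .Machine$double.xmin)))
}

#' Tree soft-Dice loss
#'
#' For every non-root node, the soft Dice between its predicted probability
#' channel and its multi-hot target over supervised voxels, with additive
#' smoothing `eps` in numerator and denominator; the loss is one minus the
#' mean over included nodes. A node is included when it is present in the
#' target; nodes absent from the target are included only if the prediction
#' assigns them at least one voxel-equivalent of probability mass (so
#' materially false-positive nodes are penalized while untouched classes do
#' not dilute the mean). An empty supervision mask yields 0 with a warning.
#'
#' @inheritParams pathCrossEntropy
#' @param eps smoothing constant (default 1e-5).
#' @return scalar loss in \[0, 1\].
#' @export
treeSoftDice <- function(field, targets, eps = 1e-5) {
  x <- .lossPrep(field, targets)
  if (!any(x$msk)) {
    warning("empty supervision mask; Dice loss defined as 0")
    return(0)
  }
  v <- which(x$msk)
  p <- x$p[v, , drop = FALSE]
  m <- multiHot(targets)[v, , drop = FALSE]
  nodes <- setdiff(seq_len(nNodes(x$tree)), rootIndex(x$tree))
  sumP <- colSums(p)[nodes]; sumT <- colSums(m)[nodes]
  inter <- colSums(p * m)[nodes]
  include <- sumT > 0 | sumP >= 1
  if (!any(include)) return(0)
  dice <- (2 * inter[include] + eps) / (sumP[include] + sumT[include] + eps)
  1 - mean(dice)
}

#' Hybrid hierarchical loss
#'
#' Weighted sum of [pathCrossEntropy()] and [treeSoftDice()], the training
#' objective used with the SALT activation (default weights 1 and 1, the
#' common practice for segmentation hybrids).
#'
#' @inheritParams treeSoftDice
#' @param wCE,wDice non-negative component weights.
#' @return scalar loss; the components are attached as attribute
#'   `"components"` for logging.
#' @export
hybridLoss <- function(field, targets, wCE = 1, wDice = 1, eps = 1e-5) {
  if (wCE < 0 || wDice < 0) stop("loss weights must be non-negative")
  ce <- pathCrossEntropy(field, targets)
  dc <- treeSoftDice(field, targets, eps = eps)
  structure(wCE * ce + wDice * dc, components = c(ce = ce, dice = dc))
}

#' Hybrid loss and its gradient with respect to raw scores
#'
#' Evaluates the SALT activation, the hybrid loss, and the analytic gradient
#' of the loss with respect to the raw score field in one pass — the
#' backpropagation rule of the conditional-softmax layer. Used by
#' [trainToySegmenter()] and by finite-difference checks.
#'
#' The chain rule through the activation uses only the reachability matrix:
#' with conditionals `q`, chained probabilities `p` and parent map `par`,
#' `d p[n] / d s[j] = p[n] (R[j, n] - q[j] R[par(j), n])`, so the Dice part
#' contracts to two sparse matrix products; the cross-entropy part is the
#' usual softmax-minus-target within every sibling group along the path.
#'
#' @param scores numeric array `(..., N)` of raw scores.
#' @param tree the [LabelTree-class].
#' @param targets a [TargetField-class].
#' @inheritParams hybridLoss
#' @return list with `loss`, `ce`, `dice`, and `grad` (same shape as
#'   `scores`).
#' @export
saltLossGradient <- function(scores, tree, targets, wCE = 1, wDice = 1,
                             eps = 1e-5) {
  n <- nNodes(tree)
  f <- .flattenField(scores, n)
  q <- .flattenField(conditionalProbabilities(scores, tree), n)$mat
  field <- chainProbabilities(array(q, dim = c(nrow(q), n)), tree)
  p <- field@data
  dim(p) <- c(nrow(q), n)
  lab <- as.vector(targets@label)
  msk <- as.vector(targets@mask) > 0L
  v <- which(msk)
  nSup <- length(v)
  root <- rootIndex(tree)
  par <- tree@parent
  grad <- matrix(0, nrow(q), n)

  M <- multiHot(targets)   # V x N

  # cross-entropy value + gradient
  ce <- 0
  if (nSup > 0L) {
    pt <- p[cbind(v, lab[v])]
    ce <- mean(-log(pmax(pt, .Machine$double.xmin)))
    notRoot <- which(!is.na(par))
    # a sibling group enters the loss only when its parent is a STRICT
    # ancestor of the target (the path must continue past it), so
    # grad[v, j] = (q[v, j] - M[v, j]) * S[v, par(j)] / nSup with
    # S = multi-hot minus the target node itself
    S <- M
    S[cbind(v, lab[v])] <- 0L
    gCE <- matrix(0, nrow(q), n)
    gCE[, notRoot] <- (q[, notRoot, drop = FALSE] -
                         M[, notRoot, drop = FALSE]) *
      S[, par[notRoot], drop = FALSE] / nSup
    gCE[!msk, ] <- 0
    grad <- grad + wCE * gCE
  }

  # Dice value + gradient
  dice <- 0
  if (nSup > 0L) {
    pv <- p[v, , drop = FALSE]; mv <- M[v, , drop = FALSE]
    nodes <- setdiff(seq_len(n), root)
    sumP <- colSums(pv); sumT <- colSums(mv); inter <- colSums(pv * mv)
    include <- rep(FALSE, n)
    include[nodes] <- sumT[nodes] > 0 | sumP[nodes] >= 1
    k <- sum(include)
    if (k > 0L) {
      num <- 2 * inter + eps; den <- sumP + sumT + eps
      dice <- 1 - mean((num / den)[include])
      # dL/dp[v, n] = -(1/k) * (2 m[v, n] * den - num) / den^2 on included n
      coefA <- ifelse(include, -(2 / k) / den, 0)         # times m[v, n]
      coefB <- ifelse(include, (num / den^2) / k, 0)      # constant in v
      G <- matrix(0, nrow(q), n)
      G[v, ] <- sweep(mv, 2, coefA, "*") + matrix(coefB, nSup, n, byrow = TRUE)
      H <- G * p
      R <- .reachabilitySparse(tree)
      A <- as.matrix(H %*% Matrix::t(R))    # A[v, j] = sum_n H[v, n] R[j, n]
      # sum over siblings of j of R[a, n] is the STRICT-ancestor indicator
      # of par(j), hence the -H correction: A' = A - H
      notRoot <- which(!is.na(par))
      gD <- matrix(0, nrow(q), n)
      gD[, notRoot] <- A[, notRoot, drop = FALSE] -
        q[, notRoot, drop = FALSE] *
          (A - H)[, par[notRoot], drop = FALSE]
      grad <- grad + wDice * gD
    }
  }
  list(loss = wCE * ce + wDice * dice, ce = ce, dice = dice,
       grad = .unflattenField(grad, f$spatial))
}
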