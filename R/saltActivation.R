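# Flatten an (..., N) array to a V x N matrix and remember the shape.
.flattenField <- function(x, n) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (d[length(d)] != n) stop("channel count does not match tree size")
  spatial <- d[-length(d)]
  list(mat = matrix(x, ncol = n), spatial = spatial)
}

.unflattenField <- function(mat, spatial) {
  array(mat, dim = c(spatial, ncol(mat)))
}

.fieldData <- function(x) if (is(x, "ScoreField") || is(x, "ProbabilityField")) x@data else x

#' Sibling-group conditional probabilities
#'
#' Normalizes raw per-node scores into conditional probabilities: within every
#' sibling group the scores pass through a softmax (numerically stabilized by
#' per-group max subtraction), so the conditionals of each group sum to 1 at
#' every voxel. The root is not part of any group and gets conditional 1.
#' A singleton group likewise yields conditional 1 regardless of its score.
#'
#' @param scores a [ScoreField-class] or a numeric array `(..., N)` with one
#'   channel per tree node on the last axis.
#' @param tree the [LabelTree-class] (ignored if `scores` is a `ScoreField`).
#' @return numeric array of the same shape holding conditionals.
#' @export
conditionalProbabilities <- function(scores, tree = NULL) {
  if (is(scores, "ScoreField")) { tree <- scores@tree; scores <- scores@data }
  if (is.null(tree)) stop("a LabelTree is required")
  n <- nNodes(tree)
  f <- .flattenField(scores, n)
  s <- f$mat
  if (any(!is.finite(s))) stop("scores must be finite")
  q <- matrix(0, nrow(s), n)
  q[, rootIndex(tree)] <- 1
  for (g in siblingGroups(tree)) {
    if (length(g) == 1L) { q[, g] <- 1; next }
    block <- s[, g, drop = FALSE]
    m <- do.call(pmax, c(as.data.frame(block), list(na.rm = FALSE)))
    e <- exp(block - m)
    q[, g] <- e / rowSums(e)
  }
  .unflattenField(q, f$spatial)
}

#' Chain conditional probabilities along root paths
#'
#' Turns per-node conditionals into unconditional node probabilities: the
#' probability of a node is the product of the conditionals of every node on
#' its root path. The product is evaluated in log space as a single sparse
#' reachability-matrix multiply (`log p = log q %*% R`), which keeps deep
#' trees free of underflow. The result obeys hierarchical consistency: the
#' root has probability 1, children of a node sum to that node's probability,
#' and no node ever exceeds its parent.
#'
#' @param conditionals numeric array `(..., N)` from
#'   [conditionalProbabilities()].
#' @param tree the [LabelTree-class].
#' @return a [ProbabilityField-class].
#' @export
chainProbabilities <- function(conditionals, tree) {
  n <- nNodes(tree)
  f <- .flattenField(conditionals, n)
  logq <- log(pmax(f$mat, .Machine$double.xmin))
  logq[, rootIndex(tree)] <- 0
  R <- .reachabilitySparse(tree)
  logp <- as.matrix(logq %*% R)
  p <- exp(logp)
  p[, rootIndex(tree)] <- 1
  new("ProbabilityField", data = .unflattenField(p, f$spatial), tree = tree)
}

#' The SALT activation: conditional softmax over a label tree
#'
#' Composition of [conditionalProbabilities()] and [chainProbabilities()]:
#' raw network scores become hierarchically consistent node probabilities.
#' On a flat tree (root plus leaves) this reduces exactly to the standard
#' softmax over the leaves; on deeper trees a node can only receive
#' probability mass if all its ancestors do, and a depth-`d` chain of
#' uniform binary forks yields leaf probability `2^-d` (the vanishing-
#' probability effect of deep hierarchies).
#'
#' @inheritParams conditionalProbabilities
#' @return a [ProbabilityField-class].
#' @examples
#' tree <- parseLabelTree(list(list(name = "root"),
#'   list(name = "a", parent = "root"), list(name = "b", parent = "root")))
#' p <- saltActivation(array(c(0, 0), dim = c(1, 1, 1, 2)) , tree)
#' p@data  # 0.5 / 0.5: flat tree == softmax
#' @export
saltActivation <- function(scores, tree = NULL) {
  if (is(scores, "ScoreField")) { tree <- scores@tree; scores <- scores@data }
  chainProbabilities(conditionalProbabilities(scores, tree), tree)
}

setMethod("show", "ProbabilityField", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityField: %s voxels x %d nodes\n",
              paste(d[-length(d)], collapse = "x"), d[length(d)]))
})

setMethod("show", "ScoreField", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScoreField: %s voxels x %d nodes\n",
              paste(d[-length(d)], collapse = "x"), d[length(d)]))
})

#' Decode a probability field to a leaf label map
#'
#' `decodeGreedy` walks each voxel from the root, repeatedly descending into
#' the child with the largest conditional probability until reaching a leaf;
#' the decoded path is hierarchically consistent by construction. Ties break
#' to the lowest node index. `decodeLeafArgmax` instead takes the argmax over
#' leaf probabilities; the two can disagree when an ancestor's mass is spread
#' over many children.
#'
#' @param field a [ProbabilityField-class].
#' @param conditionals optional precomputed conditional array; if omitted the
#'   conditionals are recovered from the chained field (`p[child]/p[parent]`).
#' @return a [LabelVolume-class] of leaf node indices.
#' @export
decodeGreedy <- function(field, conditionals = NULL) {
  tree <- field@tree
  n <- nNodes(tree)
  f <- .flattenField(field@data, n)
  p <- f$mat
  if (is.null(conditionals)) {
    q <- p
    notRoot <- which(!is.na(tree@parent))
    q[, notRoot] <- p[, notRoot] /
      pmax(p[, tree@parent[notRoot], drop = FALSE], .Machine$double.xmin)
  } else q <- .flattenField(conditionals, n)$mat

  leaf <- isLeaf(tree)
  ch <- childrenOf(tree)
  cur <- rep.int(rootIndex(tree), nrow(p))
  repeat {
    active <- which(!leaf[cur])
    if (!length(active)) break
    for (node in unique(cur[active])) {
      v <- active[cur[active] == node]
      kids <- ch[[node]]
      if (length(kids) == 1L) { cur[v] <- kids; next }
      # ties.method "first" == lowest node index (children are index-ordered)
      pick <- max.col(q[v, kids, drop = FALSE], ties.method = "first")
      cur[v] <- kids[pick]
    }
  }
  new("LabelVolume", data = array(as.integer(cur), dim = f$spatial),
      spacing = numeric(0), orientation = character(0))
}

#' @rdname decodeGreedy
#' @export
decodeLeafArgmax <- function(field) {
  tree <- field@tree
  f <- .flattenField(field@data, nNodes(tree))
  leaves <- which(isLeaf(tree))
  pick <- max.col(f$mat[, leaves, drop = FALSE], ties.method = "first")
  new("LabelVolume", data = array(as.integer(leaves[pick]), dim = f$spatial),
      spacing = numeric(0), orientation = character(0))
}

#' Project a label map onto a chosen set of tree nodes
#'
#' Relabels every voxel to its unique ancestor-or-self among `targetNodes`
#' (which must be mutually non-ancestral so the ancestor is unique), or 0 if
#' no target node lies on the voxel label's root path. Projecting lung lobes
#' onto the lung node, for example, reproduces the union of the lobes.
#'
#' @param labels a [LabelVolume-class] or integer array of node indices
#'   (0 = unlabeled, preserved as 0).
#' @param tree the [LabelTree-class].
#' @param targetNodes integer node indices or character node names.
#' @return same type as `labels`, relabeled.
#' @export
levelProjection <- function(labels, tree, targetNodes) {
  if (is.character(targetNodes)) {
    idx <- match(targetNodes, tree@name)
    if (anyNA(idx)) stop("unknown node name: ", targetNodes[is.na(idx)][1L])
    targetNodes <- idx
  }
  reach <- treeMatrices(tree)@reachability
  if (length(targetNodes) > 1L) {
    pairs <- reach[targetNodes, targetNodes]
    diag(pairs) <- 0L
    if (any(pairs > 0L))
      stop("targetNodes contains an ancestor-descendant pair")
  }
  # lookup: for each possible label, its ancestor within the target set
  lut <- integer(nNodes(tree))
  for (t in targetNodes) lut[reach[t, ] == 1L] <- t
  isVol <- is(labels, "LabelVolume")
  lab <- if (isVol) labels@data else labels
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0L
  out[nz] <- lut[lab[nz]]
  if (isVol) new("LabelVolume", data = out, spacing = labels@spacing,
                 orientation = labels@orientation) else out
}
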