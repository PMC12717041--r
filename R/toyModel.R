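# A deliberately small 3-D convolutional segmenter used to demonstrate that
# the SALT head plus hybrid loss trains end-to-end: one 3x3x3 convolution
# with ReLU into `hidden` channels followed by a 1x1x1 convolution onto the
# tree's node channels. Convolutions are evaluated as sums of shifted
# arrays, gradients are fully analytic (including through the SALT layer via
# saltLossGradient), and the optimizer is Adam.

.shift3d <- function(x, dx, dy, dz) {
  d <- dim(x)
  out <- array(0, d)
  sx <- max(1, 1 - dx):min(d[1], d[1] - dx)
  sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
  sz <- max(1, 1 - dz):min(d[3], d[3] - dz)
  out[sx + dx, sy + dy, sz + dz] <- x[sx, sy, sz]
  out
}

.conv3x3 <- function(x, W, b) {
  # x: (X,Y,Z); W: (27, H); b: H  -> (X,Y,Z,H)
  d <- dim(x)
  H <- length(b)
  out <- array(rep(b, each = prod(d)), c(d, H))
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    s <- .shift3d(x, dx, dy, dz)
    for (h in seq_len(H)) out[, , , h] <- out[, , , h] + W[k, h] * s
  }
  out
}

.conv3x3GradW <- function(x, gradOut) {
  # gradOut: (X,Y,Z,H) -> dW (27,H), db (H)
  d <- dim(x); H <- dim(gradOut)[4]
  dW <- matrix(0, 27, H)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    s <- .shift3d(x, dx, dy, dz)
    for (h in seq_len(H)) dW[k, h] <- sum(s * gradOut[, , , h])
  }
  db <- apply(gradOut, 4, sum)
  list(dW = dW, db = db)
}

.forwardToy <- function(x, par) {
  x <- (x - 0.5) * 4            # fixed input standardization
  a1 <- .conv3x3(x, par$W1, par$b1)
  h <- pmax(a1, 0)
  d <- dim(h)
  hm <- matrix(h, ncol = d[4])
  scores <- hm %*% par$W2 + matrix(par$b2, nrow(hm), length(par$b2), byrow = TRUE)
  list(a1 = a1, h = h, hm = hm,
       scores = array(scores, c(d[1:3], length(par$b2))))
}

#' Train a toy convolutional segmenter with a SALT head
#'
#' Fits the two-layer network above on seeded random crops of one or more
#' training phantoms, minimizing the hybrid hierarchical loss with Adam, and
#' returns the learned parameters together with a predict function. Meant as
#' a desk-scale, CPU-only demonstration that hierarchically consistent
#' segmentation is learnable through the SALT activation — not as a
#' replacement for a full-scale segmentation network.
#'
#' @param volumes list of `(image, labels)` pairs (arrays or volume classes)
#'   sharing one tree.
#' @param tree the [LabelTree-class] the labels refer to.
#' @param steps optimizer steps (default 200).
#' @param cropSize training crop (default 32^3).
#' @param hidden hidden channels (default 8).
#' @param lr Adam learning rate (default 0.05).
#' @param wCE,wDice loss weights (default 1, 1).
#' @param seed integer seed controlling initialization and crop sampling.
#' @return list with `par` (weights), `lossTrace`, and `predict(image)`
#'   returning a [ProbabilityField-class].
#' @export
trainToySegmenter <- function(volumes, tree, steps = 200,
                              cropSize = c(32, 32, 32), hidden = 8,
                              lr = 0.05, wCE = 1, wDice = 1, seed = 1) {
  set.seed(seed)
  n <- nNodes(tree)
  par <- list(W1 = matrix(rnorm(27 * hidden, sd = 0.3), 27, hidden),
              b1 = rnorm(hidden, sd = 0.1),
              W2 = matrix(rnorm(hidden * n, sd = 0.3), hidden, n),
              b2 = rep(0, n))
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  trace <- numeric(steps)

  for (step in seq_len(steps)) {
    vol <- volumes[[sample.int(length(volumes), 1L)]]
    crop <- randomCrop(vol$image, vol$labels, size = cropSize)
    x <- crop$image
    targets <- encodeTargets(crop$labels, tree, mask = crop$mask)

    fw <- .forwardToy(x, par)
    lg <- saltLossGradient(fw$scores, tree, targets, wCE = wCE, wDice = wDice)
    trace[step] <- lg$loss

    gs <- matrix(lg$grad, ncol = n)              # V x N
    gW2 <- t(fw$hm) %*% gs
    gb2 <- colSums(gs)
    gh <- gs %*% t(par$W2)                       # V x H
    gh <- gh * (matrix(fw$a1, ncol = hidden) > 0)
    g1 <- .conv3x3GradW((x - 0.5) * 4, array(gh, c(dim(x), hidden)))
    grads <- list(W1 = g1$dW, b1 = g1$db, W2 = gW2, b2 = gb2)

    for (nm in names(par)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^step)
      vhat <- v[[nm]] / (1 - beta2^step)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + epsA)
    }
  }

  predictFun <- function(image) {
    x <- .volData(image)
    fw <- .forwardToy(x, par)
    saltActivation(fw$scores, tree)
  }
  list(par = par, lossTrace = trace, predict = predictFun)
}

#' Mean Dice over leaf nodes of a decoded prediction
#'
#' Convenience metric for the toy training demonstration: hierarchical Dice
#' restricted to the tree's leaves, averaged over leaves present in the
#' reference.
#'
#' @param pred,ref [LabelVolume-class] or integer arrays of node labels.
#' @param tree the [LabelTree-class].
#' @return mean leaf Dice.
#' @export
meanLeafDice <- function(pred, ref, tree) {
  rep <- hierarchicalDice(pred, ref, tree)
  leaves <- which(isLeaf(tree))
  keep <- leaves[rep$n_ref[leaves] > 0]
  mean(rep$dice[keep])
}
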