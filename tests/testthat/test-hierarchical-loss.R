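test_that("target encoding activates the node and all its ancestors", {
  # spine -> lumbar -> L4 style chain: labeling the leaf activates the path
  tree <- parseLabelTree(list(list(name = "root"),
    list(name = "spine", parent = "root"),
    list(name = "lumbar", parent = "spine"),
    list(name = "L4", parent = "lumbar"),
    list(name = "cervical", parent = "spine")))
  tg <- encodeTargets(array(4L, c(1, 1, 1)), tree)
  expect_equal(as.vector(multiHot(tg)), c(1L, 1L, 1L, 1L, 0L))
  # root label activates only the root
  tgR <- encodeTargets(array(1L, c(1, 1, 1)), tree)
  expect_equal(sum(multiHot(tgR)), 1L)
  expect_equal(unname(which(multiHot(tgR)[1, ] == 1L)), 1L)
})

test_that("multi-hot rows equal per-voxel ancestor enumeration", {
  tree <- randomTree(40, seed = 41)
  set.seed(42)
  lab <- array(sample.int(40, 200, replace = TRUE), c(200, 1, 1))
  m <- multiHot(encodeTargets(lab, tree))
  for (v in sample(200, 25)) {
    expected <- integer(40)
    expected[ancestorsOf(tree, lab[v])] <- 1L
    expect_equal(unname(m[v, ]), expected)
  }
  # depth(label)+1 ones per row, all on one root path
  d <- nodeDepths(tree)
  expect_equal(unname(rowSums(m)), d[as.vector(lab)] + 1)
})

test_that("path cross-entropy has its closed forms", {
  # perfect prediction -> loss 0
  tree <- flatTree(4)
  sc <- array(c(0, 100, -100, -100, -100), c(1, 5))
  field <- saltActivation(sc, tree)
  tg <- encodeTargets(array(2L, 1), tree)
  expect_equal(pathCrossEntropy(field, tg), 0, tolerance = 1e-10)
  # uniform scores on k children -> loss log k
  for (k in c(3, 7)) {
    tr <- flatTree(k)
    f <- saltActivation(array(0, c(6, k + 1)), tr)
    t0 <- encodeTargets(array(2L, 6), tr)
    expect_equal(pathCrossEntropy(f, t0), log(k), tolerance = 1e-12)
  }
})

test_that("path CE equals the sum of per-group cross-entropies on the path", {
  tree <- parseLabelTree(list(list(name = "root"),
    list(name = "a", parent = "root"), list(name = "b", parent = "root"),
    list(name = "a1", parent = "a"), list(name = "a2", parent = "a"),
    list(name = "b1", parent = "b"), list(name = "b2", parent = "b")))
  sc <- randomScores(tree, 20, seed = 43)
  q <- conditionalProbabilities(sc, tree)
  field <- chainProbabilities(q, tree)
  set.seed(44)
  lab <- array(sample(c(2:7), 20, replace = TRUE), 20)
  tg <- encodeTargets(lab, tree)
  got <- pathCrossEntropy(field, tg)
  oracle <- mean(vapply(seq_len(20), function(v) {
    path <- setdiff(ancestorsOf(tree, lab[v]), rootIndex(tree))
    sum(-log(q[v, path]))
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("tree soft Dice matches a brute-force per-node computation", {
  tree <- randomTree(6, seed = 45)
  nv <- 64   # 4^3 grid
  sc <- randomScores(tree, nv, seed = 46)
  field <- saltActivation(sc, tree)
  set.seed(47)
  lab <- array(sample.int(6, nv, replace = TRUE), c(4, 4, 4))
  tg <- encodeTargets(lab, tree)
  got <- treeSoftDice(field, tg)
  p <- matrix(field@data, ncol = 6)
  m <- multiHot(tg)
  eps <- 1e-5
  dice <- vapply(setdiff(1:6, rootIndex(tree)), function(n) {
    if (sum(m[, n]) == 0 && sum(p[, n]) < 1) return(NA_real_)
    (2 * sum(p[, n] * m[, n]) + eps) / (sum(p[, n]) + sum(m[, n]) + eps)
  }, numeric(1))
  expect_equal(got, 1 - mean(dice, na.rm = TRUE), tolerance = 1e-12)
})

test_that("Dice loss hits its extremes", {
  tree <- flatTree(2)
  # exact one-hot match -> ~0
  lab <- array(rep(c(2L, 3L), each = 32), c(4, 4, 4))
  sc <- array(0, c(4, 4, 4, 3))
  sc[, , , 2] <- ifelse(lab == 2L, 50, -50)
  sc[, , , 3] <- ifelse(lab == 3L, 50, -50)
  field <- saltActivation(sc, tree)
  tg <- encodeTargets(lab, tree)
  expect_lt(treeSoftDice(field, tg), 1e-4)
  # complement prediction -> ~1
  swapped <- array(0, c(4, 4, 4, 3))
  swapped[, , , 2] <- sc[, , , 3]; swapped[, , , 3] <- sc[, , , 2]
  expect_gt(treeSoftDice(saltActivation(swapped, tree), tg), 0.999)
})

test_that("hybrid loss is the weighted sum of its components", {
  tree <- randomTree(10, seed = 48)
  field <- saltActivation(randomScores(tree, 50, seed = 49), tree)
  set.seed(50)
  tg <- encodeTargets(array(sample.int(10, 50, replace = TRUE), 50), tree)
  ce <- pathCrossEntropy(field, tg)
  dc <- treeSoftDice(field, tg)
  expect_equal(as.numeric(hybridLoss(field, tg, 1, 0)), ce)
  expect_equal(as.numeric(hybridLoss(field, tg, 0, 1)), dc)
  expect_equal(as.numeric(hybridLoss(field, tg, 1, 1)), ce + dc)
  expect_equal(as.numeric(hybridLoss(field, tg, 0.3, 1.7)),
               0.3 * ce + 1.7 * dc)
  expect_error(hybridLoss(field, tg, -1, 1), "non-negative")
})

test_that("an empty supervision mask yields zero loss with a warning", {
  tree <- flatTree(2)
  field <- saltActivation(array(0, c(4, 3)), tree)
  tg <- encodeTargets(array(0L, 4), tree)
  expect_warning(ce <- pathCrossEntropy(field, tg), "empty")
  expect_warning(dc <- treeSoftDice(field, tg), "empty")
  expect_equal(ce, 0); expect_equal(dc, 0)
})

test_that("the analytic gradient matches finite differences", {
  tree <- parseLabelTree(list(list(name = "root"),
    list(name = "bg", parent = "root", kind = "background"),
    list(name = "body", parent = "root"),
    list(name = "cav", parent = "body"),
    list(name = "organ", parent = "cav")))
  set.seed(51)
  V <- 9; n <- nNodes(tree)
  sc <- array(rnorm(V * n), c(V, n))
  lab <- array(sample(2:5, V, replace = TRUE), V)
  msk <- array(rep(c(1L, 1L, 0L), 3), V)
  tg <- encodeTargets(lab, tree, msk)
  lg <- saltLossGradient(sc, tree, tg, wCE = 1, wDice = 1)
  f <- function(s) {
    fl <- saltActivation(s, tree)
    pathCrossEntropy(fl, tg) + treeSoftDice(fl, tg)
  }
  expect_equal(lg$loss, f(sc), tolerance = 1e-12)
  eps <- 1e-6
  num <- array(0, dim(sc))
  for (i in seq_along(sc)) {
    s1 <- sc; s2 <- sc
    s1[i] <- s1[i] + eps; s2[i] <- s2[i] - eps
    num[i] <- (f(s1) - f(s2)) / (2 * eps)
  }
  expect_equal(lg$grad, num, tolerance = 1e-6)
  # one gradient step strictly decreases the loss
  expect_lt(f(sc - 0.05 * lg$grad), f(sc))
})

test_that("sparse supervision equals the loss on retained slices alone", {
  spec <- defaultPhantomSpec(seed = 61, gridSize = c(20, 20, 20))
  ph <- makePhantom(spec, seed = 61)
  lab <- rootToBackground(ph$labels, spec$tree)
  tree <- spec$tree
  sp <- sparsify(lab, everyK = 5)
  sc <- randomScores(tree, 20^3, seed = 62)
  dim(sc) <- c(20, 20, 20, nNodes(tree))
  field <- saltActivation(sc, tree)
  tgSparse <- encodeTargets(sp$labels, tree, mask = sp$mask)
  lossSparse <- hybridLoss(field, tgSparse)
  # oracle: restrict everything to the retained slices
  keep <- seq(1, 20, by = 5)
  scK <- sc[, , keep, , drop = FALSE]
  labK <- lab@data[, , keep, drop = FALSE]
  fieldK <- saltActivation(scK, tree)
  tgK <- encodeTargets(labK, tree)
  lossK <- hybridLoss(fieldK, tgK)
  expect_equal(as.numeric(lossSparse), as.numeric(lossK), tolerance = 1e-12)
})
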