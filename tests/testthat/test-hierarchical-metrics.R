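test_that("identical volumes score Dice 1 on every applicable node", {
  tree <- thoraxFragment()
  set.seed(71)
  lab <- array(sample(0:6, 512, replace = TRUE), c(8, 8, 8))
  rep <- hierarchicalDice(lab, lab, tree)
  applicable <- !is.na(rep$dice)
  expect_true(any(applicable))
  expect_equal(rep$dice[applicable], rep(1, sum(applicable)))
})

test_that("hierarchical Dice on a flat tree equals conventional per-class Dice", {
  tree <- flatTree(4)
  for (seed in 72:76) {
    set.seed(seed)
    pred <- array(sample(0:5, 729, replace = TRUE), c(9, 9, 9))
    ref <- array(sample(0:5, 729, replace = TRUE), c(9, 9, 9))
    rep <- hierarchicalDice(pred, ref, tree)
    for (l in 2:5)
      expect_equal(rep$dice[l], classDice(pred, ref, l))
  }
})

test_that("a correct parent with the wrong sibling child splits credit", {
  tree <- parseLabelTree(list(list(name = "root"),
    list(name = "parent", parent = "root"),
    list(name = "c1", parent = "parent"),
    list(name = "c2", parent = "parent")))
  ref <- array(3L, c(4, 4, 4))   # everywhere c1
  pred <- array(4L, c(4, 4, 4))  # everywhere the sibling c2
  rep <- hierarchicalDice(pred, ref, tree)
  expect_equal(rep$dice[rep$node == "parent"], 1)
  expect_equal(rep$dice[rep$node == "c1"], 0)
  expect_equal(rep$dice[rep$node == "c2"], 0)
})

test_that("encoded-space Dice is bit-identical to naive per-node masks", {
  for (seed in c(81, 82)) {
    tree <- randomTree(12, seed = seed)
    reach <- treeMatrices(tree)@reachability
    set.seed(seed + 10)
    pred <- array(sample(0:12, 4096, replace = TRUE), c(16, 16, 16))
    ref <- array(sample(0:12, 4096, replace = TRUE), c(16, 16, 16))
    rep <- hierarchicalDice(pred, ref, tree)
    for (node in seq_len(12)) {
      # naive: materialize the ancestor-or-self membership mask per node
      mem <- c(FALSE, reach[node, ] == 1L)
      mp <- array(mem[pred + 1L], dim(pred))
      mr <- array(mem[ref + 1L], dim(ref))
      if (!any(mp) && !any(mr)) {
        expect_true(is.na(rep$dice[node]))
      } else {
        expect_identical(rep$dice[node],
                         2 * sum(mp & mr) / (sum(mp) + sum(mr)))
      }
    }
  }
})

test_that("Dice is symmetric in prediction and reference", {
  tree <- randomTree(8, seed = 83)
  set.seed(84)
  a <- array(sample(0:8, 1000, replace = TRUE), c(10, 10, 10))
  b <- array(sample(0:8, 1000, replace = TRUE), c(10, 10, 10))
  expect_equal(hierarchicalDice(a, b, tree)$dice,
               hierarchicalDice(b, a, tree)$dice)
})

test_that("grid and spacing mismatches are rejected", {
  tree <- flatTree(2)
  a <- array(1L, c(4, 4, 4)); b <- array(1L, c(4, 4, 5))
  expect_error(hierarchicalDice(a, b, tree), "grids differ")
  va <- new("LabelVolume", data = a, spacing = c(1, 1, 1), orientation = "LPI")
  vb <- new("LabelVolume", data = a, spacing = c(1.5, 1.5, 1.5),
            orientation = "LPI")
  expect_error(hierarchicalDice(va, vb, tree), "spacing")
})

test_that("the distance transform matches brute-force distances", {
  set.seed(85)
  mask <- array(runif(8 * 7 * 6) < 0.1, c(8, 7, 6))
  mask[2, 3, 4] <- TRUE   # ensure non-empty
  spacing <- c(1.5, 0.7, 2.0)
  got <- distanceTransform(mask, spacing)
  pts <- which(mask, arr.ind = TRUE)
  phys <- sweep(pts - 1, 2, spacing, `*`)
  for (i in sample(length(mask), 40)) {
    xyz <- (arrayInd(i, dim(mask)) - 1) * spacing
    expect_equal(got[i], min(sqrt(colSums((t(phys) - as.vector(xyz))^2))),
                 tolerance = 1e-12)
  }
  # empty mask -> all infinite
  expect_true(all(is.infinite(distanceTransform(array(FALSE, c(3, 3, 3))))))
})

test_that("NSD behaves analytically for identical and shifted cubes", {
  d <- c(20, 20, 20); spacing <- c(1.5, 1.5, 1.5)
  cube <- function(off) {
    a <- array(FALSE, d)
    a[(6 + off):(15 + off), 6:15, 6:15] <- TRUE
    a
  }
  expect_equal(nsd(cube(0), cube(0), spacing, 3), 1)
  # 1-voxel axis shift at 1.5 mm: every surface distance <= 1.5 mm < 3 mm
  expect_equal(nsd(cube(0), cube(1), spacing, 3), 1)
  # 3-voxel shift (4.5 mm): below 1, equal to the all-pairs oracle
  s3 <- nsd(cube(0), cube(3), spacing, 3)
  expect_lt(s3, 1)
  expect_equal(s3, nsdOracle(cube(0), cube(3), spacing, 3), tolerance = 1e-12)
})

test_that("NSD equals the all-pairs oracle on random blobs", {
  set.seed(86)
  d <- c(10, 10, 10); spacing <- c(2, 1, 1.5)
  blob <- function() {
    a <- array(FALSE, d)
    c0 <- sample(3:8, 3, replace = TRUE)
    r <- runif(1, 1.5, 3.5)
    for (x in 1:10) for (y in 1:10) for (z in 1:10)
      if (sum(((c(x, y, z) - c0))^2) <= r^2) a[x, y, z] <- TRUE
    a
  }
  for (i in 1:3) {
    a <- blob(); b <- blob()
    expect_equal(nsd(a, b, spacing, 3), nsdOracle(a, b, spacing, 3),
                 tolerance = 1e-12)
  }
})

test_that("NSD is symmetric and degrades monotonically with shift", {
  d <- c(24, 16, 16); spacing <- c(1.5, 1.5, 1.5)
  cube <- function(off) {
    a <- array(FALSE, d)
    a[(3 + off):(10 + off), 5:12, 5:12] <- TRUE
    a
  }
  scores <- vapply(0:8, function(o) nsd(cube(0), cube(o), spacing, 3),
                   numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_equal(nsd(cube(0), cube(4), spacing, 3),
               nsd(cube(4), cube(0), spacing, 3))
  # empty-surface conventions
  empty <- array(FALSE, d)
  expect_equal(nsd(empty, empty, spacing, 3), 1)
  expect_equal(nsd(cube(0), empty, spacing, 3), 0)
})

test_that("bootstrap CI brackets the mean and is seed-reproducible", {
  expect_equal(unname(bootstrapCI(rep(0.7, 20), seed = 1)), c(0.7, 0.7))
  ci <- bootstrapCI(c(0, 1), nRounds = 2000, seed = 2)
  expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
  expect_true(ci["lower"] < 0.5 && ci["upper"] > 0.5)
  s <- runif(30)
  expect_identical(bootstrapCI(s, nRounds = 200, seed = 3),
                   bootstrapCI(s, nRounds = 200, seed = 3))
  expect_error(bootstrapCI(numeric(0)), "empty")
})

test_that("bootstrap CI agrees with an independently seeded oracle", {
  set.seed(87)
  scores <- rnorm(150, mean = 0.9, sd = 0.01)
  got <- bootstrapCI(scores, nRounds = 1000, seed = 88)
  # independent percentile-bootstrap implementation, different seed/stream
  set.seed(999)
  means <- replicate(1000, mean(scores[ceiling(runif(150) * 150)]))
  oracle <- quantile(means, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(got), oracle, tolerance = 1e-3)
})

test_that("the evaluation report combines Dice and NSD per node", {
  tree <- thoraxFragment()
  spec <- list(
    tc = list(type = "box", center = c(8, 8, 8), semiaxes = c(6, 6, 6)),
    lungs = list(type = "box", center = c(6, 8, 8), semiaxes = c(2, 4, 4)),
    med = list(type = "box", center = c(12, 8, 8), semiaxes = c(1, 3, 3)))
  d <- c(16, 16, 16)
  ref <- array(0L, d)
  mk <- function(s) {
    a <- array(FALSE, d)
    a[abs(seq_len(d[1]) - s$center[1]) <= s$semiaxes[1],
      abs(seq_len(d[2]) - s$center[2]) <= s$semiaxes[2],
      abs(seq_len(d[3]) - s$center[3]) <= s$semiaxes[3]] <- TRUE
    a
  }
  ref[mk(spec$tc)] <- 2L; ref[mk(spec$lungs)] <- 3L; ref[mk(spec$med)] <- 4L
  pred <- ref   # slightly perturbed prediction
  pred[6, , ] <- 0L
  rep <- evaluationReport(pred, ref, tree, spacing = c(1.5, 1.5, 1.5))
  expect_true(all(rep$dice[!is.na(rep$dice)] <= 1))
  expect_true(all(rep$nsd[!is.na(rep$nsd)] <= 1))
  expect_true(all(c("node", "dice", "nsd", "n_pred", "n_ref") %in% names(rep)))
  s <- attr(rep, "summary")
  expect_true(is.finite(s["meanDice"]) && is.finite(s["meanNSD"]))
})
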