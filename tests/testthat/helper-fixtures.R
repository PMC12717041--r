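# Shared fixture builders; everything is generated in code, seeded.

# random tree with n nodes: node i's parent drawn uniformly among 1..(i-1)
randomTree <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i)
    sample.int(i - 1L, 1L), integer(1)))
  new("LabelTree", name = paste0("n", seq_len(n)),
      parent = parent,
      kind = c("root", rep("anatomical", n - 1L)))
}

# flat tree: root plus k leaves
flatTree <- function(k) {
  parseLabelTree(c(list(list(name = "root")),
                   lapply(seq_len(k), function(i)
                     list(name = paste0("leaf", i), parent = "root"))))
}

# chain of d binary forks: at each level one fork child continues
binaryForkChain <- function(d) {
  recs <- list(list(name = "root"))
  parent <- "root"
  for (lev in seq_len(d)) {
    a <- paste0("L", lev, "a"); b <- paste0("L", lev, "b")
    recs <- c(recs, list(list(name = a, parent = parent),
                         list(name = b, parent = parent)))
    parent <- a
  }
  parseLabelTree(recs)
}

# the six-node thoracic fragment used across examples
thoraxFragment <- function() {
  parseLabelTree(list(
    list(name = "root"),
    list(name = "thoracic cavity", parent = "root"),
    list(name = "lungs", parent = "thoracic cavity"),
    list(name = "mediastinum", parent = "thoracic cavity"),
    list(name = "pericardium", parent = "mediastinum"),
    list(name = "heart", parent = "pericardium")))
}

# BFS ancestor-closure oracle for the reachability matrix
bfsReachability <- function(tree) {
  n <- nNodes(tree)
  ch <- childrenOf(tree)
  out <- matrix(0L, n, n)
  # BFS from root; a node's root path = parent's path plus itself
  queue <- rootIndex(tree)
  paths <- vector("list", n)
  paths[[queue]] <- queue
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out[paths[[v]], v] <- 1L
    for (c in ch[[v]]) {
      paths[[c]] <- c(paths[[v]], c)
      queue <- c(queue, c)
    }
  }
  dimnames(out) <- list(tree@name, tree@name)
  out
}

# random scores for a tree over nv voxels
randomScores <- function(tree, nv, seed, sd = 2) {
  set.seed(seed)
  array(rnorm(nv * nNodes(tree), sd = sd), c(nv, nNodes(tree)))
}

# brute-force all-pairs NSD oracle (physical distances between voxel centers)
nsdOracle <- function(pred, ref, spacing, tol) {
  bnd <- function(mask) {
    d <- dim(mask)
    out <- array(FALSE, d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (!mask[x, y, z]) next
      nb <- c(
        if (x > 1) mask[x - 1, y, z] else FALSE,
        if (x < d[1]) mask[x + 1, y, z] else FALSE,
        if (y > 1) mask[x, y - 1, z] else FALSE,
        if (y < d[2]) mask[x, y + 1, z] else FALSE,
        if (z > 1) mask[x, y, z - 1] else FALSE,
        if (z < d[3]) mask[x, y, z + 1] else FALSE)
      if (!all(nb)) out[x, y, z] <- TRUE
    }
    out
  }
  coords <- function(b) {
    w <- which(b, arr.ind = TRUE)
    sweep(w - 1, 2, spacing, `*`)
  }
  cp <- coords(bnd(pred)); cr <- coords(bnd(ref))
  if (!nrow(cp) && !nrow(cr)) return(1)
  if (!nrow(cp) || !nrow(cr)) return(0)
  dists <- function(a, b) {
    apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
  }
  dPR <- dists(cp, cr); dRP <- dists(cr, cp)
  (sum(dPR <= tol) + sum(dRP <= tol)) / (length(dPR) + length(dRP))
}

# standard per-class Dice on label maps (flat-segmentation oracle)
classDice <- function(pred, ref, label) {
  p <- pred == label; r <- ref == label
  if (!any(p) && !any(r)) return(NA_real_)
  2 * sum(p & r) / (sum(p) + sum(r))
}
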