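.saltError <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "saltValidationError", "error", "condition")))
}

#' Parse a label-tree configuration
#'
#' Reads a hierarchy description and returns a validated [LabelTree-class].
#' The configuration is a list of node records, each with a `name`, a `parent`
#' (the name of another node; omitted, `NULL` or `~` for the root) and an
#' optional `kind` (`"anatomical"`, `"other"`, `"background"`; the root gets
#' kind `"root"`). Node index order is the order of the records, so a
#' configuration file defines a reproducible node numbering.
#'
#' @param config path to a YAML or JSON file, or an already-parsed list of
#'   records, or a data.frame with columns `name`, `parent` and optionally
#'   `kind` (parent `NA`/`""` for the root).
#' @return a [LabelTree-class].
#'
#' @section Validation errors:
#' Distinct condition classes are signalled for the distinct failure modes:
#' `saltDuplicateNameError`, `saltMultipleRootError`, `saltOrphanParentError`
#' (a parent name that matches no node), and `saltCycleError` (parent links
#' that do not lead back to the root, including a node naming itself).
#' All inherit from `saltValidationError`.
#'
#' @examples
#' cfg <- list(
#'   list(name = "root"),
#'   list(name = "thoracic cavity", parent = "root"),
#'   list(name = "lungs", parent = "thoracic cavity"),
#'   list(name = "mediastinum", parent = "thoracic cavity"),
#'   list(name = "pericardium", parent = "mediastinum"),
#'   list(name = "heart", parent = "pericardium"))
#' tree <- parseLabelTree(cfg)
#' nNodes(tree)
#' nodeNames(tree)[isLeaf(tree)]
#' @export
parseLabelTree <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config) else yaml::read_yaml(config)
  }
  if (is.data.frame(config)) {
    recs <- lapply(seq_len(nrow(config)), function(i) as.list(config[i, ]))
  } else recs <- config
  if (!length(recs)) .saltError("saltMultipleRootError", "empty configuration")

  getf <- function(r, f) {
    v <- r[[f]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) NA_character_
    else as.character(v)
  }
  name <- vapply(recs, getf, character(1), "name")
  parent <- vapply(recs, getf, character(1), "parent")
  kind <- vapply(recs, getf, character(1), "kind")
  parent[!is.na(parent) & parent == ""] <- NA_character_
  if (any(is.na(name) | name == ""))
    .saltError("saltValidationError", "every node needs a non-empty name")
  if (anyDuplicated(name))
    .saltError("saltDuplicateNameError", "duplicate node name: '%s'",
               name[duplicated(name)][1L])

  rootAt <- which(is.na(parent))
  if (length(rootAt) == 0L)
    .saltError("saltMultipleRootError", "no root node (every node has a parent)")
  if (length(rootAt) > 1L)
    .saltError("saltMultipleRootError", "multiple roots: %s",
               paste(sQuote(name[rootAt]), collapse = ", "))

  pidx <- match(parent, name)
  orphan <- which(!is.na(parent) & is.na(pidx))
  if (length(orphan))
    .saltError("saltOrphanParentError",
               "node '%s' references unknown parent '%s'",
               name[orphan[1L]], parent[orphan[1L]])

  # walk to root from every node; revisiting a node means a cycle
  n <- length(name)
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (!is.na(pidx[j])) {
      if (seen[j] || pidx[j] == j)
        .saltError("saltCycleError", "cycle in parent links at node '%s'", name[j])
      seen[j] <- TRUE
      j <- pidx[j]
    }
  }

  kind[is.na(kind)] <- ifelse(is.na(pidx)[is.na(kind)], "root", "anatomical")
  kind[rootAt] <- "root"
  new("LabelTree", name = name, parent = as.integer(pidx), kind = kind)
}

#' Serialize a label tree back to its configuration form
#'
#' @param tree a [LabelTree-class].
#' @param file optional path (`.yaml`/`.yml` or `.json`); if omitted the
#'   record list is returned invisibly instead of written.
#' @return the record list, invisibly.
#' @export
writeLabelTree <- function(tree, file = NULL) {
  recs <- lapply(seq_along(tree@name), function(i) {
    r <- list(name = tree@name[i])
    if (!is.na(tree@parent[i])) r$parent <- tree@name[tree@parent[i]]
    if (!tree@kind[i] %in% c("root", "anatomical")) r$kind <- tree@kind[i]
    r
  })
  if (!is.null(file)) {
    if (grepl("\\.json$", file, ignore.case = TRUE))
      jsonlite::write_json(recs, file, auto_unbox = TRUE)
    else yaml::write_yaml(recs, file)
  }
  invisible(recs)
}

# ---- accessors ----------------------------------------------------------

#' Label-tree accessors
#'
#' Small query helpers over a [LabelTree-class]: node count, names, parent
#' indices, kinds, the root index, per-node depth (root = 0), leaf indicator,
#' children and sibling groups.
#'
#' @param tree a [LabelTree-class].
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
nNodes <- function(tree) length(tree@name)

#' @rdname tree-accessors
#' @export
nodeNames <- function(tree) tree@name

#' @rdname tree-accessors
#' @export
nodeParents <- function(tree) tree@parent

#' @rdname tree-accessors
#' @export
nodeKinds <- function(tree) tree@kind

#' @rdname tree-accessors
#' @export
rootIndex <- function(tree) which(is.na(tree@parent))

#' @rdname tree-accessors
#' @export
nodeDepths <- function(tree) {
  n <- nNodes(tree)
  d <- rep(NA_integer_, n)
  d[rootIndex(tree)] <- 0L
  repeat {
    todo <- which(is.na(d) & !is.na(d[tree@parent]))
    if (!length(todo)) break
    d[todo] <- d[tree@parent[todo]] + 1L
  }
  d
}

#' @rdname tree-accessors
#' @export
isLeaf <- function(tree) !(seq_along(tree@name) %in% tree@parent)

#' @rdname tree-accessors
#' @export
childrenOf <- function(tree) {
  lapply(seq_along(tree@name), function(i) which(tree@parent == i))
}

#' Sibling groups of a label tree
#'
#' @param tree a [LabelTree-class].
#' @return list of integer index vectors, one per internal node with children,
#'   each the ordered set of that node's children (the unit the conditional
#'   softmax normalizes over). The root itself forms no group.
#' @export
siblingGroups <- function(tree) {
  ch <- childrenOf(tree)
  ch[lengths(ch) > 0L]
}

#' Ancestors (including the node itself) along the root path
#'
#' @param tree a [LabelTree-class].
#' @param node node index.
#' @return integer vector root..node in root-first order.
#' @export
ancestorsOf <- function(tree, node) {
  path <- node
  while (!is.na(tree@parent[node])) {
    node <- tree@parent[node]
    path <- c(node, path)
  }
  path
}

setMethod("show", "LabelTree", function(object) {
  d <- nodeDepths(object)
  cat(sprintf("LabelTree: %d nodes (%d excluding root), %d leaves, depth %d\n",
              nNodes(object), nNodes(object) - 1L, sum(isLeaf(object)), max(d)))
  cat("root:", object@name[rootIndex(object)], "\n")
})

# ---- matrices -----------------------------------------------------------

#' Matrix representations of a label tree
#'
#' Builds the three N x N binary matrices the rest of the framework relies
#' on: the adjacency matrix (directed parent-to-child edges), the
#' reachability matrix (for each node, all nodes on its root path including
#' itself — the reflexive transitive closure of the adjacency matrix), and
#' the sibling matrix (nodes sharing a parent, each node included in its own
#' group).
#'
#' @param tree a [LabelTree-class].
#' @return a [TreeMatrices-class].
#' @examples
#' tree <- parseLabelTree(list(list(name = "root"),
#'   list(name = "a", parent = "root"), list(name = "b", parent = "a")))
#' treeMatrices(tree)@reachability
#' @export
treeMatrices <- function(tree) {
  n <- nNodes(tree)
  nm <- tree@name
  adj <- matrix(0L, n, n, dimnames = list(nm, nm))
  notRoot <- which(!is.na(tree@parent))
  adj[cbind(tree@parent[notRoot], notRoot)] <- 1L

  reach <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) reach[ancestorsOf(tree, i), i] <- 1L

  sib <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (g in siblingGroups(tree)) sib[g, g] <- 1L
  sib[cbind(rootIndex(tree), rootIndex(tree))] <- 1L

  new("TreeMatrices", adjacency = adj, reachability = reach, sibling = sib)
}

setMethod("show", "TreeMatrices", function(object) {
  cat(sprintf("TreeMatrices over %d nodes (%d edges)\n",
              nrow(object@adjacency), sum(object@adjacency)))
})

# internal: sparse reachability for log-space chaining
.reachabilitySparse <- function(tree) {
  n <- nNodes(tree)
  paths <- lapply(seq_len(n), function(i) ancestorsOf(tree, i))
  Matrix::sparseMatrix(i = unlist(paths), j = rep(seq_len(n), lengths(paths)),
                       x = 1, dims = c(n, n))
}

# ---- bitwise path encoding ---------------------------------------------

#' Bitwise path encoding of a label tree
#'
#' Assigns each node a fixed-width bit code describing its ancestral path.
#' The bit budget is split into one field per depth level; the field at level
#' `d` is wide enough to hold the largest sibling-group rank at that level
#' (smallest `w` with `2^w` strictly greater than the group size, so that 0
#' can mean "level unoccupied"). A node's code stores, for every level along
#' its root path, its 1-based rank within its sibling group, and 0 below its
#' depth; its mask is all-ones over the levels it occupies. Ancestor tests
#' then reduce to a masked comparison: `a` is an ancestor-or-self of `n`
#' exactly when `(codes[n] AND masks[a]) == codes[a]`.
#'
#' @param tree a [LabelTree-class].
#' @return a [PathEncoding-class] with `N x B` raw `codes` and `masks`.
#' @seealso [isAncestorEncoded()] for the prefix test.
#' @export
encodePaths <- function(tree) {
  n <- nNodes(tree)
  depth <- nodeDepths(tree)
  maxDepth <- max(depth)

  # rank within sibling group (root rank 1)
  rank <- integer(n)
  rank[rootIndex(tree)] <- 1L
  for (g in siblingGroups(tree)) rank[g] <- seq_along(g)

  # field widths per level 0..maxDepth: need 2^w > max rank at that level
  widths <- vapply(0:maxDepth, function(d) {
    m <- max(rank[depth == d])
    w <- 1L
    while (bitwShiftL(1L, w) <= m) w <- w + 1L
    w
  }, integer(1))
  totalBits <- sum(widths)
  B <- as.integer(ceiling(totalBits / 8))
  offset <- c(0L, cumsum(widths))   # bit offset of each level's field

  codes <- matrix(as.raw(0), n, B)
  masks <- matrix(as.raw(0), n, B)
  setBits <- function(bytes, bitOffset, width, value) {
    # write `width` bits of `value` MSB-first starting at global bit offset
    for (b in seq_len(width)) {
      bit <- bitOffset + b - 1L                 # 0-based global bit position
      byte <- bit %/% 8L + 1L
      posInByte <- 7L - (bit %% 8L)             # MSB-first within byte
      bitVal <- bitwAnd(bitwShiftR(value, width - b), 1L)
      if (bitVal == 1L)
        bytes[byte] <- bytes[byte] | as.raw(bitwShiftL(1L, posInByte))
    }
    bytes
  }
  for (i in seq_len(n)) {
    path <- ancestorsOf(tree, i)
    code <- rep(as.raw(0), B); mask <- rep(as.raw(0), B)
    for (a in path) {
      d <- depth[a]
      code <- setBits(code, offset[d + 1L], widths[d + 1L], rank[a])
      mask <- setBits(mask, offset[d + 1L], widths[d + 1L],
                      bitwShiftL(1L, widths[d + 1L]) - 1L)
    }
    codes[i, ] <- code; masks[i, ] <- mask
  }
  rownames(codes) <- rownames(masks) <- tree@name
  new("PathEncoding", codes = codes, masks = masks,
      bitsPerLevel = widths, bytes = B)
}

#' Masked-comparison ancestor test in encoded space
#'
#' @param encoding a [PathEncoding-class].
#' @param a,n node indices (vectors recycle).
#' @return logical: is `a` an ancestor-or-self of `n`?
#' @export
isAncestorEncoded <- function(encoding, a, n) {
  k <- max(length(a), length(n))
  a <- rep_len(a, k); n <- rep_len(n, k)
  vapply(seq_len(k), function(i) {
    all((encoding@codes[n[i], ] & encoding@masks[a[i], ]) ==
          encoding@codes[a[i], ])
  }, logical(1))
}

setMethod("show", "PathEncoding", function(object) {
  cat(sprintf("PathEncoding: %d nodes x %d bytes (%s bits per level)\n",
              nrow(object@codes), object@bytes,
              paste(object@bitsPerLevel, collapse = "+")))
})
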