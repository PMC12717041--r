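.asLabelVolume <- function(x, template = NULL) {
  if (is(x, "LabelVolume")) return(x)
  sp <- if (!is.null(template)) template@spacing else numeric(0)
  orc <- if (!is.null(template)) template@orientation else character(0)
  new("LabelVolume", data = array(as.integer(x), dim = dim(x) %||% length(x)),
      spacing = sp, orientation = orc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge a node's descendants into the node itself
#'
#' Relabels every voxel carrying any descendant of `parent` to `parent`
#' (e.g. fusing the five lung lobes into a single lung label). Voxel counts
#' are conserved: the merged parent holds exactly the sum of its descendants'
#' voxels plus its own.
#'
#' @param vol a [LabelVolume-class] (or integer array).
#' @param tree the [LabelTree-class].
#' @param parent node index or name to merge into.
#' @return relabeled volume of the same type.
#' @export
mergeChildren <- function(vol, tree, parent) {
  if (is.character(parent)) {
    p <- match(parent, tree@name)
    if (is.na(p)) stop("unknown node: ", parent)
    parent <- p
  }
  reach <- treeMatrices(tree)@reachability
  lut <- c(0L, seq_len(nNodes(tree)))           # labels 0..N
  lut[1L + which(reach[parent, ] == 1L)] <- as.integer(parent)
  isVol <- is(vol, "LabelVolume")
  lab <- .volData(vol)
  out <- array(lut[lab + 1L], dim = dim(lab))
  if (isVol) new("LabelVolume", data = out, spacing = vol@spacing,
                 orientation = vol@orientation) else out
}

#' Split a label by spatial regions
#'
#' Partitions the voxels of a binary child mask among an ordered list of
#' regions: each voxel goes to the first region (in the given precedence
#' order) that contains it; voxels in no region go to the fallback. This is
#' the operator that turns a structure crossing several parents (an aorta
#' running through mediastinum, pericardium and abdomen) into single-parent
#' pieces. The output labels partition the child mask exactly.
#'
#' @param childMask logical/0-1 array, the voxels of the label to split.
#' @param regions named list of logical/0-1 arrays (same grid), in
#'   precedence order.
#' @param fallback name for the remainder region (default
#'   `"<first name> remainder"`).
#' @return integer array with values `0` (outside the child), `1..k` for the
#'   regions in order, `k+1` for the fallback; attribute `"labels"` maps
#'   values to names.
#' @export
splitByRegion <- function(childMask, regions, fallback = NULL) {
  if (!length(regions)) stop("empty region list")
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be named")
  child <- .volData(childMask) > 0
  out <- array(0L, dim = dim(child))
  remaining <- child
  for (i in seq_along(regions)) {
    r <- .volData(regions[[i]]) > 0
    if (!identical(dim(r), dim(child))) stop("region grid differs from child")
    take <- remaining & r
    out[take] <- i
    remaining <- remaining & !take
  }
  k <- length(regions)
  out[remaining] <- k + 1L
  if (is.null(fallback)) fallback <- paste(names(regions)[1L], "remainder")
  structure(out, labels = c(names(regions), fallback))
}

#' Complete a labeling with "other" nodes
#'
#' For every internal node whose own voxels are not fully covered by its
#' labeled children (i.e. voxels whose deepest label is the internal node
#' itself), appends an `"<name> other"` leaf child to the tree and assigns
#' those voxels to it. Afterwards every internal node's voxel set is exactly
#' the union of its children's — the coverage property that makes the
#' hierarchy's ground truth consistent at every level.
#'
#' @param vol a [LabelVolume-class] (or integer array) labeled with tree
#'   nodes (deepest-node convention).
#' @param tree the [LabelTree-class].
#' @return list with elements `volume` (relabeled, same type as `vol`) and
#'   `tree` (augmented [LabelTree-class]; unchanged nodes keep their
#'   indices).
#' @export
completeWithOther <- function(vol, tree) {
  isVol <- is(vol, "LabelVolume")
  lab <- .volData(vol)
  name <- tree@name; parent <- tree@parent; kind <- tree@kind
  internal <- which(!isLeaf(tree))
  out <- lab
  for (p in internal) {
    hit <- lab == p
    if (!any(hit)) next
    name <- c(name, paste(tree@name[p], "other"))
    parent <- c(parent, p)
    kind <- c(kind, "other")
    out[hit] <- length(name)
  }
  newTree <- new("LabelTree", name = name, parent = as.integer(parent),
                 kind = kind)
  outVol <- if (isVol) new("LabelVolume", data = array(as.integer(out), dim(lab)),
                           spacing = vol@spacing, orientation = vol@orientation)
            else array(as.integer(out), dim = dim(lab))
  list(volume = outVol, tree = newTree)
}

#' Fuse two annotation sources into one tree-consistent labeling
#'
#' Combines a primary and a secondary label volume over the same tree (e.g.
#' sparse expert body-region annotations with dense model organ
#' predictions). Where only one source labels a voxel it wins; where both do,
#' the deeper (more specific) node wins, and depth ties go to the primary
#' source. Only the deepest node is stored, so the winner's ancestors are
#' implied and never contradicted.
#'
#' @param primary,secondary [LabelVolume-class] objects (or integer arrays)
#'   on the same grid, indexed in the same tree.
#' @param tree the [LabelTree-class].
#' @return fused volume (same type as `primary`) with attribute
#'   `"overridden"`: the number of voxels where the secondary source
#'   displaced a primary label.
#' @export
fuseAnnotations <- function(primary, secondary, tree) {
  p <- .volData(primary); s <- .volData(secondary)
  if (!identical(dim(p), dim(s))) stop("grids differ")
  depth <- c(-1L, nodeDepths(tree))      # label 0 shallower than everything
  dP <- array(depth[p + 1L], dim(p)); dS <- array(depth[s + 1L], dim(s))
  useS <- dS > dP                        # deeper wins; ties keep primary
  out <- p
  out[useS] <- s[useS]
  overridden <- sum(useS & p > 0L)
  res <- if (is(primary, "LabelVolume"))
    new("LabelVolume", data = array(as.integer(out), dim(p)),
        spacing = primary@spacing, orientation = primary@orientation)
  else array(as.integer(out), dim = dim(p))
  attr(res, "overridden") <- overridden
  res
}

#' Apply a harmonization rule set
#'
#' Convenience driver for the `salt harmonize` command line: applies, in
#' order, drops (each dropped node's voxels are relabeled to its parent, or
#' to 0 if the parent is the root), merges ([mergeChildren()]), and finally
#' "other" completion ([completeWithOther()]). Region splits require extra
#' mask volumes and are applied through [splitByRegion()] directly.
#'
#' @param vol a [LabelVolume-class].
#' @param tree the [LabelTree-class].
#' @param rules list with optional character vectors `drop` and `merge`
#'   (node names) and logical `completeOther` (default TRUE).
#' @return list `(volume, tree)` as from [completeWithOther()].
#' @export
applyHarmonization <- function(vol, tree, rules = list()) {
  lab <- .volData(vol)
  for (nm in rules$drop %||% character(0)) {
    i <- match(nm, tree@name)
    if (is.na(i)) stop("unknown node in drop list: ", nm)
    tgt <- tree@parent[i]
    lab[lab == i] <- if (is.na(tree@parent[tgt])) 0L else tgt
  }
  volD <- if (is(vol, "LabelVolume"))
    new("LabelVolume", data = array(as.integer(lab), dim(lab)),
        spacing = vol@spacing, orientation = vol@orientation) else lab
  for (nm in rules$merge %||% character(0))
    volD <- mergeChildren(volD, tree, nm)
  if (isTRUE(rules$completeOther %||% TRUE))
    completeWithOther(volD, tree)
  else list(volume = volD, tree = tree)
}
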