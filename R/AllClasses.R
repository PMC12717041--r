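#' @import methods
#' @importFrom stats quantile rnorm runif setNames
#' @importFrom utils head tail
NULL

#' LabelTree: a rooted single-parent hierarchy of segmentation classes
#'
#' A `LabelTree` holds the class hierarchy that every other component of the
#' package consumes: an ordered set of named nodes, each with exactly one
#' parent (the root has none) and a kind tag. Node indices are 1-based and
#' follow the order of the configuration they were parsed from, so a tree
#' round-trips bit-identically through serialization.
#'
#' @slot name character vector of unique node names, one per node.
#' @slot parent integer vector of parent indices; `NA` for the root.
#' @slot kind character vector, each one of `"root"`, `"anatomical"`,
#'   `"other"`, `"background"`.
#'
#' @seealso [parseLabelTree()], [treeMatrices()], [encodePaths()]
#' @export
setClass("LabelTree",
  representation(name = "character", parent = "integer", kind = "character"))

.validLabelTree <- function(object) {
  n <- length(object@name)
  if (length(object@parent) != n || length(object@kind) != n)
    return("name, parent and kind must have equal length")
  if (n == 0L) return("tree must contain at least a root node")
  if (anyDuplicated(object@name))
    return(sprintf("duplicate node name: '%s'",
                   object@name[duplicated(object@name)][1L]))
  roots <- which(is.na(object@parent))
  if (length(roots) != 1L)
    return(sprintf("exactly one root required, found %d", length(roots)))
  p <- object@parent[-roots]
  if (length(p) && (any(p < 1L) || any(p > n)))
    return("parent index out of range")
  # every node must reach the root (also rules out cycles)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(object@parent[j])) {
      if (seen[j]) return("parent links contain a cycle")
      seen[j] <- TRUE
      j <- object@parent[j]
    }
  }
  bad <- !object@kind %in% c("root", "anatomical", "other", "background")
  if (any(bad)) return(sprintf("unknown node kind '%s'", object@kind[bad][1L]))
  TRUE
}
setValidity("LabelTree", .validLabelTree)

#' TreeMatrices: adjacency, reachability and sibling matrices of a label tree
#'
#' All three matrices are N x N 0/1 integer matrices with node names as
#' dimnames. `adjacency[p, c] == 1` iff `p` is the parent of `c`;
#' `reachability[a, n] == 1` iff `a` lies on the root-to-`n` path (ancestors
#' plus `n` itself, so the matrix equals the reflexive transitive closure of
#' the adjacency matrix); `sibling[m, n] == 1` iff `m` and `n` share a parent
#' (each node is a sibling of itself).
#'
#' @slot adjacency,reachability,sibling integer matrices as described above.
#' @export
setClass("TreeMatrices",
  representation(adjacency = "matrix", reachability = "matrix",
                 sibling = "matrix"))

#' PathEncoding: fixed-width bitwise codes for ancestor tests
#'
#' Each node receives a code packing, level by level, its 1-based rank within
#' its sibling group along the root path (0 below its own depth), plus a mask
#' that is all-ones over the levels the node occupies. The defining (prefix)
#' property is that `(codes[n] AND masks[a]) == codes[a]` exactly when `a` is
#' an ancestor-or-self of `n`, so ancestor tests are masked byte comparisons.
#'
#' @slot codes,masks N x B raw matrices (B bytes per node).
#' @slot bitsPerLevel integer vector of field widths, one per depth level
#'   (level 1 = root).
#' @slot bytes integer, the number of bytes B.
#' @export
setClass("PathEncoding",
  representation(codes = "matrix", masks = "matrix",
                 bitsPerLevel = "integer", bytes = "integer"))

#' VoxelGrid volumes
#'
#' `ImageVolume` carries real-valued intensities (Hounsfield units or
#' normalized \[0,1\]) on a 3-D grid with voxel spacing in mm and a 3-letter
#' anatomical orientation code; `LabelVolume` carries integer node labels on
#' the same kind of grid (0 = unlabeled). `ScoreField` and `ProbabilityField`
#' carry one channel per tree node on the last axis; a `ProbabilityField` is
#' the output of [saltActivation()] and obeys hierarchical consistency.
#'
#' @slot data numeric (ImageVolume), integer (LabelVolume) or numeric array
#'   with node channels last (ScoreField / ProbabilityField).
#' @slot spacing numeric voxel spacing in mm, one value per spatial axis.
#' @slot orientation 3-letter axis code such as `"LPI"` (empty if unknown).
#' @name volumes
NULL

#' @rdname volumes
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", orientation = "character"))

#' @rdname volumes
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", orientation = "character"))

#' @rdname volumes
#' @export
setClass("ScoreField",
  representation(data = "array", tree = "LabelTree"))

#' @rdname volumes
#' @export
setClass("ProbabilityField",
  representation(data = "array", tree = "LabelTree"))

.validVoxelVolume <- function(object) {
  if (length(object@spacing) && any(!is.finite(object@spacing) | object@spacing <= 0))
    return("spacing must be positive")
  if (length(object@orientation) && nzchar(object@orientation) &&
      !grepl("^[LRAPSI]{3}$", object@orientation))
    return("orientation must be a 3-letter code over {L,R,A,P,S,I}")
  TRUE
}
setValidity("ImageVolume", .validVoxelVolume)
setValidity("LabelVolume", function(object) {
  v <- .validVoxelVolume(object)
  if (!isTRUE(v)) return(v)
  if (length(object@data) && any(object@data < 0, na.rm = TRUE))
    return("labels must be >= 0 (0 = unlabeled)")
  TRUE
})

.validField <- function(object) {
  d <- dim(object@data)
  if (is.null(d) || length(d) < 2L)
    return("field must be an array with node channels on the last axis")
  if (d[length(d)] != length(object@tree@name))
    return(sprintf("channel count %d does not match tree size %d",
                   d[length(d)], length(object@tree@name)))
  TRUE
}
setValidity("ScoreField", .validField)
setValidity("ProbabilityField", .validField)

#' TargetField: supervision targets for the hierarchical loss
#'
#' Stores, per voxel, the deepest supervised node index (which may be an
#' internal node under partial-depth supervision) and a 0/1 supervision mask;
#' unlabeled voxels (e.g. the skipped slices of sparse annotations) carry
#' mask 0 and contribute nothing to any loss. The multi-hot reachability
#' encoding (one row per voxel, equal to the reachability column of the
#' deepest label) is materialized on demand by [multiHot()].
#'
#' @slot label integer array of deepest node indices (1-based; values on
#'   masked-out voxels are ignored).
#' @slot mask integer array of the same shape, 1 = supervised.
#' @slot tree the [LabelTree-class] the labels refer to.
#' @export
setClass("TargetField",
  representation(label = "array", mask = "array", tree = "LabelTree"))

setValidity("TargetField", function(object) {
  if (!identical(dim(object@label), dim(object@mask)))
    return("label and mask shapes differ")
  n <- length(object@tree@name)
  lab <- object@label[object@mask > 0]
  if (length(lab) && (any(lab < 1L) || any(lab > n)))
    return("supervised label index outside the tree")
  TRUE
})
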