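#' Build a phantom specification
#'
#' A phantom couples a label tree with one geometric shape per node
#' (ellipsoid or box, in voxel coordinates), a per-node mean intensity in
#' normalized \[0, 1\] CT units, a noise standard deviation, and a grid size.
#' Shapes must nest: each node's shape strictly inside its parent's, sibling
#' leaf shapes disjoint. The root's shape is the whole grid.
#'
#' @param tree a [LabelTree-class].
#' @param shapes named list (by node name, root optional) of lists
#'   `list(type = "ellipsoid"|"box", center =, semiaxes =)` in voxel units.
#' @param intensities named numeric, mean intensity per node (normalized
#'   units); nodes inherit their parent's intensity when omitted.
#' @param gridSize integer length-3 (default `c(64, 64, 64)`).
#' @param noiseSd Gaussian noise sd in normalized units (default 0.02,
#'   roughly 40 HU).
#' @param spacing voxel spacing in mm (default 1.5 isotropic).
#' @return a `PhantomSpec` list (class `"PhantomSpec"`).
#' @export
phantomSpec <- function(tree, shapes, intensities, gridSize = c(64, 64, 64),
                        noiseSd = 0.02, spacing = c(1.5, 1.5, 1.5)) {
  structure(list(tree = tree, shapes = shapes, intensities = intensities,
                 gridSize = rep_len(as.integer(gridSize), 3L),
                 noiseSd = noiseSd, spacing = rep_len(spacing, 3L)),
            class = "PhantomSpec")
}

.shapeMask <- function(shape, d) {
  cx <- shape$center; ax <- shape$semiaxes
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  if (shape$type == "box") {
    X <- abs(x - cx[1]) <= ax[1]
    Y <- abs(y - cx[2]) <= ax[2]
    Z <- abs(z - cx[3]) <= ax[3]
    outer(outer(X, Y, `&`), Z, `&`)
  } else {
    X2 <- ((x - cx[1]) / ax[1])^2
    Y2 <- ((y - cx[2]) / ax[2])^2
    Z2 <- ((z - cx[3]) / ax[3])^2
    array(outer(outer(X2, Y2, `+`), Z2, `+`) <= 1, d)
  }
}

#' Generate a nested geometric phantom
#'
#' Renders the spec's shapes onto the grid: each voxel is labeled with the
#' deepest node whose shape contains it (so the ground truth is
#' hierarchically consistent by construction), and the image is each voxel's
#' node intensity plus seeded Gaussian noise. Containment (child inside
#' parent, modulo the strictness of discretization) and sibling-leaf
#' disjointness are verified and violations raise errors.
#'
#' @param spec a `PhantomSpec` from [phantomSpec()].
#' @param seed optional integer seed for the noise.
#' @return list `(image, labels)` of [ImageVolume-class] and
#'   [LabelVolume-class].
#' @export
makePhantom <- function(spec, seed = NULL) {
  tree <- spec$tree
  d <- spec$gridSize
  depth <- nodeDepths(tree)
  masks <- vector("list", nNodes(tree))
  masks[[rootIndex(tree)]] <- array(TRUE, d)
  lab <- array(rootIndex(tree), d)
  for (i in order(depth)) {
    if (i == rootIndex(tree)) next
    nm <- tree@name[i]
    if (is.null(spec$shapes[[nm]])) next
    m <- .shapeMask(spec$shapes[[nm]], d)
    pm <- masks[[tree@parent[i]]]
    if (is.null(pm)) stop("shape given for '", nm, "' but not for its parent")
    if (any(m & !pm))
      stop("shape of '", nm, "' is not contained in its parent's shape")
    if (all(pm == m))
      stop("shape of '", nm, "' is not strictly inside its parent's shape")
    for (s in which(tree@parent == tree@parent[i])) {
      if (s != i && !is.null(masks[[s]]) && any(masks[[s]] & m))
        stop("sibling shapes of '", nm, "' overlap")
    }
    masks[[i]] <- m
    lab[m] <- i          # depth order: deepest written last
  }
  mu <- rep(NA_real_, nNodes(tree))
  mu[match(names(spec$intensities), tree@name)] <- spec$intensities
  for (i in order(depth)) if (is.na(mu[i]))
    mu[i] <- if (i == rootIndex(tree)) 0 else mu[tree@parent[i]]
  if (!is.null(seed)) set.seed(seed)
  img <- array(mu[lab], d) + array(rnorm(prod(d), sd = spec$noiseSd), d)
  list(image = new("ImageVolume", data = img, spacing = spec$spacing,
                   orientation = "LPI"),
       labels = new("LabelVolume", data = array(as.integer(lab), d),
                    spacing = spec$spacing, orientation = "LPI"))
}

#' Default nested thoracic-like phantom
#'
#' A four-level nested-ellipsoid phantom emulating (coarsely) a thorax on a
#' normalized CT scale: a soft-tissue body (0.52) in air background (0.02)
#' containing an air-rich cavity (0.25, lung-like), which contains a
#' soft-tissue organ (0.57), which contains a denser core (0.66). Intensity
#' gaps are several times the default noise sd, as organ contrasts are on
#' preprocessed CT. `seed` jitters the shape centers and semiaxes so
#' different seeds give genuinely different geometry for train/test splits.
#'
#' @param seed integer seed controlling geometry (and, via [makePhantom()],
#'   reusable for noise).
#' @param gridSize grid (default 64^3).
#' @param noiseSd noise sd (default 0.02).
#' @return a `PhantomSpec`.
#' @export
defaultPhantomSpec <- function(seed = 1, gridSize = c(64, 64, 64),
                               noiseSd = 0.02) {
  tree <- parseLabelTree(list(
    list(name = "root"),
    list(name = "background", parent = "root", kind = "background"),
    list(name = "body", parent = "root"),
    list(name = "cavity", parent = "body"),
    list(name = "organ", parent = "cavity"),
    list(name = "core", parent = "organ")))
  set.seed(seed)
  d <- rep_len(gridSize, 3L)
  c0 <- d / 2 + runif(3, -0.03, 0.03) * d
  a1 <- d * 0.42 * runif(3, 0.92, 1.0)
  # nested centers with jitter proportional to the parent's size, so child
  # shapes stay strictly inside their parents at any grid size
  c1 <- c0 + runif(3, -0.04, 0.04) * a1
  c2 <- c1 + runif(3, -0.04, 0.04) * a1
  c3 <- c2 + runif(3, -0.03, 0.03) * a1
  shapes <- list(
    body  = list(type = "ellipsoid", center = c0, semiaxes = a1),
    cavity = list(type = "ellipsoid", center = c1,
                  semiaxes = a1 * runif(3, 0.66, 0.72)),
    organ = list(type = "ellipsoid", center = c2,
                 semiaxes = a1 * runif(3, 0.42, 0.47)),
    core  = list(type = "ellipsoid", center = c3,
                 semiaxes = a1 * runif(3, 0.24, 0.28)))
  # `background` has no shape: it is the part of the root outside `body`,
  # assigned below via the root-completion convention
  spec <- phantomSpec(tree, shapes,
    intensities = c(root = 0.02, background = 0.02, body = 0.52,
                    cavity = 0.25, organ = 0.57, core = 0.66),
    gridSize = d, noiseSd = noiseSd)
  spec
}

#' Label root-level remainder voxels as background
#'
#' Phantom voxels outside every shape keep the root label; this helper moves
#' them to the tree's background node, the usual convention for CT (body vs
#' non-annotated air).
#'
#' @param labels a [LabelVolume-class] from [makePhantom()].
#' @param tree the phantom's [LabelTree-class].
#' @return relabeled [LabelVolume-class].
#' @export
rootToBackground <- function(labels, tree) {
  bg <- which(tree@kind == "background")
  if (length(bg) != 1L) stop("tree has no unique background node")
  lab <- labels@data
  lab[lab == rootIndex(tree)] <- bg
  initialize(labels, data = lab)
}

#' Sparsify a label volume to every k-th axial slice
#'
#' Emulates sparse expert annotation (e.g. every fifth slice reviewed):
#' labels are retained on slices 1, 1+k, 1+2k, ... of the last axis and the
#' returned supervision mask marks exactly those voxels. `k = 1` is the
#' identity with a full mask.
#'
#' @param labels a [LabelVolume-class] or integer array.
#' @param everyK keep every k-th slice (default 5).
#' @return list `(labels, mask)`; non-retained voxels are set to 0 in
#'   `labels` and 0 in `mask`.
#' @export
sparsify <- function(labels, everyK = 5) {
  if (everyK < 1) stop("everyK must be >= 1")
  isVol <- is(labels, "LabelVolume")
  lab <- .volData(labels)
  d <- dim(lab)
  keep <- seq(1L, d[3], by = as.integer(everyK))
  mask <- array(0L, d)
  mask[, , keep] <- 1L
  out <- lab * mask
  list(labels = if (isVol) initialize(labels, data = array(as.integer(out), d))
                else array(as.integer(out), d),
       mask = mask)
}
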