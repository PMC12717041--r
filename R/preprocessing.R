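#' NIfTI input and output
#'
#' Thin wrappers around RNifti preserving spacing and orientation. Score
#' fields travel as 4-D NIfTI with node channels on the fourth axis; label
#' maps as 3-D integer NIfTI.
#'
#' @param path file path (`.nii` / `.nii.gz`).
#' @param what `"image"` or `"label"`.
#' @return [ImageVolume-class] or [LabelVolume-class].
#' @export
readNiftiVolume <- function(path, what = c("image", "label")) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  orc <- tryCatch(RNifti::orientation(img), error = function(e) "")
  arr <- as.array(img)
  if (what == "label") {
    new("LabelVolume", data = array(as.integer(round(arr)), dim(arr)),
        spacing = sp[seq_len(min(3L, length(sp)))], orientation = orc)
  } else {
    new("ImageVolume", data = array(as.numeric(arr), dim(arr)),
        spacing = sp[seq_len(min(3L, length(sp)))], orientation = orc)
  }
}

#' @rdname readNiftiVolume
#' @param vol an [ImageVolume-class], [LabelVolume-class] or array.
#' @export
writeNiftiVolume <- function(vol, path) {
  arr <- .volData(vol)
  sp <- if (is(vol, "ImageVolume") || is(vol, "LabelVolume")) vol@spacing
        else c(1, 1, 1)
  img <- RNifti::asNifti(arr)
  if (length(sp)) RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Orientation codes name the direction each voxel axis points toward
# (e.g. "LPI": +x -> Left, +y -> Posterior, +z -> Inferior).
.axisInfo <- function(code) {
  letters <- strsplit(code, "")[[1]]
  axisOf <- c(L = 1L, R = 1L, P = 2L, A = 2L, I = 3L, S = 3L)
  posDir <- c(L = "L", R = "L", P = "P", A = "P", I = "I", S = "I")
  list(axis = axisOf[letters], flip = letters != posDir[letters])
}

#' Reorient a volume to an anatomical axis convention
#'
#' Permutes and flips the voxel axes of a volume so its orientation code
#' becomes `target` (default Left-Posterior-Inferior); spacing is permuted
#' along. Operates purely on the array and the 3-letter code.
#'
#' @param vol an [ImageVolume-class] or [LabelVolume-class] with a valid
#'   orientation code.
#' @param target 3-letter target code (default `"LPI"`).
#' @return reoriented volume of the same class.
#' @export
reorientVolume <- function(vol, target = "LPI") {
  if (!length(vol@orientation) || !nzchar(vol@orientation))
    stop("volume has no orientation metadata")
  cur <- .axisInfo(vol@orientation)
  tgt <- .axisInfo(target)
  # perm[k]: which current axis becomes output axis k
  perm <- match(tgt$axis, cur$axis)
  arr <- aperm(.volData(vol), perm)
  flip <- cur$flip[perm] != tgt$flip
  for (k in which(flip)) {
    idx <- lapply(dim(arr), seq_len)
    idx[[k]] <- rev(idx[[k]])
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  sp <- if (length(vol@spacing) == 3L) vol@spacing[perm] else vol@spacing
  initialize(vol, data = arr, spacing = sp, orientation = target)
}

# positions of output voxel centers in mm: first centers aligned
.resampleAxis <- function(nIn, spIn, spOut) {
  nOut <- floor((nIn - 1) * spIn / spOut) + 1
  (seq_len(nOut) - 1) * spOut / spIn + 1   # fractional input index
}

#' Resample a volume to a new voxel spacing
#'
#' Trilinear interpolation for images, nearest-neighbour for label maps
#' (which therefore can never invent labels absent from the input). Voxel
#' centers of the first voxel are aligned, so resampling a grid to a spacing
#' that subdivides the original reproduces the original values at the
#' original grid points.
#'
#' @param vol an [ImageVolume-class] or [LabelVolume-class] with spacing.
#' @param newSpacing target spacing in mm (default 1.5 isotropic).
#' @param method `"linear"` or `"nearest"`; defaults to `"nearest"` for
#'   label volumes and `"linear"` otherwise.
#' @return resampled volume of the same class.
#' @export
resampleVolume <- function(vol, newSpacing = c(1.5, 1.5, 1.5),
                           method = if (is(vol, "LabelVolume")) "nearest" else "linear") {
  if (length(vol@spacing) != 3L) stop("volume has no spacing metadata")
  arr <- .volData(vol)
  d <- dim(arr)
  newSpacing <- rep_len(newSpacing, 3L)
  ix <- .resampleAxis(d[1], vol@spacing[1], newSpacing[1])
  iy <- .resampleAxis(d[2], vol@spacing[2], newSpacing[2])
  iz <- .resampleAxis(d[3], vol@spacing[3], newSpacing[3])
  if (method == "nearest") {
    out <- arr[pmin(pmax(round(ix), 1), d[1]),
               pmin(pmax(round(iy), 1), d[2]),
               pmin(pmax(round(iz), 1), d[3]), drop = FALSE]
  } else {
    x0 <- pmin(floor(ix), d[1] - 1); fx <- ix - x0
    y0 <- pmin(floor(iy), d[2] - 1); fy <- iy - y0
    z0 <- pmin(floor(iz), d[3] - 1); fz <- iz - z0
    if (d[1] == 1L) { x0 <- rep(1, length(ix)); fx <- rep(0, length(ix)) }
    if (d[2] == 1L) { y0 <- rep(1, length(iy)); fy <- rep(0, length(iy)) }
    if (d[3] == 1L) { z0 <- rep(1, length(iz)); fz <- rep(0, length(iz)) }
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    FX <- array(fx, c(nx, ny, nz))
    FY <- array(rep(fy, each = nx), c(nx, ny, nz))
    FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
    corner <- function(dx, dy, dz)
      arr[pmin(x0 + dx, d[1]), pmin(y0 + dy, d[2]), pmin(z0 + dz, d[3]),
          drop = FALSE]
    out <- corner(0,0,0) * (1-FX)*(1-FY)*(1-FZ) +
           corner(1,0,0) * FX*(1-FY)*(1-FZ) +
           corner(0,1,0) * (1-FX)*FY*(1-FZ) +
           corner(1,1,0) * FX*FY*(1-FZ) +
           corner(0,0,1) * (1-FX)*(1-FY)*FZ +
           corner(1,0,1) * FX*(1-FY)*FZ +
           corner(0,1,1) * (1-FX)*FY*FZ +
           corner(1,1,1) * FX*FY*FZ
  }
  if (is(vol, "LabelVolume")) storage.mode(out) <- "integer"
  initialize(vol, data = out, spacing = newSpacing,
             orientation = vol@orientation)
}

#' Normalize Hounsfield units to \[0, 1\]
#'
#' Clips intensities to \[-1024, 1024\] HU and maps the range affinely to
#' \[0, 1\] (so -1024 -> 0, 0 -> 0.5, 1024 -> 1). Inputs already inside
#' \[0, 1\] are assumed normalized and returned unchanged, which makes the
#' preprocessing pipeline idempotent.
#'
#' @param vol an [ImageVolume-class] or numeric array.
#' @return same type, normalized.
#' @export
normalizeHU <- function(vol) {
  arr <- .volData(vol)
  rng <- range(arr, finite = TRUE)
  if (rng[1] >= 0 && rng[2] <= 1) return(vol)   # already normalized
  arr <- (pmin(pmax(arr, -1024), 1024) + 1024) / 2048
  if (is(vol, "ImageVolume")) initialize(vol, data = arr) else arr
}

#' Standard CT preprocessing pipeline
#'
#' Reorients to Left-Posterior-Inferior, resamples to 1.5 mm isotropic
#' spacing (trilinear; pass a [LabelVolume-class] through
#' [resampleVolume()] with `"nearest"` separately), and normalizes
#' Hounsfield units to \[0, 1\]. Idempotent: running it on an already
#' preprocessed volume changes nothing.
#'
#' @param img an [ImageVolume-class] with spacing and orientation metadata.
#' @param spacing target spacing (default 1.5 mm isotropic).
#' @param orientation target orientation (default `"LPI"`).
#' @return preprocessed [ImageVolume-class].
#' @export
preprocessVolume <- function(img, spacing = c(1.5, 1.5, 1.5),
                             orientation = "LPI") {
  if (!length(img@spacing)) stop("volume has no spacing metadata")
  img <- reorientVolume(img, orientation)
  img <- resampleVolume(img, spacing, method = "linear")
  normalizeHU(img)
}

#' Seeded random crop of paired image and label volumes
#'
#' Draws one spatial window uniformly over all valid offsets and applies it
#' to image and labels alike. Volumes smaller than the crop are zero-padded
#' symmetrically first (padding is labeled 0/background and excluded from
#' supervision via the returned mask).
#'
#' @param img an [ImageVolume-class] or array.
#' @param labels a [LabelVolume-class] or integer array on the same grid.
#' @param size integer crop size (default `c(192, 192, 48)`).
#' @param seed optional integer seed for reproducibility.
#' @return list `(image, labels, mask)` of arrays of dimension `size`.
#' @export
randomCrop <- function(img, labels, size = c(192, 192, 48), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ia <- .volData(img); la <- .volData(labels)
  if (!identical(dim(ia), dim(la))) stop("image and label grids differ")
  d <- dim(ia)
  size <- rep_len(as.integer(size), 3L)
  pad <- pmax(size - d, 0L)
  lo <- pad %/% 2L
  if (any(pad > 0L)) {
    nd <- d + pad
    ip <- array(0, nd); lp <- array(0L, nd); mp <- array(0L, nd)
    idx <- lapply(1:3, function(k) lo[k] + seq_len(d[k]))
    ip[idx[[1]], idx[[2]], idx[[3]]] <- ia
    lp[idx[[1]], idx[[2]], idx[[3]]] <- la
    mp[idx[[1]], idx[[2]], idx[[3]]] <- 1L
    ia <- ip; la <- lp; ma <- mp; d <- nd
  } else ma <- array(1L, d)
  off <- vapply(1:3, function(k)
    if (d[k] == size[k]) 0L else sample.int(d[k] - size[k] + 1L, 1L) - 1L,
    integer(1))
  idx <- lapply(1:3, function(k) off[k] + seq_len(size[k]))
  list(image = ia[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       labels = la[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       mask = ma[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
}
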