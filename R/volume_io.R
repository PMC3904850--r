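# NIfTI input/output, orientation handling and isotropic resampling.

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 image (.nii or .nii.gz), reorients the data to the
#' internal RAS convention (axis 1 = sagittal left-right, axis 2 =
#' posterior-anterior, axis 3 = inferior-superior) and records the original
#' orientation for write-back. Intensities are returned unmodified.
#'
#' @param path path to a readable NIfTI-1 file.
#' @return A \code{\link{BrainVolume}}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("readVolume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("readVolume: cannot read '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("readVolume: expected a 3-D image, got ", length(dim(img)), "-D")
  src <- RNifti::orientation(img)
  if (!identical(src, "RAS")) RNifti::orientation(img) <- "RAS"
  spc <- RNifti::pixdim(img)[1:3]
  vol <- new("BrainVolume", data = array(as.numeric(img), dim(img)),
             spacing = as.numeric(spc), origin = c(0, 0, 0),
             orientation = "RAS", sourceOrientation = src)
  validObject(vol)
  vol
}

#' Write a volume to NIfTI
#'
#' @param vol a \code{\link{BrainVolume}}.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopIfNot3D(vol)
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a set of structure masks as an integer label map
#'
#' Encodes disjoint binary masks into one integer NIfTI volume (0 reserved
#' for background). Reading the file back and thresholding per label
#' reproduces each mask exactly.
#'
#' @param masks named list of \code{\link{BrainMask}} objects on one grid.
#' @param labels named integer vector mapping structure name to a distinct
#'   positive label (defaults to 1, 2, ... in list order).
#' @param path output path.
#' @return The label volume (invisibly).
#' @export
writeLabelMap <- function(masks, path, labels = NULL) {
  if (!length(masks)) stop("writeLabelMap: no masks")
  if (is.null(labels))
    labels <- stats::setNames(seq_along(masks), names(masks))
  labels <- labels[names(masks)]
  if (any(is.na(labels)) || any(labels <= 0) || anyDuplicated(labels))
    stop("writeLabelMap: labels must be distinct positive integers")
  d <- dim(masks[[1]]@data)
  lab <- array(0L, d)
  for (i in seq_along(masks)) {
    m <- masks[[i]]@data
    if (!identical(dim(m), d))
      stop("writeLabelMap: geometry mismatch between masks")
    if (any(lab[m] != 0L))
      stop("writeLabelMap: overlapping masks — structures must be disjoint")
    lab[m] <- as.integer(labels[i])
  }
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- masks[[1]]@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(BrainVolume(lab, spacing = masks[[1]]@spacing))
}

# Cubic (Catmull-Rom) interpolation weights for fractional offset f in [0,1).
.catmullRomWeights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  cbind(-0.5 * f3 + f2 - 0.5 * f,
        1.5 * f3 - 2.5 * f2 + 1,
        -1.5 * f3 + 2 * f2 + 0.5 * f,
        0.5 * f3 - 0.5 * f2)
}

# Resample one axis of a 3-D array from spacing s to spacing t.
.resampleAxis <- function(a, axis, s, t, order) {
  d <- dim(a)
  nIn <- d[axis]
  nOut <- max(1L, floor((nIn - 1) * s / t + 1e-9) + 1L)
  if (nIn == 1L) nOut <- 1L
  u <- (seq_len(nOut) - 1) * t / s      # 0-based input coordinate
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = nIn)
  clampi <- function(i) pmax(0L, pmin(nIn - 1L, i))
  out <- if (order == 0L) {
    m[clampi(as.integer(round(u))) + 1L, , drop = FALSE]
  } else if (order == 1L) {
    i0 <- clampi(floor(u)); f <- u - i0
    m[clampi(i0) + 1L, , drop = FALSE] * (1 - f) +
      m[clampi(i0 + 1L) + 1L, , drop = FALSE] * f
  } else {
    i0 <- floor(u); f <- u - i0
    w <- .catmullRomWeights(f)
    acc <- 0
    for (k in -1:2)
      acc <- acc + m[clampi(i0 + k) + 1L, , drop = FALSE] * w[, k + 2L]
    acc
  }
  dOut <- d; dOut[axis] <- nOut
  aperm(array(out, c(nOut, d[perm][-1])), order(perm))
}

#' Resample a volume to an isotropic grid
#'
#' Separable interpolation (cubic Catmull-Rom by default, matching the
#' cubic-spline resampling of the original pipeline) onto a grid of the
#' requested isotropic spacing. The physical extent is preserved to within
#' one voxel; the first voxel centre is kept fixed.
#'
#' @param vol a \code{\link{BrainVolume}}.
#' @param target isotropic voxel size in mm (e.g. 0.5).
#' @param order interpolation degree: 0 (nearest), 1 (linear) or 3 (cubic,
#'   default).
#' @return A resampled \code{\link{BrainVolume}}.
#' @export
resampleIsotropic <- function(vol, target, order = 3L) {
  stopIfNot3D(vol)
  if (length(target) != 1L || !is.finite(target) || target <= 0)
    stop("resampleIsotropic: target spacing must be positive")
  if (!order %in% c(0L, 1L, 3L))
    stop("resampleIsotropic: order must be 0, 1 or 3")
  a <- vol@data
  for (axis in 1:3)
    a <- .resampleAxis(a, axis, vol@spacing[axis], target, as.integer(order))
  new("BrainVolume", data = a, spacing = rep(target, 3), origin = vol@origin,
      orientation = "RAS", sourceOrientation = vol@sourceOrientation)
}

# Trilinear sampling of a 3-D array at fractional 0-based voxel coordinates
# (n x 3 matrix). Points outside the grid return NA.
.trilinearSample <- function(a, pts) {
  d <- dim(a)
  ok <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  p <- pts[ok, , drop = FALSE]
  i0 <- pmin(floor(p), rep(d - 2L, each = nrow(p)))
  i0 <- pmax(i0, 0)
  f <- p - i0
  g <- function(dx, dy, dz)
    a[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)]
  v <- g(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    g(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    g(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    g(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    g(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    g(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    g(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- v
  out
}
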