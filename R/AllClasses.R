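# S4 carrier classes for the segmentation pipeline.
#
# Internal geometric convention (enforced on load, see readVolume):
#   axis 1 = sagittal, left -> right
#   axis 2 = posterior -> anterior
#   axis 3 = inferior -> superior
# i.e. RAS voxel order. In-slice points are (y, z) pairs of 1-based voxel
# indices on a sagittal slice; 3-D points are (x, y, z). Physical (mm)
# coordinates place the centre of voxel (1,1,1) at `origin`, so
# mm = (index - 1) * spacing + origin.

#' 3-D intensity volume
#'
#' A scalar intensity grid with voxel spacing, axis orientation and origin.
#' All pipeline processing assumes the RAS axis convention (axis 1 sagittal
#' left-right, axis 2 posterior-anterior, axis 3 inferior-superior);
#' \code{\link{readVolume}} reorients on load and records the original
#' orientation for write-back.
#'
#' @slot data numeric 3-D array of intensities.
#' @slot spacing numeric(3), voxel edge lengths in mm (strictly positive).
#' @slot origin numeric(3), mm position of the centre of voxel (1,1,1).
#' @slot orientation single string naming the internal axis convention
#'   (always \code{"RAS"} after load).
#' @slot sourceOrientation orientation string of the file the volume was read
#'   from (used when writing results back).
#' @exportClass BrainVolume
setClass("BrainVolume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    orientation = "character",
    sourceOrientation = "character"
  ),
  prototype(
    spacing = c(1, 1, 1), origin = c(0, 0, 0),
    orientation = "RAS", sourceOrientation = "RAS"
  )
)

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "all axes must have length >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive numbers")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (length(object@orientation) != 1L || object@orientation != "RAS")
    msg <- c(msg, "internal orientation must be 'RAS' (axis 1 sagittal)")
  if (length(msg)) msg else TRUE
})

#' Binary mask (2-D slice or 3-D volume)
#'
#' Boolean grid sharing the geometry of its source volume (or a declared
#' sagittal slice of it).
#'
#' @slot data logical array, 2-D or 3-D.
#' @slot spacing numeric voxel spacing (mm), one value per data axis.
#' @slot origin mm position of the first voxel centre.
#' @exportClass BrainMask
setClass("BrainMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("BrainMask", function(object) {
  msg <- character()
  nd <- length(dim(object@data))
  if (!nd %in% c(2L, 3L)) msg <- c(msg, "mask must be 2-D or 3-D")
  if (!is.logical(object@data)) msg <- c(msg, "mask data must be logical")
  if (length(object@spacing) != nd || any(object@spacing <= 0))
    msg <- c(msg, "spacing must match mask dimensionality and be positive")
  if (length(msg)) msg else TRUE
})

#' Triangle surface mesh
#'
#' @slot vertices numeric matrix (n x 3) of mm coordinates.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix")
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (nrow(object@faces) > 0) {
    if (max(object@faces) > nrow(object@vertices) || min(object@faces) < 1)
      msg <- c(msg, "face indices out of range")
    if (any(object@faces[, 1] == object@faces[, 2] |
            object@faces[, 1] == object@faces[, 3] |
            object@faces[, 2] == object@faces[, 3]))
      msg <- c(msg, "degenerate faces (repeated vertex)")
  }
  if (length(msg)) msg else TRUE
})

#' Threshold configuration
#'
#' Correction factors applied to the base Otsu threshold at each pipeline
#' stage, plus the CLAHE contrast-enhancement parameters. The base threshold
#' t1 is computed within the head foreground (see
#' \code{\link{correctedThreshold}}); the stage threshold is
#' \code{factor * t1}, clipped to the image intensity range.
#'
#' @slot c_cc factor for the corpus-callosum threshold (stage 1).
#' @slot c_bs factor for the mid-sagittal brainstem threshold (stages 1-2).
#' @slot c_3d factor for the per-slice threshold of the 3-D segmentation.
#' @slot clahe_clip normalized CLAHE clip limit in (0, 1].
#' @slot clahe_tiles total CLAHE tile count (must be a perfect square).
#' @slot cc_radius_frac search radius for the corpus callosum around the
#'   head gravity centre, as a fraction of the slice diagonal.
#' @exportClass ThresholdConfig
setClass("ThresholdConfig",
  representation(
    c_cc = "numeric", c_bs = "numeric", c_3d = "numeric",
    clahe_clip = "numeric", clahe_tiles = "numeric",
    cc_radius_frac = "numeric"
  ),
  prototype(
    c_cc = 1.3, c_bs = 1.1, c_3d = 1.1,
    clahe_clip = 0.02, clahe_tiles = 64, cc_radius_frac = 0.25
  )
)

setValidity("ThresholdConfig", function(object) {
  msg <- character()
  for (s in c("c_cc", "c_bs", "c_3d"))
    if (length(slot(object, s)) != 1L || slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  if (object@clahe_clip <= 0 || object@clahe_clip > 1)
    msg <- c(msg, "clahe_clip must lie in (0, 1]")
  if (object@clahe_tiles < 1 ||
      (sqrt(object@clahe_tiles) %% 1) > 1e-9)
    msg <- c(msg, "clahe_tiles must be a positive perfect square")
  if (object@cc_radius_frac <= 0 || object@cc_radius_frac > 1)
    msg <- c(msg, "cc_radius_frac must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Anatomical landmark set of the mid-sagittal slice
#'
#' Named points, in (y, z) voxel indices of the mid-sagittal slice, of the
#' Oba/Luft parcellation scheme: the superior (p1) and inferior (p2) pontine
#' notches bounding the anterior pontine hump, the inferior (p3) and superior
#' edges of the quadrigeminal plate, the mammillary point at the rostral
#' midbrain, and the two brainstem dorsum points used for the cerebellum
#' plane.
#'
#' @slot p1,p2,p3,mammillary,qp_superior numeric(2) in-slice points (y, z).
#' @slot dorsum 2 x 2 matrix, one dorsum point per row.
#' @slot qp_mask \code{BrainMask} of the quadrigeminal plate.
#' @slot sliceIndex sagittal index of the mid-sagittal slice.
#' @slot flags character vector of low-confidence annotations.
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(
    p1 = "numeric", p2 = "numeric", p3 = "numeric",
    mammillary = "numeric", qp_superior = "numeric",
    dorsum = "matrix", qp_mask = "BrainMask",
    sliceIndex = "numeric", flags = "character"
  ),
  prototype(flags = character())
)

setValidity("LandmarkSet", function(object) {
  msg <- character()
  for (s in c("p1", "p2", "p3", "mammillary", "qp_superior"))
    if (length(slot(object, s)) != 2L)
      msg <- c(msg, paste(s, "must be an in-slice (y, z) pair"))
  if (length(msg) == 0L) {
    if (object@p1[2] <= object@p2[2])
      msg <- c(msg, "p1 must be superior to p2")
    qp <- object@qp_mask@data
    if (any(qp)) {
      idx <- which(qp, arr.ind = TRUE)
      if (object@p3[1] < min(idx[, 1]) || object@p3[1] > max(idx[, 1]) ||
          object@p3[2] < min(idx[, 2]) || object@p3[2] > max(idx[, 2]))
        msg <- c(msg, "p3 must lie inside the quadrigeminal plate bounding box")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Oriented cut planes partitioning the brainstem
#'
#' Each plane is stored as a list with mm-space \code{point} and unit
#' \code{normal}. \code{lineA} (caudal midbrain border, through p1 and p3)
#' and \code{lineB} (inferior pons limit, through p2) share their normal
#' exactly; \code{cranialMB} passes through the mammillary point and the
#' superior quadrigeminal edge; \code{cerebellum} is the coronal plane
#' through the brainstem dorsum. All are extruded along the left-right axis.
#'
#' @slot cranialMB,lineA,lineB,cerebellum lists with elements \code{point}
#'   and \code{normal} (numeric(3), mm).
#' @exportClass CutPlanes
setClass("CutPlanes",
  representation(
    cranialMB = "list", lineA = "list", lineB = "list", cerebellum = "list"
  )
)

setValidity("CutPlanes", function(object) {
  ok <- function(p) is.list(p) && all(c("point", "normal") %in% names(p)) &&
    length(p$point) == 3L && length(p$normal) == 3L &&
    abs(sqrt(sum(p$normal^2)) - 1) < 1e-8
  msg <- character()
  for (s in c("cranialMB", "lineA", "lineB", "cerebellum"))
    if (!ok(slot(object, s)))
      msg <- c(msg, paste(s, "must be a list(point, normal) with unit normal"))
  if (length(msg) == 0L &&
      !identical(object@lineA$normal, object@lineB$normal))
    msg <- c(msg, "lineA and lineB must share their normal exactly")
  if (length(msg)) msg else TRUE
})

#' Synthetic head phantom specification
#'
#' Parameters of the T1-like head phantom used for validation. Tissue means
#' are on a [0, 1] intensity scale and ordered
#' CSF < head tissue < plate <= brainstem < corpus callosum. Geometry is a
#' named list of structure dimensions (mm); see
#' \code{\link{defaultPhantomSpec}} for the fields and defaults.
#'
#' @slot shape integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot intensities named numeric vector of tissue means.
#' @slot geometry named list of structure dimensions.
#' @slot tilt_deg brainstem-axis tilt about the sagittal axis (degrees).
#' @slot scale global size factor applied to the brainstem complex.
#' @slot noise_sd additive Gaussian noise sd (intensity units).
#' @slot bias_amp amplitude of the low-order multiplicative bias field.
#' @slot blur_sigma partial-volume edge blur sd (voxels).
#' @slot pons_atrophy caudal pontine span factor (1 = none; 0.9 emulates the
#'   ~10 percent pontine loss reported in Alzheimer's disease).
#' @slot seed RNG seed for the noise and bias draws.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "numeric", spacing = "numeric", intensities = "numeric",
    geometry = "list", tilt_deg = "numeric", scale = "numeric",
    noise_sd = "numeric", bias_amp = "numeric", blur_sigma = "numeric",
    pons_atrophy = "numeric", seed = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 32))
    msg <- c(msg, "shape must be three grid sizes >= 32")
  need <- c("background", "csf", "head", "brainstem", "plate", "cc")
  if (!all(need %in% names(object@intensities)))
    msg <- c(msg, paste("intensities must name", paste(need, collapse = ", ")))
  else {
    i <- object@intensities
    if (!(i["csf"] < i["head"] && i["head"] < i["brainstem"] &&
          i["brainstem"] <= i["plate"] && i["plate"] < i["cc"]))
      msg <- c(msg, "tissue means must be ordered csf < head < brainstem <= plate < cc")
  }
  if (object@noise_sd < 0 || object@bias_amp < 0 || object@blur_sigma < 0)
    msg <- c(msg, "noise_sd, bias_amp and blur_sigma must be >= 0")
  if (object@scale <= 0 || object@pons_atrophy <= 0 || object@pons_atrophy > 1)
    msg <- c(msg, "scale must be > 0 and pons_atrophy in (0, 1]")
  if (abs(object@tilt_deg) > 15)
    msg <- c(msg, "tilt_deg beyond +/-15 degrees is not supported")
  if (length(msg)) msg else TRUE
})

#' Result of the full brainstem segmentation pipeline
#'
#' @slot midbrain,pons \code{BrainMask} on the common working grid
#'   (0.5 mm by default); guaranteed disjoint.
#' @slot volumes named numeric, structure volumes in mm^3 (voxel count times
#'   voxel volume, exactly).
#' @slot meshes named list of \code{SurfaceMesh} objects (possibly empty).
#' @slot provenance list with the configuration, landmarks, cut planes,
#'   mid-sagittal index and per-stage QC values of the run.
#' @exportClass BrainstemSegmentation
setClass("BrainstemSegmentation",
  representation(
    midbrain = "BrainMask", pons = "BrainMask",
    volumes = "numeric", meshes = "list", provenance = "list"
  )
)

setValidity("BrainstemSegmentation", function(object) {
  msg <- character()
  if (!identical(dim(object@midbrain@data), dim(object@pons@data)))
    msg <- c(msg, "midbrain and pons masks must share one grid")
  else if (any(object@midbrain@data & object@pons@data))
    msg <- c(msg, "midbrain and pons must be disjoint")
  vox <- prod(object@midbrain@spacing)
  if (!isTRUE(all.equal(unname(object@volumes[["midbrain"]]),
                        sum(object@midbrain@data) * vox)) ||
      !isTRUE(all.equal(unname(object@volumes[["pons"]]),
                        sum(object@pons@data) * vox)))
    msg <- c(msg, "volumes must equal voxel count x voxel volume")
  if (length(msg)) msg else TRUE
})

## ---- constructors and accessors ------------------------------------------

#' Create a BrainVolume
#'
#' @param data 3-D numeric array (RAS axis order).
#' @param spacing voxel spacing in mm.
#' @param origin mm position of the first voxel centre.
#' @return A \code{\link{BrainVolume}}.
#' @export
BrainVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a BrainMask
#'
#' @param data logical array (2-D slice or 3-D volume).
#' @param spacing voxel spacing, one value per axis.
#' @param origin mm position of the first voxel centre.
#' @return A \code{\link{BrainMask}}.
#' @export
BrainMask <- function(data, spacing = rep(1, length(dim(data))),
                      origin = rep(0, length(dim(data)))) {
  storage.mode(data) <- "logical"
  new("BrainMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Default threshold configuration
#'
#' Correction factors calibrated on the default phantom such that the corpus
#' callosum separates from pericallosal tissue and the brainstem is recovered
#' with Dice >= 0.95 (see the methods vignette for the calibration account).
#'
#' @param ... named overrides for any \code{\link{ThresholdConfig}} slot.
#' @return A \code{\link{ThresholdConfig}}.
#' @export
#' @examples
#' cfg <- thresholdConfig(c_cc = 1.4)
thresholdConfig <- function(...) {
  args <- list(...)
  obj <- new("ThresholdConfig")
  for (nm in names(args)) slot(obj, nm) <- as.numeric(args[[nm]])
  validObject(obj)
  obj
}

#' @export
#' @rdname voxelData
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Extract the raw data array
#'
#' @param x a \code{BrainVolume} or \code{BrainMask}.
#' @return The underlying array.
#' @export
setMethod("voxelData", "BrainVolume", function(x) x@data)

#' @rdname voxelData
#' @export
setMethod("voxelData", "BrainMask", function(x) x@data)

#' @export
#' @rdname voxelSpacing
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Voxel spacing in mm
#'
#' @param x a \code{BrainVolume} or \code{BrainMask}.
#' @return Numeric vector of voxel edge lengths.
#' @export
setMethod("voxelSpacing", "BrainVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "BrainMask", function(x) x@spacing)

#' @export
#' @rdname voxelCount
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Number of foreground voxels V(L)
#'
#' @param x a \code{BrainMask}.
#' @return Integer count of TRUE voxels.
#' @export
setMethod("voxelCount", "BrainMask", function(x) sum(x@data))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask %s, %d foreground voxels (%.1f mm^3)\n",
              paste(d, collapse = " x "), sum(object@data),
              sum(object@data) * prod(object@spacing)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, volume %.1f mm^3\n",
              nrow(object@vertices), nrow(object@faces),
              meshVolume(object)))
})

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf(
    "ThresholdConfig: c_cc=%.3g c_bs=%.3g c_3d=%.3g clahe(clip=%.3g, tiles=%d)\n",
    object@c_cc, object@c_bs, object@c_3d, object@clahe_clip,
    as.integer(object@clahe_tiles)))
})

setMethod("show", "LandmarkSet", function(object) {
  fmt <- function(p) sprintf("(%g, %g)", p[1], p[2])
  cat("LandmarkSet on sagittal slice", object@sliceIndex, "\n",
      " p1 (sup. pontine notch):", fmt(object@p1), "\n",
      " p2 (inf. pontine notch):", fmt(object@p2), "\n",
      " p3 (inf. quadrigeminal):", fmt(object@p3), "\n",
      " mammillary:", fmt(object@mammillary),
      " qp_superior:", fmt(object@qp_superior), "\n")
  if (length(object@flags))
    cat(" flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "BrainstemSegmentation", function(object) {
  cat("BrainstemSegmentation\n")
  cat(sprintf("  midbrain: %8.1f mm^3\n", object@volumes[["midbrain"]]))
  cat(sprintf("  pons:     %8.1f mm^3\n", object@volumes[["pons"]]))
  cat(sprintf("  grid: %s at %s mm\n",
              paste(dim(object@midbrain@data), collapse = " x "),
              paste(format(object@midbrain@spacing, digits = 3),
                    collapse = " x ")))
})
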