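# Stage 3 — carve the midbrain and pons subvolumes with the cut planes,
# segment them slice-by-slice on the 0.5 mm grid, and separate the middle
# cerebellar peduncles.

#' Zero a volume outside a set of half-spaces
#'
#' Voxels on the kept side of every constraint retain their intensity; all
#' others are set to zero. Sidedness uses the signed distance to each plane
#' with the stated operator; voxels exactly on a plane are kept or dropped
#' by the operator, giving a fixed tie rule (the pipeline assigns on-plane
#' voxels to the superior/anterior structure).
#'
#' @param vol a \code{\link{BrainVolume}}.
#' @param constraints list of constraints, each a list with \code{plane}
#'   (list of mm \code{point} and unit \code{normal}) and \code{op} (one of
#'   \code{">=", ">", "<", "<="}; default \code{">="}).
#' @return A \code{\link{BrainVolume}} with attribute \code{empty} set to
#'   TRUE (with a warning) when every voxel was excluded.
#' @export
cropBetweenPlanes <- function(vol, constraints) {
  stopIfNot3D(vol)
  d <- dim(vol@data)
  keep <- array(TRUE, d)
  for (ct in constraints) {
    sd <- planeSignedDistance(ct$plane, d, vol@spacing, vol@origin)
    op <- if (is.null(ct$op)) ">=" else ct$op
    keep <- keep & switch(op,
      ">=" = sd >= 0, ">" = sd > 0, "<" = sd < 0, "<=" = sd <= 0,
      stop("cropBetweenPlanes: unknown operator ", op))
  }
  a <- vol@data
  a[!keep] <- 0
  out <- new("BrainVolume", data = a, spacing = vol@spacing,
             origin = vol@origin, orientation = "RAS",
             sourceOrientation = vol@sourceOrientation)
  if (!any(keep)) {
    warning("cropBetweenPlanes: constraints exclude every voxel")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Slice-wise segmentation of a cropped structure subvolume
#'
#' For every sagittal slice of the subvolume: binarization at the corrected
#' per-slice threshold (\code{c_3d} times the base Otsu threshold of the
#' slice, recomputed slice by slice so slow intensity shading is absorbed),
#' and selection of the largest 8-connected component. Slices with no
#' acceptable component contribute nothing. Two sanity guards reject
#' degenerate slices: components smaller than \code{min_area} pixels, and
#' components filling more than \code{max_fill} of the in-crop area (a
#' near-uniform tissue slab rather than a structure). CLAHE enhancement of
#' each slice before thresholding is available via \code{enhance}; it
#' benefits strongly shaded acquisitions but amplifies noise on low-texture
#' data, so it is off by default (see the methods vignette).
#'
#' @param subvol cropped \code{\link{BrainVolume}} (resampled to the working
#'   resolution first).
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param min_area minimum component area per slice (pixels).
#' @param max_fill maximum fraction of the in-crop area a component may
#'   occupy.
#' @param global_threshold use one threshold (from the pooled subvolume
#'   histogram) for all slices instead of per-slice thresholds.
#' @param denoise apply the 3x3 median prefilter to each slice.
#' @param presmooth Gaussian pre-smoothing sd (pixels of the working grid).
#' @param enhance apply CLAHE to each slice before thresholding.
#' @return A 3-D \code{\link{BrainMask}} on the subvolume grid.
#' @export
segmentStructure <- function(subvol, cfg = thresholdConfig(), min_area = 20L,
                             max_fill = 0.6, global_threshold = FALSE,
                             denoise = TRUE, presmooth = 1.0,
                             enhance = FALSE) {
  stopIfNot3D(subvol, "subvol")
  a <- subvol@data
  d <- dim(a)
  out <- array(FALSE, d)
  tGlob <- NULL
  if (global_threshold) {
    nz <- a[a > 0]
    tGlob <- correctedThreshold(nz, cfg@c_3d,
                                mask = nz > otsuThreshold(nz))
  }
  for (x in seq_len(d[1])) {
    sl <- a[x, , ]
    support <- sl > 0
    if (sum(support) < 4 * min_area) next
    if (denoise) { sl <- medianFilter3(sl); sl[!support] <- 0 }
    if (presmooth > 0) { sl <- gaussianBlur2d(sl, presmooth); sl[!support] <- 0 }
    if (enhance && !global_threshold) {
      e <- tryCatch(claheEnhance(sl, cfg@clahe_clip, cfg@clahe_tiles),
                    error = function(err) NULL)
      if (is.null(e)) next
      sl <- e
      sl[!support] <- 0
    }
    t <- if (global_threshold) as.numeric(tGlob) else
      tryCatch(as.numeric(.stageThreshold(sl, cfg@c_3d)),
               error = function(err) NA_real_)
    if (is.na(t)) next
    m <- sl > t & support
    comps <- connectedComponents(m, 8L)
    if (comps$n == 0L) next
    sel <- selectComponent(comps, "largest")
    if (sum(sel) < min_area) next
    if (sum(sel) > max_fill * sum(support)) next
    out[x, , ] <- sel
  }
  if (!any(out))
    stop("segmentStructure: all slices empty for this structure")
  BrainMask(out, spacing = subvol@spacing, origin = subvol@origin)
}

#' Structure volume in cubic millimetres
#'
#' V = number of foreground voxels times the voxel volume.
#'
#' @param mask a \code{\link{BrainMask}} (or logical array with
#'   \code{spacing} given).
#' @param spacing voxel spacing; taken from the mask when omitted.
#' @return Volume in mm^3.
#' @export
computeVolume <- function(mask, spacing = NULL) {
  if (is(mask, "BrainMask")) {
    if (is.null(spacing)) spacing <- mask@spacing
    mask <- mask@data
  }
  if (is.null(spacing)) stop("computeVolume: spacing required")
  sum(mask) * prod(spacing)
}

#' Separate the middle cerebellar peduncles from the pons
#'
#' Builds a 40 mm slab of 0.5 mm oblique coronal sections tangent to the
#' floor of the fourth ventricle (the least-squares line through the
#' posterior brainstem contour between the lineA and lineB rows on the
#' mid-sagittal slice). On the section where the superior-cerebellar-
#' peduncle component is widest, the outermost left and right mask pixels
#' define two vertical cut planes; pons voxels lateral to either plane are
#' removed. When no peduncle is found the mask is returned unchanged with a
#' warning.
#'
#' @param ponsMask 3-D \code{\link{BrainMask}} of the pons (working grid).
#' @param vol the full-resolution source \code{\link{BrainVolume}}.
#' @param lmres result of \code{\link{detectLandmarks}}.
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param slab_mm slab thickness posterior to the ventricle floor (mm).
#' @param section_mm section spacing (mm).
#' @param radius_mm peduncle search radius around the midline reference.
#' @param min_width_mm smallest credible peduncle width.
#' @param max_width_mm widest credible peduncle span; sections whose
#'   candidate component union is wider (typically the cerebellum merging
#'   into the field) are ignored.
#' @return The refined pons \code{\link{BrainMask}}; attribute
#'   \code{mcp_margins} carries the mm cut positions when applied.
#' @export
separateMCP <- function(ponsMask, vol, lmres, cfg = thresholdConfig(),
                        slab_mm = 40, section_mm = 0.5, radius_mm = 12,
                        min_width_mm = 5, max_width_mm = 30) {
  if (!any(ponsMask@data)) stop("separateMCP: empty pons mask")
  bs <- lmres$bsMask@data
  planes <- lmres$planes
  sp <- vol@spacing; or <- vol@origin
  post <- .posteriorExtent(bs)
  zA <- lmres$dorsum[1, 2]; zB <- lmres$dorsum[2, 2]
  rows <- seq(min(zA, zB), max(zA, zB))
  rows <- rows[!is.na(post[rows])]
  if (length(rows) < 3) {
    warning("separateMCP: fourth-ventricle floor not estimable; unchanged")
    return(ponsMask)
  }
  ymm <- voxelToMM(post[rows], 2, sp, or)
  zmm <- voxelToMM(rows, 3, sp, or)
  fit <- stats::lm.fit(cbind(1, zmm), ymm)
  b <- fit$coefficients[2]
  u2 <- unitVector(c(b, 1))          # floor-line direction in (y, z)
  n2 <- c(-u2[2], u2[1])             # perpendicular
  if (n2[1] > 0) n2 <- -n2           # point posterior (decreasing y)
  P0 <- c(mean(ymm), mean(zmm))

  xmid <- voxelToMM(lmres$sliceIndex, 1, sp, or)
  xs <- seq(xmid - 30, xmid + 30, by = section_mm)
  # reference position of the superior peduncles along the floor line:
  # project the superior pontine notch (p1)
  p1mm <- c(voxelToMM(lmres$landmarks@p1[1], 2, sp, or),
            voxelToMM(lmres$landmarks@p1[2], 3, sp, or))
  bref <- sum((p1mm - P0) * u2)
  bs_ <- seq(bref - 30, bref + 30, by = section_mm)

  bestWidth <- -Inf; margins <- NULL
  nSect <- max(1L, round(slab_mm / section_mm))
  base <- as.matrix(expand.grid(x = xs, b = bs_))
  for (k in seq_len(nSect)) {
    dk <- (k - 0.5) * section_mm
    yz <- cbind(P0[1] + dk * n2[1] + base[, "b"] * u2[1],
                P0[2] + dk * n2[2] + base[, "b"] * u2[2])
    pts <- cbind((base[, "x"] - or[1]) / sp[1],
                 (yz[, 1] - or[2]) / sp[2],
                 (yz[, 2] - or[3]) / sp[3])
    v <- .trilinearSample(vol@data, pts)
    img <- matrix(v, nrow = length(xs))
    img[is.na(img)] <- 0
    if (sum(img > 0) < 200) next
    img <- gaussianBlur2d(img, 1)      # suppress speckle bridges
    t <- tryCatch(as.numeric(.stageThreshold(img, cfg@c_3d)),
                  error = function(e) NA_real_)
    if (is.na(t)) next
    comps <- connectedComponents(img > t, 8L)
    if (comps$n == 0L) next
    # peduncle components: centroid within radius of the midline reference
    cx <- (length(xs) + 1) / 2
    cbp <- (length(bs_) + 1) / 2   # bref position in section coordinates
    dd <- sqrt(((comps$centroids[, 1] - cx) * section_mm)^2 +
                 ((comps$centroids[, 2] - cbp) * section_mm)^2)
    ped <- which(dd <= radius_mm & comps$sizes >= 40L)
    if (!length(ped)) next
    sel <- comps$labels %in% ped
    dim(sel) <- dim(img)
    xr <- range(which(rowSums(sel) > 0))
    width <- (xr[2] - xr[1]) * section_mm
    if (width > max_width_mm) next
    if (width > bestWidth) {
      bestWidth <- width
      margins <- xs[xr]
    }
  }
  if (is.null(margins) || bestWidth < min_width_mm ||
      margins[1] >= xmid || margins[2] <= xmid) {
    warning("separateMCP: peduncle margins not found; pons unchanged")
    return(ponsMask)
  }
  d <- dim(ponsMask@data)
  xPos <- ponsMask@origin[1] + (seq_len(d[1]) - 1) * ponsMask@spacing[1]
  lateral <- xPos < margins[1] | xPos > margins[2]
  out <- ponsMask@data
  out[lateral, , ] <- FALSE
  res <- BrainMask(out, spacing = ponsMask@spacing,
                   origin = ponsMask@origin)
  attr(res, "mcp_margins") <- margins
  res
}

#' Run the full brainstem segmentation pipeline
#'
#' Executes mid-sagittal detection, landmark extraction, cut-plane cropping,
#' isotropic resampling to the working resolution, slice-wise segmentation
#' of midbrain and pons, and (optionally) middle-cerebellar-peduncle
#' separation. Deterministic for fixed input and configuration.
#'
#' @param vol input \code{\link{BrainVolume}}, assumed rigidly aligned to
#'   template orientation (use \code{\link{rigidRegisterToTemplate}} first
#'   if not).
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param resolution working isotropic voxel size in mm (default 0.5).
#' @param mcpSeparation apply \code{\link{separateMCP}} to the pons.
#' @param meshes also extract surface meshes of both structures.
#' @param mcp_margin_mm extra sagittal margin kept for the pons so the
#'   peduncles are available for separation.
#' @return A \code{\link{BrainstemSegmentation}}.
#' @export
runPipeline <- function(vol, cfg = thresholdConfig(), resolution = 0.5,
                        mcpSeparation = TRUE, meshes = FALSE,
                        mcp_margin_mm = 10) {
  t0 <- proc.time()[3]
  ms <- findMidsagittal(vol, cfg)
  lmres <- detectLandmarks(vol, cfg, ms = ms)
  planes <- lmres$planes
  sp <- vol@spacing; or <- vol@origin
  tStage12 <- proc.time()[3]

  # sagittal extent of the brainstem: contiguous nonzero-area run of the
  # stage-1 profile containing the mid-sagittal slice
  prof <- ms$profile
  pos <- prof$upper_bs_area > 0
  i0 <- which(prof$slice == ms$index)
  lo <- i0; while (lo > 1 && pos[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < nrow(prof) && pos[hi + 1]) hi <- hi + 1
  xlo <- prof$slice[lo]; xhi <- prof$slice[hi]
  marginVox <- ceiling(mcp_margin_mm / sp[1])

  # working bounding box (1 mm frame)
  d <- dim(vol@data)
  r1 <- lmres$r1
  corners <- rbind(r1@p1cc, r1@p2cc,
                   r1@p1cc + r1@n * (2 / 3) * r1@L,
                   r1@p2cc + r1@n * (2 / 3) * r1@L)
  yRange <- c(max(1, floor(min(corners[, 1])) - 5),
              min(d[2], ceiling(max(corners[, 1])) + 5))
  zAt <- function(plane, yIdx) {
    ymm <- voxelToMM(yIdx, 2, sp, or)
    zmm <- plane$point[3] - plane$normal[2] / plane$normal[3] *
      (ymm - plane$point[2])
    mmToVoxel(zmm, 3, sp, or)
  }
  zLo <- min(zAt(planes@lineB, yRange)) - 8
  zHi <- max(zAt(planes@cranialMB, yRange)) + 8
  zRange <- c(max(1, floor(zLo)), min(d[3], ceiling(zHi)))
  xRange <- c(max(1, xlo - marginVox), min(d[1], xhi + marginVox))

  box <- vol@data[xRange[1]:xRange[2], yRange[1]:yRange[2],
                  zRange[1]:zRange[2]]
  boxVol <- new("BrainVolume", data = box, spacing = sp,
                origin = or + (c(xRange[1], yRange[1], zRange[1]) - 1) * sp,
                orientation = "RAS", sourceOrientation = vol@sourceOrientation)
  W <- resampleIsotropic(boxVol, resolution, order = 3L)
  tResample <- proc.time()[3]

  # lateral half-spaces shared by both structures: inside the R1 band
  # (between lines B and C) and within the brainstem sagittal extent
  mmP <- function(p) c(voxelToMM(lmres$sliceIndex, 1, sp, or),
                       voxelToMM(p[1], 2, sp, or),
                       voxelToMM(p[2], 3, sp, or))
  u3 <- unitVector(c(0, r1@u))
  bandPlanes <- list(
    list(plane = list(point = mmP(r1@p1cc), normal = u3), op = ">="),
    list(plane = list(point = mmP(r1@p2cc), normal = -u3), op = ">="))
  xPlane <- function(idx, dir)
    list(plane = list(point = c(voxelToMM(idx, 1, sp, or), 0, 0),
                      normal = c(dir, 0, 0)), op = ">=")

  midVol <- cropBetweenPlanes(W, c(list(
    list(plane = planes@lineA, op = ">="),
    list(plane = planes@cranialMB, op = "<"),
    xPlane(xlo, 1), xPlane(xhi, -1)), bandPlanes))
  midMask <- segmentStructure(midVol, cfg)

  ponsVol <- cropBetweenPlanes(W, c(list(
    list(plane = planes@lineA, op = "<"),
    list(plane = planes@lineB, op = ">="),
    list(plane = planes@cerebellum, op = ">="),
    xPlane(xRange[1], 1), xPlane(xRange[2], -1)), bandPlanes))
  ponsMask <- segmentStructure(ponsVol, cfg)
  mcpMargins <- NULL
  if (mcpSeparation) {
    ponsMask <- separateMCP(ponsMask, vol, lmres, cfg,
                            section_mm = resolution)
    mcpMargins <- attr(ponsMask, "mcp_margins")
  }
  tStage3 <- proc.time()[3]

  vols <- c(midbrain = computeVolume(midMask), pons = computeVolume(ponsMask))
  if (vols[["midbrain"]] < 1500 || vols[["pons"]] < 5000)
    warning(sprintf(
      "implausibly small structure volume (midbrain %.0f, pons %.0f mm^3)",
      vols[["midbrain"]], vols[["pons"]]))

  meshList <- list()
  if (meshes)
    meshList <- list(midbrain = extractSurface(midMask),
                     pons = extractSurface(ponsMask))

  res <- new("BrainstemSegmentation",
    midbrain = midMask, pons = ponsMask, volumes = vols, meshes = meshList,
    provenance = list(
      config = list(c_cc = cfg@c_cc, c_bs = cfg@c_bs, c_3d = cfg@c_3d,
                    clahe_clip = cfg@clahe_clip,
                    clahe_tiles = cfg@clahe_tiles,
                    cc_radius_frac = cfg@cc_radius_frac),
      resolution = resolution, mcpSeparation = mcpSeparation,
      midsagittal = ms$index, aqueduct_gap = ms$qc$aqueduct_gap,
      landmarks = list(p1 = lmres$landmarks@p1, p2 = lmres$landmarks@p2,
                       p3 = lmres$landmarks@p3,
                       mammillary = lmres$landmarks@mammillary,
                       qp_superior = lmres$landmarks@qp_superior,
                       dorsum = lmres$dorsum),
      planes = list(cranialMB = planes@cranialMB, lineA = planes@lineA,
                    lineB = planes@lineB, cerebellum = planes@cerebellum),
      sagittal_extent = c(xlo, xhi), mcp_margins = mcpMargins,
      timings = c(stage12 = tStage12 - t0,
                  resample = tResample - tStage12,
                  stage3 = tStage3 - tResample)))
  validObject(res)
  res
}
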