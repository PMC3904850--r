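# Stage 2 — whole-brainstem segmentation on the mid-sagittal slice and
# extraction of the anatomical landmarks of the Oba/Luft parcellation.

# anterior (max y) extent of a (y, z) mask per z row; NA where empty
.anteriorExtent <- function(mask) {
  apply(mask, 2, function(col) if (any(col)) max(which(col)) else NA_real_)
}

# posterior (min y) extent per z row
.posteriorExtent <- function(mask) {
  apply(mask, 2, function(col) if (any(col)) min(which(col)) else NA_real_)
}

#' Segment the whole brainstem on the mid-sagittal slice
#'
#' Re-localizes the corpus callosum on this slice, builds the open-bottom R1
#' region (no inferior limit, so the full brainstem is captured), binarizes
#' at the corrected brainstem threshold and returns the largest 8-connected
#' component inside R1.
#'
#' @param slice mid-sagittal slice matrix (y, z).
#' @param centroid head gravity centre.
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param r1 optionally, a pre-built open \code{\link{R1Region}} (when NULL
#'   the corpus callosum is re-localized on this slice).
#' @return List with \code{mask} (logical matrix), \code{r1} (the open
#'   region used) and \code{threshold}.
#' @export
segmentBrainstemMidsagittal <- function(slice, centroid,
                                        cfg = thresholdConfig(), r1 = NULL) {
  if (is.null(r1)) {
    cc <- segmentCorpusCallosum(slice, centroid, cfg)
    ext <- ccBottomExtremes(cc)
    r1 <- buildR1(ext$p1cc, ext$p2cc, openBottom = TRUE)
  } else if (!r1@openBottom) {
    r1 <- buildR1(r1@p1cc, r1@p2cc, openBottom = TRUE)
  }
  t <- .stageThreshold(slice, cfg@c_bs)
  m <- (slice > t) & r1Contains(r1, dim(slice))
  comps <- connectedComponents(m, 8L)
  if (comps$n == 0L)
    stop("segmentBrainstemMidsagittal: empty result")
  list(mask = selectComponent(comps, "largest"), r1 = r1, threshold = t)
}

#' Detect the mammillary point
#'
#' Scans the anterior (ventral) contour of the upper half of the brainstem
#' mask from the rostral tip downward. The per-row thickness excess over a
#' running-median baseline marks contour enlargements; an enlargement must
#' stay at least \code{min_rise} pixels above baseline for at least
#' \code{min_rows} rows \emph{and} integrate at least \code{min_integral}
#' pixel-rows of excess (a few-pixel hemispheric bump smoothed by the
#' partial-volume blur integrates 6-8 pixel-rows, transient contour jitter
#' 1-2). The mammillary point is the junction row just inferior to the
#' first such enlargement below the tip. Without any enlargement the most
#' anterior-superior contour point is returned, flagged low-confidence.
#'
#' @param bs_mask logical matrix (y, z) of the mid-sagittal brainstem.
#' @param min_rise,min_rows,min_integral enlargement criteria on the
#'   3-sample-smoothed contour (phantom-calibrated defaults).
#' @param window running-median window (rows; phantom-calibrated default).
#' @return Named (y, z) point with attribute \code{lowConfidence}.
#' @export
detectMammillary <- function(bs_mask, min_rise = 0.5, min_rows = 2,
                             min_integral = 3, window = 21L) {
  e <- .anteriorExtent(bs_mask)
  zsup <- max(which(!is.na(e)))
  zinf <- min(which(!is.na(e)))
  lo <- ceiling((zsup + zinf) / 2)
  zz <- lo:zsup
  ee <- movingAverage(e[zz], 3L)   # damp 1-px contour jitter
  w <- min(window, 2 * floor((length(ee) - 1) / 2) + 1)
  base <- if (w >= 3) runmed(ee, w, endrule = "median") else ee
  excess <- ee - base
  runs <- rle(excess >= min_rise & !is.na(excess))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= min_rows)
  # first enlargement strictly below the rostral tip: the mask's top rows
  # are the cut toward the diencephalon, where baseline estimation is
  # unreliable, so enlargements ending there are not candidates
  hit <- hit[ends[hit] < length(zz) - 4L]
  if (length(hit)) {
    integ <- vapply(hit, function(k)
      sum(excess[starts[k]:ends[k]]), numeric(1))
    hit <- hit[integ >= min_integral]
  }
  if (!length(hit)) {
    idx <- which(bs_mask, arr.ind = TRUE)
    best <- idx[order(-(idx[, 1] + idx[, 2]))[1], ]
    return(structure(c(y = unname(best[1]), z = unname(best[2])),
                     lowConfidence = TRUE))
  }
  k <- hit[length(hit)]            # topmost run = last in ascending z order
  # junction row: one row inferior to the onset of the enlargement (the
  # detected run begins where the excess already exceeds min_rise)
  zrow <- max(zz[1], zz[starts[k]] - 1L)
  structure(c(y = round(base[starts[k]]), z = zrow), lowConfidence = FALSE)
}

#' Detect the quadrigeminal plate and its edge points
#'
#' Binarizes within the open R1 region, removes the brainstem pixels, and
#' selects the component whose centroid is nearest the midbrain tectum
#' (operationalized as the posterior-superior extreme of the brainstem
#' mask). Returns the plate mask with its most superior and most inferior
#' pixels (point 3).
#'
#' @param slice mid-sagittal slice matrix (y, z).
#' @param r1 open \code{\link{R1Region}}.
#' @param bs_mask brainstem mask from
#'   \code{\link{segmentBrainstemMidsagittal}}.
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param min_area smallest credible plate area in pixels (suppresses thin
#'   partial-volume fragments along the R1 boundary).
#' @return List with \code{qp_mask}, \code{qp_superior} and \code{p3}.
#' @export
detectQuadrigeminalPlate <- function(slice, r1, bs_mask,
                                     cfg = thresholdConfig(),
                                     min_area = 15L) {
  t <- .stageThreshold(slice, cfg@c_bs)
  m <- (slice > t) & r1Contains(r1, dim(slice), top_margin = 3) & !bs_mask
  comps <- connectedComponents(m, 8L)
  if (comps$n > 0L && any(comps$sizes < min_area)) {
    small <- which(comps$sizes < min_area)
    m[comps$labels %in% small] <- FALSE
    comps <- connectedComponents(m, 8L)
  }
  if (comps$n == 0L) stop("quadrigeminal plate not found")
  # midbrain tectum reference: posterior-superior extreme of the brainstem,
  # taken within the upper third of its extent so an axis tilt cannot pull
  # the reference to the caudal end
  idx <- which(bs_mask, arr.ind = TRUE)
  zTop <- max(idx[, 2]); zBot <- min(idx[, 2])
  up <- idx[idx[, 2] >= zTop - (zTop - zBot) / 3, , drop = FALSE]
  yPost <- min(up[, 1])
  ref <- c(yPost, max(up[up[, 1] <= yPost + 1L, 2]))
  sel <- selectComponent(comps, "centroid-nearest", point = ref)
  list(qp_mask = sel,
       qp_superior = .extremePoint(sel, "superior"),
       p3 = .extremePoint(sel, "inferior"))
}

#' Detect the pontine notches
#'
#' The anterior contour extent (as a function of the inferior-superior
#' coordinate, smoothed with a 3-sample moving average) is compared against
#' a robust straight-line baseline (Theil-Sen fit of the contour, tolerant
#' of the brainstem-axis tilt left by rigid registration); the pontine hump
#' is the contiguous excess run with the largest integrated area. Point 1
#' (superior notch) is the row immediately superior to the hump, point 2
#' (inferior notch) the row immediately inferior.
#'
#' @param bs_mask logical matrix (y, z).
#' @param smooth moving-average window for the contour.
#' @param min_excess minimal excess over the baseline (pixels) counting as
#'   part of the hump (phantom-calibrated).
#' @return List with \code{p1} and \code{p2}, named (y, z) points.
#' @export
detectPontineNotches <- function(bs_mask, smooth = 3L, min_excess = 1.5) {
  e <- .anteriorExtent(bs_mask)
  es <- movingAverage(e, smooth)
  zi <- which(!is.na(es))
  if (length(zi) < 8) stop("pontine notches not found")
  # Theil-Sen baseline: median pairwise slope over well-separated rows
  pairs <- which(outer(zi, zi, "-") >= 10, arr.ind = TRUE)
  slope <- median((es[zi[pairs[, 1]]] - es[zi[pairs[, 2]]]) /
                    (zi[pairs[, 1]] - zi[pairs[, 2]]))
  icept <- median(es[zi] - slope * zi)
  base <- icept + slope * seq_along(es)
  excess <- es - base
  above <- !is.na(excess) & excess > min_excess
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values)
  if (!length(hit)) stop("pontine notches not found")
  score <- vapply(hit, function(k) sum(excess[starts[k]:ends[k]]),
                  numeric(1))
  k <- hit[which.max(score)]
  z1 <- min(ends[k] + 1L, length(e))     # superior concavity onset
  z2 <- max(starts[k] - 1L, 1L)          # inferior concavity end
  if (z1 <= z2) stop("pontine notches not found")
  y1 <- if (!is.na(e[z1])) round(e[z1]) else round(base[ends[k]])
  y2 <- if (!is.na(e[z2])) round(e[z2]) else round(base[starts[k]])
  list(p1 = c(y = y1, z = z1), p2 = c(y = y2, z = z2))
}

# Build the three landmark-derived planes (cerebellum plane added later).
# Points are in-slice (y, z) voxel coordinates on sagittal slice sliceIndex.
.cutPlanesFromPoints <- function(p1, p2, p3, mammillary, qp_superior,
                                 sliceIndex, spacing, origin) {
  mkNormal <- function(a, b) {
    d <- (as.numeric(b) - as.numeric(a)) * spacing[2:3]   # mm direction
    if (all(d == 0)) stop("defineCutPlanes: degenerate points")
    n <- c(d[2], -d[1])
    if (n[2] < 0 || (n[2] == 0 && n[1] < 0)) n <- -n      # superior/anterior
    unitVector(c(0, n))
  }
  mmPoint <- function(p) c(
    voxelToMM(sliceIndex, 1, spacing, origin),
    voxelToMM(p[1], 2, spacing, origin),
    voxelToMM(p[2], 3, spacing, origin))
  nA <- mkNormal(p1, p3)
  nC <- mkNormal(mammillary, qp_superior)
  new("CutPlanes",
      cranialMB = list(point = mmPoint(mammillary), normal = nC),
      lineA = list(point = mmPoint(p1), normal = nA),
      lineB = list(point = mmPoint(p2), normal = nA),
      cerebellum = list(point = mmPoint(p2), normal = c(0, 1, 0)))
}

#' Build the cut planes from a landmark set
#'
#' Line A passes through the superior pontine notch (p1) and the inferior
#' quadrigeminal edge (p3); line B is the parallel plane through the
#' inferior pontine notch (p2); the cranial midbrain border passes through
#' the mammillary point and the superior quadrigeminal edge. All planes are
#' extruded along the left-right axis. The cerebellum plane is initialized
#' coronal through p2 and is normally replaced via
#' \code{\link{cerebellumPlane}}.
#'
#' @param lm a \code{\link{LandmarkSet}}.
#' @param spacing,origin geometry of the source volume.
#' @return A \code{\link{CutPlanes}} object (lineA and lineB share their
#'   normal exactly).
#' @export
defineCutPlanes <- function(lm, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  .cutPlanesFromPoints(lm@p1, lm@p2, lm@p3, lm@mammillary, lm@qp_superior,
                       lm@sliceIndex, spacing, origin)
}

#' Coronal plane separating pons and cerebellum
#'
#' The two dorsum points are the posterior contour points of the brainstem
#' at the rows where lines A and B cross the dorsum; the plane is coronal
#' (normal along the anterior-posterior axis) through the more anterior of
#' the two. Everything posterior of it is excluded from the pons.
#'
#' @param bs_mask 2-D \code{\link{BrainMask}} (or logical matrix) of the
#'   mid-sagittal brainstem.
#' @param planes \code{\link{CutPlanes}} with lineA/lineB set.
#' @param sliceIndex sagittal index of the slice.
#' @param spacing,origin volume geometry.
#' @return List with \code{plane} and \code{dorsum} (2 x 2 matrix of (y, z)
#'   points).
#' @export
cerebellumPlane <- function(bs_mask, planes, sliceIndex,
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  m <- if (is(bs_mask, "BrainMask")) bs_mask@data else bs_mask
  post <- .posteriorExtent(m)
  zrows <- which(!is.na(post))
  crossRow <- function(plane) {
    ymm <- voxelToMM(post[zrows], 2, spacing, origin)
    zmm <- voxelToMM(zrows, 3, spacing, origin)
    sd <- (ymm - plane$point[2]) * plane$normal[2] +
      (zmm - plane$point[3]) * plane$normal[3]
    zrows[which.min(abs(sd))]
  }
  zA <- crossRow(planes@lineA)
  zB <- crossRow(planes@lineB)
  if (abs(zA - zB) < 2)
    stop("cerebellumPlane: dorsum contour shorter than the lineA-lineB span")
  dA <- c(post[zA], zA); dB <- c(post[zB], zB)
  anterior <- if (dA[1] >= dB[1]) dA else dB
  plane <- list(point = c(voxelToMM(sliceIndex, 1, spacing, origin),
                          voxelToMM(anterior[1], 2, spacing, origin),
                          voxelToMM(anterior[2], 3, spacing, origin)),
                normal = c(0, 1, 0))
  list(plane = plane, dorsum = rbind(dA, dB))
}

#' Detect all mid-sagittal landmarks and cut planes
#'
#' Stage 2 of the pipeline: segments the whole brainstem on the mid-sagittal
#' slice, detects the mammillary point, quadrigeminal plate and pontine
#' notches, and assembles the cut planes (including the cerebellum plane).
#'
#' @param vol a \code{\link{BrainVolume}}.
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param ms result of \code{\link{findMidsagittal}} (computed when NULL).
#' @param sliceIndex explicit mid-sagittal index overriding \code{ms}.
#' @param denoise apply the 3x3 median prefilter to the slice (see
#'   \code{\link{findMidsagittal}}).
#' @return List with \code{landmarks} (\code{\link{LandmarkSet}}),
#'   \code{planes} (\code{\link{CutPlanes}}), \code{bsMask} (2-D
#'   \code{BrainMask}), \code{r1}, \code{dorsum} and \code{midsagittal}.
#' @export
detectLandmarks <- function(vol, cfg = thresholdConfig(), ms = NULL,
                            sliceIndex = NULL, denoise = TRUE) {
  if (is.null(sliceIndex)) {
    if (is.null(ms)) ms <- findMidsagittal(vol, cfg, denoise = denoise)
    sliceIndex <- ms$index
  }
  slice <- vol@data[sliceIndex, , ]
  if (denoise) slice <- medianFilter3(slice)
  centroid <- headCentroid(slice)
  bs <- segmentBrainstemMidsagittal(slice, centroid, cfg)
  mam <- detectMammillary(bs$mask)
  qp <- detectQuadrigeminalPlate(slice, bs$r1, bs$mask, cfg)
  pn <- detectPontineNotches(bs$mask)
  flags <- character()
  if (isTRUE(attr(mam, "lowConfidence")))
    flags <- c(flags, "mammillary fallback (no contour enlargement)")
  lmset <- new("LandmarkSet",
    p1 = as.numeric(pn$p1), p2 = as.numeric(pn$p2),
    p3 = as.numeric(qp$p3), mammillary = as.numeric(mam),
    qp_superior = as.numeric(qp$qp_superior),
    dorsum = matrix(NA_real_, 2, 2),
    qp_mask = BrainMask(qp$qp_mask, spacing = vol@spacing[2:3]),
    sliceIndex = sliceIndex, flags = flags)
  planes <- defineCutPlanes(lmset, vol@spacing, vol@origin)
  cer <- cerebellumPlane(bs$mask, planes, sliceIndex, vol@spacing,
                         vol@origin)
  planes@cerebellum <- cer$plane
  validObject(planes)
  lmset@dorsum <- cer$dorsum
  validObject(lmset)
  list(landmarks = lmset, planes = planes,
       bsMask = BrainMask(bs$mask, spacing = vol@spacing[2:3]),
       r1 = bs$r1, dorsum = cer$dorsum, midsagittal = ms,
       sliceIndex = sliceIndex)
}
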