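# Stage 1 — mid-sagittal plane detection.
#
# The corpus callosum is tracked across a sagittal sub-volume S1; the R1
# rectangle anchored to its bottom extremes delimits the upper brainstem,
# whose per-slice area is minimized to find the mid-sagittal slice (the
# slice with the widest aqueduct gap between tectum and quadrigeminal
# plate).

#' R1 region anchored to the corpus callosum
#'
#' Oriented rectangle of width L (the distance between the two callosal
#' bottom extremes) extending (2/3) L inferior to the line through them
#' (line A); lines B and C are the perpendicular sides through the two
#' points. With \code{openBottom} the rectangle extends to the image edge,
#' as used for whole-brainstem segmentation.
#'
#' @slot p1cc,p2cc numeric(2) in-slice (y, z) anchor points.
#' @slot L distance between the anchors (pixels).
#' @slot u unit vector along line A; \code{n} unit normal pointing inferior.
#' @slot openBottom logical.
#' @exportClass R1Region
setClass("R1Region",
  representation(p1cc = "numeric", p2cc = "numeric", L = "numeric",
                 u = "numeric", n = "numeric", openBottom = "logical"))

setValidity("R1Region", function(object) {
  if (object@L <= 0) "L must be positive" else TRUE
})

#' Extract the sagittal sub-volume S1
#'
#' The \code{width} sagittal slices centred on \code{center};
#' \code{center = "auto"} uses the middle slice \code{floor((N + 1) / 2)} of
#' the sagittal extent (slice 184 of a 368-slice acquisition). A window
#' exceeding the volume bounds is clipped with a warning.
#'
#' @param vol a \code{\link{BrainVolume}}.
#' @param center sagittal slice index, or \code{"auto"}.
#' @param width number of slices (>= 3, default 40).
#' @return List with \code{indices} (sagittal slice indices) and
#'   \code{center}.
#' @export
extractS1 <- function(vol, center = "auto", width = 40L) {
  stopIfNot3D(vol)
  if (width < 3L) stop("extractS1: width must be >= 3")
  nx <- dim(vol@data)[1]
  if (identical(center, "auto")) center <- floor((nx + 1) / 2)
  if (center < 1L || center > nx) stop("extractS1: center out of bounds")
  lo <- center - floor(width / 2)
  hi <- lo + width - 1L
  if (lo < 1L || hi > nx) {
    warning("extractS1: window clipped to the volume bounds")
    lo <- max(1L, lo); hi <- min(nx, hi)
  }
  list(indices = lo:hi, center = center)
}

#' Gravity centre of the head mask
#'
#' Binarizes the slice at the plain Otsu threshold and returns the barycentre
#' of the head mask (for a binary mask the intensity-weighted and geometric
#' centroids coincide).
#'
#' @param slice numeric matrix, a sagittal slice in (y, z) orientation.
#' @return Named numeric(2): mean (y, z) of the foreground pixels.
#' @export
headCentroid <- function(slice) {
  t0 <- otsuThreshold(slice)
  m <- slice > t0
  if (!any(m)) stop("headCentroid: empty head mask")
  idx <- which(m, arr.ind = TRUE)
  c(y = mean(idx[, 1]), z = mean(idx[, 2]))
}

# Base threshold for a pipeline stage: Otsu restricted to the head
# foreground (itself defined by a plain whole-slice Otsu), times `factor`.
# On a degenerate two-level slice the head foreground is constant; the
# whole-slice threshold is then the only one available.
.stageThreshold <- function(slice, factor) {
  headfg <- slice > otsuThreshold(slice)
  tryCatch(correctedThreshold(slice, factor, mask = headfg),
           error = function(e) correctedThreshold(slice, factor))
}

#' Segment the corpus callosum on a sagittal slice
#'
#' CLAHE enhancement, binarization at the corrected callosal threshold
#' (\code{c_cc} times the base Otsu threshold), 8-connected components, and
#' selection of the largest component whose centroid lies near the head
#' gravity centre.
#'
#' @param slice sagittal slice matrix (y, z).
#' @param centroid head gravity centre from \code{\link{headCentroid}}.
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param min_area smallest acceptable callosal area (pixels).
#' @param presmooth Gaussian pre-smoothing sd in pixels applied before
#'   CLAHE (0 disables). Adaptive equalization amplifies uncorrelated noise
#'   roughly fivefold around flat-tissue modes, so the callosal stage
#'   smooths first; the callosum is thick enough (~8 px) that its bottom
#'   extremes move by at most ~2 px.
#' @return Logical matrix of the callosal mask (attribute \code{label});
#'   errors if no suitable component exists (callers treat this as a
#'   per-slice failure).
#' @export
segmentCorpusCallosum <- function(slice, centroid, cfg = thresholdConfig(),
                                  min_area = 50L, presmooth = 1.2) {
  e <- claheEnhance(gaussianBlur2d(slice, presmooth),
                    cfg@clahe_clip, cfg@clahe_tiles)
  t <- .stageThreshold(e, cfg@c_cc)
  comps <- connectedComponents(e > t, 8L)
  radius <- cfg@cc_radius_frac * sqrt(sum(dim(slice)^2))
  sel <- selectComponent(comps, "largest-near", point = centroid,
                         radius = radius)
  if (sum(sel) < min_area)
    stop("segmentCorpusCallosum: component too small (", sum(sel), " px)")
  sel
}

#' Bottom extreme points of the corpus callosum
#'
#' Point 1 is the lowest pixel of the anterior-most column of the mask,
#' point 2 the lowest pixel of the posterior-most column (ties resolved
#' toward the most inferior, then most extreme pixel).
#'
#' @param cc_mask logical matrix (y, z) of the callosal mask.
#' @return List with \code{p1cc} (anterior) and \code{p2cc} (posterior),
#'   each a named (y, z) pair.
#' @export
ccBottomExtremes <- function(cc_mask) {
  idx <- which(cc_mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("ccBottomExtremes: degenerate mask")
  yA <- max(idx[, 1])
  p1 <- c(y = yA, z = min(idx[idx[, 1] == yA, 2]))
  yP <- min(idx[, 1])
  p2 <- c(y = yP, z = min(idx[idx[, 1] == yP, 2]))
  if (all(p1 == p2)) stop("ccBottomExtremes: degenerate mask")
  list(p1cc = p1, p2cc = p2)
}

#' Build the R1 region from the callosal bottom extremes
#'
#' @param p1cc,p2cc (y, z) anchor points (distinct).
#' @param openBottom if TRUE the rectangle has no inferior limit
#'   (whole-brainstem mode).
#' @return An \code{\link{R1Region}}.
#' @export
buildR1 <- function(p1cc, p2cc, openBottom = FALSE) {
  d <- as.numeric(p2cc) - as.numeric(p1cc)
  L <- sqrt(sum(d^2))
  if (L == 0) stop("buildR1: degenerate points")
  u <- d / L
  n <- c(u[2], -u[1])              # one of the two perpendiculars
  if (n[2] > 0 || (n[2] == 0 && n[1] > 0)) n <- -n  # point inferior
  new("R1Region", p1cc = as.numeric(p1cc), p2cc = as.numeric(p2cc),
      L = L, u = u, n = n, openBottom = openBottom)
}

#' Rasterize an R1 region
#'
#' @param r1 an \code{\link{R1Region}}.
#' @param dims dimensions (rows, cols) of the target slice.
#' @param top_margin exclude pixels closer than this to line A (used to keep
#'   callosal partial-volume pixels on the R1 boundary out of landmark
#'   searches).
#' @return Logical membership matrix.
#' @export
r1Contains <- function(r1, dims, top_margin = 0) {
  Yv <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1], dims[2])
  Zv <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1], dims[2])
  py <- Yv - r1@p1cc[1]; pz <- Zv - r1@p1cc[2]
  s <- py * r1@u[1] + pz * r1@u[2]
  dd <- py * r1@n[1] + pz * r1@n[2]
  inside <- s >= 0 & s <= r1@L & dd >= top_margin
  if (!r1@openBottom) inside <- inside & dd <= (2 / 3) * r1@L
  inside
}

#' Upper-brainstem cross-sectional area within R1
#'
#' Binarizes the slice at the corrected brainstem threshold, zeroes pixels
#' outside the (closed) R1 rectangle, and returns the pixel count of the
#' largest 8-connected component (0 if none).
#'
#' @param slice sagittal slice matrix (y, z).
#' @param r1 a closed \code{\link{R1Region}}.
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param min_area components smaller than this count as absent (suppresses
#'   isolated bright fragments, e.g. callosal pixels on the R1 boundary).
#' @return Integer pixel count (0 when no credible component).
#' @export
upperBrainstemArea <- function(slice, r1, cfg = thresholdConfig(),
                               min_area = 50L) {
  if (r1@openBottom) stop("upperBrainstemArea: R1 must be closed")
  t <- .stageThreshold(slice, cfg@c_bs)
  m <- (slice > t) & r1Contains(r1, dim(slice))
  comps <- connectedComponents(m, 8L)
  if (comps$n == 0L) return(0L)
  big <- max(comps$sizes)
  if (big < min_area) return(0L)
  big
}

#' Locate the mid-sagittal slice
#'
#' Stage 1 of the pipeline: (a) segment the corpus callosum on every slice
#' of the S1 window, (b) fix R1 from the slice with the smallest callosal
#' area, (c) compute the upper-brainstem area on every slice with that R1,
#' and (d) return the slice minimizing that area (ties resolved toward the
#' window centre). Slices where callosal segmentation fails, or whose
#' upper-brainstem area is zero, are excluded.
#'
#' @param vol a \code{\link{BrainVolume}} (assumed aligned; see
#'   \code{\link{rigidRegisterToTemplate}} for the optional registration).
#' @param cfg a \code{\link{ThresholdConfig}}.
#' @param center,width S1 window placement, see \code{\link{extractS1}}.
#' @param denoise apply an edge-preserving 3x3 median prefilter to each
#'   slice before thresholding (identity on piecewise-constant regions;
#'   stabilizes CLAHE and component selection under speckle noise).
#' @return List with \code{index} (mid-sagittal sagittal index),
#'   \code{profile} (data.frame slice / cc_area / upper_bs_area),
#'   \code{r1} (the fixed \code{\link{R1Region}}), \code{centroid}
#'   (head gravity centre of the window centre slice) and \code{qc}
#'   (aqueduct gap width at the chosen slice, in pixels, NA if not
#'   measurable).
#' @export
findMidsagittal <- function(vol, cfg = thresholdConfig(), center = "auto",
                            width = 40L, denoise = TRUE) {
  s1 <- extractS1(vol, center, width)
  idxs <- s1$indices
  getSlice <- function(i) {
    sl <- vol@data[i, , ]
    if (denoise) medianFilter3(sl) else sl
  }
  centroid <- headCentroid(getSlice(s1$center))

  ccArea <- rep(NA_integer_, length(idxs))
  ccMasks <- vector("list", length(idxs))
  for (i in seq_along(idxs)) {
    sl <- getSlice(idxs[i])
    m <- tryCatch(segmentCorpusCallosum(sl, centroid, cfg),
                  error = function(e) NULL)
    if (!is.null(m)) { ccMasks[[i]] <- m; ccArea[i] <- sum(m) }
  }
  valid <- which(!is.na(ccArea))
  if (length(valid) < 3L)
    stop("mid-sagittal detection failed: corpus callosum found on fewer ",
         "than 3 slices")

  # fix R1 on the slice with minimal callosal area (ties -> window centre).
  # A mis-selected component on a noisy slice can masquerade as a small
  # callosum, so the anchor must also be geometrically consistent: its
  # bottom-extreme span L has to agree with the across-slice median span.
  exts <- lapply(valid, function(i)
    tryCatch(ccBottomExtremes(ccMasks[[i]]), error = function(e) NULL))
  Ls <- vapply(exts, function(e)
    if (is.null(e)) NA_real_ else
      sqrt(sum((e$p1cc - e$p2cc)^2)), numeric(1))
  medL <- median(Ls, na.rm = TRUE)
  eligible <- valid[!is.na(Ls) & abs(Ls - medL) <= 0.25 * medL]
  if (!length(eligible)) eligible <- valid[!is.na(Ls)]
  minA <- min(ccArea[eligible])
  cand <- eligible[ccArea[eligible] == minA]
  anchor <- cand[order(abs(idxs[cand] - s1$center), idxs[cand])][1]
  ext <- exts[[match(anchor, valid)]]
  r1 <- buildR1(ext$p1cc, ext$p2cc, openBottom = FALSE)

  bsArea <- integer(length(idxs))
  for (i in seq_along(idxs))
    bsArea[i] <- upperBrainstemArea(getSlice(idxs[i]), r1, cfg)

  ok <- which(bsArea > 0L)
  if (!length(ok))
    stop("mid-sagittal detection failed: empty upper-brainstem profile")
  minB <- min(bsArea[ok])
  cand <- ok[bsArea[ok] == minB]
  # a plateau of minima is resolved to its centre slice (plateaus compared
  # by distance to the window centre): this is translation-equivariant,
  # unlike a plain nearest-to-centre rule
  runsId <- cumsum(c(1L, diff(cand) != 1L))
  runs <- split(cand, runsId)
  mids <- vapply(runs, function(r) r[ceiling(length(r) / 2)], numeric(1))
  pick <- mids[order(abs(idxs[mids] - s1$center), idxs[mids])][1]
  index <- idxs[pick]

  qc <- tryCatch(.aqueductGap(getSlice(index), r1, cfg),
                 error = function(e) NA_real_)

  list(index = index,
       profile = data.frame(slice = idxs, cc_area = ccArea,
                            upper_bs_area = bsArea),
       r1 = r1, centroid = centroid, anchorSlice = idxs[anchor],
       qc = list(aqueduct_gap = qc))
}

# Width of the aqueduct gap between the upper brainstem and the
# quadrigeminal plate on one slice (consistency log only, not a selector).
.aqueductGap <- function(slice, r1, cfg) {
  t <- .stageThreshold(slice, cfg@c_bs)
  m <- (slice > t) & r1Contains(r1, dim(slice))
  comps <- connectedComponents(m, 8L)
  if (comps$n < 2L) return(NA_real_)
  ord <- order(-comps$sizes)
  a <- comps$labels == ord[1]; b <- comps$labels == ord[2]
  gaps <- c()
  for (j in seq_len(ncol(m))) {
    ya <- which(a[, j]); yb <- which(b[, j])
    if (length(ya) && length(yb)) {
      gp <- min(ya) - max(yb) - 1L
      if (gp < 0) gp <- min(yb) - max(ya) - 1L
      if (gp >= 0) gaps <- c(gaps, gp)
    }
  }
  if (length(gaps)) max(gaps) else NA_real_
}
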