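# Synthetic T1-like head phantom with voxel-exact ground truth.
#
# The phantom emulates the anatomy the segmentation algorithm relies on:
# a bright corpus-callosum arch above the brainstem, a brainstem column with
# an anterior pontine bulge bounded by two notches, a mammillary protrusion
# at the rostral midbrain, a quadrigeminal plate separated from the tectum
# by a dark aqueduct gap that is widest at the symmetry plane, paired
# superior cerebellar peduncles, middle-cerebellar-peduncle wings joining a
# cerebellum block, all embedded in a darker head ellipsoid with a CSF rim
# (the cisterns) around the brainstem complex. Ground-truth masks and
# landmark coordinates are frozen before noise, bias and blur are applied.

#' Default phantom specification
#'
#' Returns the reference \code{\link{PhantomSpec}}: a 181 x 217 x 181 grid at
#' 1 mm (MNI-like extents), tissue means background 0, CSF 0.1, head tissue
#' 0.35, brainstem 0.55, quadrigeminal plate 0.6, corpus callosum 0.85,
#' noiseless with a 0.4-voxel partial-volume edge blur. Geometry dimensions
#' are in mm; see the methods vignette for their anatomical rationale.
#'
#' @param ... named overrides for any slot (e.g. \code{noise_sd = 0.03},
#'   \code{tilt_deg = 3}) or any geometry field (e.g. \code{wing_reach}).
#' @return A validated \code{\link{PhantomSpec}}.
#' @export
#' @examples
#' spec <- defaultPhantomSpec(noise_sd = 0.02, seed = 7)
defaultPhantomSpec <- function(...) {
  geometry <- list(
    bs_centre = c(y = 105, z = 90),     # rotation/scale centre of the complex
    head_centre = c(x = 91, y = 108, z = 90),
    head_semi = c(78, 92, 80),
    col_y = c(96, 114), col_z = c(40, 126), col_halfwidth = 10,
    bulge_amp = 8, notch_sup_z = 95, notch_inf_z = 60,
    mam_z = c(112, 117), mam_amp = 3,
    plate_y = c(87, 92), plate_z = c(100, 118),
    aqueduct_halfwidth = 1,             # |dx| with an open aqueduct gap
    scp_x = c(3, 10), scp_y = c(88, 95), scp_z = c(90, 98),
    wing_x = c(11, 18), wing_y = c(85, 105), wing_z = c(60, 88),
    cereb_y = c(70, 90), cereb_z = c(40, 88), cereb_halfwidth = 40,
    cc_centre = c(y = 111, z = 130), cc_radii = c(18, 26), cc_halfwidth = 22,
    moat = 2                            # CSF rim thickness (voxels)
  )
  args <- list(...)
  geomOver <- intersect(names(args), names(geometry))
  geometry[geomOver] <- args[geomOver]
  args <- args[setdiff(names(args), geomOver)]
  spec <- new("PhantomSpec",
    shape = c(181, 217, 181), spacing = c(1, 1, 1),
    intensities = c(background = 0, csf = 0.1, head = 0.35,
                    brainstem = 0.55, plate = 0.6, cc = 0.85),
    geometry = geometry, tilt_deg = 0, scale = 1,
    noise_sd = 0, bias_amp = 0, blur_sigma = 0.4,
    pons_atrophy = 1, seed = 0)
  for (nm in names(args)) slot(spec, nm) <- args[[nm]]
  validObject(spec)
  spec
}

# Reject geometrically impossible specifications early.
.checkPhantomGeometry <- function(spec) {
  g <- spec@geometry
  if (g$plate_y[2] >= g$col_y[1])
    stop("phantom spec rejected: quadrigeminal plate overlaps the brainstem ",
         "column (plate_y must stay posterior of col_y)")
  if (g$cc_centre["z"] <= g$col_z[2])
    stop("phantom spec rejected: corpus callosum must lie superior to the ",
         "brainstem column")
  if (g$scp_z[1] >= g$plate_z[1])
    stop("phantom spec rejected: superior cerebellar peduncles must stay ",
         "inferior to the quadrigeminal plate")
  lim <- spec@shape * spec@spacing
  if (g$cc_centre["z"] + g$cc_radii[2] > lim[3])
    stop("phantom spec rejected: corpus callosum exceeds the grid")
  invisible(TRUE)
}

#' Generate a synthetic head phantom
#'
#' Builds the T1-like volume, the voxel-exact ground-truth midbrain and pons
#' masks, the generator's landmark coordinates and the true cut planes.
#' Deterministic for a fixed spec (noise and bias are drawn from
#' \code{spec@seed}); truth is frozen before blur, bias and noise.
#'
#' @param spec a \code{\link{PhantomSpec}} (default
#'   \code{defaultPhantomSpec()}).
#' @return List with elements \code{volume} (\code{BrainVolume}),
#'   \code{truth} (list of 3-D \code{BrainMask}: \code{midbrain},
#'   \code{pons}, plus the 2-D mid-sagittal \code{brainstem2d} and
#'   \code{plate2d}), \code{landmarks} (list of named in-slice (y, z) points
#'   and the \code{symmetry} sagittal index), \code{planes}
#'   (\code{CutPlanes} built from the true landmarks) and \code{spec}.
#' @export
#' @examples
#' ph <- brainPhantom(defaultPhantomSpec(shape = c(64, 96, 96)))
brainPhantom <- function(spec = defaultPhantomSpec()) {
  validObject(spec)
  .checkPhantomGeometry(spec)
  g <- spec@geometry
  dims <- as.integer(spec@shape)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- ceiling(nx / 2)                   # symmetry plane (sagittal index)
  s <- spec@scale
  th <- spec@tilt_deg * pi / 180
  y0 <- g$bs_centre["y"]; z0 <- g$bs_centre["z"]

  # frame coordinates: world grid -> structure frame (undo tilt and scale)
  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  dxf <- (xs - cx) / s
  Y <- matrix(rep(ys, nz), ny, nz)
  Z <- matrix(rep(zs, each = ny), ny, nz)
  yc <- Y - y0; zc <- Z - z0
  YF <- ( cos(th) * yc + sin(th) * zc) / s + y0
  ZF <- (-sin(th) * yc + cos(th) * zc) / s + z0

  # forward transform: frame point -> world (y, z)
  toWorld <- function(p) {
    yc <- (p[1] - y0) * s; zc <- (p[2] - z0) * s
    c(y = unname(cos(th) * yc - sin(th) * zc + y0),
      z = unname(sin(th) * yc + cos(th) * zc + z0))
  }

  expand <- function(xcond, yzcond) outer(xcond, yzcond, FUN = "&")

  span0 <- g$notch_sup_z - g$notch_inf_z
  p2z <- g$notch_sup_z - span0 * spec@pons_atrophy
  p1z <- g$notch_sup_z
  zmid <- (p1z + p2z) / 2; zh <- (p1z - p2z) / 2
  colA <- g$col_y[2]                      # anterior face of the column

  inCol <- abs(dxf) <= g$col_halfwidth
  yzCol <- YF >= g$col_y[1] & YF <= colA & ZF >= g$col_z[1] & ZF <= g$col_z[2]
  column <- expand(inCol, yzCol)

  bt <- pmax(0, 1 - ((ZF - zmid) / zh)^2)
  yzBulge <- YF > colA & YF <= colA + g$bulge_amp * sqrt(bt) &
    ZF > p2z & ZF < p1z
  bulge <- expand(inCol, yzBulge)

  mt <- pmax(0, 1 - ((ZF - mean(g$mam_z)) / (diff(g$mam_z) / 2))^2)
  yzBump <- YF > colA & YF <= colA + g$mam_amp * sqrt(mt) &
    ZF >= g$mam_z[1] & ZF <= g$mam_z[2]
  bump <- expand(abs(dxf) <= g$col_halfwidth / 2, yzBump)

  yzPlate <- YF >= g$plate_y[1] & YF <= g$plate_y[2] &
    ZF >= g$plate_z[1] & ZF <= g$plate_z[2]
  plate <- expand(inCol, yzPlate)

  # tectum-plate merge away from the symmetry plane: the aqueduct gap is
  # open only within aqueduct_halfwidth of the mid-sagittal slice
  yzBridge <- YF > g$plate_y[2] & YF < g$col_y[1] &
    ZF >= g$plate_z[1] & ZF <= g$plate_z[2]
  bridge <- expand(abs(dxf) > g$aqueduct_halfwidth & inCol, yzBridge)

  yzScp <- YF >= g$scp_y[1] & YF <= g$scp_y[2] &
    ZF >= g$scp_z[1] & ZF <= g$scp_z[2]
  scp <- expand(abs(dxf) >= g$scp_x[1] & abs(dxf) <= g$scp_x[2], yzScp)

  yzWing <- YF >= g$wing_y[1] & YF <= g$wing_y[2] &
    ZF >= g$wing_z[1] & ZF <= g$wing_z[2]
  wings <- expand(abs(dxf) >= g$wing_x[1] & abs(dxf) <= g$wing_x[2], yzWing)

  yzCereb <- YF >= g$cereb_y[1] & YF <= g$cereb_y[2] &
    ZF >= g$cereb_z[1] & ZF <= g$cereb_z[2]
  cereb <- expand(abs(dxf) <= g$cereb_halfwidth, yzCereb)

  rr <- sqrt((YF - g$cc_centre["y"])^2 + (ZF - g$cc_centre["z"])^2)
  yzCC <- rr >= g$cc_radii[1] & rr <= g$cc_radii[2] & ZF >= g$cc_centre["z"]
  cc <- expand(abs(dxf) <= g$cc_halfwidth, yzCC)

  bright <- column | bulge | bump | plate | bridge | scp | wings | cereb | cc
  # dilation restricted to the bounding box of the bright complex
  bb <- lapply(1:3, function(ax) {
    r <- range(which(apply(bright, ax, any)))
    c(max(1L, r[1] - as.integer(g$moat) - 4L),
      min(dims[ax], r[2] + as.integer(g$moat) + 4L))
  })
  moat <- array(FALSE, dims)
  sub <- bright[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
                bb[[3]][1]:bb[[3]][2]]
  moat[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2], bb[[3]][1]:bb[[3]][2]] <-
    dilate3d(sub, as.integer(g$moat))
  moat <- moat & !bright

  # head ellipsoid (world frame; the head does not tilt or scale)
  hx <- ((xs - g$head_centre["x"]) / g$head_semi[1])^2
  hyz <- ((Y - g$head_centre["y"]) / g$head_semi[2])^2 +
    ((Z - g$head_centre["z"]) / g$head_semi[3])^2
  headm <- outer(hx, hyz, "+") < 1

  ii <- spec@intensities
  vol <- array(ii[["background"]], dims)
  vol[headm] <- ii[["head"]]
  vol[moat] <- ii[["csf"]]
  vol[column | bulge | bump | scp | wings | cereb | bridge] <- ii[["brainstem"]]
  vol[plate] <- ii[["plate"]]
  vol[cc] <- ii[["cc"]]

  # ---- ground truth (frozen before blur / bias / noise) ----
  plate2d <- plate[cx, , ]
  p3 <- .extremePoint(plate2d, which = "inferior")
  qpSup <- .extremePoint(plate2d, which = "superior")
  lm <- list(
    p1 = toWorld(c(colA, p1z)),
    p2 = toWorld(c(colA, p2z)),
    p3 = p3, qp_superior = qpSup,
    mammillary = toWorld(c(colA, g$mam_z[1])),
    symmetry = cx
  )
  stopifnot(lm$p1[2] > lm$p2[2])  # superior notch above inferior notch

  planes <- .cutPlanesFromPoints(
    p1 = lm$p1, p2 = lm$p2, p3 = lm$p3,
    mammillary = lm$mammillary, qp_superior = lm$qp_superior,
    sliceIndex = cx, spacing = spec@spacing, origin = c(0, 0, 0))
  bs2d <- (column | bulge | bump)[cx, , ]
  cerebPlane <- cerebellumPlane(
    BrainMask(bs2d, spacing = spec@spacing[2:3]),
    planes, sliceIndex = cx, spacing = spec@spacing, origin = c(0, 0, 0))
  planes@cerebellum <- cerebPlane$plane
  validObject(planes)

  structAll <- column | bulge | bump
  sdA <- planeSignedDistance(planes@lineA, dims, spec@spacing, c(0, 0, 0))
  sdC <- planeSignedDistance(planes@cranialMB, dims, spec@spacing, c(0, 0, 0))
  sdB <- planeSignedDistance(planes@lineB, dims, spec@spacing, c(0, 0, 0))
  sdCer <- planeSignedDistance(planes@cerebellum, dims, spec@spacing,
                               c(0, 0, 0))
  # the tectal plate and its fusion with the tegmentum are midbrain tissue;
  # only the thin para-midline aqueduct cleft separates them on T1
  truthMid <- (structAll | plate | bridge) & sdA >= 0 & sdC < 0
  truthPons <- structAll & sdA < 0 & sdB >= 0 & sdCer >= 0
  stopifnot(!any(truthMid & truthPons), any(truthMid), any(truthPons))
  # generator consistency: the notches lie on the anterior pons boundary
  w1 <- lm$p1
  stopifnot(bs2d[round(w1["y"]), round(w1["z"])] ||
              bs2d[round(w1["y"]) - 1, round(w1["z"])])

  # ---- degrade: blur, bias, noise ----
  # partial-volume blur applied around the structure complex (the head/air
  # edge far from the brainstem is irrelevant to every pipeline stage)
  out <- vol
  if (spec@blur_sigma > 0) {
    m <- ceiling(3 * spec@blur_sigma) + 1L
    ex <- lapply(1:3, function(ax) c(max(1L, bb[[ax]][1] - m),
                                     min(dims[ax], bb[[ax]][2] + m)))
    out[ex[[1]][1]:ex[[1]][2], ex[[2]][1]:ex[[2]][2], ex[[3]][1]:ex[[3]][2]] <-
      gaussianBlur3d(vol[ex[[1]][1]:ex[[1]][2], ex[[2]][1]:ex[[2]][2],
                         ex[[3]][1]:ex[[3]][2]], spec@blur_sigma)
  }
  bv <- new("BrainVolume", data = out, spacing = spec@spacing,
            origin = c(0, 0, 0), orientation = "RAS",
            sourceOrientation = "RAS")
  if (spec@noise_sd > 0 || spec@bias_amp > 0)
    bv <- perturbVolume(bv, spec@noise_sd, spec@bias_amp, spec@seed)

  list(
    volume = bv,
    truth = list(
      midbrain = BrainMask(truthMid, spec@spacing),
      pons = BrainMask(truthPons, spec@spacing),
      brainstem2d = BrainMask(bs2d, spec@spacing[2:3]),
      plate2d = BrainMask(plate2d, spec@spacing[2:3])
    ),
    landmarks = lm,
    planes = planes,
    spec = spec
  )
}

# inferior/superior extreme pixel of a 2-D (y, z) mask;
# ties broken toward the most anterior (largest y) pixel.
.extremePoint <- function(mask2d, which = c("inferior", "superior")) {
  which <- match.arg(which)
  idx <- which(mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask in .extremePoint")
  zBest <- if (which == "inferior") min(idx[, 2]) else max(idx[, 2])
  rows <- idx[idx[, 2] == zBest, , drop = FALSE]
  c(y = max(rows[, 1]), z = zBest)
}

#' Degrade a volume with bias field and noise
#'
#' Multiplies by a smooth low-order polynomial field confined to
#' \code{[1 - bias_amp, 1 + bias_amp]}, adds white Gaussian noise, and clips
#' to [0, 1]. Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param vol a \code{\link{BrainVolume}} with intensities in [0, 1].
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param bias_amp bias-field amplitude (0 disables).
#' @param seed RNG seed for the field coefficients and noise draw.
#' @return A degraded \code{\link{BrainVolume}}.
#' @export
perturbVolume <- function(vol, noise_sd = 0, bias_amp = 0, seed = 0) {
  stopIfNot3D(vol)
  if (noise_sd < 0 || bias_amp < 0)
    stop("perturbVolume: noise_sd and bias_amp must be >= 0")
  if (noise_sd == 0 && bias_amp == 0) return(vol)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  a <- vol@data
  d <- dim(a)
  if (bias_amp > 0) {
    u <- seq(-1, 1, length.out = d[1])
    v <- seq(-1, 1, length.out = d[2])
    w <- seq(-1, 1, length.out = d[3])
    cf <- runif(9, -1, 1)
    U <- rep(u, times = d[2] * d[3])
    V <- rep(rep(v, each = d[1]), times = d[3])
    W <- rep(w, each = d[1] * d[2])
    gfld <- cf[1] * U + cf[2] * V + cf[3] * W + cf[4] * U * V +
      cf[5] * U * W + cf[6] * V * W + cf[7] * U^2 + cf[8] * V^2 + cf[9] * W^2
    gfld <- gfld / max(abs(gfld), 1e-12)
    a <- a * (1 + bias_amp * array(gfld, d))
  }
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  a <- pmin(1, pmax(0, a))
  new("BrainVolume", data = array(a, d), spacing = vol@spacing,
      origin = vol@origin, orientation = "RAS",
      sourceOrientation = vol@sourceOrientation)
}

#' Serialize / restore a phantom spec
#'
#' Round-tripping a spec through JSON reproduces identical phantom output.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @param path file path; for \code{phantomSpecFromJSON}, a path written by
#'   \code{phantomSpecToJSON}.
#' @return \code{phantomSpecToJSON} returns the path invisibly;
#'   \code{phantomSpecFromJSON} returns a \code{PhantomSpec}.
#' @export
phantomSpecToJSON <- function(spec, path) {
  slots <- c("shape", "spacing", "intensities", "geometry", "tilt_deg",
             "scale", "noise_sd", "bias_amp", "blur_sigma", "pons_atrophy",
             "seed")
  obj <- lapply(slots, function(s) slot(spec, s))
  names(obj) <- slots
  # keep element names (write_json drops them on atomic vectors)
  obj$intensities <- as.list(obj$intensities)
  obj$geometry <- lapply(obj$geometry, function(v)
    if (is.null(names(v))) v else as.list(v))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname phantomSpecToJSON
#' @export
phantomSpecFromJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- defaultPhantomSpec()
  for (nm in setdiff(names(obj), "geometry")) {
    v <- obj[[nm]]
    if (nm == "intensities") v <- unlist(v)
    slot(spec, nm) <- as.numeric(v)
    if (nm == "intensities") names(slot(spec, nm)) <- names(unlist(obj[[nm]]))
  }
  geo <- lapply(obj$geometry, function(v) {
    v2 <- unlist(v)
    if (!is.null(names(v))) names(v2) <- names(v)
    v2
  })
  spec@geometry[names(geo)] <- geo
  validObject(spec)
  spec
}
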