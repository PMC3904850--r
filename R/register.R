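# Optional 6-parameter rigid registration to a template, maximizing a
# joint-histogram mutual-information metric by local optimization.
# Registration is a pluggable convenience: the pipeline assumes pre-aligned
# input by default and callers may bypass this step entirely.

# rotation matrix from (rx, ry, rz) in degrees, applied as Rz %*% Ry %*% Rx
.rotationMatrix <- function(r) {
  r <- r * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# mm coordinates (relative to the grid centre) of the voxels selected by
# the index vectors idx1..idx3 of a grid with `dims` and `spacing`.
.centredCoords <- function(dims, spacing, idx = NULL) {
  if (is.null(idx)) idx <- lapply(dims, seq_len)
  ctr <- (dims - 1) / 2 * spacing
  xs <- (idx[[1]] - 1) * spacing[1] - ctr[1]
  ys <- (idx[[2]] - 1) * spacing[2] - ctr[2]
  zs <- (idx[[3]] - 1) * spacing[3] - ctr[3]
  n1 <- length(xs); n2 <- length(ys); n3 <- length(zs)
  cbind(rep(xs, times = n2 * n3),
        rep(rep(ys, each = n1), times = n3),
        rep(zs, each = n1 * n2))
}

# Sample `vol` at the mm points `pts` (relative to the template grid
# centre) transformed by the registration parameters (rot, trans): the
# transform maps template space into the moving volume's space.
.sampleTransformed <- function(vol, pts, rot, trans) {
  R <- .rotationMatrix(rot)
  src <- pts %*% t(R)
  src <- sweep(src, 2, trans, "+")
  ctrV <- (dim(vol@data) - 1) / 2 * vol@spacing
  srcIdx <- sweep(src, 2, ctrV, "+")
  srcIdx <- sweep(srcIdx, 2, vol@spacing, "/")
  .trilinearSample(vol@data, srcIdx)
}

# Negative mutual information from a 32-bin joint histogram. Evaluated on
# the full fixed sample support (callers map out-of-view samples to the
# background intensity) so that poses with smaller overlap cannot score
# spuriously high MI.
.negMutualInformation <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 100) return(Inf)
  a <- a[ok]; b <- b[ok]
  qa <- pmin(bins, floor((a - min(a)) / max(diff(range(a)), 1e-12) * bins) + 1L)
  qb <- pmin(bins, floor((b - min(b)) / max(diff(range(b)), 1e-12) * bins) + 1L)
  h <- tabulate((qb - 1L) * bins + qa, bins * bins)
  p <- h / sum(h)
  px <- rowSums(matrix(p, bins)); py <- colSums(matrix(p, bins))
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz])) - sum(px[px > 0] * log(px[px > 0])) -
    sum(py[py > 0] * log(py[py > 0]))
  -mi
}

#' Apply a rigid transform to a volume
#'
#' Moves the image content by the forward transform: rotate by \code{rot}
#' (degrees, about the grid centre), then translate by \code{trans} (mm).
#' Registering the result back to the original recovers exactly these
#' parameters.
#'
#' @param vol a \code{\link{BrainVolume}}.
#' @param rot numeric(3) rotations about x, y, z axes in degrees.
#' @param trans numeric(3) translation in mm.
#' @param fill value for voxels mapped outside the source grid.
#' @return A transformed \code{\link{BrainVolume}} on the same grid.
#' @export
applyRigidTransform <- function(vol, rot = c(0, 0, 0), trans = c(0, 0, 0),
                                fill = 0) {
  stopIfNot3D(vol)
  d <- dim(vol@data)
  pts <- .centredCoords(d, vol@spacing)
  # forward motion: out(x) = vol(R^-1 (x - t))
  R <- .rotationMatrix(rot)
  src <- sweep(pts, 2, trans, "-") %*% R   # == t(R^-1) applied to rows
  ctrV <- (d - 1) / 2 * vol@spacing
  srcIdx <- sweep(sweep(src, 2, ctrV, "+"), 2, vol@spacing, "/")
  a <- array(.trilinearSample(vol@data, srcIdx), d)
  a[is.na(a)] <- fill
  new("BrainVolume", data = a, spacing = vol@spacing, origin = vol@origin,
      orientation = "RAS", sourceOrientation = vol@sourceOrientation)
}

#' Rigid registration to a template
#'
#' Six-parameter (3 rotations + 3 translations) registration maximizing the
#' mutual information between the moving volume and the template, with
#' centre-of-mass initialization and Nelder-Mead refinement on a subsampled
#' grid. The transform maps template-space positions into the moving
#' volume's space; the returned volume is the moving image resampled onto
#' the template grid.
#'
#' Registration is optional and off by default in the pipeline: input is
#' assumed pre-aligned to template orientation, and this implementation is a
#' self-contained convenience rather than a reproduction of any external
#' registration package.
#'
#' @param vol moving \code{\link{BrainVolume}}.
#' @param template reference \code{\link{BrainVolume}}.
#' @param subsample integer step between metric samples (voxels).
#' @param maxit maximum Nelder-Mead iterations.
#' @return List with \code{volume} (resampled to the template grid),
#'   \code{rotation} (degrees), \code{translation} (mm), \code{mi} (final
#'   mutual information), and \code{failed} (TRUE when the fields of view
#'   did not overlap; the input is then returned unregistered).
#' @export
rigidRegisterToTemplate <- function(vol, template, subsample = 3L,
                                    maxit = 300L) {
  stopIfNot3D(vol); stopIfNot3D(template, "template")
  tDims <- dim(template@data)
  step <- max(1L, as.integer(subsample))
  sub <- lapply(tDims, function(n) seq(1L, n, by = step))
  tSub <- as.vector(template@data[sub[[1]], sub[[2]], sub[[3]]])
  subPts <- .centredCoords(tDims, template@spacing, sub)

  # centre-of-mass translation initialization
  com <- function(a, spacing) {
    w <- pmax(a - min(a), 0)
    idx <- .centredCoords(dim(a), spacing)
    colSums(idx * as.vector(w)) / sum(w)
  }
  t0 <- com(vol@data, vol@spacing) - com(template@data, template@spacing)

  objective <- function(p) {
    m <- .sampleTransformed(vol, subPts, p[1:3], p[4:6])
    overlap <- mean(is.finite(m))
    if (overlap < 0.25) return(1e6 * (1 - overlap))
    m[!is.finite(m)] <- 0   # fixed support: no overlap bias
    .negMutualInformation(tSub, m)
  }

  p0 <- c(0, 0, 0, t0)
  if (any(!is.finite(p0)) || !is.finite(objective(p0)) ||
      objective(p0) >= 1e5) {
    warning("rigidRegisterToTemplate: fields of view do not overlap; ",
            "returning input unregistered")
    return(list(volume = vol, rotation = c(0, 0, 0),
                translation = c(0, 0, 0), mi = NA_real_, failed = TRUE))
  }
  # coarse rotation search: the mutual-information surface is locally flat,
  # so seed the simplex from the best point of a 4.5-degree rotation grid
  best <- objective(p0)
  for (rx in seq(-9, 9, by = 4.5)) for (ry in seq(-9, 9, by = 4.5))
    for (rz in seq(-9, 9, by = 4.5)) {
      v <- objective(c(rx, ry, rz, t0))
      if (v < best) { best <- v; p0 <- c(rx, ry, rz, t0) }
    }
  fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9,
                                     parscale = c(2, 2, 2, 5, 5, 5)))
  # polish with a restarted simplex (Nelder-Mead can stall on MI plateaus)
  fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9,
                                     parscale = c(0.5, 0.5, 0.5, 1, 1, 1)))
  p <- fit$par
  out <- array(.sampleTransformed(vol, .centredCoords(tDims, template@spacing),
                                  p[1:3], p[4:6]), tDims)
  out[is.na(out)] <- 0
  list(volume = new("BrainVolume", data = out, spacing = template@spacing,
                    origin = template@origin, orientation = "RAS",
                    sourceOrientation = vol@sourceOrientation),
       rotation = p[1:3], translation = p[4:6], mi = -fit$value,
       failed = FALSE)
}
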