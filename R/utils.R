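# Internal numeric helpers shared across modules.

# Iterative union-find over 1..n with path compression; merges is a 2-column
# matrix of pairs. Returns the root label for each element.
unionFind <- function(n, merges) {
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(merges)) {
    for (k in seq_len(nrow(merges))) {
      a <- findRoot(merges[k, 1]); b <- findRoot(merges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), findRoot, integer(1))
}

# Centered moving average with shrinking windows at the ends (NA-tolerant).
movingAverage <- function(x, window = 3L) {
  if (window <= 1L) return(x)
  h <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- mean(x[j], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

# Centered running minimum (NA values ignored; all-NA window -> NA).
runningMin <- function(x, window) {
  h <- window %/% 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    v <- x[j]
    v <- v[!is.na(v)]
    if (length(v)) out[i] <- min(v)
  }
  out
}

# Binary dilation of a 3-D logical array by a Chebyshev ball of given radius,
# done with array shifts (radius is small in practice).
dilate3d <- function(mask, radius = 1L) {
  d <- dim(mask)
  out <- mask
  offs <- seq(-radius, radius)
  shift1 <- function(m, s, axis) {
    if (s == 0L) return(m)
    res <- array(FALSE, dim(m))
    n <- dim(m)[axis]
    src <- if (s > 0) 1:(n - s) else (1 - s):n
    dst <- if (s > 0) (1 + s):n else 1:(n + s)
    idx <- function(a, rng) if (a == axis) rng else TRUE
    res[idx(1, dst), idx(2, dst), idx(3, dst)] <-
      m[idx(1, src), idx(2, src), idx(3, src)]
    res
  }
  # separable: dilate along each axis in turn (box structuring element)
  for (axis in 1:3) {
    acc <- out
    for (s in offs) if (s != 0L) acc <- acc | shift1(out, s, axis)
    out <- acc
  }
  out
}

# Separable Gaussian blur of a 2-D matrix.
gaussianBlur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  gaussianBlur3d(array(m, c(dim(m), 1L)), sigma)[, , 1]
}

# Separable Gaussian blur of a 3-D array (sigma in voxels; sigma 0 = identity).
gaussianBlur3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  blurAxis <- function(a, axis) {
    # fold target axis to rows of a matrix, filter columnwise via matrix mult
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])
    n <- nrow(m)
    # replicate-pad convolution
    padTop <- m[rep(1L, r), , drop = FALSE]
    padBot <- m[rep(n, r), , drop = FALSE]
    mp <- rbind(padTop, m, padBot)
    out <- 0
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
    aperm(array(out, d[perm]), order(perm))
  }
  for (axis in 1:3) x <- blurAxis(x, axis)
  x
}

# 3x3 median filter with replicated edges (edge-preserving speckle
# suppression; identity on piecewise-constant interiors). Implemented as a
# 19-exchange minimum-exchange sorting network over the 9 shifted copies.
medianFilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(s) pmin(nr, pmax(1L, seq_len(nr) + s))
  ci <- function(s) pmin(nc, pmax(1L, seq_len(nc) + s))
  v <- vector("list", 9)
  k <- 0
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1
    v[[k]] <- m[ri(dr), ci(dc)]
  }
  ex <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  ex(2, 3); ex(5, 6); ex(8, 9); ex(1, 2); ex(4, 5); ex(7, 8)
  ex(2, 3); ex(5, 6); ex(8, 9); ex(1, 4); ex(6, 9); ex(5, 8)
  ex(4, 7); ex(2, 5); ex(3, 6); ex(5, 8); ex(5, 3); ex(7, 5); ex(5, 3)
  v[[5]]
}

# Binary closing (dilate then erode) with a 3x3 box, r iterations.
close2d <- function(mask, r = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- function(s) pmin(nr, pmax(1L, seq_len(nr) + s))
  ci <- function(s) pmin(nc, pmax(1L, seq_len(nc) + s))
  pass <- function(m, op) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) acc <- op(acc, m[ri(dr), ci(dc)])
    acc
  }
  for (i in seq_len(r)) mask <- pass(mask, `|`)
  for (i in seq_len(r)) mask <- pass(mask, `&`)
  mask
}

# Signed distance of grid voxel centres to a plane; vol gives geometry.
# Returns an array of dim(vol@data).
planeSignedDistance <- function(plane, dims, spacing, origin) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  n <- plane$normal
  p <- plane$point
  dx <- (xs - p[1]) * n[1]
  dy <- (ys - p[2]) * n[2]
  dz <- (zs - p[3]) * n[3]
  array(rep(dx, times = dims[2] * dims[3]) +
          rep(rep(dy, each = dims[1]), times = dims[3]) +
          rep(dz, each = dims[1] * dims[2]),
        dims)
}

# mm coordinate of a voxel index along an axis.
voxelToMM <- function(index, axis, spacing, origin) {
  origin[axis] + (index - 1) * spacing[axis]
}

mmToVoxel <- function(mm, axis, spacing, origin) {
  (mm - origin[axis]) / spacing[axis] + 1
}

# Normalize a vector to unit length.
unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

stopIfNot3D <- function(vol, what = "volume") {
  if (!is(vol, "BrainVolume")) stop(what, " must be a BrainVolume")
  invisible(TRUE)
}
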