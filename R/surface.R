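# Surface extraction from binary masks and PLY export.
#
# The surface is the set of voxel faces between foreground and background
# (iso-level 0.5 on the voxel grid): a closed, consistently oriented
# triangle mesh whose enclosed volume equals voxel count x voxel volume
# exactly.

#' Extract a closed surface mesh from a 3-D mask
#'
#' Builds the boundary-face surface of the mask: every voxel face adjacent
#' to background contributes two outward-oriented triangles, with vertices
#' at voxel corners in mm coordinates. The mesh is closed and its enclosed
#' (signed) volume equals the mask volume exactly.
#'
#' @param mask non-empty 3-D \code{\link{BrainMask}}.
#' @return A \code{\link{SurfaceMesh}}.
#' @export
extractSurface <- function(mask) {
  if (!is(mask, "BrainMask") || length(dim(mask@data)) != 3L)
    stop("extractSurface: need a 3-D BrainMask")
  m <- mask@data
  if (!any(m)) stop("extractSurface: empty mask")
  d <- dim(m)
  sp <- mask@spacing
  or <- mask@origin

  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m

  quads <- list()
  # for each axis and direction, faces where voxel is fg and neighbour bg
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(6)) {
    dv <- dirs[k, ]
    nb <- pad[2:(d[1] + 1) + dv[1], 2:(d[2] + 1) + dv[2], 2:(d[3] + 1) + dv[3]]
    face <- which(m & !nb, arr.ind = TRUE)
    if (nrow(face) == 0) next
    # face centre offset by half voxel along dv; quad spans the two
    # perpendicular axes
    axis <- which(dv != 0)
    s <- dv[axis]
    perp <- setdiff(1:3, axis)
    ctr <- sweep(face - 1, 2, sp, "*")
    ctr <- sweep(ctr, 2, or, "+")
    ctr[, axis] <- ctr[, axis] + s * sp[axis] / 2
    h1 <- sp[perp[1]] / 2; h2 <- sp[perp[2]] / 2
    corner <- function(a, b) {
      v <- ctr
      v[, perp[1]] <- v[, perp[1]] + a * h1
      v[, perp[2]] <- v[, perp[2]] + b * h2
      v
    }
    c00 <- corner(-1, -1); c10 <- corner(1, -1)
    c11 <- corner(1, 1); c01 <- corner(-1, 1)
    # winding: outward normal along s * axis
    flip <- (s > 0) == (axis == 2)  # chosen so cross product points outward
    if ((axis == 1 && s > 0) || (axis == 2 && s < 0) || (axis == 3 && s > 0)) {
      quads[[length(quads) + 1]] <- list(c00, c10, c11, c01)
    } else {
      quads[[length(quads) + 1]] <- list(c00, c01, c11, c10)
    }
  }
  allV <- do.call(rbind, lapply(quads, function(q) do.call(rbind, q)))
  nq <- vapply(quads, function(q) nrow(q[[1]]), integer(1))
  # deduplicate vertices on the half-voxel lattice
  key <- paste(round(allV[, 1] / (min(sp) / 4)),
               round(allV[, 2] / (min(sp) / 4)),
               round(allV[, 3] / (min(sp) / 4)))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- allV[uk, , drop = FALSE]
  # reassemble faces: within each quad block the 4 corners are stacked
  faces <- list()
  off <- 0L
  for (b in seq_along(quads)) {
    n <- nq[b]
    i1 <- vid[off + seq_len(n)]
    i2 <- vid[off + n + seq_len(n)]
    i3 <- vid[off + 2L * n + seq_len(n)]
    i4 <- vid[off + 3L * n + seq_len(n)]
    faces[[length(faces) + 1]] <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
    off <- off + 4L * n
  }
  faces <- do.call(rbind, faces)
  mesh <- new("SurfaceMesh", vertices = unname(verts),
              faces = unname(faces))
  # orient globally outward: positive signed volume
  if (meshVolume(mesh, signed = TRUE) < 0)
    mesh@faces <- mesh@faces[, c(1, 3, 2)]
  validObject(mesh)
  mesh
}

#' Enclosed volume of a closed mesh
#'
#' Signed tetrahedron sum over faces; for the closed, outward-oriented
#' meshes produced by \code{\link{extractSurface}} this equals the enclosed
#' volume in mm^3.
#'
#' @param mesh a \code{\link{SurfaceMesh}}.
#' @param signed return the raw signed value (default takes the absolute).
#' @return Volume in mm^3.
#' @export
meshVolume <- function(mesh, signed = FALSE) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
             a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  if (signed) s else abs(s)
}

#' Connected components of a mesh
#'
#' @param mesh a \code{\link{SurfaceMesh}}.
#' @return Number of vertex-connected components.
#' @export
meshComponentCount <- function(mesh) {
  n <- nrow(mesh@vertices)
  e <- rbind(mesh@faces[, 1:2], mesh@faces[, 2:3], mesh@faces[, c(1, 3)])
  root <- unionFind(n, e)
  length(unique(root))
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a \code{\link{SurfaceMesh}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSurfacePLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(mesh@vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(mesh@faces)),
    "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh@vertices, trim = TRUE, digits = 7), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh@faces - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
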