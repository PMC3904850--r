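test_that("mid-sagittal brainstem segmentation matches the generator truth", {
  ph <- defaultPhantom()
  sl <- labseg:::medianFilter3(voxelData(ph$volume)[ph$landmarks$symmetry, , ])
  bs <- segmentBrainstemMidsagittal(sl, headCentroid(sl))
  expect_gte(diceCoefficient(bs$mask, voxelData(ph$truth$brainstem2d)), 0.95)
  expect_true(bs$r1@openBottom)
  expect_error(segmentBrainstemMidsagittal(matrix(0, 50, 50), c(25, 25)),
               "constant|empty|no component")
})

test_that("all landmarks land within 2 px of the generator truth", {
  ph <- defaultPhantom()
  lr <- detectLandmarks(ph$volume)
  lm <- lr$landmarks
  for (nm in c("p1", "p2", "p3", "mammillary", "qp_superior")) {
    det <- slot(lm, nm)
    tru <- ph$landmarks[[nm]]
    expect_lte(max(abs(det - tru)), 2, label = paste(nm, "error"))
  }
  expect_length(lm@flags, 0)
})

test_that("cut planes satisfy the geometric invariants", {
  ph <- defaultPhantom()
  lr <- detectLandmarks(ph$volume)
  pl <- lr$planes
  expect_identical(pl@lineA$normal, pl@lineB$normal)
  expect_equal(sqrt(sum(pl@lineA$normal^2)), 1, tolerance = 1e-12)
  lm <- lr$landmarks
  expect_gt(lm@p1[2], lm@p2[2])          # p1 strictly superior to p2
  # cranial border strictly superior to line A at the anterior brainstem edge
  yA <- max(which(apply(voxelData(lr$bsMask), 1, any)))
  zOn <- function(p) p$point[3] - p$normal[2] / p$normal[3] *
    ((yA - 1) - p$point[2])
  expect_gt(zOn(pl@cranialMB), zOn(pl@lineA))
  # line A passes through p1 and p3 (both at zero signed distance)
  sd2 <- function(p, pt) sum((c(pt[1] - 1, pt[2] - 1) -
                                p$point[2:3]) * p$normal[2:3])
  expect_equal(sd2(pl@lineA, lm@p1), 0, tolerance = 1e-9)
  expect_equal(sd2(pl@lineA, lm@p3), 0, tolerance = 1e-9)
  expect_equal(sd2(pl@lineB, lm@p2), 0, tolerance = 1e-9)
})

test_that("landmark detection is translation-equivariant", {
  ph <- defaultPhantom()
  a <- voxelData(ph$volume)
  dy <- 4L; dz <- 3L
  d <- dim(a)
  shifted <- array(0, d)
  shifted[, (1 + dy):d[2], (1 + dz):d[3]] <-
    a[, 1:(d[2] - dy), 1:(d[3] - dz)]
  lr0 <- detectLandmarks(ph$volume, sliceIndex = ph$landmarks$symmetry)
  lr1 <- detectLandmarks(BrainVolume(shifted, spacing = ph$volume@spacing),
                         sliceIndex = ph$landmarks$symmetry)
  for (nm in c("p1", "p2", "p3", "mammillary", "qp_superior"))
    expect_equal(slot(lr1$landmarks, nm),
                 slot(lr0$landmarks, nm) + c(dy, dz),
                 label = paste("shifted", nm))
})

test_that("mammillary detector picks the superior of two bumps and flags
           featureless contours", {
  col <- matrix(FALSE, 60, 100)
  col[20:40, 10:90] <- TRUE
  bump <- function(z0, z1) col[41:43, z0:z1] <<- TRUE
  bump(70, 75)      # superior bump
  bump(50, 55)      # inferior bump
  pt <- detectMammillary(col)
  expect_false(attr(pt, "lowConfidence"))
  expect_lte(abs(pt["z"] - 69), 2)          # junction below the superior bump
  plain <- matrix(FALSE, 60, 100)
  plain[20:40, 10:90] <- TRUE
  pf <- detectMammillary(plain)
  expect_true(attr(pf, "lowConfidence"))
})

test_that("pontine notch detection matches a hand-traced profile", {
  # anterior extent profile ...,5,5,9,12,12,9,5,5,... (superior -> inferior)
  extent <- c(rep(5, 12), 9, 12, 12, 12, 12, 9, rep(5, 12))
  zlen <- length(extent)
  m <- matrix(FALSE, 20, zlen)
  for (j in seq_len(zlen)) m[1:extent[zlen + 1 - j], j] <- TRUE
  pn <- detectPontineNotches(m, smooth = 1L, min_excess = 1)
  expect_equal(unname(pn$p1["z"]), zlen - 11)     # row above the hump
  expect_equal(unname(pn$p2["z"]), 12)            # row below the hump
  expect_equal(unname(pn$p1["y"]), 5)
  # straight column has no hump
  straight <- matrix(FALSE, 20, 40); straight[1:8, 5:35] <- TRUE
  expect_error(detectPontineNotches(straight), "not found")
})

test_that("notch detection is stable under 1-px contour jitter", {
  ph <- defaultPhantom()
  lr <- detectLandmarks(ph$volume)
  bs <- voxelData(lr$bsMask)
  set.seed(17)
  for (rep in 1:3) {
    jit <- bs
    ext <- apply(bs, 2, function(col) if (any(col)) max(which(col)) else NA)
    for (j in which(!is.na(ext))) {
      dj <- sample(c(-1L, 0L, 1L), 1)
      if (dj == 1L) jit[ext[j] + 1L, j] <- TRUE
      if (dj == -1L) jit[ext[j], j] <- FALSE
    }
    pn <- detectPontineNotches(jit)
    expect_lte(abs(pn$p1["z"] - lr$landmarks@p1[2]), 2)
    expect_lte(abs(pn$p2["z"] - lr$landmarks@p2[2]), 2)
  }
})

test_that("quadrigeminal plate detection fails cleanly when absent", {
  ph <- defaultPhantom()
  sl <- labseg:::medianFilter3(voxelData(ph$volume)[ph$landmarks$symmetry, , ])
  bs <- segmentBrainstemMidsagittal(sl, headCentroid(sl))
  qp <- detectQuadrigeminalPlate(sl, bs$r1, bs$mask)
  expect_lte(max(abs(qp$p3 - ph$landmarks$p3)), 2)
  # erase everything but the brainstem: detection must fail with a named
  # error (no remaining component)
  sl2 <- sl
  sl2[!bs$mask] <- 0.1
  expect_error(detectQuadrigeminalPlate(sl2, bs$r1, bs$mask), "plate")
})

test_that("cerebellum plane passes through the brainstem dorsum", {
  ph <- defaultPhantom()
  lr <- detectLandmarks(ph$volume)
  pl <- lr$planes@cerebellum
  expect_equal(pl$normal, c(0, 1, 0))
  # the phantom dorsum is the flat posterior face of the column
  expect_lte(abs(pl$point[2] - (min(which(apply(
    voxelData(ph$truth$brainstem2d), 1, any))) - 1)), 2)
})
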