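test_that("S1 window placement follows the middle-slice convention", {
  vol368 <- BrainVolume(array(0.1, c(368, 4, 4)))
  s1 <- extractS1(vol368, "auto", 40L)
  expect_equal(s1$center, 184)                 # 368-slice acquisition
  expect_equal(range(s1$indices), c(164, 203))
  expect_equal(length(s1$indices), 40L)
  vol <- BrainVolume(array(0.1, c(20, 4, 4)))
  s2 <- extractS1(vol, 5L, 3L)
  expect_equal(s2$indices, 4:6)
  expect_warning(s3 <- extractS1(vol, 1L, 40L), "clipped")
  expect_equal(range(s3$indices), c(1, 20))
  expect_error(extractS1(vol, 50L, 5L), "bounds")
  expect_error(extractS1(vol, 5L, 2L), "width")
})

test_that("head centroid equals the coordinate mean of the head mask", {
  sl <- matrix(0, 40, 40)
  sl[11:30, 6:25] <- 1                       # centred filled square
  expect_equal(unname(headCentroid(sl)), c(20.5, 15.5))
  sl2 <- matrix(0, 20, 20)
  sl2[5, 3] <- sl2[15, 3] <- 1
  expect_equal(unname(headCentroid(sl2)), c(10, 3))
  set.seed(5)
  blob <- matrix(0, 30, 30)
  blob[cbind(sample(5:25, 40, TRUE), sample(5:25, 40, TRUE))] <- 1
  ctr <- headCentroid(blob)
  idx <- which(blob > otsuThreshold(blob), arr.ind = TRUE)
  expect_equal(unname(ctr), c(mean(idx[, 1]), mean(idx[, 2])))
})

test_that("callosal bottom extremes follow the tie rules", {
  # bar along the anterior-posterior direction at one height
  m <- matrix(FALSE, 30, 30)
  m[3:20, 10] <- TRUE
  ext <- ccBottomExtremes(m)
  expect_equal(unname(ext$p1cc), c(20, 10))   # anterior-most, inferior
  expect_equal(unname(ext$p2cc), c(3, 10))
  # arch: two limbs reaching down, bottom tips at distinct heights
  arch <- matrix(FALSE, 40, 40)
  yc <- 20; zc <- 25
  for (y in 1:40) for (z in 1:40) {
    r <- sqrt((y - yc)^2 + (z - zc)^2)
    if (r >= 8 && r <= 12 && z >= zc) arch[y, z] <- TRUE
  }
  e2 <- ccBottomExtremes(arch)
  expect_equal(unname(e2$p1cc), c(32, 25))    # outer limb tips at z = zc
  expect_equal(unname(e2$p2cc), c(8, 25))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(ccBottomExtremes(single), "degenerate")
})

test_that("R1 rectangles rasterize to the expected extents", {
  # axis-aligned: L = 30 along y at z = 30, depth (2/3)L = 20 inferior
  r1 <- buildR1(c(5, 30), c(35, 30))
  expect_equal(r1@L, 30)
  inside <- r1Contains(r1, c(50, 50))
  idx <- which(inside, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(5, 35))
  expect_equal(range(idx[, 2]), c(10, 30))
  # rotated by 90 degrees: area preserved within rasterization error
  r2 <- buildR1(c(20, 5), c(20, 35))
  a2 <- sum(r1Contains(r2, c(60, 60)))
  expect_lt(abs(a2 - 30 * 20) / (30 * 20), 0.12)
  # open bottom reaches the slice edge
  r3 <- buildR1(c(5, 30), c(35, 30), openBottom = TRUE)
  idx3 <- which(r1Contains(r3, c(50, 50)), arr.ind = TRUE)
  expect_equal(min(idx3[, 2]), 1)
  expect_error(buildR1(c(5, 5), c(5, 5)), "degenerate")
})

test_that("upper-brainstem area counts the largest credible component", {
  r1 <- buildR1(c(5, 40), c(45, 40))
  empty <- matrix(0, 60, 60)
  expect_error(upperBrainstemArea(empty, r1), "constant")
  dark <- matrix(0, 60, 60); dark[50:55, 50:55] <- 1  # bright outside R1
  expect_equal(upperBrainstemArea(dark, r1), 0L)
  full <- matrix(0, 60, 60)
  full[which(r1Contains(r1, c(60, 60)))] <- 1
  full[2:3, 2:3] <- 0.4                      # secondary tissue level
  area <- upperBrainstemArea(full, r1, thresholdConfig(c_bs = 1))
  expect_equal(area, sum(r1Contains(r1, c(60, 60))))
  expect_error(upperBrainstemArea(full, buildR1(c(5, 40), c(45, 40),
                                                openBottom = TRUE)),
               "closed")
})

test_that("mid-sagittal detection recovers the phantom symmetry plane", {
  ph <- defaultPhantom()
  ms <- findMidsagittal(ph$volume)
  expect_equal(ms$index, ph$landmarks$symmetry)
  expect_true(all(ms$profile$upper_bs_area >= 0))
  valid <- ms$profile$upper_bs_area > 0
  expect_equal(min(ms$profile$upper_bs_area[valid]),
               ms$profile$upper_bs_area[ms$profile$slice == ms$index])
})

test_that("mid-sagittal detection is shift-equivariant", {
  ph <- defaultPhantom()
  a <- voxelData(ph$volume)
  shifted <- array(0, dim(a))
  shifted[4:dim(a)[1], , ] <- a[1:(dim(a)[1] - 3), , ]
  ms <- findMidsagittal(BrainVolume(shifted, spacing = ph$volume@spacing))
  expect_equal(ms$index, ph$landmarks$symmetry + 3L)
})
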