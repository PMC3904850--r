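test_that("plane cropping keeps exact half-open slabs", {
  a <- array(1, c(30, 30, 30))
  vol <- BrainVolume(a)
  # keep z in [10, 20) in mm: signed distances against two axial planes
  out <- cropBetweenPlanes(vol, list(
    list(plane = list(point = c(0, 0, 9), normal = c(0, 0, 1)), op = ">="),
    list(plane = list(point = c(0, 0, 19), normal = c(0, 0, 1)), op = "<")))
  kept <- apply(voxelData(out), 3, sum)
  expect_equal(which(kept > 0), 10:19)       # exactly 10 slices
  expect_equal(sum(kept > 0), 10)
})

test_that("oblique cropping matches the per-voxel signed-distance oracle", {
  set.seed(41)
  a <- array(runif(20^3), c(20, 20, 20))
  vol <- BrainVolume(a, spacing = c(1, 1, 1))
  n <- labseg:::unitVector(c(0, 1, 1))       # 45-degree plane
  p <- c(0, 9.3, 9.7)
  out <- cropBetweenPlanes(vol, list(list(
    plane = list(point = p, normal = n), op = ">")))
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  sd <- as.vector((idx[, 2] - 1 - p[2]) * n[2] + (idx[, 3] - 1 - p[3]) * n[3])
  expect_equal(sum(voxelData(out) > 0), sum(sd > 0))
  expect_identical(voxelData(out)[array(sd > 0, c(20, 20, 20))],
                   a[array(sd > 0, c(20, 20, 20))])
})

test_that("contradictory planes empty the volume with a warning", {
  vol <- BrainVolume(array(1, c(8, 8, 8)))
  expect_warning(out <- cropBetweenPlanes(vol, list(
    list(plane = list(point = c(0, 0, 20), normal = c(0, 0, 1)), op = ">="),
    list(plane = list(point = c(0, 0, -20), normal = c(0, 0, 1)), op = "<"))),
    "exclude")
  expect_true(attr(out, "empty"))
  expect_equal(sum(voxelData(out)), 0)
})

test_that("computeVolume multiplies count by voxel volume", {
  m <- array(FALSE, c(20, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE  # 1000 vox
  expect_equal(computeVolume(BrainMask(m, spacing = c(0.5, 0.5, 0.5))), 125)
  expect_equal(computeVolume(BrainMask(array(FALSE, c(4, 4, 4)))), 0)
  # 1 mm isotropic: mm^3 equals the voxel count (printed volumes convention)
  m2 <- array(FALSE, c(20, 20, 20)); m2[seq_len(4981 %% 400 + 10)] <- TRUE
  expect_equal(computeVolume(BrainMask(m2)), sum(m2))
})

test_that("segmentStructure takes the largest in-slice component and
           rejects degenerate slices", {
  # one-slice volume: two components, darker background
  a <- array(0, c(1, 40, 40))
  a[1, 5:30, 5:30] <- 0.35
  a[1, 8:20, 8:20] <- 0.8
  a[1, 25:28, 25:28] <- 0.8
  out <- segmentStructure(BrainVolume(a), thresholdConfig(), min_area = 5L,
                          presmooth = 0, denoise = FALSE)
  m <- voxelData(out)[1, , ]
  expect_true(all(m[9:19, 9:19]))
  expect_false(any(m[25:28, 25:28]))
  # pure-noise volume: no credible component on any slice
  set.seed(43)
  noise <- array(abs(rnorm(6 * 30 * 30, 0.3, 0.01)), c(6, 30, 30))
  expect_error(segmentStructure(BrainVolume(noise), thresholdConfig(),
                                presmooth = 0),
               "empty")
})

test_that("the full pipeline recovers the phantom subregions", {
  ph <- defaultPhantom()
  seg <- defaultSegmentation()
  expect_gte(gridDice(seg@midbrain, ph$truth$midbrain), 0.85)
  expect_gte(gridDice(seg@pons, ph$truth$pons), 0.9)
  expect_false(any(voxelData(seg@midbrain) & voxelData(seg@pons)))
  expect_equal(seg@volumes[["midbrain"]],
               voxelCount(seg@midbrain) * 0.5^3)
  # volumes track the generator's ground truth up to the sub-voxel
  # partial-volume erosion shell of strict thresholding (see the methods
  # vignette); overlap and ratio-based results are unaffected by it
  expect_lt(abs(seg@volumes[["midbrain"]] -
                  computeVolume(ph$truth$midbrain)) /
              computeVolume(ph$truth$midbrain), 0.25)
  expect_lt(abs(seg@volumes[["pons"]] -
                  computeVolume(ph$truth$pons)) /
              computeVolume(ph$truth$pons), 0.25)
  # provenance carries the configuration and landmark coordinates
  expect_equal(seg@provenance$config$c_cc, 1.3)
  expect_true(all(c("p1", "p2", "p3", "mammillary") %in%
                    names(seg@provenance$landmarks)))
})

test_that("pipeline is deterministic and intensity-scale invariant", {
  ph <- defaultPhantom()
  seg1 <- defaultSegmentation()
  seg2 <- runPipeline(ph$volume)
  expect_identical(voxelData(seg1@midbrain), voxelData(seg2@midbrain))
  expect_identical(voxelData(seg1@pons), voxelData(seg2@pons))
  scaled <- BrainVolume(voxelData(ph$volume) * 2.7,
                        spacing = ph$volume@spacing)
  seg3 <- runPipeline(scaled)
  expect_identical(voxelData(seg1@midbrain), voxelData(seg3@midbrain))
  expect_identical(voxelData(seg1@pons), voxelData(seg3@pons))
})

test_that("MCP separation removes the peduncle wings and keeps the core", {
  ph <- defaultPhantom()
  seg <- defaultSegmentation()
  margins <- seg@provenance$mcp_margins
  expect_false(is.null(margins))
  # generator wings span |dx| in [11, 18]; SCP margins sit at |dx| = 10
  ctr <- ph$landmarks$symmetry - 1        # mm of the mid-sagittal slice
  expect_lte(abs((ctr - margins[1]) - 10), 1.5)
  expect_lte(abs((margins[2] - ctr) - 10), 1.5)
  # no pons voxels beyond the margins
  xs <- seg@pons@origin[1] + (seq_len(dim(voxelData(seg@pons))[1]) - 1) * 0.5
  outside <- xs < margins[1] | xs > margins[2]
  expect_equal(sum(voxelData(seg@pons)[outside, , ]), 0)
})

test_that("a wingless pons passes through MCP separation unchanged", {
  ph <- defaultPhantom()
  lr <- detectLandmarks(ph$volume)
  m <- array(FALSE, c(21, 20, 30))
  m[6:16, 5:15, 5:25] <- TRUE
  pons <- BrainMask(m, spacing = c(0.5, 0.5, 0.5),
                    origin = c(80, 95, 60))
  # a volume with no peduncles anywhere near the slab
  flat <- BrainVolume(array(0.05, dim(voxelData(ph$volume))))
  expect_warning(out <- separateMCP(pons, flat, lr), "unchanged|not found")
  expect_identical(voxelData(out), m)
})
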