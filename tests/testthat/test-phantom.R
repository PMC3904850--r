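test_that("phantom generation is seed-deterministic and spec-serializable", {
  spec <- defaultPhantomSpec(shape = c(96, 150, 160), noise_sd = 0.02,
                             seed = 9)
  a <- brainPhantom(spec)
  b <- brainPhantom(spec)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  tmp <- tempfile(fileext = ".json")
  phantomSpecToJSON(spec, tmp)
  spec2 <- phantomSpecFromJSON(tmp)
  c2 <- brainPhantom(spec2)
  expect_identical(voxelData(a$volume), voxelData(c2$volume))
  unlink(tmp)
})

test_that("noiseless tissue means are exact inside each structure", {
  ph <- defaultPhantom()
  v <- voxelData(ph$volume)
  # erode truth beyond the partial-volume blur support (Chebyshev erosion)
  core <- function(m) m & !labseg:::dilate3d(!m, 3L)
  pons <- core(voxelData(ph$truth$pons))
  expect_gt(sum(pons), 100)
  expect_true(all(abs(v[pons] - 0.55) < 1e-6))
  # midbrain truth includes the tectal plate, so its interior carries the
  # brainstem (0.55) and plate (0.6) means and their internal interface
  mid <- core(voxelData(ph$truth$midbrain))
  expect_gt(sum(mid), 100)
  expect_true(all(v[mid] >= 0.55 - 1e-6 & v[mid] <= 0.6 + 1e-6))
  expect_true(any(abs(v[mid] - 0.55) < 1e-6))
})

test_that("truth masks are frozen before noise and bias", {
  s0 <- defaultPhantomSpec(shape = c(96, 150, 160))
  s1 <- defaultPhantomSpec(shape = c(96, 150, 160), noise_sd = 0.05,
                           bias_amp = 0.2, seed = 3)
  a <- brainPhantom(s0); b <- brainPhantom(s1)
  expect_identical(voxelData(a$truth$midbrain), voxelData(b$truth$midbrain))
  expect_identical(voxelData(a$truth$pons), voxelData(b$truth$pons))
  expect_false(identical(voxelData(a$volume), voxelData(b$volume)))
})

test_that("perturbVolume is identity at zero and bounds the bias field", {
  vol <- BrainVolume(array(0.5, c(12, 12, 12)))
  expect_identical(voxelData(perturbVolume(vol, 0, 0, 1)), voxelData(vol))
  out <- perturbVolume(vol, 0, 0.2, 7)
  ratio <- voxelData(out) / 0.5
  expect_true(all(ratio >= 0.8 - 1e-9 & ratio <= 1.2 + 1e-9))
  # same seed, same draw; different seed, different draw
  out2 <- perturbVolume(vol, 0.01, 0.1, 5)
  out3 <- perturbVolume(vol, 0.01, 0.1, 5)
  out4 <- perturbVolume(vol, 0.01, 0.1, 6)
  expect_identical(voxelData(out2), voxelData(out3))
  expect_false(identical(voxelData(out2), voxelData(out4)))
})

test_that("phantom invariants hold: symmetry, disjoint truth, landmarks", {
  ph <- defaultPhantom()
  expect_equal(ph$landmarks$symmetry, ceiling(dim(voxelData(ph$volume))[1] / 2))
  expect_false(any(voxelData(ph$truth$midbrain) & voxelData(ph$truth$pons)))
  expect_gt(voxelCount(ph$truth$midbrain), 0)
  expect_gt(voxelCount(ph$truth$pons), 0)
  # notch landmarks sit on the anterior pons boundary of the 2-D truth
  bs2 <- voxelData(ph$truth$brainstem2d)
  p1 <- round(ph$landmarks$p1)
  expect_true(bs2[p1["y"], p1["z"]] || bs2[p1["y"] - 1, p1["z"]])
  # line A and line B of the truth planes share their normal exactly
  expect_identical(ph$planes@lineA$normal, ph$planes@lineB$normal)
})

test_that("impossible geometry is rejected with a reason", {
  expect_error(brainPhantom(defaultPhantomSpec(plate_y = c(90, 100))),
               "overlaps the brainstem")
  expect_error(defaultPhantomSpec(noise_sd = -0.1), ">= 0")
})
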