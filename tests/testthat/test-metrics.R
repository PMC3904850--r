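mk <- function(v, d = c(4, 5, 5)) BrainMask(array(v, d))

test_that("Dice handles agreement, disjointness and the empty convention", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[3:4, , ] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, b), 0)
  # |A| = |B| = 32, overlap 16
  c2 <- array(FALSE, c(4, 4, 4)); c2[2:3, , ] <- TRUE
  expect_equal(diceCoefficient(a, c2), 0.5)
  expect_warning(d0 <- diceCoefficient(array(FALSE, c(2, 2, 2)),
                                       array(FALSE, c(2, 2, 2))), "empty")
  expect_equal(d0, 1)
  expect_error(diceCoefficient(a, array(TRUE, c(3, 3, 3))), "mismatch")
})

test_that("AVD is the absolute percentage difference against the gold", {
  gold <- array(FALSE, c(10, 5, 5)); gold[1:8, 1:5, 1:5] <- TRUE   # 200 vox
  auto <- array(FALSE, c(10, 5, 5)); auto[1:6, 1:5, 1:5] <- TRUE   # 150 vox
  expect_equal(absoluteVolumeDifference(BrainMask(gold), BrainMask(auto)), 25)
  expect_equal(absoluteVolumeDifference(BrainMask(gold), BrainMask(gold)), 0)
  # over-segmentation: gold 100 voxels, auto 130 -> 30% (absolute value)
  gold2 <- array(FALSE, c(10, 5, 5)); gold2[1:4, , ] <- TRUE        # 100
  auto2 <- gold2; auto2[5, , ] <- TRUE; auto2[6, 1, 1:5] <- TRUE     # 130
  expect_equal(absoluteVolumeDifference(BrainMask(gold2),
                                        BrainMask(auto2)), 30)
  expect_error(absoluteVolumeDifference(BrainMask(array(FALSE, c(2, 2, 2))),
                                        BrainMask(array(TRUE, c(2, 2, 2)))),
               "empty")
})

test_that("modified Hausdorff matches hand values and the brute-force oracle", {
  A <- matrix(c(0, 0), 1, 2)
  B <- matrix(c(3, 4), 1, 2)
  expect_equal(modifiedHausdorff(A, B), 5)
  expect_equal(modifiedHausdorff(A, A), 0)
  set.seed(23)
  for (i in 1:6) {
    P <- matrix(runif(2 * 50, 0, 20), ncol = 2)
    Q <- matrix(runif(2 * 40, 0, 20), ncol = 2)
    expect_equal(modifiedHausdorff(P, Q), mhdOracle(P, Q), tolerance = 1e-12)
    expect_equal(modifiedHausdorff(P, Q, symmetric = FALSE),
                 mhdOracle(P, Q, symmetric = FALSE), tolerance = 1e-12)
  }
})

test_that("mask-based Hausdorff uses boundary voxels in mm", {
  a <- array(FALSE, c(8, 8, 8)); a[3:6, 3:6, 3:6] <- TRUE
  m1 <- BrainMask(a, spacing = c(1, 1, 1))
  expect_equal(modifiedHausdorff(m1, m1), 0)
  # shifting by one voxel moves every boundary point by 1 mm
  b <- array(FALSE, c(8, 8, 8)); b[4:7, 3:6, 3:6] <- TRUE
  expect_lte(modifiedHausdorff(m1, BrainMask(b)), 1 + 1e-9)
  # spacing scales distances
  m2 <- BrainMask(a, spacing = c(2, 2, 2))
  b2 <- BrainMask(b, spacing = c(2, 2, 2))
  expect_equal(modifiedHausdorff(m2, b2),
               2 * modifiedHausdorff(m1, BrainMask(b)), tolerance = 1e-9)
})

test_that("metric symmetry properties hold on random masks", {
  set.seed(29)
  for (i in 1:10) {
    a <- array(runif(6^3) < 0.4, c(6, 6, 6))
    b <- array(runif(6^3) < 0.4, c(6, 6, 6))
    if (!any(a) || !any(b)) next
    expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
    ma <- BrainMask(a); mb <- BrainMask(b)
    expect_equal(modifiedHausdorff(ma, mb), modifiedHausdorff(mb, ma))
    # AVD and volume ratio are gold-referenced, hence asymmetric in general
    if (sum(a) != sum(b)) {
      expect_false(isTRUE(all.equal(absoluteVolumeDifference(ma, mb),
                                    absoluteVolumeDifference(mb, ma))))
      expect_false(isTRUE(all.equal(volumeRatio(ma, mb), volumeRatio(mb, ma))))
    }
  }
})

test_that("volume ratio reproduces printed per-subject values", {
  expect_equal(round(volumeRatio(4981, 5256), 3), 0.948)   # HC1 midbrain
  expect_equal(round(volumeRatio(5688, 5655), 3), 1.006)   # AD 012_S_0689
  a <- array(TRUE, c(3, 3, 3))
  expect_equal(volumeRatio(BrainMask(a), BrainMask(a)), 1)
  expect_error(volumeRatio(BrainMask(a), BrainMask(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("summary statistics use the sample convention", {
  expect_equal(unname(summarizeMetrics(c(1, 2, 3))), c(2, 1))
  expect_equal(unname(summarizeMetrics(rep(4, 10))[2]), 0)
  expect_error(summarizeMetrics(numeric(0)), "empty")
})

test_that("summary t statistic matches a direct two-sample t test", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  ours <- tFromSummary(mean(x), sd(x), 3, mean(y), sd(y), 3)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(ours["t"]), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-12)
  expect_equal(unname(tFromSummary(5, 1, 10, 5, 2, 12)["t"]), 0)
  w <- tFromSummary(mean(x), sd(x), 3, mean(y), sd(y), 3, welch = TRUE)
  refw <- t.test(x, y)
  expect_equal(unname(w["t"]), unname(refw$statistic), tolerance = 1e-12)
  expect_equal(unname(w["df"]), unname(refw$parameter), tolerance = 1e-12)
})

test_that("Pearson correlation behaves on exact and random data", {
  x <- 1:10
  expect_equal(pearsonCorrelation(x, 2 * x), 1)
  expect_equal(pearsonCorrelation(x, -x + 7), -1)
  set.seed(31)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearsonCorrelation(a, b),
               cov(a, b) / (sd(a) * sd(b)), tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "constant")
  expect_error(pearsonCorrelation(1:2, 1:2), "lengths")
})

test_that("maskOnGrid majority downsampling is volume-preserving", {
  set.seed(33)
  fine <- array(runif(20^3) < 0.5, c(20, 20, 20))
  m <- BrainMask(fine, spacing = c(0.5, 0.5, 0.5))
  coarse <- maskOnGrid(m, c(10, 10, 10), c(1, 1, 1))
  expect_equal(dim(voxelData(coarse)), c(10, 10, 10))
  # a solid interior fine block maps to the corresponding coarse block
  solid <- array(FALSE, c(20, 20, 20)); solid[3:12, 3:12, 3:12] <- TRUE
  cs <- maskOnGrid(BrainMask(solid, spacing = c(0.5, 0.5, 0.5)),
                   c(10, 10, 10), c(1, 1, 1))
  expect_true(all(voxelData(cs)[3:6, 3:6, 3:6]))
  expect_equal(sum(voxelData(cs)[8:10, , ]), 0)
  expect_equal(sum(voxelData(cs)[1, , ]), 0)
})
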