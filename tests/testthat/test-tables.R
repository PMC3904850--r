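# The bundled per-subject validation tables (30 healthy controls and 10
# Alzheimer's-disease patients, two raters) and their printed summary rows.

test_that("bundled tables load with the expected shape", {
  for (k in 1:4) {
    df <- readPerformanceTable(k)
    expect_setequal(unique(df$structure), c("midbrain", "pons"))
    expect_equal(nrow(df), if (k <= 2) 60 else 20)
    expect_true(all(df$dice > 0 & df$dice <= 1))
    expect_true(all(df$hausdorff >= 0))
  }
})

test_that("printed volume ratios equal LABS/manual volume quotients", {
  for (k in 1:4) {
    df <- readPerformanceTable(k)
    recomputed <- df$labs_volume / df$manual_volume
    # printed ratios are rounded to 1-4 decimals
    expect_lt(max(abs(recomputed - df$volume_ratio)), 6e-3)
  }
})

test_that("healthy-control summary rows match the printed means and SDs", {
  s1 <- summarizePerformanceTable(readPerformanceTable(1))
  get <- function(s, st, m, col) s[s$structure == st & s$metric == m, col]
  expect_equal(get(s1, "midbrain", "manual_volume", "mean"), 4090.6,
               tolerance = 0.05 / 4090.6)
  expect_equal(get(s1, "midbrain", "labs_volume", "mean"), 4031.6,
               tolerance = 0.05 / 4031.6)
  expect_equal(get(s1, "midbrain", "dice", "mean"), 0.91, tolerance = 0.006)
  expect_equal(get(s1, "midbrain", "hausdorff", "mean"), 3.004,
               tolerance = 0.001)
  expect_equal(get(s1, "pons", "labs_volume", "mean"), 10440.4,
               tolerance = 0.05 / 10440)
  expect_equal(get(s1, "pons", "hausdorff", "mean"), 1.966, tolerance = 0.001)
  expect_equal(get(s1, "midbrain", "manual_volume", "sd"), 893.41,
               tolerance = 0.01 / 893)
  expect_equal(get(s1, "pons", "hausdorff", "sd"), 1.8624, tolerance = 1e-4)

  s2 <- summarizePerformanceTable(readPerformanceTable(2))
  expect_equal(get(s2, "midbrain", "dice", "mean"), 0.9, tolerance = 0.006)
  expect_equal(get(s2, "pons", "dice", "mean"), 0.95, tolerance = 0.006)
  expect_equal(get(s2, "midbrain", "hausdorff", "mean"), 2.895,
               tolerance = 0.001)
})

test_that("Alzheimer cohort summary rows match the printed means and SDs", {
  s3 <- summarizePerformanceTable(readPerformanceTable(3))
  get <- function(s, st, m, col) s[s$structure == st & s$metric == m, col]
  expect_equal(get(s3, "midbrain", "manual_volume", "mean"), 4262.9,
               tolerance = 0.05 / 4262.9)
  expect_equal(get(s3, "midbrain", "dice", "mean"), 0.86, tolerance = 0.006)
  expect_equal(get(s3, "midbrain", "hausdorff", "mean"), 1.71,
               tolerance = 0.006)
  expect_equal(get(s3, "pons", "hausdorff", "mean"), 1.07, tolerance = 0.006)
  expect_equal(get(s3, "pons", "volume_ratio", "mean"), 0.97,
               tolerance = 0.006)
  s4 <- summarizePerformanceTable(readPerformanceTable(4))
  expect_equal(get(s4, "midbrain", "dice", "mean"), 0.884, tolerance = 0.001)
  expect_equal(get(s4, "midbrain", "hausdorff", "mean"), 2.152,
               tolerance = 0.001)
  expect_equal(get(s4, "pons", "dice", "mean"), 0.946, tolerance = 0.001)
  expect_equal(get(s4, "pons", "hausdorff", "sd"), 0.509, tolerance = 0.001)
})

test_that("group t statistics recompute from the printed summaries", {
  pons <- tFromSummary(10693.02, 917.2, 40, 9587.266, 1260.4, 40)
  expect_lt(abs(unname(pons["t"]) - 4.48), 0.01)
  expect_equal(unname(pons["df"]), 78)
  expect_lt(unname(pons["p"]), 0.0001)
  mid <- tFromSummary(4864.21, 492.3, 40, 4461.6, 729.8, 40)
  expect_lt(abs(unname(mid["t"]) - 2.89), 0.01)
})
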