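# Shared fixtures: phantoms are expensive, so they are generated once per
# test run and cached. All fixtures are built in code; nothing is stored on
# disk.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (is.null(.fixtureCache[[key]]))
    assign(key, builder(), envir = .fixtureCache)
  .fixtureCache[[key]]
}

defaultPhantom <- function() {
  cachedFixture("phantom_default", function() brainPhantom())
}

defaultSegmentation <- function() {
  cachedFixture("segmentation_default", function()
    runPipeline(defaultPhantom()$volume))
}

# Dice between a working-grid mask and a truth mask on the truth grid.
gridDice <- function(pred, truth) {
  diceCoefficient(maskOnGrid(pred, dim(truth@data), truth@spacing), truth)
}

# digitized ball mask used by resampling/surface tests
ballMask <- function(r, pad = 3L, spacing = c(1, 1, 1)) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  xs <- seq_len(n)
  d2 <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  BrainMask(d2 <= r^2, spacing = spacing)
}

# smooth blob volume for registration tests
blobVolume <- function(n = 48L, spacing = c(1, 1, 1)) {
  xs <- seq(-1, 1, length.out = n)
  g <- function(c1, c2, c3, s)
    exp(-(outer(outer((xs - c1)^2, (xs - c2)^2, "+"), (xs - c3)^2, "+")) /
          (2 * s^2))
  a <- g(0, 0, 0, 0.45) + 0.6 * g(0.35, 0.2, -0.1, 0.2) +
    0.4 * g(-0.3, -0.25, 0.2, 0.15)
  BrainVolume(a / max(a), spacing = spacing)
}

# brute-force Otsu oracle: exhaustive search over all 256-bin cut points,
# computing class weights and means by direct masking over the histogram-
# quantized intensities (Otsu's criterion is defined on the histogram);
# plateau resolved as the mean of maximizing cut points.
otsuOracle <- function(v, bins = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  edges <- lo + seq_len(bins - 1L) / bins * (hi - lo)
  bin <- floor((v - lo) / (hi - lo) * bins) + 1L
  bin[bin > bins] <- bins
  vq <- lo + (bin - 0.5) / bins * (hi - lo)   # bin-centre values
  sigma <- vapply(seq_len(bins - 1L), function(k) {
    m0 <- bin <= k
    w0 <- mean(m0)
    if (w0 == 0 || w0 == 1) return(-Inf)
    (w0 * (1 - w0)) * (mean(vq[m0]) - mean(vq[!m0]))^2
  }, numeric(1))
  best <- max(sigma)
  mean(edges[sigma >= best - 1e-12 * max(best, 1)])
}

# brute-force modified Hausdorff oracle (double loop)
mhdOracle <- function(A, B, symmetric = TRUE) {
  h <- function(P, Q) {
    tot <- 0
    for (i in seq_len(nrow(P))) {
      dmin <- Inf
      for (j in seq_len(nrow(Q)))
        dmin <- min(dmin, sqrt(sum((P[i, ] - Q[j, ])^2)))
      tot <- tot + dmin
    }
    tot / nrow(P)
  }
  if (symmetric) max(h(A, B), h(B, A)) else h(A, B)
}
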