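# Corrected Otsu thresholding and CLAHE contrast enhancement — the primitive
# operators used by every pipeline stage.

#' Otsu threshold of an intensity image
#'
#' Computes the threshold maximizing the between-class variance over a
#' 256-bin histogram spanning the image intensity range. When several
#' candidate thresholds attain the maximum (a plateau, typical for images
#' with well-separated modes and empty histogram bins in between), the mean
#' of the maximizing candidates is returned, matching the convention of the
#' common reference implementations.
#'
#' @param image numeric vector, matrix or array of intensities.
#' @param bins number of histogram bins (default 256).
#' @return A single threshold on the intensity scale of \code{image}.
#'   Foreground is defined by strict inequality \code{image > t}.
#' @export
#' @examples
#' x <- c(rep(0.1, 50), rep(0.8, 50))
#' t1 <- otsuThreshold(x)  # strictly between the two levels
otsuThreshold <- function(image, bins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsuThreshold: no finite intensities")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("otsuThreshold: constant image, no threshold exists")
  h <- tabulate(pmin(bins, floor((v - lo) / (hi - lo) * bins) + 1L), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  muT <- mu[bins]
  # between-class variance for cuts after bin k (k = 1..bins-1)
  k <- seq_len(bins - 1L)
  w0 <- omega[k]
  sigmaB <- (muT * w0 - mu[k])^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  best <- max(sigmaB)
  kstar <- mean(k[sigmaB >= best - 1e-12 * max(best, 1)])
  lo + kstar / bins * (hi - lo)
}

#' Corrected Otsu threshold
#'
#' The stage thresholds of the pipeline are small multiples of a base Otsu
#' threshold t1: \code{t = factor * t1}, clipped to the image intensity
#' range. When \code{mask} is supplied, t1 is computed over the masked
#' pixels only; the pipeline uses the head-foreground mask so that t1
#' separates gray tissue from bright structures rather than head from air
#' (see the methods vignette).
#'
#' @param image numeric matrix or array.
#' @param factor positive unitless correction factor.
#' @param mask optional logical array selecting the pixels whose histogram
#'   defines the base threshold.
#' @return Threshold value with attributes \code{t1} (base threshold) and
#'   \code{clipped} (TRUE if the corrected value exceeded the intensity
#'   range and was clipped, leaving an empty foreground).
#' @export
correctedThreshold <- function(image, factor, mask = NULL) {
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("correctedThreshold: factor must be a single positive number")
  vals <- if (is.null(mask)) image else image[mask]
  t1 <- otsuThreshold(vals)
  t <- factor * t1
  hi <- max(image[is.finite(image)])
  lo <- min(image[is.finite(image)])
  clipped <- FALSE
  if (t >= hi) { t <- hi; clipped <- TRUE }  # empty foreground under strict >
  if (t < lo) t <- lo
  structure(t, t1 = t1, clipped = clipped)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Local histogram equalization with a normalized clip limit, in the style
#' of the classical adaptive-equalization scheme: the image is divided into
#' a square grid of tiles, each tile's 256-bin histogram is clipped at
#' \code{clip} times the tile pixel count (excess redistributed uniformly),
#' and per-pixel mappings are bilinearly interpolated between the
#' neighbouring tile transforms. Intensities are rescaled to [0, 1] before
#' equalization; a constant image is returned unchanged.
#'
#' @param image numeric matrix (2-D).
#' @param clip normalized contrast-enhancement limit in (0, 1].
#' @param tiles total tile count; must be a perfect square (64 = 8 x 8).
#' @return Equalized image in [0, 1], same dimensions as \code{image}.
#' @export
claheEnhance <- function(image, clip = 0.02, tiles = 64L) {
  if (length(dim(image)) != 2L) stop("claheEnhance: image must be 2-D")
  if (clip <= 0 || clip > 1) stop("claheEnhance: clip must be in (0, 1]")
  ng <- sqrt(tiles)
  if (ng < 1 || ng %% 1 != 0) stop("claheEnhance: tiles must be a perfect square")
  ng <- as.integer(ng)
  lo <- min(image); hi <- max(image)
  if (lo == hi) return(image)
  x <- (image - lo) / (hi - lo)
  nr <- nrow(x); nc <- ncol(x)
  nbins <- 256L
  bin <- floor(x * nbins) + 1L
  bin[bin > nbins] <- nbins

  # tile index ranges (as equal as possible)
  rowBrk <- floor(seq(0, nr, length.out = ng + 1L))
  colBrk <- floor(seq(0, nc, length.out = ng + 1L))
  maps <- array(0, c(nbins, ng, ng))
  ctrR <- numeric(ng); ctrC <- numeric(ng)
  for (i in seq_len(ng)) {
    ri <- (rowBrk[i] + 1L):rowBrk[i + 1L]
    ctrR[i] <- mean(range(ri))
    for (j in seq_len(ng)) {
      cj <- (colBrk[j] + 1L):colBrk[j + 1L]
      if (i == 1L) ctrC[j] <- mean(range(cj))
      h <- tabulate(bin[ri, cj], nbins)
      npix <- length(ri) * length(cj)
      climit <- max(ceiling(npix / nbins), round(clip * npix))
      # clip and redistribute uniformly (few passes suffice)
      for (pass in 1:16) {
        excess <- sum(pmax(h - climit, 0))
        if (excess <= 0) break
        h <- pmin(h, climit)
        h <- h + excess / nbins
      }
      maps[, i, j] <- cumsum(h) / sum(h)
    }
  }

  # bilinear interpolation between tile mappings
  pr <- row(x); pc <- col(x)
  fi <- approx(ctrR, seq_len(ng), xout = as.vector(pr), rule = 2)$y
  fj <- approx(ctrC, seq_len(ng), xout = as.vector(pc), rule = 2)$y
  i0 <- pmax(1L, pmin(ng - 1L, floor(fi))); if (ng == 1L) i0 <- rep(1L, length(fi))
  j0 <- pmax(1L, pmin(ng - 1L, floor(fj))); if (ng == 1L) j0 <- rep(1L, length(fj))
  wi <- pmin(1, pmax(0, fi - i0)); wj <- pmin(1, pmax(0, fj - j0))
  i1 <- pmin(ng, i0 + 1L); j1 <- pmin(ng, j0 + 1L)
  b <- as.vector(bin)
  g <- function(ii, jj) maps[cbind(b, ii, jj)]
  out <- (1 - wi) * (1 - wj) * g(i0, j0) + (1 - wi) * wj * g(i0, j1) +
    wi * (1 - wj) * g(i1, j0) + wi * wj * g(i1, j1)
  matrix(out, nr, nc)
}

#' Binarize an image at a threshold
#'
#' Foreground is \code{image > t} (strict inequality).
#'
#' @param image numeric matrix or array.
#' @param t threshold value.
#' @param spacing,origin optional geometry carried into the mask.
#' @return A \code{\link{BrainMask}}.
#' @export
binarize <- function(image, t, spacing = rep(1, length(dim(image))),
                     origin = rep(0, length(dim(image)))) {
  m <- image > as.numeric(t)
  BrainMask(array(m, dim(image)), spacing = spacing, origin = origin)
}

#' @importFrom stats approx
NULL
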