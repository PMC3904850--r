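# Evaluation metrics: Dice overlap, absolute volume difference, modified
# Hausdorff distance, volume ratios, summary statistics, and the
# group-comparison statistics used for cohort reporting.

#' Dice coefficient
#'
#' 2 V(A intersect B) / (V(A) + V(B)); ranges from 0 (no overlap) to 1
#' (perfect agreement). Two empty masks compare as 1 with a warning, so
#' batch evaluation stays total.
#'
#' @param A,B \code{\link{BrainMask}} objects (or logical arrays) on the
#'   same grid.
#' @return Dice coefficient in [0, 1].
#' @export
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2))
#' diceCoefficient(a, b)  # 0.5
diceCoefficient <- function(A, B) {
  a <- if (is(A, "BrainMask")) A@data else A
  b <- if (is(B, "BrainMask")) B@data else B
  if (!identical(dim(a), dim(b)))
    stop("diceCoefficient: geometry mismatch")
  va <- sum(a); vb <- sum(b)
  if (va + vb == 0) {
    warning("diceCoefficient: both masks empty; defined as 1")
    return(1)
  }
  2 * sum(a & b) / (va + vb)
}

#' Absolute volume difference (percent)
#'
#' 100 |V(gold) - V(auto)| / V(gold), volumes in mm^3. The absolute value
#' accounts for segmentations both smaller and larger than the gold
#' standard.
#'
#' @param gold gold-standard \code{\link{BrainMask}} (non-empty).
#' @param auto evaluated \code{\link{BrainMask}}.
#' @param spacing voxel spacing; taken from the masks when omitted.
#' @return AVD in percent (>= 0).
#' @export
absoluteVolumeDifference <- function(gold, auto, spacing = NULL) {
  vg <- computeVolume(gold, spacing)
  va <- computeVolume(auto, spacing)
  if (vg == 0) stop("absoluteVolumeDifference: empty gold standard")
  100 * abs(vg - va) / vg
}

#' Volume ratio V(auto) / V(manual)
#'
#' @param auto,manual \code{\link{BrainMask}} objects (manual non-empty), or
#'   plain volumes in mm^3 when \code{numeric}.
#' @param spacing voxel spacing for mask inputs.
#' @return Unitless ratio.
#' @export
volumeRatio <- function(auto, manual, spacing = NULL) {
  va <- if (is.numeric(auto) && is.null(dim(auto))) auto else
    computeVolume(auto, spacing)
  vm <- if (is.numeric(manual) && is.null(dim(manual))) manual else
    computeVolume(manual, spacing)
  if (vm == 0) stop("volumeRatio: empty manual reference")
  va / vm
}

# Boundary voxels of a mask: foreground with at least one face-adjacent
# background neighbour (or on the array edge). Returns mm coordinates.
.boundaryPoints <- function(mask) {
  m <- if (is(mask, "BrainMask")) mask@data else mask
  sp <- if (is(mask, "BrainMask")) mask@spacing else rep(1, length(dim(m)))
  or <- if (is(mask, "BrainMask")) mask@origin else rep(0, length(dim(m)))
  d <- dim(m)
  nd <- length(d)
  interior <- array(TRUE, d)
  idx <- function(axis, rng) {
    args <- rep(list(quote(expr = )), nd)
    args[[axis]] <- rng
    args
  }
  shiftAnd <- function(acc, axis, s) {
    n <- d[axis]
    res <- array(FALSE, d)
    src <- if (s > 0) 1:(n - s) else (1 - s):n
    dst <- if (s > 0) (1 + s):n else 1:(n + s)
    if (nd == 2L) res[idx(axis, dst)[[1]], idx(axis, dst)[[2]]] <-
        m[idx(axis, src)[[1]], idx(axis, src)[[2]]]
    else res[idx(axis, dst)[[1]], idx(axis, dst)[[2]], idx(axis, dst)[[3]]] <-
        m[idx(axis, src)[[1]], idx(axis, src)[[2]], idx(axis, src)[[3]]]
    acc & res
  }
  for (axis in seq_len(nd)) {
    interior <- shiftAnd(interior, axis, 1L)
    interior <- shiftAnd(interior, axis, -1L)
  }
  bnd <- m & !interior
  pts <- which(bnd, arr.ind = TRUE)
  sweep(sweep(pts - 1, 2, sp[seq_len(nd)], "*"), 2, or[seq_len(nd)], "+")
}

#' Modified Hausdorff distance (Dubuisson-Jain)
#'
#' Symmetric form \code{max(h(A,B), h(B,A))} with
#' \code{h(A,B) = mean over a in A of min over b in B of |a - b|}. Mask
#' inputs are reduced to their boundary voxels in mm; point-matrix inputs
#' (n x d) are used as-is. The one-directional variant \code{h(A,B)} is
#' available via \code{symmetric = FALSE}.
#'
#' @param A,B \code{\link{BrainMask}} objects or point matrices (non-empty).
#' @param symmetric return the symmetric max (default) or the directed
#'   distance h(A, B).
#' @param max_points cap on boundary points per set; larger sets are
#'   deterministically strided down (exact below the cap).
#' @return Distance in mm (grid units for unit spacing).
#' @export
modifiedHausdorff <- function(A, B, symmetric = TRUE, max_points = 6000L) {
  pts <- function(x) {
    p <- if (is.matrix(x) && !is.logical(x)) x else .boundaryPoints(x)
    if (nrow(p) == 0) stop("modifiedHausdorff: empty point set")
    if (nrow(p) > max_points)
      p <- p[seq(1L, nrow(p), length.out = max_points), , drop = FALSE]
    p
  }
  a <- pts(A); b <- pts(B)
  directed <- function(p, q) {
    # chunked nearest-neighbour distances
    qsq <- rowSums(q^2)
    tot <- 0
    step <- max(1L, floor(2e7 / nrow(q)))
    for (i0 in seq(1L, nrow(p), by = step)) {
      ii <- i0:min(nrow(p), i0 + step - 1L)
      pp <- p[ii, , drop = FALSE]
      d2 <- outer(rowSums(pp^2), qsq, "+") - 2 * pp %*% t(q)
      tot <- tot + sum(sqrt(pmax(0, apply(d2, 1, min))))
    }
    tot / nrow(p)
  }
  hab <- directed(a, b)
  if (!symmetric) return(hab)
  max(hab, directed(b, a))
}

#' Resample a mask onto a reference grid
#'
#' Maps each foreground voxel centre to its nearest reference voxel. With
#' \code{method = "majority"} (default) a reference voxel becomes foreground
#' when at least half of the fine voxels mapping into it are foreground —
#' the unbiased choice when moving a fine working-grid segmentation onto a
#' coarser acquisition grid for evaluation. \code{method = "any"} marks a
#' reference voxel on any hit.
#'
#' @param mask a \code{\link{BrainMask}} (3-D).
#' @param dims,spacing,origin geometry of the reference grid.
#' @param method \code{"majority"} or \code{"any"}.
#' @return A \code{\link{BrainMask}} on the reference grid.
#' @export
maskOnGrid <- function(mask, dims, spacing, origin = c(0, 0, 0),
                       method = c("majority", "any")) {
  method <- match.arg(method)
  d <- dim(mask@data)
  idx <- which(mask@data, arr.ind = TRUE)
  out <- array(FALSE, dims)
  if (nrow(idx)) {
    mm <- sweep(sweep(idx - 1, 2, mask@spacing, "*"), 2, mask@origin, "+")
    # floor(x + 0.5): round() half-to-even would map cells unevenly
    gi <- floor(sweep(sweep(mm, 2, origin, "-"), 2, spacing, "/") + 0.5) + 1
    ok <- gi[, 1] >= 1 & gi[, 1] <= dims[1] & gi[, 2] >= 1 &
      gi[, 2] <= dims[2] & gi[, 3] >= 1 & gi[, 3] <= dims[3]
    gi <- gi[ok, , drop = FALSE]
    lin <- gi[, 1] + (gi[, 2] - 1) * dims[1] + (gi[, 3] - 1) * dims[1] * dims[2]
    if (method == "any") {
      out[unique(lin)] <- TRUE
    } else {
      counts <- tabulate(lin, prod(dims))
      perCell <- prod(spacing / mask@spacing)
      out[counts >= perCell / 2] <- TRUE
    }
  }
  BrainMask(out, spacing = spacing, origin = origin)
}

#' Full metric report for one structure
#'
#' @param pred predicted \code{\link{BrainMask}}.
#' @param gold gold-standard \code{\link{BrainMask}} on the same grid.
#' @return One-row data.frame: dice, avd_pct, mhd_mm, volume_ratio,
#'   vol_pred_mm3, vol_gold_mm3.
#' @export
evaluateSegmentation <- function(pred, gold) {
  data.frame(
    dice = diceCoefficient(pred, gold),
    avd_pct = absoluteVolumeDifference(gold, pred),
    mhd_mm = modifiedHausdorff(pred, gold),
    volume_ratio = volumeRatio(pred, gold),
    vol_pred_mm3 = computeVolume(pred),
    vol_gold_mm3 = computeVolume(gold))
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector (>= 2 values for the sd).
#' @return Named numeric: \code{mean} and \code{sd} (n-1 denominator).
#' @export
summarizeMetrics <- function(values) {
  if (!length(values)) stop("summarizeMetrics: empty input")
  c(mean = mean(values),
    sd = if (length(values) >= 2) sd(values) else NA_real_)
}

#' Unpaired t statistic from group summaries
#'
#' Pooled-variance two-sample t test recomputed from printed summary
#' statistics (means, SDs and group sizes); a Welch variant is available.
#'
#' @param m1,s1,n1 mean, sd and size of group 1.
#' @param m2,s2,n2 mean, sd and size of group 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return Named numeric: \code{t}, \code{df}, \code{p} (two-sided).
#' @export
#' @examples
#' tFromSummary(10693.02, 917.2, 40, 9587.266, 1260.4, 40)  # t ~ 4.48
tFromSummary <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("tFromSummary: need n >= 2 per group")
  if (s1 < 0 || s2 < 0) stop("tFromSummary: negative sd")
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0 && m1 != m2)
      stop("tFromSummary: zero pooled variance with unequal means")
    t <- if (m1 == m2) 0 else (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return Sample Pearson correlation in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearsonCorrelation: need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearsonCorrelation: constant input")
  cor(x, y)
}
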