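# 2-D connected-component labeling with selectable 4/8 connectivity, and the
# component-selection rules used by the pipeline.

#' Connected components of a 2-D mask
#'
#' Labels the foreground of a 2-D mask under 4- or 8-connectivity using
#' run-based union-find. Component sizes always partition the foreground
#' (sizes sum to the foreground pixel count).
#'
#' @param mask logical matrix or 2-D \code{\link{BrainMask}}.
#' @param connectivity 4 or 8 (the pipeline uses 8 throughout, following the
#'   eight-pixel neighbourhood of the original method).
#' @return List with \code{labels} (integer matrix, 0 = background),
#'   \code{sizes} (pixel counts per component), \code{centroids}
#'   (n x 2 matrix of mean (row, col) positions) and \code{n} components.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
#' connectedComponents(m, 8)$n  # 1
#' connectedComponents(m, 4)$n  # 2
connectedComponents <- function(mask, connectivity = 8L) {
  if (is(mask, "BrainMask")) mask <- mask@data
  if (length(dim(mask)) != 2L) stop("connectedComponents: mask must be 2-D")
  if (!connectivity %in% c(4L, 8L))
    stop("connectedComponents: connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (!any(mask)) {
    return(list(labels = labels, sizes = integer(0),
                centroids = matrix(numeric(0), 0, 2), n = 0L))
  }
  # vertical runs per column
  up <- rbind(FALSE, mask[-nr, , drop = FALSE])
  starts <- mask & !up
  runId <- matrix(0L, nr, nc)
  runId[mask] <- cumsum(starts)[mask]
  nRuns <- max(runId)
  idx <- which(starts)
  runStartRow <- ((idx - 1L) %% nr) + 1L
  runCol <- ((idx - 1L) %/% nr) + 1L
  runLen <- tabulate(runId[mask], nRuns)
  runEndRow <- runStartRow + runLen - 1L

  # merge runs in adjacent columns whose row spans touch
  slack <- if (connectivity == 8L) 1L else 0L
  merges <- vector("list", nc)
  runsInCol <- split(seq_len(nRuns), runCol)
  for (j in seq_len(nc - 1L)) {
    a <- runsInCol[[as.character(j)]]
    b <- runsInCol[[as.character(j + 1L)]]
    if (is.null(a) || is.null(b)) next
    pairs <- NULL
    for (ra in a) {
      hit <- b[runStartRow[b] <= runEndRow[ra] + slack &
                 runEndRow[b] >= runStartRow[ra] - slack]
      if (length(hit)) pairs <- rbind(pairs, cbind(ra, hit))
    }
    merges[[j]] <- pairs
  }
  merges <- do.call(rbind, merges)
  root <- unionFind(nRuns, merges)
  lab <- match(root, sort(unique(root)))  # compact labels 1..n
  labels[mask] <- lab[runId[mask]]

  n <- max(lab)
  fg <- which(mask)
  lv <- labels[fg]
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  sizes <- tabulate(lv, n)
  centroids <- cbind(
    row = as.numeric(tapply(rows, lv, mean)),
    col = as.numeric(tapply(cols, lv, mean))
  )
  list(labels = labels, sizes = sizes, centroids = centroids, n = n)
}

#' Select one connected component
#'
#' Selection rules used by the pipeline:
#' \describe{
#'   \item{\code{largest}}{maximal pixel count; ties broken by smaller
#'     centroid distance to the image centre, then by lowest label.}
#'   \item{\code{largest-near}}{among components whose centroid lies within
#'     \code{radius} of \code{point}, the largest (the "biggest connected
#'     component positioned closer to the gravity centre" rule).}
#'   \item{\code{centroid-nearest}}{minimal centroid distance to
#'     \code{point}; ties broken by larger size.}
#' }
#'
#' @param comps result of \code{\link{connectedComponents}}.
#' @param rule one of \code{"largest"}, \code{"largest-near"},
#'   \code{"centroid-nearest"}.
#' @param point numeric(2) (row, col) reference point for proximity rules.
#' @param radius search radius in pixels for \code{"largest-near"}.
#' @return Logical matrix of the selected component, with attribute
#'   \code{label}.
#' @export
selectComponent <- function(comps, rule = c("largest", "largest-near",
                                            "centroid-nearest"),
                            point = NULL, radius = NULL) {
  rule <- match.arg(rule)
  if (comps$n == 0L)
    stop("selectComponent: no components (rule '", rule, "')")
  dists <- NULL
  if (rule != "largest") {
    if (is.null(point) || length(point) != 2L)
      stop("selectComponent: rule '", rule, "' needs a (row, col) point")
    dists <- sqrt((comps$centroids[, 1] - point[1])^2 +
                    (comps$centroids[, 2] - point[2])^2)
  }
  lab <- switch(rule,
    largest = {
      ctr <- c((nrow(comps$labels) + 1) / 2, (ncol(comps$labels) + 1) / 2)
      dc <- sqrt((comps$centroids[, 1] - ctr[1])^2 +
                   (comps$centroids[, 2] - ctr[2])^2)
      ord <- order(-comps$sizes, dc, seq_len(comps$n))
      ord[1]
    },
    `largest-near` = {
      if (is.null(radius) || radius <= 0)
        stop("selectComponent: largest-near needs a positive radius")
      ok <- which(dists <= radius)
      if (!length(ok))
        stop("selectComponent: no component within radius ", radius,
             " of the reference point (rule 'largest-near')")
      ok[order(-comps$sizes[ok], dists[ok])][1]
    },
    `centroid-nearest` = {
      ord <- order(dists, -comps$sizes)
      ord[1]
    })
  structure(comps$labels == lab, label = lab)
}
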