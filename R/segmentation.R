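#' Local image entropy
#'
#' Shannon entropy (bits) of the binned intensity histogram in the window
#' centered at each pixel. Entropy measures the heterogeneity of intensity
#' values in the neighborhood of a pixel: textured cell tissue produces high
#' local entropy while smooth background produces low entropy, which makes it
#' a robust coarse cell detector even for strongly spread-out, low-contrast
#' cells. Borders are handled by reflection padding.
#'
#' @param frame an [ImageFrame-class] (or a numeric matrix in [0, 1]).
#' @param window odd window side length in px (>= 3).
#' @param nBins number of intensity histogram bins (>= 2) over [0, 1].
#' @return numeric matrix of entropies (bits), same shape as the input.
#' @examples
#' f <- imageFrame(matrix(rep(c(0, 1), 50), 10, 10))  # checkerboard columns
#' e <- localEntropy(f, window = 3, nBins = 2)
#' @seealso [coarseRegionMask()], [segmentFrame()]
#' @export
localEntropy <- function(frame, window = 9L, nBins = 16L) {
  I <- if (is(frame, "ImageFrame")) pixels(frame) else frame
  window <- as.integer(window); nBins <- as.integer(nBins)
  if (window %% 2L != 1L || window < 3L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  if (nBins < 2L) stop("'nBins' must be >= 2", call. = FALSE)
  if (window > nrow(I) || window > ncol(I))
    stop("window larger than image dimensions", call. = FALSE)
  bins <- pmin(floor(I * nBins) + 1L, nBins)
  n <- window * window
  ent <- matrix(0, nrow(I), ncol(I))
  for (k in sort(unique(as.vector(bins)))) {
    cnt <- boxSum((bins == k) * 1, window)
    p <- cnt / n
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

#' Coarse cell-region segmentation of an entropy map
#'
#' Thresholds a local-entropy map into a binary cell-region mask, then cleans
#' it up morphologically: closing with a disc to bridge intra-cell entropy
#' gaps, hole filling, and removal of components below an area floor.
#'
#' With \code{method = "otsu"} the threshold is Otsu's on the entropy map,
#' floored at \code{minEntropy} so that featureless background (whose entropy
#' never reaches cell-texture levels) yields an empty mask; a degenerate
#' all-equal map also yields an empty mask. With \code{method = "fixed"} the
#' supplied \code{threshold} is used directly (strictly-greater comparison).
#'
#' @param entropyMap numeric matrix of local entropies (bits), values >= 0.
#' @param method "otsu" or "fixed".
#' @param threshold fixed threshold in bits (only for \code{method =
#'   "fixed"}).
#' @param minEntropy floor (bits) under the automatic threshold.
#' @param closeRadius radius (px) of the closing disc; 0 disables.
#' @param minArea minimum component area (px).
#' @param fillHoles fill enclosed holes in the mask.
#' @return logical matrix marking cell-region pixels.
#' @seealso [localEntropy()], [segmentFrame()]
#' @export
coarseRegionMask <- function(entropyMap, method = c("otsu", "fixed"),
                             threshold = NA_real_, minEntropy = 1.5,
                             closeRadius = 5L, minArea = 100L,
                             fillHoles = TRUE) {
  method <- match.arg(method)
  if (min(entropyMap) < 0) stop("entropy values must be >= 0", call. = FALSE)
  if (method == "fixed") {
    if (is.na(threshold)) stop("'threshold' required for method 'fixed'")
    t <- threshold
  } else {
    rng <- range(entropyMap)
    if (rng[2] <= rng[1]) return(matrix(FALSE, nrow(entropyMap), ncol(entropyMap)))
    t <- max(EBImage::otsu(entropyMap / rng[2], range = c(0, 1)) * rng[2],
             minEntropy)
  }
  mask <- entropyMap > t
  if (!any(mask)) return(mask)
  if (closeRadius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(closeRadius) + 1L, "disc")
    mask <- as.matrix(EBImage::closing(mask * 1, brush)) > 0
  }
  if (fillHoles) mask <- as.matrix(EBImage::fillHull(mask * 1)) > 0
  if (minArea > 0L) {
    lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
    keep <- which(tabulate(lab[lab > 0L]) >= minArea)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Cell-detail segmentation by local intensity thresholding
#'
#' Marks pixels whose intensity deviates from the mean of the surrounding
#' window by more than \code{offset}. Comparing against the local mean makes
#' the detector robust to illumination gradients across the image; the
#' two-sided comparison captures both the bright and the dark shear lobes
#' that cells show in DIC images. Borders use reflection padding.
#'
#' @param frame an [ImageFrame-class] (or numeric matrix).
#' @param window odd local-mean window side length in px (>= 3).
#' @param offset minimum absolute intensity deviation from the local mean.
#' @return logical matrix marking cell-detail pixels.
#' @seealso [extractCentroids()], [segmentFrame()]
#' @export
detailMask <- function(frame, window = 15L, offset = 0.05) {
  I <- if (is(frame, "ImageFrame")) pixels(frame) else frame
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 3L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  if (window > nrow(I) || window > ncol(I))
    stop("window larger than image dimensions", call. = FALSE)
  localMean <- boxSum(I, window) / (window * window)
  abs(I - localMean) > offset
}

#' Extract component centroids from a binary mask
#'
#' One centroid per 8-connected component: the arithmetic mean of the member
#' pixel coordinates (sub-pixel, 0-based, x = column, y = row). Components
#' smaller than \code{minArea} pixels are discarded as noise.
#'
#' @param mask logical (or 0/1) matrix.
#' @param frameIndex 0-based frame index recorded on the result.
#' @param minArea minimum component area in px.
#' @return a [CentroidSet-class].
#' @examples
#' m <- matrix(FALSE, 12, 16); m[5:7, 11:13] <- TRUE
#' centroids(extractCentroids(m))  # x = 11, y = 5
#' @export
extractCentroids <- function(mask, frameIndex = 0L, minArea = 5L) {
  mask <- mask > 0
  if (!any(mask)) return(centroidSet(frameIndex = frameIndex))
  comp <- labelCentroids(labelMask8(mask))
  comp <- comp[comp$area >= minArea, , drop = FALSE]
  centroidSet(cbind(x = comp$x, y = comp$y), frameIndex = frameIndex)
}

#' Propagate centroids from the previous frame and filter by cell regions
#'
#' Combines the current frame's detail centroids with the centroids of one
#' past frame, so that a cell missed by the detail segmentation in a single
#' frame is carried forward and centroids propagate steadily through the
#' sequence. Every candidate that does not fall on a cell-region pixel is
#' then deleted, which removes both stale propagated positions and detections
#' in non-cell regions.
#'
#' @param current [CentroidSet-class] of the current frame.
#' @param previous [CentroidSet-class] of the previous processed frame (may
#'   be empty for the first frame).
#' @param region logical cell-region mask of the current frame.
#' @return a [CentroidSet-class] with the current frame's index.
#' @seealso [coarseRegionMask()], [mergeAndShift()]
#' @export
propagateAndFilter <- function(current, previous, region) {
  if (!is.matrix(region))
    stop("'region' must be a matrix mask", call. = FALSE)
  pts <- rbind(centroids(current), centroids(previous))
  if (nrow(pts) == 0L)
    return(centroidSet(frameIndex = frameIndex(current)))
  col <- round(pts[, 1]) + 1L
  row <- round(pts[, 2]) + 1L
  inside <- row >= 1L & row <= nrow(region) & col >= 1L & col <= ncol(region)
  keep <- inside
  idx <- which(inside)
  keep[idx] <- region[cbind(row[idx], col[idx])]
  centroidSet(pts[keep, , drop = FALSE], frameIndex = frameIndex(current))
}

#' Merge groups of candidate centroids within one cell
#'
#' Clusters candidate centroids by single linkage: points whose mutual
#' distance is at most \code{mergeRadius} end up in one cluster, and each
#' cluster is replaced by its coordinate mean ("shifting"). Clustering is
#' repeated on the cluster means until no two output points are within the
#' merge radius, so the result is idempotent and satisfies the minimum
#' distance guarantee.
#'
#' @param candidates a [CentroidSet-class].
#' @param mergeRadius merge distance in px (> 0).
#' @return a [CentroidSet-class] whose points are pairwise farther apart than
#'   \code{mergeRadius}.
#' @examples
#' cs <- centroidSet(cbind(x = c(0, 2), y = c(0, 0)))
#' centroids(mergeAndShift(cs, 10))  # midpoint (1, 0)
#' @export
mergeAndShift <- function(candidates, mergeRadius = 20) {
  if (mergeRadius <= 0) stop("'mergeRadius' must be > 0", call. = FALSE)
  pts <- centroids(candidates)
  while (nrow(pts) > 1L) {
    hc <- stats::hclust(stats::dist(pts), method = "single")
    cl <- stats::cutree(hc, h = mergeRadius)
    if (max(cl) == nrow(pts)) break
    pts <- cbind(x = as.numeric(rowsum(pts[, 1], cl) / tabulate(cl)),
                 y = as.numeric(rowsum(pts[, 2], cl) / tabulate(cl)))
  }
  centroidSet(pts, frameIndex = frameIndex(candidates))
}

#' Segment one frame into cell centroids
#'
#' Full per-frame centroid extraction: the frame is processed in two
#' independent branches — cell-region segmentation ([localEntropy()] followed
#' by [coarseRegionMask()]) and cell-detail segmentation ([detailMask()]
#' followed by [extractCentroids()]). The detail centroids are combined with
#' the centroids of one past frame and filtered by the region mask
#' ([propagateAndFilter()]), and finally consolidated so that each cell
#' carries a single centroid ([mergeAndShift()]).
#'
#' @param frame an [ImageFrame-class].
#' @param previous [CentroidSet-class] of the previous processed frame, or
#'   NULL/empty for the first frame.
#' @param config configuration list from [trackingConfig()].
#' @return a [CentroidSet-class] for the frame.
#' @seealso [segmentSequence()], [trackSequence()]
#' @export
segmentFrame <- function(frame, previous = NULL, config = trackingConfig()) {
  stopifnot(is(frame, "ImageFrame"))
  if (is.null(previous)) previous <- centroidSet(frameIndex = frameIndex(frame))
  ent <- localEntropy(frame, config$entropyWindow, config$entropyBins)
  region <- coarseRegionMask(ent, method = config$regionMethod,
                             threshold = config$regionThreshold,
                             minEntropy = config$minRegionEntropy,
                             closeRadius = config$closeRadius,
                             minArea = config$minRegionArea)
  detail <- detailMask(frame, config$detailWindow, config$detailOffset)
  cand <- extractCentroids(detail, frameIndex = frameIndex(frame),
                           minArea = config$minDetailArea)
  cand <- propagateAndFilter(cand, previous, region)
  mergeAndShift(cand, config$mergeRadius)
}

#' Segment an image sequence
#'
#' Runs [segmentFrame()] over a list of frames in order, feeding each frame's
#' result to the next as the propagation source.
#'
#' @param frames list of [ImageFrame-class] objects (forward frame order).
#' @param config configuration list from [trackingConfig()].
#' @param verbose print per-frame progress messages.
#' @return list of [CentroidSet-class] objects, one per frame.
#' @export
segmentSequence <- function(frames, config = trackingConfig(),
                            verbose = FALSE) {
  if (length(frames) == 0L) stop("no frames supplied", call. = FALSE)
  out <- vector("list", length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    out[[i]] <- segmentFrame(frames[[i]], prev, config)
    prev <- out[[i]]
    if (verbose)
      message("frame ", frameIndex(frames[[i]]), ": ",
              nCentroids(out[[i]]), " centroids")
  }
  out
}
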