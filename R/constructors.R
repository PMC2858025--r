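#' Create an ImageFrame
#'
#' Wraps a numeric intensity matrix as an [ImageFrame-class]. Intensities
#' outside [0, 1] are an error unless \code{normalize = TRUE}, in which case
#' the matrix is rescaled to span [0, 1] (a constant image maps to all zeros).
#'
#' @param pixels numeric matrix; rows are image rows (y), columns are image
#'   columns (x).
#' @param pixelSize pixel pitch in um/px (default 1.5, the DIC acquisition
#'   pitch assumed throughout).
#' @param frameIndex 0-based frame index.
#' @param normalize rescale intensities to [0, 1] first.
#' @return an [ImageFrame-class] object.
#' @examples
#' f <- imageFrame(matrix(runif(100), 10, 10))
#' frameHeight(f); frameWidth(f)
#' @export
imageFrame <- function(pixels, pixelSize = 1.5, frameIndex = 0L,
                       normalize = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (normalize) {
    rng <- range(pixels, finite = TRUE)
    pixels <- if (rng[2] > rng[1])
      (pixels - rng[1]) / (rng[2] - rng[1]) else pixels * 0
  }
  new("ImageFrame", pixels = pixels, pixelSize = as.numeric(pixelSize),
      frameIndex = as.integer(frameIndex))
}

#' Create a CentroidSet
#'
#' @param points numeric matrix (or 2-column object coercible to one) with
#'   columns x, y in pixels; 0-based coordinates, x = column, y = row.
#' @param frameIndex 0-based frame index.
#' @return a [CentroidSet-class] object.
#' @examples
#' centroidSet(cbind(x = c(10, 40), y = c(5, 22)), frameIndex = 0)
#' @export
centroidSet <- function(points = matrix(numeric(0), 0, 2), frameIndex = 0L) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 2L)
  if (ncol(points) != 2L)
    stop("'points' must have two columns (x, y)", call. = FALSE)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  new("CentroidSet", frameIndex = as.integer(frameIndex), points = points)
}

#' Create a Track
#'
#' @param id integer track id.
#' @param points data.frame with columns frame, x, y (or a matrix with x, y
#'   and implied frames 0..n-1).
#' @param status lifecycle status (see [Track-class]).
#' @param events optional event-log data.frame (kind, frame, detail).
#' @param kf optional [KFState-class].
#' @param missingCount consecutive missing-measurement counter.
#' @return a [Track-class] object.
#' @examples
#' tr <- track(1, cbind(x = c(0, 3, 3), y = c(0, 4, 4)))
#' meanDisplacement(tr)
#' @export
track <- function(id, points, status = "completed",
                  events = data.frame(kind = character(0),
                                      frame = integer(0),
                                      detail = character(0)),
                  kf = NULL, missingCount = 0L) {
  if (is.matrix(points)) {
    points <- data.frame(frame = seq_len(nrow(points)) - 1L,
                         x = points[, 1], y = points[, 2])
  }
  points <- as.data.frame(points)[, c("frame", "x", "y")]
  points$frame <- as.integer(points$frame)
  points <- points[order(points$frame), , drop = FALSE]
  rownames(points) <- NULL
  new("Track", id = as.integer(id), points = points, status = status,
      missingCount = as.integer(missingCount), events = events, kf = kf)
}

emptyEvents <- function() {
  data.frame(kind = character(0), frame = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}
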