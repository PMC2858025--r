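#' @import methods
NULL

#' ImageFrame: one normalized grayscale frame
#'
#' A single grayscale microscopy frame with its pixel pitch and position in
#' the sequence. Intensities are stored normalized to [0, 1]; integer images
#' read from disk are rescaled by the readers (see [readSequence()]).
#'
#' @slot pixels numeric matrix of intensities in [0, 1]; rows are image rows
#'   (y), columns are image columns (x).
#' @slot pixelSize physical pixel pitch in micrometers per pixel.
#' @slot frameIndex 0-based index of the frame within its sequence.
#'
#' @seealso [imageFrame()], [segmentFrame()]
#' @export
setClass("ImageFrame",
  representation(pixels = "matrix", pixelSize = "numeric",
                 frameIndex = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p) || length(dim(p)) != 2L)
      return("'pixels' must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L)
      return("frame must have positive height and width")
    if (anyNA(p) || min(p) < 0 || max(p) > 1)
      return("intensities must lie in [0, 1] (normalize on input)")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("'pixelSize' must be a single positive number")
    if (length(object@frameIndex) != 1L || object@frameIndex < 0L)
      return("'frameIndex' must be a single non-negative integer")
    TRUE
  })

#' CentroidSet: candidate cell centers for one frame
#'
#' Extracted cell centroids for one frame, in pixel coordinates. Coordinates
#' are 0-based with x = column and y = row, origin at the top-left corner;
#' centroids are real-valued (sub-pixel).
#'
#' @slot frameIndex 0-based frame index the centroids belong to.
#' @slot points numeric matrix with columns \code{x} and \code{y} (pixels),
#'   one row per centroid. May have zero rows.
#'
#' @seealso [centroidSet()], [extractCentroids()], [mergeAndShift()]
#' @export
setClass("CentroidSet",
  representation(frameIndex = "integer", points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2L) return("'points' must have two columns (x, y)")
    if (nrow(p) > 0L && (anyNA(p) || any(!is.finite(p))))
      return("centroid coordinates must be finite")
    if (length(object@frameIndex) != 1L)
      return("'frameIndex' must be a single integer")
    TRUE
  })

#' MotionModel: constant-velocity Kalman filter model
#'
#' The matrices of the discrete constant-velocity motion model used for
#' tracking. The state is (x, y, vx, vy) with positions in pixels and
#' velocities in pixels per frame; one time step is one frame.
#'
#' @slot A 4x4 state transition matrix mapping
#'   (x, y, vx, vy) to (x + vx, y + vy, vx, vy).
#' @slot H 2x4 observation matrix extracting the position.
#' @slot Q 4x4 symmetric positive semi-definite process-noise covariance.
#' @slot R 2x2 symmetric positive semi-definite measurement-noise covariance
#'   (pixels squared).
#'
#' @seealso [motionModel()], [kfPredict()], [kfCorrect()]
#' @export
setClass("MotionModel",
  representation(A = "matrix", H = "matrix", Q = "matrix", R = "matrix"),
  validity = function(object) {
    if (!all(dim(object@A) == c(4L, 4L))) return("'A' must be 4x4")
    if (!all(dim(object@H) == c(2L, 4L))) return("'H' must be 2x4")
    if (!all(dim(object@Q) == c(4L, 4L))) return("'Q' must be 4x4")
    if (!all(dim(object@R) == c(2L, 2L))) return("'R' must be 2x2")
    if (!isTRUE(all.equal(object@Q, t(object@Q), tolerance = 1e-8)))
      return("'Q' must be symmetric")
    if (!isTRUE(all.equal(object@R, t(object@R), tolerance = 1e-8)))
      return("'R' must be symmetric")
    if (min(eigen(object@Q, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-9)
      return("'Q' must be positive semi-definite")
    if (min(eigen(object@R, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-9)
      return("'R' must be positive semi-definite")
    TRUE
  })

#' KFState: Kalman filter state for one track
#'
#' State estimate of one tracked cell: position and velocity, the state
#' covariance, and the gain used in the most recent correction step.
#'
#' @slot x numeric length-4 state vector (x, y, vx, vy); positions in px,
#'   velocities in px/frame.
#' @slot P 4x4 symmetric positive semi-definite state covariance.
#' @slot K 4x2 Kalman gain from the last correction (zeros before the first).
#'
#' @seealso [kfInit()], [kfPredict()], [kfCorrect()]
#' @export
setClass("KFState",
  representation(x = "numeric", P = "matrix", K = "matrix"),
  validity = function(object) {
    if (length(object@x) != 4L) return("'x' must have length 4")
    if (!all(dim(object@P) == c(4L, 4L))) return("'P' must be 4x4")
    if (!all(dim(object@K) == c(4L, 2L))) return("'K' must be 4x2")
    if (!isTRUE(all.equal(object@P, t(object@P), tolerance = 1e-6)))
      return("'P' must be symmetric")
    if (min(eigen(object@P, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-9)
      return("'P' must be positive semi-definite")
    TRUE
  })

#' Track: one cell's path through the sequence
#'
#' Ordered positions of one cell across frames, together with its lifecycle
#' status and the event log produced by the monitoring module. Positions are
#' pixel coordinates (0-based, x = column, y = row). In a finalized track the
#' frame indices are contiguous; frames in which the measurement was missing
#' hold the coasted (last determined) position.
#'
#' Status values: \code{active} (still being tracked), \code{completed}
#' (reached the first video frame), \code{terminated_lost} (measurement
#' missing too often away from the border), \code{left_view} (lost near the
#' border), \code{merged_mitosis} (merged into a partner track during
#' backward tracking, i.e. a cell division).
#'
#' @slot id integer track identifier.
#' @slot points data.frame with columns \code{frame}, \code{x}, \code{y},
#'   at most one row per frame, sorted by frame.
#' @slot status character, one of the values above.
#' @slot missingCount integer, current number of consecutive missing
#'   measurements.
#' @slot events data.frame with columns \code{kind}, \code{frame},
#'   \code{detail} logging monitoring decisions.
#' @slot kf the track's [KFState-class], or NULL for tracks not produced by
#'   the tracking engine (e.g. manual or synthetic tracks).
#'
#' @seealso [track()], [trackSequence()], [meanDisplacement()]
#' @export
setClass("Track",
  representation(id = "integer", points = "data.frame", status = "character",
                 missingCount = "integer", events = "data.frame", kf = "ANY"),
  validity = function(object) {
    pts <- object@points
    if (!all(c("frame", "x", "y") %in% names(pts)))
      return("'points' needs columns frame, x, y")
    if (anyDuplicated(pts$frame))
      return("at most one point per frame index")
    if (is.unsorted(pts$frame))
      return("'points' must be sorted by frame")
    ok <- c("active", "completed", "terminated_lost", "left_view",
            "merged_mitosis")
    if (length(object@status) != 1L || !object@status %in% ok)
      return(paste("'status' must be one of:", paste(ok, collapse = ", ")))
    if (object@missingCount < 0L) return("'missingCount' must be >= 0")
    TRUE
  })

#' MigrationStats: population migration-rate summary
#'
#' Per-track mean displacement (MD, micrometers traveled per minute) and the
#' population average mean displacement (AMD): the unweighted mean of the
#' per-track MDs, with their standard deviation.
#'
#' @slot perTrack data.frame with columns \code{track_id} and \code{md}
#'   (um/min).
#' @slot amd average mean displacement, um/min.
#' @slot sd standard deviation of the per-track MDs, um/min (NA for a single
#'   track).
#' @slot nTracks number of tracks summarized.
#'
#' @seealso [averageMeanDisplacement()]
#' @export
setClass("MigrationStats",
  representation(perTrack = "data.frame", amd = "numeric", sd = "numeric",
                 nTracks = "integer"),
  validity = function(object) {
    if (!all(c("track_id", "md") %in% names(object@perTrack)))
      return("'perTrack' needs columns track_id, md")
    if (object@nTracks != nrow(object@perTrack))
      return("'nTracks' must equal nrow(perTrack)")
    if (object@nTracks > 0L &&
        !isTRUE(all.equal(object@amd, mean(object@perTrack$md))))
      return("'amd' must be the mean of the per-track MDs")
    TRUE
  })

#' TrackEvaluation: tracking quality against reference tracks
#'
#' Evaluation of automatically extracted tracks against ground-truth
#' reference tracks: per-frame cell detection rates, identity swap errors,
#' lost or deleted tracks, and the count of valid tracks. An automatic track
#' is valid only if it follows one reference cell (and only that one) through
#' all frames in which the cell is visible.
#'
#' @slot detectionPerFrame numeric vector of per-frame detection rates.
#' @slot detectionSummary named numeric vector (median, min, max).
#' @slot nAssociationsRequired total number of frame-to-frame associations in
#'   the reference set (sum over reference tracks of length minus one).
#' @slot swapErrors number of frame-to-frame identity changes over all
#'   automatic tracks.
#' @slot lostOrDeleted reference tracks whose final visible frame is covered
#'   by no automatic track.
#' @slot correctTracks number of reference tracks followed by a valid
#'   automatic track.
#' @slot totalTracks number of reference tracks.
#' @slot percentCorrect 100 * correctTracks / totalTracks.
#'
#' @seealso [evaluateTracks()], [cellDetectionRate()]
#' @export
setClass("TrackEvaluation",
  representation(detectionPerFrame = "numeric", detectionSummary = "numeric",
                 nAssociationsRequired = "integer", swapErrors = "integer",
                 lostOrDeleted = "integer", correctTracks = "integer",
                 totalTracks = "integer", percentCorrect = "numeric"),
  validity = function(object) {
    if (object@correctTracks > object@totalTracks)
      return("correctTracks must be <= totalTracks")
    if (object@totalTracks > 0L &&
        !isTRUE(all.equal(object@percentCorrect,
                          100 * object@correctTracks / object@totalTracks)))
      return("percentCorrect must be 100 * correct / total")
    TRUE
  })
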