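#' @name accessors
#' @title Accessors for celltracker classes
#'
#' @description Small accessor functions used instead of direct slot access:
#' pixel data and geometry of an [ImageFrame-class], the coordinate matrix of
#' a [CentroidSet-class], and the points, id, status and event log of a
#' [Track-class].
#'
#' @param x the object.
#' @return the corresponding slot content (see individual functions).
NULL

#' @rdname accessors
#' @export
pixels <- function(x) x@pixels

#' @rdname accessors
#' @export
pixelSize <- function(x) x@pixelSize

#' @rdname accessors
#' @export
frameIndex <- function(x) x@frameIndex

#' @rdname accessors
#' @export
frameHeight <- function(x) nrow(x@pixels)

#' @rdname accessors
#' @export
frameWidth <- function(x) ncol(x@pixels)

#' @rdname accessors
#' @export
centroids <- function(x) x@points

#' @rdname accessors
#' @export
nCentroids <- function(x) nrow(x@points)

#' @rdname accessors
#' @export
trackId <- function(x) x@id

#' @rdname accessors
#' @export
trackPoints <- function(x) x@points

#' @rdname accessors
#' @export
trackStatus <- function(x) x@status

#' @rdname accessors
#' @export
trackEvents <- function(x) x@events

#' @rdname accessors
#' @export
kfState <- function(x) x@kf

#' @rdname accessors
#' @export
amd <- function(x) x@amd

#' @rdname accessors
#' @export
perTrackMD <- function(x) x@perTrack

#' @name show-methods
#' @title Compact display of celltracker objects
#' @description Short one-object summaries printed at the console for all
#'   classes of the package.
#' @param object the object to display.
#' @return \code{invisible(NULL)}, called for its side effect.
#' @aliases show,ImageFrame-method show,CentroidSet-method show,Track-method
#'   show,MigrationStats-method show,TrackEvaluation-method
#'   show,MotionModel-method show,KFState-method
#' @exportMethod show
setMethod("show", "ImageFrame", function(object) {
  cat("ImageFrame ", nrow(object@pixels), "x", ncol(object@pixels),
      " px (", object@pixelSize, " um/px), frame ", object@frameIndex,
      ", intensity range [", signif(min(object@pixels), 3), ", ",
      signif(max(object@pixels), 3), "]\n", sep = "")
})

setMethod("show", "CentroidSet", function(object) {
  cat("CentroidSet: ", nrow(object@points), " centroids in frame ",
      object@frameIndex, "\n", sep = "")
  if (nrow(object@points) > 0L) {
    n <- min(5L, nrow(object@points))
    print(round(object@points[seq_len(n), , drop = FALSE], 2))
    if (nrow(object@points) > n) cat("...\n")
  }
})

setMethod("show", "Track", function(object) {
  pts <- object@points
  cat("Track ", object@id, " [", object@status, "]: ", nrow(pts),
      " points", sep = "")
  if (nrow(pts) > 0L)
    cat(", frames ", min(pts$frame), "-", max(pts$frame), sep = "")
  if (nrow(object@events) > 0L)
    cat(", ", nrow(object@events), " events", sep = "")
  cat("\n")
})

setMethod("show", "MigrationStats", function(object) {
  cat("MigrationStats: ", object@nTracks, " tracks, AMD = ",
      signif(object@amd, 4), " um/min (SD ", signif(object@sd, 4), ")\n",
      sep = "")
})

setMethod("show", "TrackEvaluation", function(object) {
  ds <- object@detectionSummary
  cat("TrackEvaluation\n",
      "  detection rate median (min, max): ", round(ds["median"], 3), " (",
      round(ds["min"], 3), ", ", round(ds["max"], 3), ")\n",
      "  associations required: ", object@nAssociationsRequired, "\n",
      "  swap errors: ", object@swapErrors, "\n",
      "  lost or deleted: ", object@lostOrDeleted, "\n",
      "  track detection (correct/total): ", object@correctTracks, "/",
      object@totalTracks, " (", round(object@percentCorrect, 1), "%)\n",
      sep = "")
})

setMethod("show", "MotionModel", function(object) {
  cat("MotionModel (constant velocity, 1 frame step)\n  Q diag:",
      paste(signif(diag(object@Q), 3), collapse = " "),
      "\n  R diag:", paste(signif(diag(object@R), 3), collapse = " "), "\n")
})

setMethod("show", "KFState", function(object) {
  cat("KFState: pos (", signif(object@x[1], 5), ", ", signif(object@x[2], 5),
      ") px, vel (", signif(object@x[3], 4), ", ", signif(object@x[4], 4),
      ") px/frame\n", sep = "")
})
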