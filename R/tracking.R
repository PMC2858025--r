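#' Monitoring-module decision for one track
#'
#' Decides what happens to an active track given the outcome of the UNN
#' association. A first threshold (\code{gate}, widened by \code{gateGrowth}
#' px per consecutive missed frame to reflect the growing position
#' uncertainty of a coasting track) on the track-to-measurement
#' distance determines whether the pairing is likely correct; if so the pair
#' is accepted and the missing counter resets. If the measurement is missing
#' or the pair distance exceeds the gate, the missing path is taken: while
#' fewer than \code{maxMissing} consecutive measurements have been missed,
#' the track coasts — the substitute measurement is formed by the last
#' determined cell position. Once the limit is reached the track terminates,
#' classified \code{left_view} when its last position lies within
#' \code{borderMargin} of any frame edge (the cell plausibly moved out of the
#' field of view) and \code{terminated_lost} otherwise.
#'
#' @param lastPos numeric length-2 last determined position of the track.
#' @param missingCount current consecutive-missing counter of the track.
#' @param distance distance (px) of the UNN pair, or NA when unmatched.
#' @param frameIndex 0-based frame being processed (recorded on the event).
#' @param width,height frame size in px (for the border classification).
#' @param config configuration list from [trackingConfig()].
#' @return list with \code{kind} (one of \code{accepted},
#'   \code{missing_coasted}, \code{terminated}), \code{status} (track status
#'   implied by the decision) and \code{frame}.
#' @seealso [trackSequence()]
#' @export
monitorDecision <- function(lastPos, missingCount, distance, frameIndex,
                            width, height, config = trackingConfig()) {
  if (!is.na(distance) &&
      distance <= config$gate + missingCount * config$gateGrowth)
    return(list(kind = "accepted", status = "active",
                frame = as.integer(frameIndex)))
  if (missingCount < config$maxMissing)
    return(list(kind = "missing_coasted", status = "active",
                frame = as.integer(frameIndex)))
  nearBorder <- lastPos[1] <= config$borderMargin ||
    lastPos[1] >= (width - 1) - config$borderMargin ||
    lastPos[2] <= config$borderMargin ||
    lastPos[2] >= (height - 1) - config$borderMargin
  list(kind = "terminated",
       status = if (nearBorder) "left_view" else "terminated_lost",
       frame = as.integer(frameIndex))
}

#' Detect mitosis merges among unmatched tracks
#'
#' During backward tracking a cell division appears as two tracks merging
#' onto one centroid. A track left unmatched by the UNN pass whose prediction
#' lies within \code{mitosisGate} of a measurement already assigned to
#' another track is ended with a \code{mitosis_merge}; the partner track
#' survives and continues as the parent lineage.
#'
#' @param predicted numeric matrix (n x 2) of predicted positions of all
#'   tracks passed to the UNN (row i = track i).
#' @param assignment result of [unnAssociate()] on those predictions.
#' @param measurements numeric matrix (m x 2) of frame measurements.
#' @param mitosisGate distance threshold in px.
#' @return data.frame with columns \code{track} (the merging, i.e. ending,
#'   track row), \code{partner} (the surviving track row) and
#'   \code{measurement}; zero rows when every track is matched.
#' @export
detectMitosisMerges <- function(predicted, assignment, measurements,
                                mitosisGate = 25) {
  predicted <- toPointMatrix(predicted)
  measurements <- toPointMatrix(measurements)
  un <- assignment$unmatchedTracks
  prs <- assignment$pairs
  out <- data.frame(track = integer(0), partner = integer(0),
                    measurement = integer(0))
  if (length(un) == 0L || nrow(prs) == 0L) return(out)
  for (ti in un) {
    d <- sqrt((measurements[prs$measurement, 1] - predicted[ti, 1])^2 +
              (measurements[prs$measurement, 2] - predicted[ti, 2])^2)
    j <- which.min(d)
    if (d[j] <= mitosisGate)
      out <- rbind(out, data.frame(track = ti, partner = prs$track[j],
                                   measurement = prs$measurement[j]))
  }
  out
}

#' Which unmatched measurements may start new tracks
#'
#' Under backward tracking cells can only newly emerge by migrating into the
#' field of view, i.e. at the border of the frame, so only unmatched
#' measurements within \code{borderMargin} of an edge start new tracks;
#' interior unmatched measurements are ignored as segmentation noise. (On the
#' first processed frame every measurement seeds a track instead.)
#'
#' @param measurements numeric matrix (m x 2) of unmatched measurements (px).
#' @param width,height frame size in px.
#' @param borderMargin border zone width in px.
#' @return logical vector: TRUE for measurements allowed to initialize.
#' @export
nearBorder <- function(measurements, width, height, borderMargin = 30) {
  m <- toPointMatrix(measurements)
  if (nrow(m) == 0L) return(logical(0))
  m[, 1] <= borderMargin | m[, 1] >= (width - 1) - borderMargin |
    m[, 2] <= borderMargin | m[, 2] >= (height - 1) - borderMargin
}

#' Track a sequence of centroid sets (backward tracking)
#'
#' The complete tracking stage: cells are followed from the last to the first
#' frame. Per frame, every active track's state is advanced by [kfPredict()]
#' and its last determined position, extrapolated by the damped filter
#' velocity (\code{velDamping}), is associated to the frame's centroids by
#' [unnAssociate()],
#' and each outcome passes the monitoring module ([monitorDecision()]):
#' accepted pairs are appended and corrected with the measurement; rejected
#' or unmatched tracks first get a chance to merge as a mitosis
#' ([detectMitosisMerges()]), then coast on their last determined position
#' (corrected with an inflated measurement covariance so coasting does not
#' collapse the state covariance) or terminate. Unmatched measurements within
#' the border margin initialize new tracks; interior ones are ignored as
#' noise. Mitosis resolution runs after the UNN pass and before border
#' initialization, so a division is preferred over spawning a border track.
#'
#' Tracks still active at the first video frame (the end of the backward
#' pass) get status \code{completed}. All finalized tracks are reported with
#' their points in forward frame order.
#'
#' @param centroidSets list of [CentroidSet-class], one per frame, covering
#'   frames 0..N-1 in forward order.
#' @param width,height frame size in px.
#' @param config configuration list from [trackingConfig()].
#' @param model optional [MotionModel-class]; defaults to
#'   \code{motionModel(config$accelSd, config$jitterSd)}.
#' @param verbose print per-frame progress messages.
#' @return list of [Track-class] objects.
#' @examples
#' sets <- lapply(0:9, function(f)
#'   centroidSet(cbind(x = 100 + 5 * f, y = 50), frameIndex = f))
#' tr <- trackSequence(sets, width = 200, height = 100)
#' trackStatus(tr[[1]])
#' @export
trackSequence <- function(centroidSets, width, height,
                          config = trackingConfig(), model = NULL,
                          verbose = FALSE) {
  nF <- length(centroidSets)
  if (nF == 0L) stop("empty frame list", call. = FALSE)
  if (is.null(model)) model <- motionModel(config$accelSd, config$jitterSd)
  coastR <- model@R * config$coastRInflation
  velVar <- (2 * config$gate)^2

  tracks <- list()      # finalized + active track records
  activeIdx <- integer(0)
  nextId <- 1L

  newTrack <- function(pos, frame, kind) {
    rec <- list(id = nextId,
                frames = integer(0), xs = numeric(0), ys = numeric(0),
                status = "active", missing = 0L,
                evKind = character(0), evFrame = integer(0),
                evDetail = character(0),
                kf = kfInit(pos, model, p0 = config$p0, velVar = velVar),
                lastPos = pos)
    rec <- recPoint(rec, frame, pos)
    rec <- recEvent(rec, kind, frame, "")
    nextId <<- nextId + 1L
    rec
  }
  recPoint <- function(rec, frame, pos) {
    rec$frames <- c(rec$frames, as.integer(frame))
    rec$xs <- c(rec$xs, pos[1]); rec$ys <- c(rec$ys, pos[2])
    rec$lastPos <- pos
    rec
  }
  recEvent <- function(rec, kind, frame, detail) {
    rec$evKind <- c(rec$evKind, kind)
    rec$evFrame <- c(rec$evFrame, as.integer(frame))
    rec$evDetail <- c(rec$evDetail, detail)
    rec
  }

  frameOrder <- rev(seq_len(nF))
  first <- TRUE
  for (fi in frameOrder) {
    cs <- centroidSets[[fi]]
    f <- frameIndex(cs)
    meas <- centroids(cs)
    if (first) {
      for (k in seq_len(nrow(meas))) {
        tracks[[length(tracks) + 1L]] <- newTrack(meas[k, ], f, "initialized")
        activeIdx <- c(activeIdx, length(tracks))
      }
      first <- FALSE
      if (verbose) message("frame ", f, ": seeded ", nrow(meas), " tracks")
      next
    }

    # predict all active tracks; the association anchor is the last
    # determined position extrapolated by a damped velocity: anchoring on
    # the filtered state makes the prediction overshoot badly after sharp
    # maneuvers (contact deflections), whereas the damped-velocity anchor
    # is never more than about one step length from the cell
    for (i in activeIdx) tracks[[i]]$kf <- kfPredict(tracks[[i]]$kf, model)
    pred <- do.call(rbind, lapply(activeIdx, function(i)
      tracks[[i]]$lastPos + config$velDamping * tracks[[i]]$kf@x[3:4]))
    if (is.null(pred)) pred <- matrix(numeric(0), 0L, 2L)

    asn <- unnAssociate(pred, meas)

    matchedMeas <- logical(nrow(meas))
    acceptedPairIdx <- logical(nrow(asn$pairs))
    unmatchedLocal <- asn$unmatchedTracks

    # monitoring: first threshold on pair distance; a coasting track's
    # acceptance region widens with its miss count so it can re-acquire
    # its cell after an outlier step
    if (nrow(asn$pairs) > 0L) {
      for (p in seq_len(nrow(asn$pairs))) {
        effGate <- config$gate +
          tracks[[activeIdx[asn$pairs$track[p]]]]$missing * config$gateGrowth
        if (asn$pairs$distance[p] <= effGate) {
          acceptedPairIdx[p] <- TRUE
          matchedMeas[asn$pairs$measurement[p]] <- TRUE
        } else {
          unmatchedLocal <- c(unmatchedLocal, asn$pairs$track[p])
        }
      }
    }

    # mitosis merges: unmatched tracks converging onto an accepted measurement
    acceptedPairs <- asn$pairs[acceptedPairIdx, , drop = FALSE]
    merged <- integer(0)
    # only cleanly tracked candidates (no miss streak) may merge: a true
    # division fuses two tracked daughters onto one centroid, whereas a
    # coasting track near a neighbor is a lost cell, not a division
    cleanCand <- unmatchedLocal[vapply(unmatchedLocal, function(ti)
      tracks[[activeIdx[ti]]]$missing == 0L, logical(1))]
    if (length(cleanCand) > 0L && nrow(acceptedPairs) > 0L) {
      mg <- detectMitosisMerges(pred,
                                list(pairs = acceptedPairs,
                                     unmatchedTracks = cleanCand),
                                meas, config$mitosisGate)
      for (r in seq_len(nrow(mg))) {
        gi <- activeIdx[mg$track[r]]
        partner <- activeIdx[mg$partner[r]]
        z <- meas[mg$measurement[r], ]
        tracks[[gi]] <- recPoint(tracks[[gi]], f, z)
        tracks[[gi]] <- recEvent(tracks[[gi]], "mitosis_merge", f,
                                 paste0("partner=", tracks[[partner]]$id))
        tracks[[gi]]$status <- "merged_mitosis"
        merged <- c(merged, mg$track[r])
      }
    }
    unmatchedLocal <- setdiff(unmatchedLocal, merged)

    # accepted pairs: append measurement, correct
    for (p in which(acceptedPairIdx)) {
      gi <- activeIdx[asn$pairs$track[p]]
      z <- meas[asn$pairs$measurement[p], ]
      tracks[[gi]] <- recPoint(tracks[[gi]], f, z)
      tracks[[gi]] <- recEvent(tracks[[gi]], "accepted", f, "")
      tracks[[gi]]$missing <- 0L
      tracks[[gi]]$kf <- kfCorrect(tracks[[gi]]$kf, z, model)
    }

    # missing path: coast or terminate
    dropIdx <- merged
    for (ti in unmatchedLocal) {
      gi <- activeIdx[ti]
      dec <- monitorDecision(tracks[[gi]]$lastPos, tracks[[gi]]$missing,
                             NA_real_, f, width, height, config)
      if (dec$kind == "missing_coasted") {
        z <- tracks[[gi]]$lastPos
        tracks[[gi]] <- recPoint(tracks[[gi]], f, z)
        tracks[[gi]] <- recEvent(tracks[[gi]], "missing_coasted", f, "")
        tracks[[gi]]$missing <- tracks[[gi]]$missing + 1L
        tracks[[gi]]$kf <- kfCorrect(tracks[[gi]]$kf, z, model, R = coastR)
      } else {
        tracks[[gi]] <- recEvent(tracks[[gi]], "terminated", f,
                                 dec$status)
        tracks[[gi]]$status <- dec$status
        dropIdx <- c(dropIdx, ti)
      }
    }
    if (length(dropIdx) > 0L) activeIdx <- activeIdx[-dropIdx]

    # border initialization of unmatched measurements
    unMeas <- which(!matchedMeas)
    if (length(unMeas) > 0L) {
      ok <- nearBorder(meas[unMeas, , drop = FALSE], width, height,
                       config$borderMargin)
      for (k in unMeas[ok]) {
        tracks[[length(tracks) + 1L]] <- newTrack(meas[k, ], f, "initialized")
        activeIdx <- c(activeIdx, length(tracks))
      }
    }
    if (verbose)
      message("frame ", f, ": ", length(activeIdx), " active tracks")
  }

  # survivors of the backward pass reached the video start
  for (i in activeIdx) tracks[[i]]$status <- "completed"

  lapply(tracks, function(rec) {
    ord <- order(rec$frames)
    track(rec$id,
          data.frame(frame = rec$frames[ord], x = rec$xs[ord],
                     y = rec$ys[ord]),
          status = rec$status, missingCount = rec$missing,
          events = data.frame(kind = rec$evKind, frame = rec$evFrame,
                              detail = rec$evDetail,
                              stringsAsFactors = FALSE),
          kf = rec$kf)
  })
}
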