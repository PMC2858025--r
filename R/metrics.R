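#' Mean displacement (MD) of one track
#'
#' The migration rate of a cell: the mean distance in micrometers traveled
#' per minute by its centroid over consecutive frames,
#' MD = mean over steps of ||p[i+1] - p[i]|| * pixelSize / dt.
#'
#' @param track a [Track-class] (positions in px).
#' @param dt frame interval in minutes.
#' @param pixelSize pixel pitch in um/px.
#' @return MD in um/min.
#' @examples
#' tr <- track(1, cbind(x = c(0, 3, 3), y = c(0, 4, 4)))
#' meanDisplacement(tr)  # steps 7.5 and 0 um over 15 min -> 0.25
#' @export
meanDisplacement <- function(track, dt = 15, pixelSize = 1.5) {
  pts <- trackPoints(track)
  if (nrow(pts) < 2L)
    stop("track needs at least 2 points", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  steps <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  mean(steps) * pixelSize / dt
}

#' Average mean displacement (AMD) of a track population
#'
#' The migratory potential of a cell population: per-track MDs and their
#' unweighted mean (the AMD) and standard deviation.
#'
#' @param tracks list of [Track-class] objects, each with >= 2 points.
#' @param dt frame interval in minutes.
#' @param pixelSize pixel pitch in um/px.
#' @return a [MigrationStats-class].
#' @examples
#' trs <- list(track(1, cbind(x = c(0, 2), y = c(0, 0))),
#'             track(2, cbind(x = c(0, 4), y = c(0, 0))))
#' amd(averageMeanDisplacement(trs))  # 0.3
#' @export
averageMeanDisplacement <- function(tracks, dt = 15, pixelSize = 1.5) {
  if (length(tracks) == 0L) stop("empty track list", call. = FALSE)
  mds <- vapply(tracks, meanDisplacement, numeric(1), dt = dt,
                pixelSize = pixelSize)
  ids <- vapply(tracks, trackId, integer(1))
  new("MigrationStats",
      perTrack = data.frame(track_id = ids, md = mds),
      amd = mean(mds),
      sd = if (length(mds) > 1L) stats::sd(mds) else NA_real_,
      nTracks = length(mds))
}

#' Smooth a track by a centered moving average
#'
#' Replaces each coordinate by the centered moving average over
#' \code{window} frames, the smoothing applied to noisy tracks prior to AMD
#' calculation. At the track ends the window shrinks symmetrically (sizes 1,
#' 3, ..., window), so the track length and frame indices are preserved;
#' tracks shorter than the window use the maximal symmetric windows.
#'
#' @param track a [Track-class].
#' @param window odd window size >= 3 (default 5).
#' @return the smoothed [Track-class].
#' @export
smoothTrack <- function(track, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 3L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  pts <- trackPoints(track)
  n <- nrow(pts)
  if (n < 2L) return(track)
  r <- (window - 1L) %/% 2L
  sm <- function(v) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      h <- min(r, i - 1L, n - i)
      out[i] <- mean(v[(i - h):(i + h)])
    }
    out
  }
  new("Track", id = track@id,
      points = data.frame(frame = pts$frame, x = sm(pts$x), y = sm(pts$y)),
      status = track@status, missingCount = track@missingCount,
      events = track@events, kf = track@kf)
}

#' Per-frame cell detection rate
#'
#' For each frame, the fraction of true cell positions that have a detected
#' centroid within \code{matchRadius}, matched one-to-one greedily by
#' distance (each detected point can explain at most one true cell).
#'
#' @param detected list of [CentroidSet-class] (detections per frame).
#' @param truth list of [CentroidSet-class] (ground truth per frame), same
#'   length.
#' @param matchRadius matching radius in px.
#' @return list with \code{perFrame} (numeric vector; frames without true
#'   cells count as 1) and \code{summary} (named vector median, min, max).
#' @seealso [evaluateTracks()]
#' @export
cellDetectionRate <- function(detected, truth, matchRadius = 20) {
  if (length(detected) != length(truth))
    stop("'detected' and 'truth' must cover the same frames", call. = FALSE)
  rates <- vapply(seq_along(truth), function(i) {
    tp <- centroids(truth[[i]])
    dp <- centroids(detected[[i]])
    if (nrow(tp) == 0L) return(1)
    if (nrow(dp) == 0L) return(0)
    hits <- greedyMatch(tp, dp, matchRadius)
    sum(!is.na(hits)) / nrow(tp)
  }, numeric(1))
  list(perFrame = rates,
       summary = c(median = stats::median(rates), min = min(rates),
                   max = max(rates)))
}

# One-to-one greedy matching by increasing distance; returns for each row of
# 'a' the matched row of 'b' (NA if none within radius).
greedyMatch <- function(a, b, radius) {
  D <- crossDist(a, b)
  D[D > radius] <- NA
  out <- rep(NA_integer_, nrow(a))
  usedB <- logical(nrow(b))
  ord <- order(D, na.last = NA)
  for (k in ord) {
    i <- (k - 1L) %% nrow(a) + 1L
    j <- (k - 1L) %/% nrow(a) + 1L
    if (is.na(out[i]) && !usedB[j]) {
      out[i] <- j
      usedB[j] <- TRUE
    }
  }
  out
}

#' Evaluate automatic tracks against reference tracks
#'
#' Applies the strict validity criterion to automatically generated tracks:
#' an automatic track is valid only if it follows one reference cell (and
#' only that one) through all frames in which the cell is visible. Per frame,
#' each automatic track point is matched to the nearest reference position
#' within \code{matchRadius}; a frame-to-frame change of the matched identity
#' counts one swap error. The criterion is violated if a track fails to
#' initialize, is prematurely terminated, or swaps between two cells;
#' isolated points matching no reference (the coasted positions recorded
#' while a measurement was missing) do not invalidate an otherwise complete
#' single-identity track.
#' Reference tracks whose final visible frame is covered by no automatic
#' track count as lost or deleted.
#'
#' @param auto list of [Track-class]: automatically extracted tracks.
#' @param reference list of [Track-class]: ground-truth tracks.
#' @param matchRadius matching radius in px.
#' @return a [TrackEvaluation-class]; \code{totalTracks} is the number of
#'   reference tracks and \code{correctTracks} the number of them followed by
#'   a valid automatic track.
#' @export
evaluateTracks <- function(auto, reference, matchRadius = 20) {
  frames <- sort(unique(unlist(lapply(reference, function(tr)
    trackPoints(tr)$frame))))
  refPos <- lapply(frames, function(f) {
    do.call(rbind, lapply(seq_along(reference), function(ri) {
      pts <- trackPoints(reference[[ri]])
      row <- pts[pts$frame == f, , drop = FALSE]
      if (nrow(row) == 0L) return(NULL)
      c(ri, row$x[1], row$y[1])
    }))
  })
  names(refPos) <- as.character(frames)

  identitySeq <- lapply(auto, function(tr) {
    pts <- trackPoints(tr)
    vapply(seq_len(nrow(pts)), function(k) {
      rp <- refPos[[as.character(pts$frame[k])]]
      if (is.null(rp)) return(NA_integer_)
      d <- sqrt((rp[, 2] - pts$x[k])^2 + (rp[, 3] - pts$y[k])^2)
      j <- which.min(d)
      if (d[j] <= matchRadius) as.integer(rp[j, 1]) else NA_integer_
    }, integer(1))
  })

  swaps <- sum(vapply(identitySeq, function(ids) {
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2L) return(0L)
    sum(diff(ids) != 0L)
  }, integer(1)))

  # a reference is correctly tracked if some auto track covers every frame
  # of its visible span and matches this reference and nothing else. Points
  # matching no reference (coasted positions during missed detections) do
  # not invalidate the track: the criterion's violations are failure to
  # initialize, premature termination, and identity swaps.
  # per auto point, distance to a given reference and to the closest other
  # reference: a point is foreign to ri only when some other reference is
  # strictly closer (ties occur legitimately where two daughter cells share
  # the division-frame position)
  correct <- vapply(seq_along(reference), function(ri) {
    span <- trackPoints(reference[[ri]])$frame
    for (ai in seq_along(auto)) {
      af <- trackPoints(auto[[ai]])$frame
      if (!all(span %in% af)) next
      pts <- trackPoints(auto[[ai]])
      dRi <- vapply(seq_len(nrow(pts)), function(k) {
        rp <- refPos[[as.character(pts$frame[k])]]
        if (is.null(rp)) return(NA_real_)
        j <- which(rp[, 1] == ri)
        if (length(j) == 0L) return(Inf)
        sqrt((rp[j, 2] - pts$x[k])^2 + (rp[j, 3] - pts$y[k])^2)
      }, numeric(1))
      dOther <- vapply(seq_len(nrow(pts)), function(k) {
        rp <- refPos[[as.character(pts$frame[k])]]
        if (is.null(rp)) return(NA_real_)
        j <- which(rp[, 1] != ri)
        if (length(j) == 0L) return(Inf)
        min(sqrt((rp[j, 2] - pts$x[k])^2 + (rp[j, 3] - pts$y[k])^2))
      }, numeric(1))
      hit <- !is.na(dRi) & dRi <= matchRadius & dRi <= dOther + 1e-9
      foreign <- !is.na(dOther) & dOther <= matchRadius & dOther < dRi - 1e-9
      if (sum(hit[match(span, af)]) >= 1L && !any(foreign))
        return(TRUE)
    }
    FALSE
  }, logical(1))

  lost <- vapply(seq_along(reference), function(ri) {
    pts <- trackPoints(reference[[ri]])
    lastF <- max(pts$frame)
    for (ai in seq_along(auto)) {
      af <- trackPoints(auto[[ai]])$frame
      if (lastF %in% af) {
        k <- match(lastF, af)
        if (!is.na(identitySeq[[ai]][k]) && identitySeq[[ai]][k] == ri)
          return(FALSE)
      }
    }
    TRUE
  }, logical(1))

  # detection rate from the reference positions vs auto points per frame
  truthSets <- lapply(seq_along(frames), function(i) {
    rp <- refPos[[i]]
    centroidSet(cbind(x = rp[, 2], y = rp[, 3]), frameIndex = frames[i])
  })
  autoSets <- lapply(frames, function(f) {
    pm <- do.call(rbind, lapply(auto, function(tr) {
      pts <- trackPoints(tr)
      row <- pts[pts$frame == f, , drop = FALSE]
      if (nrow(row) == 0L) return(NULL)
      c(row$x[1], row$y[1])
    }))
    if (is.null(pm)) pm <- matrix(numeric(0), 0L, 2L)
    centroidSet(pm, frameIndex = f)
  })
  det <- cellDetectionRate(autoSets, truthSets, matchRadius)

  nAssoc <- sum(vapply(reference, function(tr)
    nrow(trackPoints(tr)) - 1L, integer(1)))

  nc <- as.integer(sum(correct)); nt <- length(reference)
  new("TrackEvaluation",
      detectionPerFrame = det$perFrame, detectionSummary = det$summary,
      nAssociationsRequired = as.integer(nAssoc),
      swapErrors = as.integer(swaps),
      lostOrDeleted = as.integer(sum(lost)),
      correctTracks = nc, totalTracks = as.integer(nt),
      percentCorrect = if (nt > 0L) 100 * nc / nt else NA_real_)
}
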