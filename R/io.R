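# Readers and writers: image sequences (TIFF/PNG), track tables (native CSV
# and the ImageJ Manual Tracking layout), centroid tables, study results and
# track overlays.

#' Read an image sequence
#'
#' Accepts either a directory of single-page TIFF or PNG frames (sorted
#' lexicographically) or one multi-page TIFF file. Integer images are
#' rescaled to [0, 1] by the readers (division by the dtype maximum); RGB
#' frames are converted to grayscale by channel averaging. All frames must
#' share the same dimensions.
#'
#' @param path directory or multi-page TIFF path.
#' @param pixelSize pixel pitch in um/px recorded on the frames.
#' @return list of [ImageFrame-class] objects, frame indices 0..N-1.
#' @seealso [writeSequence()], [segmentSequence()]
#' @export
readSequence <- function(path, pixelSize = 1.5) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no TIFF/PNG frames found in ", path, call. = FALSE)
    mats <- lapply(files, function(fp) {
      if (grepl("\\.png$", fp, ignore.case = TRUE))
        toGray(png::readPNG(fp))
      else
        toGray(tiff::readTIFF(fp))
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 0L) stop("no frames in ", path, call. = FALSE)
    mats <- lapply(pages, toGray)
  } else {
    stop("path not found: ", path, call. = FALSE)
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed dimensions", call. = FALSE)
  lapply(seq_along(mats), function(i)
    imageFrame(mats[[i]], pixelSize = pixelSize, frameIndex = i - 1L))
}

toGray <- function(a) {
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}

#' Write an image sequence as a multi-page TIFF
#'
#' Intensities are quantized to the requested bit depth before writing, so a
#' written sequence reads back with exactly the stored values.
#'
#' @param frames list of [ImageFrame-class] objects.
#' @param path output .tif path.
#' @param bits bits per sample (8 or 16).
#' @return \code{path}, invisibly.
#' @export
writeSequence <- function(frames, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  mats <- lapply(frames, function(f) round(pixels(f) * mx) / mx)
  tiff::writeTIFF(mats, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read / write tracks in the ImageJ Manual Tracking layout
#'
#' CSV with columns \code{"Track n°"}, \code{"Slice n°"}, \code{X},
#' \code{Y} and 1-based slice numbers, as produced by the ImageJ Manual
#' Tracking plugin. On reading, slice numbers become 0-based frame indices
#' and rows are grouped into [Track-class] objects; missing columns or a
#' duplicated (track, slice) pair are format errors.
#'
#' @param path CSV file path.
#' @param tracks list of [Track-class] objects (for the writer).
#' @return \code{readManualTracks}: list of [Track-class];
#'   \code{writeManualTracks}: \code{path}, invisibly.
#' @export
readManualTracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("Track n°", "Slice n°", "X", "Y")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  tid <- df[["Track n°"]]; slice <- df[["Slice n°"]]
  if (anyDuplicated(paste(tid, slice)))
    stop("duplicated (track, slice) rows", call. = FALSE)
  lapply(sort(unique(tid)), function(id) {
    sel <- tid == id
    track(id, data.frame(frame = as.integer(slice[sel]) - 1L,
                         x = df$X[sel], y = df$Y[sel]))
  })
}

#' @rdname readManualTracks
#' @export
writeManualTracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    pts <- trackPoints(tr)
    data.frame(track = trackId(tr), slice = pts$frame + 1L,
               X = pts$x, Y = pts$y)
  }))
  names(rows) <- c("Track n°", "Slice n°", "X", "Y")
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the native track table
#'
#' One row per (track, frame): \code{track_id}, \code{frame}, \code{x_px},
#' \code{y_px}, \code{status}, \code{event} (the monitoring event recorded at
#' that frame, empty when none).
#'
#' @param tracks list of [Track-class] objects.
#' @param path CSV file path.
#' @return \code{writeTrackTable}: \code{path} invisibly;
#'   \code{readTrackTable}: list of [Track-class] (status restored, event log
#'   restored from the event column).
#' @export
writeTrackTable <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    pts <- trackPoints(tr)
    ev <- trackEvents(tr)
    evAt <- ev$kind[match(pts$frame, ev$frame)]
    evAt[is.na(evAt)] <- ""
    data.frame(track_id = trackId(tr), frame = pts$frame,
               x_px = pts$x, y_px = pts$y, status = trackStatus(tr),
               event = evAt)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  lapply(sort(unique(df$track_id)), function(id) {
    sel <- df[df$track_id == id, , drop = FALSE]
    ev <- if ("event" %in% names(sel)) {
      sel$event <- as.character(sel$event)
      has <- !is.na(sel$event) & nzchar(sel$event)
      data.frame(kind = sel$event[has], frame = as.integer(sel$frame[has]),
                 detail = rep("", sum(has)), stringsAsFactors = FALSE)
    } else emptyEvents()
    track(id, data.frame(frame = sel$frame, x = sel$x_px, y = sel$y_px),
          status = if ("status" %in% names(sel)) sel$status[1] else
            "completed",
          events = ev)
  })
}

#' Write per-frame centroids as CSV
#'
#' Columns \code{frame}, \code{x}, \code{y} in pixels.
#'
#' @param centroidSets list of [CentroidSet-class].
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeCentroids <- function(centroidSets, path) {
  rows <- do.call(rbind, lapply(centroidSets, function(cs) {
    p <- centroids(cs)
    if (nrow(p) == 0L) return(NULL)
    data.frame(frame = frameIndex(cs), x = p[, 1], y = p[, 2])
  }))
  if (is.null(rows))
    rows <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCentroids
#' @export
readCentroids <- function(path) {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  lapply(frames, function(f) {
    sel <- df$frame == f
    centroidSet(cbind(x = df$x[sel], y = df$y[sel]), frameIndex = f)
  })
}

#' Write a migration-statistics report
#'
#' Per-track MD table plus a one-line AMD summary appended as comment-style
#' trailer columns.
#'
#' @param stats a [MigrationStats-class].
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeMigrationStats <- function(stats, path) {
  df <- perTrackMD(stats)
  df$amd <- amd(stats)
  df$amd_sd <- stats@sd
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Overlay tracks onto frames and write PNG images
#'
#' Draws each track's path up to the current frame in a per-track color onto
#' the grayscale frames, marking divisions (mitosis merges) with a green spot
#' and track losses or leave-view events with a red spot, then writes one RGB
#' PNG per frame into \code{outDir}.
#'
#' @param frames list of [ImageFrame-class].
#' @param tracks list of [Track-class].
#' @param outDir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
overlayTracks <- function(frames, tracks, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cols <- grDevices::hsv(h = (seq_along(tracks) * 0.61803) %% 1,
                         s = 0.9, v = 1)
  rgbCols <- grDevices::col2rgb(cols) / 255
  out <- character(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    f <- frameIndex(fr)
    H <- frameHeight(fr); W <- frameWidth(fr)
    img <- array(pixels(fr), dim = c(H, W, 3L))
    for (ti in seq_along(tracks)) {
      pts <- trackPoints(tracks[[ti]])
      pts <- pts[pts$frame <= f, , drop = FALSE]
      if (nrow(pts) == 0L) next
      img <- drawPath(img, pts$x, pts$y, rgbCols[, ti])
      ev <- trackEvents(tracks[[ti]])
      ev <- ev[ev$frame == f, , drop = FALSE]
      for (e in seq_len(nrow(ev))) {
        col <- switch(ev$kind[e], mitosis_merge = c(0, 1, 0),
                      terminated = c(1, 0, 0), NULL)
        if (is.null(col)) next
        at <- trackPoints(tracks[[ti]])
        at <- at[at$frame == f, , drop = FALSE]
        if (nrow(at) == 0L)
          at <- utils::tail(trackPoints(tracks[[ti]]), 1L)
        img <- drawSpot(img, at$x[1], at$y[1], col, 4L)
      }
    }
    out[i] <- file.path(outDir, sprintf("frame_%04d.png", f))
    png::writePNG(img, out[i])
  }
  invisible(out)
}

drawPath <- function(img, xs, ys, col) {
  H <- dim(img)[1]; W <- dim(img)[2]
  for (k in seq_len(length(xs) - 1L)) {
    n <- max(2L, ceiling(sqrt((xs[k + 1] - xs[k])^2 +
                              (ys[k + 1] - ys[k])^2)) + 1L)
    px <- round(seq(xs[k], xs[k + 1], length.out = n)) + 1L
    py <- round(seq(ys[k], ys[k + 1], length.out = n)) + 1L
    ok <- px >= 1L & px <= W & py >= 1L & py <= H
    for (ch in 1:3) img[cbind(py[ok], px[ok], ch)] <- col[ch]
  }
  img
}

drawSpot <- function(img, x, y, col, r) {
  H <- dim(img)[1]; W <- dim(img)[2]
  py <- max(1L, round(y) + 1L - r):min(H, round(y) + 1L + r)
  px <- max(1L, round(x) + 1L - r):min(W, round(x) + 1L + r)
  for (ch in 1:3) img[py, px, ch] <- col[ch]
  img
}
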