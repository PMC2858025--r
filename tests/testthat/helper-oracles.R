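# Shared helpers and independent oracle implementations used by the tests.

# Brute-force unique nearest-neighbor association: repeatedly take the
# globally smallest remaining distance (lexicographic tie-break on
# (track, measurement)), independent of the package implementation.
bruteForceUnn <- function(pred, meas) {
  nT <- nrow(pred); nM <- nrow(meas)
  D <- matrix(NA_real_, nT, nM)
  for (i in seq_len(nT)) for (j in seq_len(nM))
    D[i, j] <- sqrt(sum((pred[i, ] - meas[j, ])^2))
  pairs <- NULL
  freeT <- rep(TRUE, nT); freeM <- rep(TRUE, nM)
  while (any(freeT) && any(freeM)) {
    best <- NULL
    for (i in which(freeT)) for (j in which(freeM)) {
      if (is.null(best) || D[i, j] < best$d - 1e-12) {
        best <- list(i = i, j = j, d = D[i, j])
      } else if (abs(D[i, j] - best$d) <= 1e-12) {
        if (i < best$i || (i == best$i && j < best$j))
          best <- list(i = i, j = j, d = D[i, j])
      }
    }
    pairs <- rbind(pairs, c(best$i, best$j, best$d))
    freeT[best$i] <- FALSE; freeM[best$j] <- FALSE
  }
  pairs
}

# Naive O(n^2) local entropy at one pixel, with edge reflection, matching
# the documented definition: base-2 entropy of the binned intensity
# histogram in a (2r+1)^2 window.
naiveEntropyAt <- function(img, row, col, window, nBins) {
  r <- (window - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  # edge-inclusive symmetric reflection, the documented border convention
  refl <- function(i, n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
    i
  }
  vals <- numeric(0)
  for (dy in -r:r) for (dx in -r:r)
    vals <- c(vals, img[refl(row + dy, H), refl(col + dx, W)])
  bins <- pmin(floor(vals * nBins) + 1L, nBins)
  p <- tabulate(bins, nBins) / length(vals)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Straight-line reference track builder.
lineTrack <- function(id, n, start, step) {
  track(id, cbind(x = start[1] + (0:(n - 1)) * step[1],
                  y = start[2] + (0:(n - 1)) * step[2]))
}

# Centroid sets from a matrix of per-track positions: one CentroidSet per
# frame built from a list of tracks (all tracks must cover the frame range).
trackSets <- function(tracks, frames) {
  lapply(frames, function(f) {
    pm <- do.call(rbind, lapply(tracks, function(tr) {
      pts <- trackPoints(tr)
      row <- pts[pts$frame == f, , drop = FALSE]
      if (nrow(row) == 0L) return(NULL)
      c(row$x[1], row$y[1])
    }))
    if (is.null(pm)) pm <- matrix(numeric(0), 0, 2)
    centroidSet(pm, frameIndex = f)
  })
}
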