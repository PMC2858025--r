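#' Pooled centroid-click standard deviation
#'
#' Quantifies the imprecision of manual point-and-click centroid selection
#' from replicate clicks: per frame the replicate mean is subtracted from
#' each clicked point, all centered x and y coordinates are pooled into a
#' single sample (a single variability value is assumed for both
#' coordinates), and its standard deviation is returned in micrometers.
#'
#' Centering on the per-frame mean consumes one degree of freedom per frame
#' and coordinate, so the pooled variance divides the residual sum of squares
#' by \code{sum(2 * (n_frame - 1))} rather than the raw residual count;
#' otherwise the estimate would be biased low for small replicate counts.
#'
#' @param replicates list (one element per frame) of n x 2 matrices of
#'   clicked positions in px; every frame needs >= 2 replicates.
#' @param pixelSize pixel pitch in um/px.
#' @return pooled standard deviation in um.
#' @examples
#' reps <- list(rbind(c(0, 0), c(2, 0)), rbind(c(1, 1), c(1, 3)))
#' pooledCentroidSd(reps, pixelSize = 1.5)  # 1.5: unit pooled SD in px
#' @export
pooledCentroidSd <- function(replicates, pixelSize = 1.5) {
  ssr <- 0; dof <- 0L
  for (m in replicates) {
    m <- toPointMatrix(m)
    if (nrow(m) < 2L)
      stop("every frame needs at least 2 replicate clicks", call. = FALSE)
    ssr <- ssr + sum((m[, 1] - mean(m[, 1]))^2) +
      sum((m[, 2] - mean(m[, 2]))^2)
    dof <- dof + 2L * (nrow(m) - 1L)
  }
  sqrt(ssr / dof) * pixelSize
}

#' Impose centroid-selection noise on a track
#'
#' Creates replicate tracks, each adding independent zero-mean Gaussian noise
#' with per-coordinate standard deviation \code{sigmaUm} (given in um,
#' applied in px via the pixel pitch, before any pixel rounding) to every
#' position of the track. This emulates the centroid click jitter of manual
#' tracking.
#'
#' @param track a [Track-class].
#' @param sigmaUm per-coordinate noise SD in um (>= 0).
#' @param nReplicates number of noisy replicates.
#' @param pixelSize pixel pitch in um/px.
#' @param seed optional integer seed for reproducibility.
#' @return list of \code{nReplicates} noisy [Track-class] objects.
#' @seealso [clickNoiseStudy()]
#' @export
imposeClickNoise <- function(track, sigmaUm, nReplicates = 200,
                             pixelSize = 1.5, seed = NULL) {
  stopifnot(sigmaUm >= 0, nReplicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  pts <- trackPoints(track)
  n <- nrow(pts)
  sPx <- sigmaUm / pixelSize
  lapply(seq_len(nReplicates), function(r) {
    track(r, data.frame(frame = pts$frame,
                        x = pts$x + stats::rnorm(n, 0, sPx),
                        y = pts$y + stats::rnorm(n, 0, sPx)),
          status = track@status)
  })
}

#' Noise-injection study of manual centroid selection
#'
#' Reproduces the click-noise experiment: for each (track, sigma) cell of the
#' grid, \code{nReplicates} noisy replicates of the track are generated with
#' [imposeClickNoise()], and the AMD of the raw noisy replicates and of their
#' smoothed versions ([smoothTrack()]) is compared with the MD of the
#' original track. Percent columns are 100 * AMD / original MD, so values
#' above 100 quantify the overestimation of cell speed caused by centroid
#' selection noise.
#'
#' @param labeledTracks named list of [Track-class] objects (e.g. slow,
#'   medium and fast reference cells).
#' @param sigmasUm noise levels in um (default 3, 4.5, 6, 7.5, i.e. 2-5 px at
#'   1.5 um/px).
#' @param nReplicates replicates per grid cell (default 200).
#' @param smoothWindow centered moving-average window (default 5).
#' @param dt frame interval in minutes.
#' @param pixelSize pixel pitch in um/px.
#' @param seed integer seed.
#' @return data.frame with one row per (track, sigma): \code{cell_label},
#'   \code{sigma_um}, \code{original_md}, \code{amd_noisy},
#'   \code{percent_of_original}, \code{amd_smoothed},
#'   \code{percent_smoothed}.
#' @export
clickNoiseStudy <- function(labeledTracks, sigmasUm = c(3, 4.5, 6, 7.5),
                            nReplicates = 200, smoothWindow = 5L,
                            dt = 15, pixelSize = 1.5, seed = 20100408L) {
  stopifnot(length(labeledTracks) > 0, all(sigmasUm > 0), nReplicates >= 2)
  labels <- names(labeledTracks)
  if (is.null(labels)) labels <- paste0("track", seq_along(labeledTracks))
  rows <- list()
  cellSeed <- seed
  for (li in seq_along(labeledTracks)) {
    tr <- labeledTracks[[li]]
    md0 <- meanDisplacement(tr, dt, pixelSize)
    for (s in sigmasUm) {
      cellSeed <- cellSeed + 1L
      reps <- imposeClickNoise(tr, s, nReplicates, pixelSize,
                               seed = cellSeed)
      amdNoisy <- amd(averageMeanDisplacement(reps, dt, pixelSize))
      smoothed <- lapply(reps, smoothTrack, window = smoothWindow)
      amdSmooth <- amd(averageMeanDisplacement(smoothed, dt, pixelSize))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_label = labels[li], sigma_um = s, original_md = md0,
        amd_noisy = amdNoisy,
        percent_of_original = 100 * amdNoisy / md0,
        amd_smoothed = amdSmooth,
        percent_smoothed = 100 * amdSmooth / md0)
    }
  }
  do.call(rbind, rows)
}

#' Subset-selection resampling study
#'
#' Quantifies how much the population migration rate can vary when only a
#' subset of k cells is analyzed: subsets of \code{k} tracks are drawn
#' repeatedly without replacement and the AMD of each subset is recorded,
#' giving the distribution of AMD values attainable by subset selection.
#'
#' @param tracks list of [Track-class] objects (the population).
#' @param k subset size (default 20).
#' @param iterations number of random subsets (default 2e5).
#' @param dt frame interval in minutes.
#' @param pixelSize pixel pitch in um/px.
#' @param seed integer seed.
#' @return list with \code{amdDistribution} (numeric vector of subset AMDs),
#'   \code{quantiles} (2.5, 25, 50, 75, 97.5 percent), \code{populationAmd},
#'   \code{k} and \code{iterations}.
#' @export
subsetResamplingStudy <- function(tracks, k = 20, iterations = 2e5,
                                  dt = 15, pixelSize = 1.5,
                                  seed = 20100408L) {
  n <- length(tracks)
  if (k > n) stop("'k' exceeds the population size", call. = FALSE)
  set.seed(seed)
  mds <- vapply(tracks, meanDisplacement, numeric(1), dt = dt,
                pixelSize = pixelSize)
  dist <- vapply(seq_len(iterations), function(i)
    mean(mds[sample.int(n, k)]), numeric(1))
  list(amdDistribution = dist,
       quantiles = stats::quantile(dist, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       populationAmd = mean(mds), k = k, iterations = iterations)
}

#' Pairwise agreement of subset selections
#'
#' For rater-chosen track subsets, the number of commonly selected cells for
#' any combination of two raters, summarized as mean and SD over all
#' unordered rater pairs.
#'
#' @param selections list (>= 2 elements) of track-id vectors, one per rater.
#' @return list with \code{mean}, \code{sd} and \code{pairCounts} (the
#'   intersection size of every rater pair).
#' @examples
#' pairwiseAgreement(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$mean  # 5/3
#' @export
pairwiseAgreement <- function(selections) {
  if (length(selections) < 2L) stop("need >= 2 raters", call. = FALSE)
  pairs <- utils::combn(length(selections), 2L)
  counts <- apply(pairs, 2L, function(p)
    length(intersect(selections[[p[1]]], selections[[p[2]]])))
  list(mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else NA_real_,
       pairCounts = counts)
}
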