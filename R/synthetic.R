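# Synthetic ground-truth generator: tracks, populations and rendered image
# sequences emulating textured cells on a smooth background, so segmentation,
# tracking and the migration statistics are testable against known truth.

#' Generate one synthetic cell track
#'
#' Simulates a migrating cell as a correlated random walk. Step lengths are
#' i.i.d. gamma distributed with mean \code{mdMean * dt} and SD
#' \code{mdSd * dt} micrometers (gamma keeps step lengths strictly positive
#' while matching both printed moments of observed per-step displacement
#' statistics); headings follow a von Mises distribution with concentration
#' \code{kappa} around the previous heading (\code{kappa = 0} gives
#' uncorrelated uniform headings, large values nearly straight paths).
#'
#' With \code{momentMatch = TRUE} the sampled step lengths are affinely
#' standardized so the realized sample mean and SD equal the requested
#' moments exactly — appropriate when the requested values are themselves the
#' realized sample moments of an observed track that the synthetic one stands
#' in for (draws are repeated if standardization would produce a negative
#' step length).
#'
#' @param nFrames number of positions (>= 2).
#' @param mdMean mean per-step displacement rate, um/min (> 0).
#' @param mdSd SD of the per-step displacement rate, um/min (>= 0).
#' @param dt frame interval in minutes.
#' @param kappa heading persistence (von Mises concentration, >= 0).
#' @param start start position (x, y) in px.
#' @param pixelSize pixel pitch in um/px.
#' @param momentMatch standardize sampled step lengths to the exact moments.
#' @param id track id for the returned object.
#' @param seed optional integer seed.
#' @return a [Track-class] with positions in px, frames 0..nFrames-1.
#' @examples
#' tr <- generateTrack(63, mdMean = 0.622, mdSd = 0.411, seed = 1)
#' meanDisplacement(tr)
#' @export
generateTrack <- function(nFrames = 63, mdMean, mdSd, dt = 15, kappa = 0,
                          start = c(0, 0), pixelSize = 1.5,
                          momentMatch = FALSE, id = 1L, seed = NULL) {
  stopifnot(nFrames >= 2, mdMean > 0, mdSd >= 0, dt > 0, kappa >= 0)
  if (!is.null(seed)) set.seed(seed)
  nSteps <- nFrames - 1L
  L <- sampleStepLengths(nSteps, mdMean * dt, mdSd * dt, momentMatch)
  theta <- cumsum(rvonmises(nSteps, 0, kappa)) + stats::runif(1, -pi, pi)
  xs <- c(0, cumsum(L * cos(theta))) / pixelSize + start[1]
  ys <- c(0, cumsum(L * sin(theta))) / pixelSize + start[2]
  track(id, data.frame(frame = seq_len(nFrames) - 1L, x = xs, y = ys))
}

# Gamma step lengths (um) with mean m and SD s; optional exact sample-moment
# standardization.
sampleStepLengths <- function(n, m, s, momentMatch = FALSE) {
  if (s <= 0) return(rep(m, n))
  draw <- function() stats::rgamma(n, shape = (m / s)^2, rate = m / s^2)
  if (!momentMatch || n < 3L) return(draw())
  for (try in seq_len(100L)) {
    L <- draw()
    Lstd <- m + (L - mean(L)) * s / stats::sd(L)
    if (all(Lstd > 0)) return(Lstd)
  }
  stop("could not standardize step lengths to positive values", call. = FALSE)
}

#' Scene specification for synthetic image sequences
#'
#' Parameters of a synthetic time-lapse scene: frame geometry, cell count and
#' sizes, appearance (interior texture amplitude and grain, background noise,
#' illumination ramp), scripted division events and how many cells may leave
#' the field of view. Defaults mirror a typical acquisition: 1024 x 1344 px
#' frames, 1.5 um/px, 15-min steps, 58-63 frames and 68-103 cells per video.
#'
#' @param height,width frame size in px.
#' @param nFrames number of frames.
#' @param nCells number of cells placed at frame 0.
#' @param radiusRange min/max cell radius in px.
#' @param textureAmplitude SD of the cell-interior intensity texture
#'   (emulating bright and dark DIC shear lobes).
#' @param grainSize odd box width (px) of the texture grain smoothing.
#' @param backgroundNoiseSd SD of the additive background noise.
#' @param rampAmplitude peak-to-half amplitude of a linear illumination ramp
#'   across the image width (0 disables).
#' @param nLeaving number of cells free to migrate out of the field of view
#'   (the rest reflect at the borders).
#' @param divisions data.frame with columns \code{cell} (1-based cell index)
#'   and \code{frame} (0-based split frame), or NULL.
#' @param dt frame interval in minutes.
#' @param pixelSize pixel pitch in um/px.
#' @param seed integer seed.
#' @return a named list ("sceneSpec").
#' @seealso [generatePopulation()], [renderSequence()], [benchmarkScene()]
#' @export
sceneSpec <- function(height = 1024L, width = 1344L, nFrames = 60L,
                      nCells = 80L, radiusRange = c(15, 40),
                      textureAmplitude = 0.3, grainSize = 3L,
                      backgroundNoiseSd = 0.01, rampAmplitude = 0.05,
                      nLeaving = 8L, divisions = NULL, dt = 15,
                      pixelSize = 1.5, seed = 20100408L) {
  stopifnot(height > 0, width > 0, nFrames >= 2, nCells >= 0,
            length(radiusRange) == 2L, radiusRange[1] > 0,
            radiusRange[2] >= radiusRange[1],
            grainSize %% 2L == 1L, nLeaving >= 0L)
  if (is.null(divisions))
    divisions <- data.frame(cell = integer(0), frame = integer(0))
  list(height = as.integer(height), width = as.integer(width),
       nFrames = as.integer(nFrames), nCells = as.integer(nCells),
       radiusRange = radiusRange, textureAmplitude = textureAmplitude,
       grainSize = as.integer(grainSize),
       backgroundNoiseSd = backgroundNoiseSd,
       rampAmplitude = rampAmplitude, nLeaving = as.integer(nLeaving),
       divisions = divisions, dt = dt, pixelSize = pixelSize,
       seed = as.integer(seed))
}

#' The default synthetic tracking benchmark scene
#'
#' An 80-cell, 60-frame scene with a speed mixture of slow, medium and fast
#' cells (per-step moments 0.181 +/- 0.213, 0.622 +/- 0.411 and
#' 1.787 +/- 0.821 um/min), directional persistence kappa = 8, three
#' scripted divisions and eight cells free to leave the field of view.
#'
#' @param seed integer seed.
#' @return list with elements \code{scene} (a [sceneSpec()]) and
#'   \code{specs} (the per-cell motion mixture, see [generatePopulation()]).
#' @export
benchmarkScene <- function(seed = 20100408L) {
  scene <- sceneSpec(divisions = data.frame(cell = c(20L, 40L, 60L),
                                            frame = c(20L, 32L, 44L)),
                     seed = seed)
  specs <- list(
    list(mdMean = 0.181, mdSd = 0.213, kappa = 8, weight = 10),
    list(mdMean = 0.622, mdSd = 0.411, kappa = 8, weight = 58),
    list(mdMean = 1.787, mdSd = 0.821, kappa = 8, weight = 12))
  list(scene = scene, specs = specs)
}

#' Generate a ground-truth cell population
#'
#' Places \code{nCells} non-overlapping cells and simulates their motion over
#' the scene's frames: step lengths gamma distributed and headings von Mises
#' correlated per the motion mixture, cells never interpenetrating (a step
#' that would overlap another cell is re-drawn, else the cell pauses), border
#' reflection for resident cells and free exit for the leave-field subset
#' (a cell whose center crosses the frame border retires and its track ends).
#' Scripted divisions split a cell at the given frame: the parent continues
#' as one daughter (the same track id, as a human tracker following one cell
#' would record it), and a second daughter track starts at the split frame
#' sharing the parent position, both at reduced radius and with diverging
#' headings.
#'
#' @param scene a [sceneSpec()].
#' @param specs list of motion components, each a list with \code{mdMean},
#'   \code{mdSd} um/min, \code{kappa} and \code{weight}; cells are assigned
#'   components in proportion to the weights.
#' @return list ("groundTruth") with \code{tracks} (list of
#'   [Track-class]), \code{centroidSets} (per-frame true [CentroidSet-class]
#'   of visible cells), \code{cells} (per-cell geometry for rendering),
#'   \code{divisions} (realized division events) and \code{scene}.
#' @export
generatePopulation <- function(scene, specs = benchmarkScene()$specs) {
  set.seed(scene$seed)
  nC <- scene$nCells
  if (nC == 0L)
    return(list(tracks = list(),
                centroidSets = lapply(seq_len(scene$nFrames) - 1L,
                                      function(f) centroidSet(frameIndex = f)),
                cells = list(), divisions = scene$divisions, scene = scene))

  w <- vapply(specs, function(s) s$weight, numeric(1))
  compOf <- rep(seq_along(specs), times = round(w / sum(w) * nC))
  compOf <- c(compOf, rep(which.max(w), max(0, nC - length(compOf))))[1:nC]
  compOf <- sample(compOf)

  rad <- stats::runif(nC, scene$radiusRange[1], scene$radiusRange[2])
  # initial non-overlapping placement, fully inside the frame
  pos <- matrix(NA_real_, nC, 2)
  for (i in seq_len(nC)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      p <- c(stats::runif(1, rad[i], scene$width - 1 - rad[i]),
             stats::runif(1, rad[i], scene$height - 1 - rad[i]))
      if (i == 1L ||
          all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                            matrix(p, i - 1L, 2, byrow = TRUE))^2)) >
              rad[i] + rad[seq_len(i - 1L)] + 6)) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", nC, " non-overlapping cells; reduce nCells ",
           "or radii", call. = FALSE)
  }

  leaving <- rep(FALSE, nC)
  nonDividing <- setdiff(seq_len(nC), scene$divisions$cell)
  if (scene$nLeaving > 0L && length(nonDividing) > 0L)
    leaving[sample(nonDividing, min(scene$nLeaving, length(nonDividing)))] <-
      TRUE

  stepPx <- function(comp) {
    s <- specs[[comp]]
    sampleStepLengths(1L, s$mdMean * scene$dt, s$mdSd * scene$dt) /
      scene$pixelSize
  }

  cells <- lapply(seq_len(nC), function(i) list(
    id = i, comp = compOf[i], frames = 0L, x = pos[i, 1], y = pos[i, 2],
    rad = rad[i], heading = stats::runif(1, -pi, pi), leaving = leaving[i],
    alive = TRUE, b = stats::runif(1, 0.65, 1), phi = stats::runif(1, 0, pi)))
  realizedDiv <- data.frame(cell = integer(0), daughter = integer(0),
                            frame = integer(0))

  curPos <- function() {
    alive <- vapply(cells, function(c) c$alive, logical(1))
    m <- t(vapply(cells, function(c) c(c$x[length(c$x)], c$y[length(c$y)],
                                       c$rad), numeric(3)))
    list(m = m, alive = alive)
  }

  for (f in seq_len(scene$nFrames - 1L)) {
    st <- curPos()
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      if (!cl$alive) next
      kap <- specs[[cl$comp]]$kappa
      accepted <- FALSE
      for (try in seq_len(12L)) {
        dth <- if (try <= 2L) rvonmises(1, 0, kap) else
          stats::runif(1, -pi, pi)
        th <- cl$heading + dth
        L <- stepPx(cl$comp)
        p <- c(cl$x[length(cl$x)] + L * cos(th),
               cl$y[length(cl$y)] + L * sin(th))
        if (!cl$leaving) {   # reflect residents at the borders
          lim <- c(scene$width - 1 - cl$rad, scene$height - 1 - cl$rad)
          for (d in 1:2) {
            if (p[d] < cl$rad) p[d] <- 2 * cl$rad - p[d]
            if (p[d] > lim[d]) p[d] <- 2 * lim[d] - p[d]
          }
        }
        others <- st$alive
        others[i] <- FALSE
        if (any(others)) {
          cur <- c(cl$x[length(cl$x)], cl$y[length(cl$y)])
          dd <- sqrt((st$m[others, 1] - p[1])^2 + (st$m[others, 2] - p[2])^2)
          d0 <- sqrt((st$m[others, 1] - cur[1])^2 +
                     (st$m[others, 2] - cur[2])^2)
          # contact avoidance; cells already in contact (fresh division
          # daughters) may move as long as they do not approach each other
          if (any(dd < pmin(st$m[others, 3] + cl$rad + 4, d0))) next
        }
        cl$heading <- th
        accepted <- TRUE
        break
      }
      if (!accepted) p <- c(cl$x[length(cl$x)], cl$y[length(cl$y)])  # pause
      if (cl$leaving &&
          (p[1] < 0 || p[1] > scene$width - 1 ||
           p[2] < 0 || p[2] > scene$height - 1)) {
        cl$alive <- FALSE          # center crossed the border: cell retired
      } else {
        cl$frames <- c(cl$frames, f)
        cl$x <- c(cl$x, p[1]); cl$y <- c(cl$y, p[2])
        st$m[i, 1:2] <- p
      }
      cells[[i]] <- cl
    }

    # scripted divisions at this frame
    div <- scene$divisions[scene$divisions$frame == f, , drop = FALSE]
    for (r in seq_len(nrow(div))) {
      pi_ <- div$cell[r]
      par <- cells[[pi_]]
      if (!par$alive || f != par$frames[length(par$frames)]) next
      par$rad <- par$rad / sqrt(2)
      did <- length(cells) + 1L
      dau <- list(id = did, comp = par$comp, frames = f,
                  x = par$x[length(par$x)], y = par$y[length(par$y)],
                  rad = par$rad, heading = par$heading + pi,
                  leaving = FALSE, alive = TRUE, b = par$b,
                  phi = stats::runif(1, 0, pi))
      cells[[pi_]] <- par
      cells[[did]] <- dau
      realizedDiv <- rbind(realizedDiv,
                           data.frame(cell = pi_, daughter = did, frame = f))
    }
  }

  tracks <- lapply(cells, function(cl)
    track(cl$id, data.frame(frame = cl$frames, x = cl$x, y = cl$y)))
  centroidSets <- lapply(seq_len(scene$nFrames) - 1L, function(f) {
    pm <- do.call(rbind, lapply(cells, function(cl) {
      k <- match(f, cl$frames)
      if (is.na(k)) NULL else c(cl$x[k], cl$y[k])
    }))
    if (is.null(pm)) pm <- matrix(numeric(0), 0L, 2L)
    centroidSet(pm, frameIndex = f)
  })
  list(tracks = tracks, centroidSets = centroidSets, cells = cells,
       divisions = realizedDiv, scene = scene)
}

#' Render a ground-truth population as an image sequence
#'
#' Draws each visible cell as an ellipse filled with high-variance smoothed
#' texture (bright and dark grains emulating DIC shear lobes) on a smooth
#' background with additive Gaussian noise and an optional linear
#' illumination ramp; intensities are clipped to [0, 1].
#'
#' @param truth result of [generatePopulation()].
#' @param seed optional seed for the rendering noise (defaults to the scene
#'   seed).
#' @return list of [ImageFrame-class] objects.
#' @export
renderSequence <- function(truth, seed = NULL) {
  scene <- truth$scene
  set.seed(if (is.null(seed)) scene$seed + 1L else seed)
  H <- scene$height; W <- scene$width
  ramp <- if (scene$rampAmplitude > 0)
    matrix(scene$rampAmplitude * (seq_len(W) / W - 0.5), H, W, byrow = TRUE)
  else 0
  frames <- vector("list", scene$nFrames)
  for (f in seq_len(scene$nFrames) - 1L) {
    img <- 0.5 + ramp +
      matrix(stats::rnorm(H * W, 0, scene$backgroundNoiseSd), H, W)
    for (cl in truth$cells) {
      k <- match(f, cl$frames)
      if (is.na(k)) next
      cx <- cl$x[k]; cy <- cl$y[k]
      # radius history: before its division frame a parent was sqrt(2) larger
      r <- cl$rad
      dv <- truth$divisions[truth$divisions$cell == cl$id, , drop = FALSE]
      if (nrow(dv) > 0L && f < dv$frame[1]) r <- r * sqrt(2)
      a <- r; b <- r * cl$b
      rows <- max(1L, floor(cy - a + 1)):min(H, ceiling(cy + a + 1))
      cols <- max(1L, floor(cx - a + 1)):min(W, ceiling(cx + a + 1))
      if (length(rows) < 2L || length(cols) < 2L) next
      dy <- (rows - 1) - cy
      dx <- (cols - 1) - cx
      DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
      DY <- matrix(dy, length(rows), length(cols))
      u <- (DX * cos(cl$phi) + DY * sin(cl$phi)) / a
      v <- (-DX * sin(cl$phi) + DY * cos(cl$phi)) / b
      inside <- u * u + v * v <= 1
      if (!any(inside)) next
      g <- boxSum(matrix(stats::runif(length(rows) * length(cols)),
                         length(rows), length(cols)), scene$grainSize)
      g <- (g - mean(g)) / max(stats::sd(g), 1e-12)
      patch <- img[rows, cols]
      patch[inside] <- 0.5 + scene$textureAmplitude * g[inside]
      img[rows, cols] <- patch
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    frames[[f + 1L]] <- imageFrame(img, pixelSize = scene$pixelSize,
                                   frameIndex = f)
  }
  frames
}
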