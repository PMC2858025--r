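#' Constant-velocity motion model
#'
#' Builds the [MotionModel-class] of the discrete Kalman filter. The state
#' transition advances the position by the current velocity over one frame
#' and keeps the velocity (constant-velocity assumption); the observation
#' extracts the position.
#'
#' Process noise defaults to the white-acceleration form: per coordinate, an
#' acceleration disturbance with standard deviation \code{accelSd}
#' (px/frame^2) enters position and velocity through G = (1/2, 1), giving
#' block entries Q_pos = s^2/4, Q_pos,vel = s^2/2, Q_vel = s^2. Measurement
#' noise defaults to \code{jitterSd^2 * I}, the pooled manual centroid click
#' jitter (5.14 px per coordinate) when no data-driven estimate is supplied.
#' Pass explicit \code{Q} and/or \code{R} (e.g. from
#' [estimateModelNoise()]) to override.
#'
#' @param accelSd per-coordinate acceleration noise SD, px/frame^2.
#' @param jitterSd per-coordinate measurement noise SD, px.
#' @param Q optional 4x4 process-noise covariance overriding \code{accelSd}.
#' @param R optional 2x2 measurement-noise covariance overriding
#'   \code{jitterSd}.
#' @return a [MotionModel-class].
#' @examples
#' m <- motionModel()
#' m@A %*% c(0, 0, 1, 1)  # advance by one frame
#' @export
motionModel <- function(accelSd = 1.0, jitterSd = 5.14, Q = NULL, R = NULL) {
  A <- diag(4)
  A[1, 3] <- 1; A[2, 4] <- 1
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  if (is.null(Q)) {
    s2 <- accelSd^2
    Q <- matrix(0, 4, 4)
    Q[1, 1] <- Q[2, 2] <- s2 / 4
    Q[3, 3] <- Q[4, 4] <- s2
    Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- s2 / 2
  }
  if (is.null(R)) R <- diag(jitterSd^2, 2)
  new("MotionModel", A = A, H = H, Q = symmetrize(Q), R = symmetrize(R))
}

#' Initialize a Kalman filter state from a first position
#'
#' The state starts at the measured position with zero velocity (no velocity
#' measurement exists). The initial covariance is \code{p0} on the position
#' entries and \code{velVar} on the velocity entries; the velocity variance
#' defaults to (2 x association gate)^2 so that the first few corrections can
#' establish the velocity.
#'
#' @param position numeric length-2 (x, y) in px.
#' @param model a [MotionModel-class] (unused by the initialization itself,
#'   accepted for a uniform call signature).
#' @param p0 initial position variance, px^2 (> 0).
#' @param velVar initial velocity variance, px^2/frame^2.
#' @return a [KFState-class].
#' @export
kfInit <- function(position, model = motionModel(), p0 = 26.4,
                   velVar = (2 * 25)^2) {
  stopifnot(length(position) == 2L, p0 > 0, velVar > 0)
  new("KFState", x = c(position[1], position[2], 0, 0),
      P = diag(c(p0, p0, velVar, velVar)), K = matrix(0, 4, 2))
}

#' Kalman filter prediction (a priori state)
#'
#' Advances the state one frame ahead under the constant-velocity model:
#' x- = A x, P- = A P A' + Q.
#'
#' @param state a [KFState-class].
#' @param model a [MotionModel-class].
#' @return the a-priori [KFState-class].
#' @export
kfPredict <- function(state, model) {
  x <- as.vector(model@A %*% state@x)
  P <- symmetrize(model@A %*% state@P %*% t(model@A) + model@Q)
  new("KFState", x = x, P = P, K = state@K)
}

#' Kalman filter correction (a posteriori state)
#'
#' Computes the optimized state estimate as a weighted difference between the
#' a-priori state and the actual (noisy) measurement. The weighting term
#' (gain) K = P- H' (H P- H' + R)^-1 is updated from the current prediction
#' quality and stored on the returned state; the covariance uses the standard
#' update (I - K H) P- followed by symmetrization.
#'
#' @param prior the a-priori [KFState-class] from [kfPredict()].
#' @param z numeric length-2 measurement (x, y) in px.
#' @param model a [MotionModel-class].
#' @param R optional 2x2 override of the measurement covariance for this
#'   correction (used for coasted pseudo-measurements).
#' @return the a-posteriori [KFState-class].
#' @export
kfCorrect <- function(prior, z, model, R = NULL) {
  if (is.null(R)) R <- model@R
  H <- model@H
  S <- H %*% prior@P %*% t(H) + R
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular innovation covariance (S = ",
         paste(signif(S, 4), collapse = " "), ")", call. = FALSE))
  K <- prior@P %*% t(H) %*% Sinv
  x <- as.vector(prior@x + K %*% (z - H %*% prior@x))
  P <- symmetrize((diag(4) - K %*% H) %*% prior@P)
  new("KFState", x = x, P = P, K = K)
}

#' Estimate motion-model noise from observed tracks
#'
#' Estimates the process-noise covariance Q empirically from tracks (e.g.
#' manually extracted ones): the residuals of a one-step constant-velocity
#' prediction are the discrete accelerations p[t+1] - 2 p[t] + p[t-1], and
#' their empirical 2x2 covariance C enters Q through the white-acceleration
#' structure (Q_pos = C/4, Q_pos,vel = C/2, Q_vel = C). The measurement
#' covariance is taken from a supplied per-coordinate centroid-jitter SD
#' (e.g. the replicate-click estimate) as R = jitterSd^2 I.
#'
#' @param tracks list of [Track-class] objects, each with >= 3 positions.
#' @param jitterSd per-coordinate centroid jitter SD in px (default the
#'   pooled manual click estimate, 5.14 px).
#' @return list with elements \code{Q} (4x4), \code{R} (2x2),
#'   \code{accelCov} (the raw 2x2 acceleration covariance) and \code{model},
#'   a ready-to-use [MotionModel-class].
#' @export
estimateModelNoise <- function(tracks, jitterSd = 5.14) {
  acc <- do.call(rbind, lapply(tracks, function(tr) {
    pts <- trackPoints(tr)
    if (nrow(pts) < 3L) return(NULL)
    cbind(diff(diff(pts$x)), diff(diff(pts$y)))
  }))
  if (is.null(acc) || nrow(acc) < 2L)
    stop("need at least one track with >= 3 positions", call. = FALSE)
  C <- stats::cov(acc)
  Q <- matrix(0, 4, 4)
  Q[1:2, 1:2] <- C / 4
  Q[1:2, 3:4] <- C / 2
  Q[3:4, 1:2] <- C / 2
  Q[3:4, 3:4] <- C
  R <- diag(jitterSd^2, 2)
  list(Q = symmetrize(Q), R = R, accelCov = C,
       model = motionModel(Q = Q, R = R))
}
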