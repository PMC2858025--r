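test_that("motionModel builds the documented constant-velocity matrices", {
  m <- motionModel(accelSd = 2, jitterSd = 3)
  # [TRIVIAL] A maps (x, y, vx, vy) -> (x+vx, y+vy, vx, vy)
  expect_equal(as.numeric(m@A %*% c(1, 2, 3, 4)), c(4, 6, 3, 4))
  expect_equal(m@H, rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  # [DERIVED] white-acceleration discretization with s^2 = 4:
  # Q_pos = s^2/4 = 1, Q_cross = s^2/2 = 2, Q_vel = s^2 = 4
  expect_equal(diag(m@Q), c(1, 1, 4, 4))
  expect_equal(m@Q[1, 3], 2)
  expect_equal(m@Q[2, 4], 2)
  expect_equal(m@R, diag(9, 2))
})

test_that("one predict/correct cycle matches hand-computed algebra", {
  # [DERIVED] scalar-friendly setup: diagonal P0, Q = 0, R = 4 I.
  m <- motionModel(Q = matrix(0, 4, 4), R = diag(4, 2))
  s0 <- kfInit(c(10, 20), m, p0 = 9)
  expect_equal(s0@x, c(10, 20, 0, 0))
  pr <- kfPredict(s0, m)
  expect_equal(pr@x[1:2], c(10, 20))
  # P- = A P A^T: var(x) = P_x + P_vx
  velVar <- s0@P[3, 3]
  expect_equal(pr@P[1, 1], 9 + velVar)
  # correction with z = (14, 20): K_x = P-/(P- + R)
  co <- kfCorrect(pr, c(14, 20), m)
  kx <- (9 + velVar) / (9 + velVar + 4)
  expect_equal(co@x[1], 10 + kx * 4, tolerance = 1e-10)
  expect_equal(co@x[2], 20, tolerance = 1e-10)
  # posterior variance (1,1) = (1 - K) P-
  expect_equal(co@P[1, 1], (1 - kx) * (9 + velVar), tolerance = 1e-8)
})

test_that("kalman filter state covariance stays symmetric PSD", {
  set.seed(71)
  m <- motionModel(accelSd = 1, jitterSd = 5.14)
  s <- kfInit(c(0, 0), m)
  for (i in 1:50) {
    s <- kfPredict(s, m)
    z <- s@x[1:2] + rnorm(2, 0, 5)
    s <- kfCorrect(s, z, m)
    expect_equal(s@P, t(s@P))
    ev <- eigen(s@P, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
  }
})

test_that("filter locks onto constant-velocity motion", {
  m <- motionModel(accelSd = 0.5, jitterSd = 2)
  s <- kfInit(c(0, 0), m)
  for (f in 1:40) {
    s <- kfPredict(s, m)
    s <- kfCorrect(s, c(3 * f, -2 * f), m)
  }
  expect_equal(s@x[3], 3, tolerance = 0.05)
  expect_equal(s@x[4], -2, tolerance = 0.05)
  expect_equal(s@x[1], 120, tolerance = 0.5)
})

test_that("filtering reduces position error on noisy tracks", {
  set.seed(72)
  m <- motionModel(accelSd = 1, jitterSd = 5)
  n <- 80
  truth <- cbind(50 + cumsum(rep(2, n)), 50 + cumsum(rep(1.5, n)))
  noisy <- truth + matrix(rnorm(2 * n, 0, 5), n, 2)
  s <- kfInit(noisy[1, ], m)
  est <- noisy
  for (f in 2:n) {
    s <- kfPredict(s, m)
    s <- kfCorrect(s, noisy[f, ], m)
    est[f, ] <- s@x[1:2]
  }
  burn <- 11:n
  rmse <- function(a) sqrt(mean((a[burn, ] - truth[burn, ])^2))
  expect_lt(rmse(est), 0.8 * rmse(noisy))
})

test_that("estimateModelNoise sets R from jitter and Q from accelerations", {
  tr <- lineTrack(1L, 40, c(0, 0), c(2, 1))
  est <- estimateModelNoise(list(tr), jitterSd = 4)
  expect_equal(est$R, diag(16, 2))
  # Q from second differences of straight tracks is ~0
  expect_lt(max(abs(est$accelCov)), 1e-10)
  expect_error(estimateModelNoise(list(), jitterSd = 4), "3 positions")
})
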