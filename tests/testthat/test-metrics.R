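test_that("meanDisplacement matches hand-computed values", {
  # [DERIVED] steps (0,0)->(3,4)->(3,4): distances 5 and 0 px -> 7.5 um and
  # 0 um over 15 min each -> MD = (0.5 + 0)/2 = 0.25 um/min
  tr <- track(1, cbind(x = c(0, 3, 3), y = c(0, 4, 4)))
  expect_equal(meanDisplacement(tr), 0.25)
  # unit handling: doubling pixel size doubles MD, doubling dt halves it
  expect_equal(meanDisplacement(tr, pixelSize = 3), 0.5)
  expect_equal(meanDisplacement(tr, dt = 30), 0.125)
  expect_error(meanDisplacement(track(1, cbind(x = 1, y = 1))), "2 points")
})

test_that("MD is invariant under rigid motions of the track", {
  set.seed(91)
  pts <- cbind(x = cumsum(rnorm(30)), y = cumsum(rnorm(30)))
  md0 <- meanDisplacement(track(1, pts))
  # translation
  expect_equal(meanDisplacement(track(1, pts + 100)), md0)
  # rotation by 37 degrees
  th <- 37 * pi / 180
  rot <- pts %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  colnames(rot) <- c("x", "y")
  expect_equal(meanDisplacement(track(1, rot)), md0)
})

test_that("averageMeanDisplacement averages per-track MDs unweighted", {
  # [DERIVED] MDs 0.2 (2 px/step) and 0.4 (4 px/step): AMD 0.3 regardless
  # of track lengths
  t1 <- track(1, cbind(x = c(0, 2), y = c(0, 0)))
  t2 <- track(2, cbind(x = c(0, 4, 8, 12), y = c(0, 0, 0, 0)))
  st <- averageMeanDisplacement(list(t1, t2))
  expect_equal(amd(st), 0.3)
  expect_equal(sort(perTrackMD(st)$md), c(0.2, 0.4))
  expect_equal(st@sd, sd(c(0.2, 0.4)))
})

test_that("smoothTrack equals a hand moving average with shrinking ends", {
  v <- c(0, 10, 0, 10, 0, 10, 0)
  tr <- track(1, cbind(x = v, y = rep(0, 7)))
  sm <- trackPoints(smoothTrack(tr, window = 5))
  # [DERIVED] centered windows: sizes 1,3,5,5,5,3,1
  expect_equal(sm$x, c(0, 10/3, 4, 6, 4, 10/3, 0))
  expect_equal(sm$y, rep(0, 7))
  expect_equal(sm$frame, trackPoints(tr)$frame)
})

test_that("smoothing never increases MD on random noisy tracks", {
  set.seed(92)
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    tr <- track(1, cbind(x = cumsum(rnorm(n, 0, 2)) + rnorm(n, 0, 3),
                         y = cumsum(rnorm(n, 0, 2)) + rnorm(n, 0, 3)))
    expect_lte(meanDisplacement(smoothTrack(tr)),
               meanDisplacement(tr) + 1e-12)
  }
})

test_that("cellDetectionRate counts one-to-one matches within the radius", {
  truth <- list(centroidSet(cbind(x = c(10, 50), y = c(10, 50)), 0L))
  # both true cells near one detection: only one can be explained
  det1 <- list(centroidSet(cbind(x = 12, y = 12), 0L))
  expect_equal(cellDetectionRate(det1, truth, matchRadius = 100)$perFrame,
               0.5)
  det2 <- list(centroidSet(cbind(x = c(12, 48), y = c(8, 53)), 0L))
  expect_equal(cellDetectionRate(det2, truth)$perFrame, 1)
  # out of radius: no match
  det3 <- list(centroidSet(cbind(x = 500, y = 500), 0L))
  expect_equal(cellDetectionRate(det3, truth)$perFrame, 0)
})

test_that("evaluateTracks applies the strict validity criterion", {
  n <- 11L
  ref1 <- lineTrack(1L, n, c(50, 50), c(5, 0))
  ref2 <- lineTrack(2L, n, c(50, 200), c(5, 0))
  # auto 1 follows ref1 exactly; auto 2 follows ref2 but misses two frames
  auto1 <- ref1
  p2 <- trackPoints(ref2)[1:(n - 2), ]
  auto2 <- track(12L, p2)
  ev <- evaluateTracks(list(auto1, auto2), list(ref1, ref2),
                       matchRadius = 10)
  expect_equal(ev@correctTracks, 1L)
  expect_equal(ev@totalTracks, 2L)
  expect_equal(ev@percentCorrect, 50)
  expect_equal(ev@lostOrDeleted, 1L)  # ref2's final frame is uncovered
  expect_equal(ev@swapErrors, 0L)
})

test_that("evaluateTracks counts identity changes as swap errors", {
  n <- 11L
  ref1 <- lineTrack(1L, n, c(50, 50), c(5, 0))
  ref2 <- lineTrack(2L, n, c(50, 80), c(5, 0))
  # an auto track that jumps from ref1 to ref2 at frame 5
  p1 <- trackPoints(ref1); p2 <- trackPoints(ref2)
  mix <- rbind(p1[1:5, ], p2[6:n, ])
  auto <- track(21L, mix)
  ev <- evaluateTracks(list(auto), list(ref1, ref2), matchRadius = 10)
  expect_equal(ev@swapErrors, 1L)
  expect_equal(ev@correctTracks, 0L)
})
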