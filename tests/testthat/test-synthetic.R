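test_that("generateTrack step lengths converge to the requested moments", {
  # one long track: sample mean/SD of step speeds within 2% at 1e4 steps
  tr <- generateTrack(10001, mdMean = 0.62, mdSd = 0.41, seed = 111L)
  pts <- trackPoints(tr)
  sp <- sqrt(diff(pts$x)^2 + diff(pts$y)^2) * 1.5 / 15
  expect_equal(mean(sp), 0.62, tolerance = 0.02)
  expect_equal(sd(sp), 0.41, tolerance = 0.02)
})

test_that("momentMatch reproduces the moments exactly", {
  tr <- generateTrack(63, mdMean = 0.181, mdSd = 0.213, momentMatch = TRUE,
                      seed = 112L)
  pts <- trackPoints(tr)
  sp <- sqrt(diff(pts$x)^2 + diff(pts$y)^2) * 1.5 / 15
  expect_equal(mean(sp), 0.181, tolerance = 1e-10)
  expect_equal(sd(sp), 0.213, tolerance = 1e-10)
  expect_true(all(sp >= 0))
  expect_equal(meanDisplacement(tr), 0.181, tolerance = 1e-10)
})

test_that("generateTrack is deterministic given a seed", {
  a <- generateTrack(30, mdMean = 1, mdSd = 0.5, kappa = 4, seed = 113L)
  b <- generateTrack(30, mdMean = 1, mdSd = 0.5, kappa = 4, seed = 113L)
  expect_equal(trackPoints(a), trackPoints(b))
})

test_that("persistent headings shorten with smoothing less than random ones", {
  # kappa controls directional persistence: net displacement over the same
  # number of equal-speed steps grows with kappa
  net <- vapply(c(0, 8), function(k) {
    tr <- generateTrack(200, mdMean = 1, mdSd = 0.01, kappa = k, seed = 114L)
    pts <- trackPoints(tr)
    sqrt((pts$x[200] - pts$x[1])^2 + (pts$y[200] - pts$y[1])^2)
  }, numeric(1))
  expect_gt(net[2], 3 * net[1])
})

test_that("generatePopulation respects the scene contract", {
  scene <- sceneSpec(height = 400, width = 500, nFrames = 10, nCells = 6,
                     nLeaving = 1, divisions = data.frame(cell = 2L,
                                                          frame = 5L),
                     seed = 115L)
  truth <- generatePopulation(scene,
    list(list(mdMean = 0.6, mdSd = 0.4, kappa = 0, weight = 1)))
  expect_length(truth$tracks, 7L)  # 6 cells + 1 division daughter
  expect_length(truth$centroidSets, 10L)
  # daughter track starts at the division frame at the parent position
  dau <- truth$tracks[[7]]
  dp <- trackPoints(dau)
  expect_equal(min(dp$frame), 5L)
  par <- trackPoints(truth$tracks[[2]])
  expect_equal(dp$x[1], par$x[par$frame == 5])
  expect_equal(dp$y[1], par$y[par$frame == 5])
  # all positions inside the frame
  for (tr in truth$tracks) {
    p <- trackPoints(tr)
    expect_true(all(p$x >= 0 & p$x <= 499 & p$y >= 0 & p$y <= 399))
  }
  # centroid sets agree with the track points
  for (f in 0:9) {
    n <- sum(vapply(truth$tracks, function(tr)
      f %in% trackPoints(tr)$frame, logical(1)))
    expect_equal(nCentroids(truth$centroidSets[[f + 1]]), n)
  }
})

test_that("rendered cells are textured against a clean background", {
  scene <- sceneSpec(height = 200, width = 200, nFrames = 2, nCells = 1,
                     nLeaving = 0, radiusRange = c(20, 25), seed = 116L)
  truth <- generatePopulation(scene,
    list(list(mdMean = 0.6, mdSd = 0.4, kappa = 0, weight = 1)))
  frames <- renderSequence(truth, seed = 117L)
  img <- pixels(frames[[1]])
  c0 <- centroids(truth$centroidSets[[1]])[1, ]
  cx <- round(c0[1]) + 1L; cy <- round(c0[2]) + 1L
  inside <- as.vector(img[(cy - 8):(cy + 8), (cx - 8):(cx + 8)])
  # background patch away from the cell
  bx <- if (cx > 100) 20 else 180
  outside <- as.vector(img[10:40, (bx - 15):(bx + 15)])
  expect_gt(sd(inside), 3 * sd(outside))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("benchmarkScene fixes the documented study conditions", {
  bm <- benchmarkScene()
  expect_equal(bm$scene$nCells, 80L)
  expect_equal(bm$scene$nFrames, 60L)
  expect_equal(bm$scene$height, 1024L)
  expect_equal(bm$scene$width, 1344L)
  w <- vapply(bm$specs, function(s) s$weight, numeric(1))
  expect_equal(sum(w), 80)
  expect_equal(nrow(bm$scene$divisions), 3L)
})
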