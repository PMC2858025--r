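test_that("localEntropy matches a naive sliding-window oracle", {
  set.seed(11)
  img <- matrix(runif(30 * 25), 30, 25)
  ent <- localEntropy(imageFrame(img), window = 5L, nBins = 8L)
  for (rc in list(c(1, 1), c(3, 7), c(15, 12), c(30, 25), c(30, 1))) {
    expect_equal(ent[rc[1], rc[2]],
                 naiveEntropyAt(img, rc[1], rc[2], 5L, 8L),
                 tolerance = 1e-10)
  }
})

test_that("localEntropy separates textured from uniform areas", {
  # [DERIVED] constant region: single occupied bin -> entropy exactly 0;
  # uniform random texture in a 9x9 window approaches log2(nBins) bits
  set.seed(21)
  img <- matrix(0.5, 60, 60)
  img[20:40, 20:40] <- runif(21 * 21)
  ent <- localEntropy(imageFrame(img), window = 9L, nBins = 16L)
  expect_equal(ent[5, 5], 0)
  expect_gt(ent[30, 30], 3)
  expect_gt(min(ent[25:35, 25:35]), max(ent[1:10, 1:10]))
})

test_that("coarseRegionMask finds the textured object and fills holes", {
  set.seed(31)
  img <- matrix(0.5, 80, 80)
  img[25:55, 25:55] <- 0.5 + (runif(31 * 31) - 0.5) * 0.6
  ent <- localEntropy(imageFrame(img))
  mask <- coarseRegionMask(ent, minArea = 50L)
  expect_true(mask[40, 40])
  expect_false(mask[5, 5])
  # a blank frame yields an empty mask thanks to the minimum-entropy floor
  blank <- matrix(0.5, 80, 80)
  entB <- localEntropy(imageFrame(blank))
  expect_false(any(coarseRegionMask(entB, minArea = 50L)))
})

test_that("detailMask is two-sided around the local mean", {
  img <- matrix(0.5, 40, 40)
  img[10, 10] <- 0.9   # brighter than local mean
  img[30, 30] <- 0.1   # darker than local mean
  m <- detailMask(imageFrame(img), window = 15L, offset = 0.05)
  expect_true(m[10, 10])
  expect_true(m[30, 30])
  expect_false(m[20, 20])
})

test_that("extractCentroids uses 8-connectivity and area filtering", {
  mask <- matrix(FALSE, 20, 20)
  # two blobs touching only diagonally: one 8-connected component
  mask[5:7, 5:7] <- TRUE
  mask[8:10, 8:10] <- TRUE
  cs <- extractCentroids(mask, frameIndex = 0L, minArea = 5L)
  expect_equal(nCentroids(cs), 1L)
  # [DERIVED] centroid of the union of the two 3x3 blocks: mean index 6.5
  # (1-based rows/cols 5..10 symmetric) -> 0-based 6.5
  expect_equal(unname(centroids(cs)[1, ]), c(6.5, 6.5))
  # small blob dropped by minArea
  mask2 <- matrix(FALSE, 20, 20)
  mask2[3, 3] <- TRUE
  mask2[10:12, 10:12] <- TRUE
  cs2 <- extractCentroids(mask2, frameIndex = 1L, minArea = 5L)
  expect_equal(nCentroids(cs2), 1L)
  expect_equal(unname(centroids(cs2)[1, ]), c(10, 10))
})

test_that("propagateAndFilter keeps only centroids on the region mask", {
  region <- matrix(FALSE, 30, 30)
  region[10:20, 10:20] <- TRUE
  cur <- centroidSet(cbind(x = c(15, 2), y = c(15, 2)), frameIndex = 1L)
  prev <- centroidSet(cbind(x = c(12, 25), y = c(12, 25)), frameIndex = 0L)
  out <- propagateAndFilter(cur, prev, region)
  pts <- centroids(out)
  expect_equal(nrow(pts), 2L)  # (15,15) current + (12,12) propagated
  expect_true(all(pts[, 1] %in% c(15, 12)))
})

test_that("mergeAndShift merges clusters below the radius and is idempotent", {
  pts <- cbind(x = c(0, 3, 100, 103, 200), y = c(0, 4, 0, 4, 0))
  m <- mergeAndShift(centroidSet(pts, 0L), mergeRadius = 10)
  res <- centroids(m)
  expect_equal(nrow(res), 3L)
  # [DERIVED] cluster means: (1.5, 2), (101.5, 2), (200, 0)
  expect_equal(sort(res[, 1]), c(1.5, 101.5, 200))
  # invariant: all pairwise distances >= radius after merging
  d <- as.matrix(dist(res))
  expect_true(all(d[upper.tri(d)] >= 10))
  # idempotence
  m2 <- mergeAndShift(m, mergeRadius = 10)
  expect_equal(centroids(m2), centroids(m))
})

test_that("mergeAndShift min-distance invariant holds on random inputs", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    cs <- centroidSet(cbind(x = runif(n, 0, 100), y = runif(n, 0, 100)), 0L)
    r <- runif(1, 2, 25)
    out <- centroids(mergeAndShift(cs, mergeRadius = r))
    if (nrow(out) > 1L) {
      d <- as.matrix(dist(out))
      expect_true(all(d[upper.tri(d)] >= r - 1e-9))
    }
  }
})

test_that("segmentFrame recovers centroids of rendered cells", {
  scene <- sceneSpec(height = 200, width = 260, nFrames = 2, nCells = 3,
                     nLeaving = 0, seed = 51L)
  truth <- generatePopulation(scene,
    list(list(mdMean = 0.6, mdSd = 0.4, kappa = 0, weight = 1)))
  frames <- renderSequence(truth, seed = 52L)
  seg <- segmentFrame(frames[[1]])
  truePts <- centroids(truth$centroidSets[[1]])
  segPts <- centroids(seg)
  expect_gte(nrow(segPts), nrow(truePts))
  for (i in seq_len(nrow(truePts))) {
    d <- sqrt((segPts[, 1] - truePts[i, 1])^2 +
              (segPts[, 2] - truePts[i, 2])^2)
    expect_lt(min(d), 15)
  }
})
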