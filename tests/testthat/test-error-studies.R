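test_that("pooledCentroidSd matches a hand-pooled example", {
  # [DERIVED] two frames of two clicks each; centered residuals are
  # {-1, 1, 0, 0} and {0, 0, -1, 1}: SSR = 4 over 2 frames x 2 coords x
  # (2 - 1) = 4 degrees of freedom -> pooled SD 1 px = 1.5 um
  reps <- list(rbind(c(0, 0), c(2, 0)), rbind(c(1, 1), c(1, 3)))
  expect_equal(pooledCentroidSd(reps, pixelSize = 1.5), 1.5)
  expect_error(pooledCentroidSd(list(rbind(c(1, 1)))), "2 replicate")
})

test_that("pooledCentroidSd recovers a known jitter SD", {
  set.seed(101)
  sigmaPx <- 3
  reps <- lapply(1:200, function(i)
    cbind(rnorm(10, 50, sigmaPx), rnorm(10, 80, sigmaPx)))
  est <- pooledCentroidSd(reps, pixelSize = 1.5)
  expect_equal(est, 1.5 * sigmaPx, tolerance = 0.03)
})

test_that("imposeClickNoise preserves frames and adds the right jitter", {
  tr <- lineTrack(1L, 50, c(100, 100), c(2, 1))
  reps <- imposeClickNoise(tr, sigmaUm = 6, nReplicates = 100, seed = 5L)
  expect_length(reps, 100)
  ref <- trackPoints(tr)
  resid <- unlist(lapply(reps, function(r) {
    p <- trackPoints(r)
    expect_equal(p$frame, ref$frame)
    c(p$x - ref$x, p$y - ref$y)
  }))
  # sigma 6 um = 4 px at 1.5 um/px
  expect_equal(sd(resid), 4, tolerance = 0.03)
  expect_equal(mean(resid), 0, tolerance = 0.1)
  # sigma 0 reproduces the input
  same <- imposeClickNoise(tr, 0, 2, seed = 6L)
  expect_equal(trackPoints(same[[1]]), ref)
})

test_that("noisy AMD of a stationary cell approaches sigma*sqrt(pi)/dt", {
  # [DERIVED] for a stationary cell, each apparent step is the norm of a
  # bivariate normal difference: mean sigma*sqrt(pi)/dt in um/min
  z <- track(1L, cbind(x = rep(0, 63), y = rep(0, 63)))
  for (sUm in c(3, 6)) {
    reps <- imposeClickNoise(z, sUm, 300, seed = 7L)
    got <- amd(averageMeanDisplacement(reps))
    expect_equal(got, sUm * sqrt(pi) / 15, tolerance = 0.02)
  }
})

test_that("clickNoiseStudy output grid is complete and monotone in sigma", {
  tr <- generateTrack(63, mdMean = 0.6, mdSd = 0.4, momentMatch = TRUE,
                      seed = 8L)
  res <- clickNoiseStudy(list(cell = tr), sigmasUm = c(3, 6),
                         nReplicates = 50, seed = 9L)
  expect_equal(nrow(res), 2L)
  expect_equal(res$cell_label, c("cell", "cell"))
  expect_equal(res$original_md, rep(meanDisplacement(tr), 2))
  # apparent speed grows with noise and always exceeds the original
  expect_lt(res$amd_noisy[1], res$amd_noisy[2])
  expect_true(all(res$percent_of_original > 100))
  # smoothing reduces the noisy AMD
  expect_true(all(res$amd_smoothed < res$amd_noisy))
})

test_that("subset quantiles match exhaustive enumeration for small n", {
  # population of 8 tracks with known MDs; k = 5 -> 56 subsets, enumerable
  set.seed(102)
  mds <- c(0.1, 0.2, 0.35, 0.5, 0.8, 1.1, 1.5, 2.0)
  tracks <- lapply(seq_along(mds), function(i)
    track(i, cbind(x = c(0, mds[i] * 15 / 1.5), y = c(0, 0))))
  allAmd <- apply(combn(8, 5), 2, function(ix) mean(mds[ix]))
  res <- subsetResamplingStudy(tracks, k = 5, iterations = 20000, seed = 10L)
  expect_equal(res$populationAmd, mean(mds))
  gap <- max(diff(sort(allAmd)))
  for (q in c(0.025, 0.25, 0.5, 0.75, 0.975)) {
    expect_lt(abs(res$quantiles[[paste0(q * 100, "%")]] -
                  quantile(allAmd, q)[[1]]), gap + 1e-9)
  }
  expect_equal(mean(res$amdDistribution), mean(allAmd), tolerance = 0.01)
  expect_error(subsetResamplingStudy(tracks, k = 9), "exceeds")
})

test_that("pairwiseAgreement counts common selections per rater pair", {
  # [DERIVED] intersections: {2,3}, {3}, {3,4} -> counts 2,1,2
  res <- pairwiseAgreement(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(sort(res$pairCounts), c(1, 2, 2))
  expect_equal(res$mean, 5 / 3)
  expect_error(pairwiseAgreement(list(1:3)), "2 raters")
})
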