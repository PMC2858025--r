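test_that("monitorDecision implements the three monitoring outcomes", {
  cfg <- trackingConfig()
  # within gate: accepted
  d <- monitorDecision(c(500, 500), 0L, 10, 30L, 1344L, 1024L, cfg)
  expect_equal(d$kind, "accepted")
  # no measurement, few misses, mid-field: coast
  d <- monitorDecision(c(500, 500), 1L, NA, 30L, 1344L, 1024L, cfg)
  expect_equal(d$kind, "missing_coasted")
  # too many misses mid-field: terminated lost
  d <- monitorDecision(c(500, 500), cfg$maxMissing, NA, 30L, 1344L, 1024L,
                       cfg)
  expect_equal(d$kind, "terminated")
  expect_equal(d$status, "terminated_lost")
  # too many misses near border: left view
  d <- monitorDecision(c(5, 500), cfg$maxMissing, NA, 30L, 1344L, 1024L, cfg)
  expect_equal(d$status, "left_view")
  # recovery gate: distance above the base gate is accepted while coasting
  d <- monitorDecision(c(500, 500), 2L, cfg$gate + 1.5 * cfg$gateGrowth,
                       30L, 1344L, 1024L, cfg)
  expect_equal(d$kind, "accepted")
  d <- monitorDecision(c(500, 500), 0L, cfg$gate + 1, 30L, 1344L, 1024L, cfg)
  expect_equal(d$kind, "missing_coasted")
})

test_that("tracking follows crossing paths without swaps", {
  # two cells whose x-paths cross at frame 10; minimum separation 60 px
  # stays above the association gate
  n <- 21L
  t1 <- lineTrack(1L, n, c(100, 100), c(10, 5))
  t2 <- lineTrack(2L, n, c(300, 160), c(-10, 5))
  sets <- trackSets(list(t1, t2), 0:(n - 1))
  tks <- trackSequence(sets, width = 500, height = 400)
  expect_equal(length(tks), 2L)
  ev <- evaluateTracks(tks, list(t1, t2), matchRadius = 10)
  expect_equal(ev@swapErrors, 0L)
  expect_equal(ev@correctTracks, 2L)
})

test_that("tracked positions equal measurements for clean input", {
  n <- 15L
  tr <- lineTrack(1L, n, c(50, 60), c(4, -2))
  sets <- trackSets(list(tr), 0:(n - 1))
  tks <- trackSequence(sets, width = 300, height = 300)
  expect_equal(length(tks), 1L)
  pts <- trackPoints(tks[[1]])
  ref <- trackPoints(tr)
  expect_equal(pts$frame, ref$frame)
  expect_equal(pts$x, ref$x)
  expect_equal(pts$y, ref$y)
  expect_equal(trackStatus(tks[[1]]), "completed")
})

test_that("every measurement is claimed by exactly one track point", {
  # conservation: with clean, well-separated cells, the union of track
  # points per frame equals the measurement set
  set.seed(81)
  n <- 12L
  trs <- lapply(1:5, function(i)
    lineTrack(i, n, c(100 + 150 * i, 200), c(runif(1, -5, 5),
                                             runif(1, -5, 5))))
  sets <- trackSets(trs, 0:(n - 1))
  tks <- trackSequence(sets, width = 1200, height = 500)
  for (f in 0:(n - 1)) {
    pm <- do.call(rbind, lapply(tks, function(tr) {
      pts <- trackPoints(tr)
      r <- pts[pts$frame == f, c("x", "y")]
      if (nrow(r)) as.numeric(r) else NULL
    }))
    meas <- centroids(sets[[f + 1]])
    expect_equal(nrow(pm), nrow(meas))
    expect_equal(pm[order(pm[, 1]), ], unname(meas[order(meas[, 1]), ]))
  }
})

test_that("coasting bridges isolated missing measurements", {
  n <- 15L
  tr <- lineTrack(1L, n, c(100, 100), c(6, 0))
  sets <- trackSets(list(tr), 0:(n - 1))
  # remove the cell's measurement at frame 7 (mid-field)
  sets[[8]] <- centroidSet(matrix(numeric(0), 0, 2), frameIndex = 7L)
  tks <- trackSequence(sets, width = 400, height = 300)
  expect_equal(length(tks), 1L)
  pts <- trackPoints(tks[[1]])
  expect_equal(nrow(pts), n)  # coasted point fills frame 7
  expect_equal(trackStatus(tks[[1]]), "completed")
  ev <- trackEvents(tks[[1]])
  expect_true("missing_coasted" %in% ev$kind)
})

test_that("a cell entering the view mid-sequence yields a left_view track", {
  # under backward tracking, a cell that appears at the border mid-sequence
  # (forward time) loses its measurements near the border during the
  # backward pass and must be classified left_view, not terminated_lost
  sets <- lapply(0:14, function(f) {
    if (f >= 8) centroidSet(rbind(c(10 + 12 * (f - 8), 150)), frameIndex = f)
    else centroidSet(matrix(numeric(0), 0, 2), frameIndex = f)
  })
  # add a resident cell so every frame has content
  resident <- lineTrack(9L, 15L, c(160, 260), c(2, 0))
  rs <- trackSets(list(resident), 0:14)
  for (i in 1:15)
    sets[[i]] <- centroidSet(rbind(centroids(sets[[i]]),
                                   centroids(rs[[i]])), frameIndex = i - 1L)
  tks <- trackSequence(sets, width = 320, height = 300,
                       config = trackingConfig(borderMargin = 40))
  statuses <- vapply(tks, trackStatus, character(1))
  expect_true("completed" %in% statuses)
  expect_true("left_view" %in% statuses)
  leaver <- tks[[which(statuses == "left_view")[1]]]
  # its real points cover frames 8..14 (plus coasted fill-ins below 8)
  expect_true(all(8:14 %in% trackPoints(leaver)$frame))
  ev <- trackEvents(leaver)
  expect_equal(ev$detail[ev$kind == "terminated"], "left_view")
})

test_that("a division is detected as a mitosis merge near the split frame", {
  # parent moves right; at frame 8 two daughters separate
  n <- 16L
  parent <- c(200, 200)
  mk <- function(f) {
    if (f < 8) rbind(parent + c(6 * f, 0))
    else rbind(parent + c(6 * 8 + 5 * (f - 8), -14 * (f - 7)),
               parent + c(6 * 8 + 5 * (f - 8), 14 * (f - 7)))
  }
  sets <- lapply(0:(n - 1), function(f) centroidSet(mk(f), frameIndex = f))
  tks <- trackSequence(sets, width = 600, height = 500)
  statuses <- vapply(tks, trackStatus, character(1))
  expect_equal(sum(statuses == "merged_mitosis"), 1L)
  merged <- tks[[which(statuses == "merged_mitosis")]]
  ev <- trackEvents(merged)
  mitFrame <- ev$frame[ev$kind == "mitosis_merge"]
  expect_lte(abs(mitFrame - 8L), 1L)
})

test_that("track frame indices are contiguous and within the sequence", {
  set.seed(82)
  n <- 10L
  trs <- lapply(1:4, function(i)
    lineTrack(i, n, c(80 * i + 50, 150), c(rnorm(1, 0, 3), rnorm(1, 0, 3))))
  sets <- trackSets(trs, 0:(n - 1))
  tks <- trackSequence(sets, width = 600, height = 300)
  for (tr in tks) {
    f <- trackPoints(tr)$frame
    expect_equal(f, seq(min(f), max(f)))
    expect_gte(min(f), 0L)
    expect_lte(max(f), n - 1L)
  }
})
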