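# celltracker

Fully automated identification and tracking of unstained cells in time-lapse
microscopy image sequences, with migration statistics and a quantitative
treatment of the errors of the manual tracking it replaces.

## The problem

Measuring how fast cells migrate traditionally means a person clicking on the
same cells frame after frame. That is slow, so only a handful of cells get
tracked — and the two resulting error sources are substantial:

* **Click noise.** Repeated clicks on the same cell scatter around its true
  centroid. Apparent per-frame steps add this jitter in quadrature to the
  true motion, so slow cells can appear several times faster than they are.
* **Subset selection.** A hand-picked subset of a few cells can
  misrepresent the population's average speed considerably.

`celltracker` automates the whole measurement — every visible cell, every
frame — and ships the noise-injection and resampling studies that quantify
both manual error sources.

## The method

1. **Entropy-based segmentation.** Unstained cells match the background in
   mean intensity but not in texture. Local Shannon entropy of the intensity
   histogram separates textured cell regions from smooth background; a
   second, local-intensity pass inside those regions finds cell detail, and
   fragment centroids are merged into one centroid per cell.
2. **Backward Kalman tracking.** Centroids are linked from the last frame to
   the first with a constant-velocity Kalman filter and iterative unique
   nearest neighbor association. Running time backwards makes cell divisions
   appear as simple track merges and restricts new tracks to the image
   border, where cells genuinely enter the view.
3. **Monitoring.** Each track is accepted, coasted over missed detections,
   merged at a mitosis, or terminated (lost vs. left the field of view) by
   explicit distance-gate rules.
4. **Migration statistics.** Per-track mean displacement (MD) and population
   average mean displacement (AMD) in micrometers per minute.

A synthetic scene generator with exact ground truth (textured cells, contact
avoidance, scripted divisions, cells leaving the view) and evaluation
metrics (per-frame detection rate, strict track validity, swap counts) close
the loop for end-to-end validation. See the vignette
(`vignettes/celltracker-methods.Rmd`) for the full model and parameter
rationale.

## Worked example

Generate a small synthetic scene, render it, and run the full pipeline:

```r
library(celltracker)

scene  <- sceneSpec(height = 400, width = 500, nFrames = 15, nCells = 8,
                    nLeaving = 0, seed = 42L)
truth  <- generatePopulation(scene)
frames <- renderSequence(truth, seed = 43L)

segs <- segmentSequence(frames)
segs[[1]]
#> CentroidSet: 8 centroids in frame 0
#>           x      y
#> [1,]  83.76 191.34
#> [2,]  93.30 361.99
#> [3,] 255.25 160.17
#> [4,] 276.70 339.06
#> [5,] 327.49  40.95
#> ...

tracks <- trackSequence(segs, width = 500, height = 400)
table(vapply(tracks, trackStatus, character(1)))
#> completed left_view
#>         8         1

evaluateTracks(tracks, truth$tracks)
#> TrackEvaluation
#>   detection rate median (min, max): 1 (1, 1)
#>   associations required: 112
#>   swap errors: 0
#>   lost or deleted: 0
#>   track detection (correct/total): 8/8 (100%)

full <- Filter(function(tr) nrow(trackPoints(tr)) == 15, tracks)
averageMeanDisplacement(full)
#> MigrationStats: 8 tracks, AMD = 0.5163 um/min (SD 0.357)
```

Real image sequences enter through `readSequence()` (TIFF/PNG directory or
multi-page TIFF); manual tracks in the ImageJ Manual Tracking CSV layout
through `readManualTracks()`. A command-line interface covering the whole
pipeline is installed at `system.file("scripts", "celltracker.R",
package = "celltracker")`.

## Error studies

```r
slow <- generateTrack(nFrames = 30, mdMean = 0.2, mdSd = 0.2,
                      momentMatch = TRUE, seed = 9L)
fast <- generateTrack(nFrames = 30, mdMean = 1.8, mdSd = 0.8,
                      momentMatch = TRUE, seed = 10L)
clickNoiseStudy(list(slow = slow, fast = fast), sigmasUm = c(3, 6),
                nReplicates = 100, seed = 11L)
#>   cell_label sigma_um original_md amd_noisy percent_of_original amd_smoothed
#> 1       slow        3         0.2  0.423203            211.6015    0.1349157
#> 2       slow        6         0.2  0.757602            378.8010    0.1959054
#> 3       fast        3         1.8  1.823700            101.3167    0.9566695
#> 4       fast        6         1.8  1.915709            106.4283    0.9677433
```

A slow cell under 6 um click noise appears almost four times faster than it
really is; a fast cell is barely affected. `subsetResamplingStudy()`
quantifies the second error source, and `pooledCentroidSd()` estimates the
click jitter itself from replicate click sets.

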