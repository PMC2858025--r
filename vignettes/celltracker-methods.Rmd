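---
title: "Automated cell identification and tracking: methods and parameters"
author: "celltracker package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cell identification and tracking: methods and parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltracker)
```

# Overview

`celltracker` implements a fully automated pipeline for identifying and
following unstained cells in time-lapse microscopy image sequences, and for
quantifying the error sources of the manual point-and-click tracking it
replaces. The pipeline has four stages:

1. **Segmentation** — per-frame extraction of cell centroids from
   texture (local entropy) rather than intensity, because unstained cells in
   DIC-like imaging have roughly the same mean brightness as the background
   but far higher local variation.
2. **Tracking** — linking centroids across frames with a discrete Kalman
   filter (constant-velocity motion model) and iterative unique nearest
   neighbor (UNN) data association, run *backwards* in time.
3. **Monitoring** — a per-track decision layer that accepts, coasts,
   merges (mitosis) or terminates tracks, making the tracker robust to
   missed detections, divisions and cells leaving the field of view.
4. **Migration statistics** — per-track mean displacement (MD) and the
   population average mean displacement (AMD), in micrometers per minute.

Alongside the pipeline the package ships a synthetic scene generator with
exact ground truth, evaluation metrics, and two error studies for manual
tracking (click-noise injection and subset resampling).

# Segmentation

A frame is segmented in two passes (`segmentFrame()`):

* **Coarse cell regions.** `localEntropy()` computes the Shannon entropy of
  the intensity histogram in a sliding window around every pixel
  (`entropyWindow = 9` px, `entropyBins = 16`; borders are handled by
  edge-inclusive symmetric reflection). Cell texture produces high entropy;
  smooth background produces low entropy. `coarseRegionMask()` thresholds
  the entropy map with Otsu's method, floored at
  `minRegionEntropy = 1.5` bits so that a frame of pure background — where
  Otsu would split noise into two halves — yields an empty mask. The mask is
  cleaned by morphological closing (`closeRadius = 5` px), hole filling and
  an area floor (`minRegionArea = 100` px).
* **Detail segmentation.** Within the coarse regions, `detailMask()` marks
  pixels deviating from their local mean (`detailWindow = 15` px) by more
  than `detailOffset = 0.05`, capturing the bright/dark shear lobes of each
  cell. Connected components of at least `minDetailArea = 5` px become
  candidate fragments.
* **Consolidation.** One cell usually yields several fragments;
  `mergeAndShift()` merges fragment centroids by single linkage within
  `mergeRadius = 20` px (about one cell radius) into one centroid per cell.
  `propagateAndFilter()` optionally stabilizes detections across adjacent
  frames. `segmentSequence()` applies all of this to every frame.

# Motion model and Kalman filter

The tracker models each cell with state $(x, y, v_x, v_y)$ under a
constant-velocity transition with white-acceleration process noise
(`motionModel()`): for acceleration SD $s$ per frame, the process covariance
has position variance $s^2/4$, velocity variance $s^2$ and covariance
$s^2/2$ per axis. The measurement is the centroid position with isotropic
noise `jitterSd = 5.14` px per coordinate — the pooled SD of repeated manual
clicks on the same cells, i.e. the tracker treats segmentation centroids as
at least as uncertain as human clicks. `kfInit()`, `kfPredict()` and
`kfCorrect()` implement the standard filter cycle; `estimateModelNoise()`
estimates the acceleration covariance from second differences of observed
tracks and the measurement covariance from a jitter SD, for data-driven
tuning.

# Backward tracking with UNN association

`trackSequence()` follows cells from the *last* frame to the first. Running
time backwards turns the two difficult track-management events into simple
ones:

* A cell **division** (one centroid becoming two, forward in time) appears
  backwards as two tracks converging onto one centroid — a *merge*, which
  needs no branching logic.
* A track may only **start** where a cell can genuinely appear. Backwards,
  appearance means a cell migrating into the field of view, so new tracks
  are seeded only from unmatched centroids within `borderMargin = 30` px of
  the frame edge (`nearBorder()`); interior unmatched centroids are treated
  as segmentation noise.

Per frame, every active track is advanced by `kfPredict()`. The association
anchor for a track is its **last determined position plus a damped velocity
extrapolation** (`velDamping = 0.6`): cells in a crowded field maneuver far
more sharply than their nominal directional persistence suggests (contact
deflections can turn the heading by 90 degrees or more within one frame),
so a full constant-velocity extrapolation can overshoot by several cell
diameters after a turn, while the damped anchor is never more than about
one step length from the cell. `unnAssociate()` then pairs anchors and
centroids by iteratively taking the globally closest remaining pair, so each
centroid is claimed by at most one track and each track gets at most one
centroid.

# Monitoring

Each association outcome passes `monitorDecision()`:

* **Accept** if the pair distance is within `gate = 40` px, widened by
  `gateGrowth = 20` px per consecutively missed frame — a coasting track's
  position uncertainty grows, so its acceptance region must grow for it to
  re-acquire its cell after an outlier step. The measurement is appended and
  the filter corrected.
* **Mitosis merge**: an unmatched track whose prediction lies within
  `mitosisGate = 25` px of a centroid already claimed by another track is
  ended with a `mitosis_merge` event (`detectMitosisMerges()`); the partner
  continues as the parent lineage. Only cleanly tracked candidates (no
  active miss streak) may merge, because a coasting track near a neighbor is
  a lost cell, not a division.
* **Coast**: an unmatched track substitutes its last determined position as
  a pseudo-measurement (corrected with the measurement covariance inflated
  by `coastRInflation = 100`, so coasting does not collapse the state
  covariance) for up to `maxMissing = 3` consecutive frames.
* **Terminate**: beyond the miss limit a track ends — `left_view` if its
  last position is within `borderMargin` of an edge, otherwise
  `terminated_lost`. Tracks alive at frame 0 are `completed`.

# Migration statistics

`meanDisplacement()` is the mean step length of a track converted to
micrometers per minute (defaults `pixelSize = 1.5` um/px, `dt = 15` min);
`averageMeanDisplacement()` averages MD over a track population (AMD).
`smoothTrack()` applies a centered moving average (`smoothWindow = 5`)
before MD computation when working with noisy (e.g. manually clicked)
tracks; at the track ends the window shrinks symmetrically so frame indices
are preserved.

# Manual-tracking error studies

* **Click noise.** Repeatedly clicking the same cell yields centroid
  positions scattered around the truth. `pooledCentroidSd()` estimates the
  click jitter from replicate click sets by pooling per-frame centered
  residuals with the correct degrees of freedom (each frame and coordinate
  loses one for its own mean). `imposeClickNoise()` injects Gaussian jitter
  of a given SD (in micrometers) into a clean track, and
  `clickNoiseStudy()` maps apparent AMD as a function of true cell speed
  and click noise — slow cells can appear several times faster than they
  are, because noise-induced apparent steps add in quadrature to true
  steps. Smoothing recovers much of the bias.
* **Subset selection.** Manual tracking forces small samples.
  `subsetResamplingStudy()` resamples size-*k* subsets of a tracked
  population and reports the distribution of subset AMDs around the
  population AMD, quantifying how unrepresentative a hand-picked subset can
  be. `pairwiseAgreement()` counts common cell selections between raters.

# Synthetic benchmark

`sceneSpec()` and `generatePopulation()` create a ground-truth population:
gamma-distributed step lengths and von Mises headings (optionally
moment-matched so a generated track's sample MD moments are exact), contact
avoidance between cells, border reflection for resident cells, free exit
for a leave-view subset, and scripted divisions in which a daughter starts
at the parent position with diverging heading. `renderSequence()` draws
each cell as a textured ellipse (high local variance against a smooth
background with optional illumination ramp and noise) so that the entropy
segmentation faces realistic input. `benchmarkScene()` is the package's
default end-to-end benchmark: 80 cells at 1344 x 1024 px, 60 frames, a
slow/medium/fast speed mixture, three scripted divisions and eight cells
free to leave. `cellDetectionRate()` and `evaluateTracks()` score
segmentation and tracking against the ground truth; a reference track
counts as validly tracked only if a single automatic track covers its whole
visible span and matches no other reference anywhere (coasted points
matching nothing do not invalidate; at a division frame two references
coincide, so only a *strictly closer* other reference makes a point
foreign).

Two limitations are worth knowing. First, right after a division the two
daughters overlap for several frames and segmentation necessarily sees one
fused blob, so only one of the two ground-truth branches per division can
satisfy the strict validity criterion — an imaging limit, not a tracker
defect. Second, MD/AMD quantify speed, not directedness; a cell jittering
in place and a cell moving ballistically can share an MD.

# Worked example

A small end-to-end run (kept tiny so the vignette builds quickly):

```{r example}
scene <- sceneSpec(height = 300, width = 400, nFrames = 12, nCells = 6,
                   nLeaving = 0, seed = 7L)
truth <- generatePopulation(scene)
frames <- renderSequence(truth, seed = 8L)
segs <- segmentSequence(frames)
tracks <- trackSequence(segs, width = 400, height = 300)
evaluateTracks(tracks, truth$tracks)
stats <- averageMeanDisplacement(tracks)
stats
```

Click-noise study on two synthetic cells:

```{r noise}
slow <- generateTrack(nFrames = 30, mdMean = 0.2, mdSd = 0.2,
                      momentMatch = TRUE, seed = 9L)
fast <- generateTrack(nFrames = 30, mdMean = 1.8, mdSd = 0.8,
                      momentMatch = TRUE, seed = 10L)
clickNoiseStudy(list(slow = slow, fast = fast), sigmasUm = c(3, 6),
                nReplicates = 100, seed = 11L)
```

# Session info

```{r session}
sessionInfo()
```
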