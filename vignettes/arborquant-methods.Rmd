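---
title: "Methods: quantifying sensory arbor development and zebrafish behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sensory arbor development and zebrafish behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborquant)
```

arborquant quantifies four linked readouts of zebrafish Rohon-Beard (RB)
sensory neuron biology: the orientation structure of peripheral axon
arbors in fluorescence images, the density and dynamics of axon
branches, intracellular transport measured from kymographs, and
larval/adult behavior measured from movement traces and swim
trajectories. The raw microscopy movies and behavioral videos behind
such studies are rarely shareable at desk scale, so the package pairs
every estimator with a seeded synthetic-data generator that produces
inputs with exact ground truth. All validation claims in this vignette
are properties the test suite and `scripts/acceptance.R` actually
compute.

## Conventions

Images are matrices with row 1 at the top. Anatomically, anterior is
left and dorsal is up. Orientations are axial (defined modulo 180
degrees), reported in (-90, 90] with 0 along the anterior-posterior
axis; negative angles descend toward posterior, so the
posterior-ventral growth typical of these arbors appears at negative
angles. Along an axon path, distance increases away from the cell body
and positive (anterograde) velocities move that way.

## Orientation profiling

`orientationMap()` computes per-pixel orientation from the structure
tensor: Gaussian-derivative gradients at scale $\sigma_g$ (default 1
pixel, configurable in micrometres) form the outer-product tensor,
which is smoothed with a Gaussian of scale $\sigma_T$ (default 2
pixels). The minor eigenvector of the smoothed tensor gives the local
line orientation; the trace gives an energy weight and the normalized
eigenvalue anisotropy a coherency in [0, 1].
`orientationHistogram()` accumulates weight = energy x coherency into
right-closed 1-degree bins over (-90, 90] (half-integer centers), with
a coherency floor (default 0.1) excluding isotropic background. The
histogram total therefore equals the summed weights of contributing
pixels exactly, which the tests assert. Pixels are weighted rather
than counted so that bright, well-aligned axon segments contribute in
proportion to their signal, mirroring how orientation-survey tools
weight fluorescence.

Two scales matter. $\sigma_g$ sets the width of the edge detector and
should be near the line width (1 pixel suffices for
diffraction-limited neurites at 0.5 um/px); $\sigma_T$ sets the
neighbourhood over which orientation is averaged - larger values
stabilize noisy images at the cost of blurring orientation changes at
branch points. On noise-free synthetic gratings the per-pixel tensor
orientation agrees with a brute-force finite-difference gradient
computation within 2 degrees for over 99% of high-gradient pixels, and
the histogram argmax recovers every programmed orientation from -85 to
+85 degrees within half a bin; at a peak SNR of 3 the mean argmax
error stays below one degree.

`tubeness()` is the pre-filter for raw images: a Frangi-type
vesselness composed from scale-normalized Hessian eigenvalues
(gamma = 2), responding only where the larger-magnitude eigenvalue is
negative (bright ridge) and suppressing blobs through the eigenvalue
ratio. Constant regions respond exactly zero; the response peaks on
ridge centerlines and commutes with quarter-turn rotation.

`normalizeProfile()` rescales each image's histogram to percent of its
total (rows sum to 100), separating arbor *pattern* from arbor
*abundance*. `compareAUC()` integrates each sample's profile over an
angular range by the trapezoid rule and compares per-image AUCs with a
Welch two-sample t test. The field sometimes summarizes first and
tests on group means and standard errors; that z-style reading is
available as `method = "summary"`, but per-image testing is the
default because it propagates between-image variance honestly. With
20 images per group, a 10% excess of orientation mass injected into
the (-50.5, -20.5) degree band - the band where a posterior-growth
bias manifests - is detected at p < 0.05 in over 90% of replicates.

## Branch density and dynamics

`roiGrid()` builds the standard eight 3-um-high bands, regularly
spaced dorsal to ventral; band spacing is derived from the requested
span because acquisition protocols state regular spacing without an
interval, and the resolved geometry is carried in the output.
`countBranchCrossings()` thresholds each band strip (Otsu per strip by
default, so counts are invariant to global intensity rescaling),
binarizes, labels connected components with EBImage and counts objects
of at least 2 pixels - the particle-counting reading of "branches
crossing the ROI".

The synthetic arbor generator renders straight Gaussian-profile
segments whose orientations follow an axial von Mises mixture (von
Mises on the doubled angle, the natural distribution for axial data).
Segments are rejection-sampled to keep a minimum mutual separation
(default 3 um), the in-silico counterpart of the contact repulsion
that tiles real peripheral arbors; it also guarantees that thresholded
objects cannot merge, which makes the band-crossing ground truth well
defined. Ground truth counts a segment as crossing a band when that
segment's own analytic footprint clears the strip's threshold by at
least 2 pixels - an independent per-segment recount that the
connected-component path must match exactly, and does, across all
bands and seeds tested. Note what this does and does not show about
real images: it validates the counting machinery, not the threshold's
robustness to uneven background, which real data should assess with
the tubeness pre-filter.

Branch dynamics are closed-form functions of manually scored event
tables: `initiationRate()` (events per neuron per hour by branch type,
growth-cone bifurcation vs interstitial back-branching),
`lossRatio()` (retracted over total events; undefined - not zero -
when a type has no events), and `retractionDirectionBias()`
(per-neuron anterior/posterior percentages with a two-sided test
against 50%). Both pooled and per-neuron ratios are emitted because
panel-level reports are ambiguous between the two. Growth-cone
kinetics use total path length over elapsed time
(`growthVelocity()`, invariant under time reversal), 15-degree rose
sectors by default for `growthDirectionHistogram()`, and
node-to-tip vectors for `sisterBranchAngle()` at 15 and 75 minutes
after bifurcation - a retracted branch yields a missing value at that
offset rather than a zero. Fasciculation, midline-crossing and
nascent-branch acetylation metrics follow the operational definitions
directly; the acetylation scorer admits only terminal branches up to
10 um and reports how many were rejected by the filter.

## Kymographs and transport

`buildKymograph()` resamples a traced polyline at 1-pixel steps and
averages bilinearly over a perpendicular line of configurable width,
producing a distance x time matrix with the cell-body end at distance
zero. `detectTracks()` automates what is usually measured by hand:
per-frame peaks (after 1.2-px Gaussian presmoothing along distance,
threshold background + 2.5 noise SDs, parabolic sub-pixel refinement)
are linked frame to frame by a globally resolved nearest-prediction
assignment. Newborn tracks accept candidates within the full
per-frame displacement gate; once a track has two points its
constant-velocity prediction takes over with a tight innovation gate,
and up to two missed frames are bridged. Tracks are then fitted with
a constant-velocity line; net displacement below 0.5 um marks a
non-motile vesicle (kept, for motile-fraction denominators), and
tracks shorter than 5 frames are dropped. Crossing ridges are
resolved greedily; the benchmark quantifies the consequences rather
than hiding them: on 20-particle movies at SNR 3 the detector reaches
a mean F1 above 0.9 with direction accuracy above 95%, velocities on
isolated noise-free tracks are recovered within 10% from 0.1 to 2.0
um/s, and direction (the sign of the fitted slope) is exact on
isolated noise-free tracks. Hand-traced tracks can bypass detection
entirely through `importTracks()`.

`transportSummary()` normalizes frequency to tracks per minute per
10 um so segments of different lengths compare; run length is net
displacement, velocities are reported as magnitudes by direction.
`branchpointAccumulation()` implements the photoactivation readout:
post-activation frames split into four equal windows, each
maximum-projected; the pre-activation window is the background, and
the background-subtracted window means are expressed as percent of
the first window. The normalization makes the series exactly
invariant to affine rescaling of the whole stack, and a corrected
first window at or below zero flags the series invalid rather than
dividing by it.

## Behavior

`touchResponse()` encodes the larval touch assay at 50 frames per
second: the response runs from the first post-stimulus movement to
the start of a gap longer than 15 frames, and bouts are movement runs
separated by gaps longer than 5 frames. The two gaps are distinct
parameters because observed inter-bout pauses (7-8 frames) sit
between them. Non-responders are flagged and excluded from summaries
rather than contributing zeros.

`detectFreezing()` operationalizes "cessation of all movement except
gills for at least 3 s" as: forward-difference frame speed, a 3-frame
running median to suppress tracking jitter, and maximal sub-threshold
runs of at least 3.0 s (inclusive). The speed threshold (default
0.2 cm/s) is this package's operational choice - digitized tracks are
never exactly zero - and is configurable and logged. The trajectory
generator emits states that are constant over frame intervals with
displacement governed by the state at the interval's start, so
frame-wise speed reflects the state sequence exactly; on such data
the detector attains precision and recall of 1.0, a 3.0-s bout is
found and a 2.9-s bout never is. Real tracking data add jitter
structure the generator does not model (identity swaps, reflections),
so those guarantees bound detector logic, not tracker quality.

`tankSession()` summarizes the novel-tank test with the boundary at
half the water-column height: per frame, upper plus lower time equals
the session length exactly. Total velocity is path length over
session length; mobile-only velocity excludes sub-threshold frames
and is therefore never below total velocity. Freezing dwell means in
the generator default to several seconds with a 25% freeze
probability per stop - values in the range reported for anxious
adult zebrafish - and the generator truncates pause dwells below the
freezing minimum so that labels and detector semantics cannot
disagree by construction. `groupSessionStats()` compares binary
outcomes (entered upper zone, froze) with Fisher's exact test and
continuous ones through `chooseTest()`; `habituationSeries()`
aggregates across six exposures, reporting missing groups as missing
rather than zero and counting untrackable sessions it omits.

## Statistics glue

`chooseTest()` screens each sample with Shapiro-Wilk at alpha = 0.01
and routes to Welch t / one-way ANOVA or Mann-Whitney /
Kruskal-Wallis. The stricter-than-usual screen level is deliberate: a
pre-test should abandon the parametric branch only on clear evidence,
and a 0.05 per-sample screen would reroute almost one in ten
genuinely Gaussian two-group comparisons. No multiple-comparison
correction is applied by default, matching per-panel testing
practice; `stats::p.adjust` can be applied downstream. `runPipeline()`
executes YAML-configured simulate/orient/compare stages with
per-sample error isolation and writes the resolved configuration
beside the outputs so reruns reproduce results bit for bit.

## Numerical choices and problem sizes

Simulation sizes were chosen so the full validation runs comfortably
on a laptop-class single core: 160x160-px arbors at 0.5 um/px (128 px
for the 100-replicate power study, 30 segments per image), 20-seed
sweeps for recovery checks, 200-replicate power studies at the
published group sizes (30 vs 39 fish; 50 vs 20 embryos of ~30
neurons), and 50 trajectories for the freezing benchmark. Von Mises
sampling uses the Best-Fisher rejection algorithm with the
concentration-infinity limit collapsing to the mean. Degenerate
inputs are handled explicitly: zero-gradient images yield an
empty-flagged histogram, zero-total profiles refuse normalization,
zero events give an undefined loss ratio, fully frozen sessions give
an undefined mobile velocity, and kymograph thresholds fall back from
a collapsed median absolute deviation to the global standard
deviation on noise-free input.

## Known limitations

Orientation profiling assumes the plugin-style weighting
(energy x coherency); other weightings change absolute profiles
though rarely group contrasts. Track linking is greedy and can swap
identities where ridges cross - quantified by the F1 benchmark, and
avoidable via manual track import. The synthetic arbors are straight
segments: curvature, branch nodes and intensity falloff are absent,
so tests validate estimator logic rather than segmentation of real
arbors. Trajectories are consumed, not computed from video; the
upstream tracker's background-subtraction contract (subtract the
first, empty-tank frame) is documented here but out of scope.
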