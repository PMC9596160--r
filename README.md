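# arborquant

Quantification of zebrafish Rohon-Beard (RB) sensory axon arbor
development and zebrafish behavior, for developmental neurobiologists
measuring how perturbations (mutants, drugs) reshape sensory arbors,
intracellular transport and behavior.

RB neurons tile the larval skin with branched peripheral axon arbors.
Characterizing a branching phenotype takes four kinds of measurement,
each implemented here as a tested, reusable module:

- **Orientation profiling** (`tubeness`, `orientationHistogram`,
  `normalizeProfile`, `compareAUC`): per-pixel axial orientation
  θ ∈ (−90°, 90°] from the smoothed structure tensor
  J = G_{σ_T} ∗ (∇I ∇Iᵀ), with each pixel contributing weight
  trace(J) × coherency to a 1°-bin fluorescence-signal histogram;
  group differences are tested as per-image trapezoidal AUC over an
  angular band with a Welch t test.
- **Branch metrics** (`roiGrid`, `countBranchCrossings`,
  `initiationRate`, `lossRatio`, `growthVelocity`,
  `growthDirectionHistogram`, `sisterBranchAngle`, …): eight 3-µm
  dorsoventral ROI bands counted by threshold → binarize → connected
  components; branch dynamics (growth-cone bifurcation vs interstitial
  branching) as events/neuron/hour and retracted/total loss ratios;
  rose histograms and node-to-tip sister-branch angles.
- **Kymograph transport** (`buildKymograph`, `detectTracks`,
  `transportSummary`, `branchpointAccumulation`): distance × time
  resampling of traced axon segments, automated comet/vesicle track
  extraction (peak–link–fit with a constant-velocity model;
  anterograde = increasing distance from the cell body), frequency per
  10 µm per min, run lengths, velocities, and the photoactivated-Rab5
  four-window branch-point accumulation series normalized to t1.
- **Behavior** (`touchResponse`, `detectFreezing`, `tankSession`,
  `groupSessionStats`, `habituationSeries`): larval touch response at
  50 fps (termination gap > 15 frames, bout gap > 5), freezing as
  sub-threshold speed for ≥ 3 s, and novel-tank metrics (upper-zone
  entry/latency/occupancy, total vs mobile-only velocity) over 3- or
  10-minute sessions.

A first-class synthetic-data module (`simulateArbor`,
`simulateParticleMovie`, `simulateEventTable`, `simulateTrajectory`)
generates images, movies, event tables and trajectories with exact,
seeded ground truth, so every estimator is validated end to end
without any raw imaging data. `runPipeline` ties stages together from
a YAML config with per-sample error isolation; `chooseTest` provides
the normality-screened t/Mann-Whitney choice used for group
comparisons.

## Worked example

Simulate two groups of arbor images — a wild-type-like orientation
mixture and one with 10% extra orientation mass in the posterior
(−50.5°, −20.5°) band — then profile, normalize and compare them:

```r
library(arborquant)

mixWT   <- data.frame(mean_deg = c(-65, 65), kappa = c(6, 6),
                      weight = c(0.55, 0.45))
mixBias <- data.frame(mean_deg = c(-65, 65, -35.5), kappa = c(6, 6, 20),
                      weight = c(0.495, 0.405, 0.10))
profileGroup <- function(mix, seeds)
  combineProfiles(lapply(seeds, function(s) {
    img <- simulateArbor(arborSpec(mixture = mix, snr = 5, seed = s,
                                   minSeparationUm = 0))$image
    orientationHistogram(img, pxSizeUm = 0.5)
  }))
wt   <- profileGroup(mixWT,  1:8)
bias <- profileGroup(mixBias, 101:108)
wt
#> OrientationProfile: 8 image(s), 180 bins of 1.00 deg (signal units)
#>   peak bin: 69.5 deg

compareAUC(normalizeProfile(wt), normalizeProfile(bias),
           range = c(-50.5, -20.5))
#> AUCComparison over [-50.5, -20.5]: meanA = 9.469, meanB = 14.78
#>   t = -3.446, p = 0.004849 (per_image)
```

The biased group carries ~15% of its orientation signal in the
posterior band versus ~9.5% for the baseline group; with only 8 images
per group the Welch t test already rejects at p ≈ 0.005.

Branch density against generator ground truth, and branch dynamics at
wild-type rates (2.22 GCB initiations/neuron/h, loss probability 0.13):

```r
sim <- simulateArbor(arborSpec(nSegments = 15, snr = Inf, seed = 4))
rbind(counted = countBranchCrossings(sim$image, sim$grid, pxSizeUm = 0.5),
      truth   = sim$bandCounts)
#>         [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8]
#> counted    2    7    5    5    5    6    5    3
#> truth      2    7    5    5    5    6    5    3

ev <- simulateEventTable(eventTableSpec(nNeurons = 115, seed = 11))
c(gcb_rate = initiationRate(ev, 115, 2)$rate[["GCB"]],
  gcb_loss = lossRatio(ev)$ratio[["GCB"]])
#>  gcb_rate  gcb_loss
#> 2.2173913 0.1470588
```

Transport from a noisy synthetic kymograph, and behavior from a
simulated novel-tank session:

```r
mov <- simulateParticleMovie(movieBenchmarkSpec(seed = 9, nParticles = 10,
                                                snr = 3))
tracks <- detectTracks(asKymograph(mov$profile, pxSizeUm = 0.2,
                                   frameIntervalS = 2.5))
transportSummary(tracks, segmentLengthUm = 40,
                 durationMin = 100 * 2.5 / 60)[
  c("nTracks", "frequencyPer10umPerMin", "pctAnterogradeOfMotile")]
#> $nTracks              [1] 10
#> $frequencyPer10umPerMin  [1] 0.6
#> $pctAnterogradeOfMotile  [1] 40

fish <- simulateTrajectory(trajectorySpec(durationS = 180, pFreeze = 0.5,
                                          seed = 21))
round(unlist(tankSession(fish$trajectory, tankHeightCm = 18)[
  c("pctTimeUpper", "nFreezeBouts", "totalFrozenS",
    "totalVelocityCmS", "mobileVelocityCmS")]), 3)
#>      pctTimeUpper      nFreezeBouts      totalFrozenS  totalVelocityCmS
#>            12.556             5.000            18.700             5.179
#> mobileVelocityCmS
#>             5.991
```

All 10 particles are recovered with their directions; the fish froze 5
times for 18.7 s total, and its mobile-only velocity (6.0 cm/s)
exceeds its total velocity (5.2 cm/s) because frozen time is excluded.

See `vignettes/arborquant-methods.Rmd` for the models, parameter
choices and known limitations.

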