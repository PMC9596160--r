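#' @import methods
NULL

## ---------------------------------------------------------------------------
## Simulation specification classes
## ---------------------------------------------------------------------------

#' Specification of a synthetic arbor image
#'
#' Describes a 2D fluorescence image of a peripheral sensory axon arbor to be
#' rendered by [simulateArbor()]. Segments are straight Gaussian-profile lines
#' whose orientations are drawn from an axial von Mises mixture (von Mises on
#' the doubled angle, since line orientation is defined modulo 180 degrees).
#' The anatomical convention throughout is anterior to the left, dorsal at the
#' top; angles lie in (-90, 90] with 0 = the anterior-posterior axis and
#' negative angles descending toward posterior.
#'
#' @slot imageSize integer(2), image height and width in pixels (rows, cols).
#' @slot pxSizeUm numeric(1), pixel size in micrometres.
#' @slot nSegments integer(1), number of rendered axon segments.
#' @slot mixture data.frame with columns `mean_deg` (in (-90, 90]),
#'   `kappa` (axial von Mises concentration; `Inf` collapses the component
#'   to its mean) and `weight` (summing to 1).
#' @slot segmentLengthUm numeric(2), min/max segment length in micrometres.
#' @slot tubeSigmaPx numeric(1), Gaussian cross-profile sigma of a rendered
#'   line, in pixels (diffraction-limited neurite width surrogate).
#' @slot minSeparationUm numeric(1), minimum mutual distance enforced between
#'   segments (contact-repulsion/tiling surrogate; keeps thresholded objects
#'   from merging). Set to 0 to disable.
#' @slot snr numeric(1), peak signal over noise standard deviation; `Inf`
#'   renders noise-free.
#' @slot noiseModel character(1), `"gaussian"` or `"poisson+gaussian"`.
#' @slot seed integer(1), RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @export
setClass("ArborSpec",
  representation(
    imageSize = "integer", pxSizeUm = "numeric", nSegments = "integer",
    mixture = "data.frame", segmentLengthUm = "numeric",
    tubeSigmaPx = "numeric", minSeparationUm = "numeric", snr = "numeric",
    noiseModel = "character", seed = "integer"
  )
)

setValidity("ArborSpec", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be two integers >= 16")
  if (object@pxSizeUm <= 0) msg <- c(msg, "pxSizeUm must be > 0")
  if (object@nSegments < 0L) msg <- c(msg, "nSegments must be >= 0")
  m <- object@mixture
  if (!all(c("mean_deg", "kappa", "weight") %in% names(m)))
    msg <- c(msg, "mixture needs columns mean_deg, kappa, weight")
  else {
    if (abs(sum(m$weight) - 1) > 1e-8)
      msg <- c(msg, "mixture weights must sum to 1")
    if (any(m$mean_deg <= -90 | m$mean_deg > 90))
      msg <- c(msg, "mixture mean_deg must lie in (-90, 90]")
    if (any(m$kappa < 0)) msg <- c(msg, "mixture kappa must be >= 0")
  }
  if (length(object@segmentLengthUm) != 2L ||
      any(object@segmentLengthUm <= 0) ||
      diff(object@segmentLengthUm) < 0)
    msg <- c(msg, "segmentLengthUm must be an increasing positive range")
  if (object@tubeSigmaPx <= 0) msg <- c(msg, "tubeSigmaPx must be > 0")
  if (object@minSeparationUm < 0) msg <- c(msg, "minSeparationUm must be >= 0")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (!object@noiseModel %in% c("gaussian", "poisson+gaussian"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson+gaussian'")
  if (length(msg)) msg else TRUE
})

#' Construct an ArborSpec
#'
#' @param imageSize integer(2) image size in pixels (rows, cols).
#' @param pxSizeUm pixel size, micrometres per pixel.
#' @param nSegments number of segments to render.
#' @param mixture data.frame (`mean_deg`, `kappa`, `weight`) describing the
#'   axial orientation mixture.
#' @param segmentLengthUm numeric(2) segment length range, micrometres.
#' @param tubeSigmaPx Gaussian line-profile sigma, pixels.
#' @param minSeparationUm minimum mutual segment separation, micrometres.
#' @param snr peak signal over noise SD; `Inf` for noise-free.
#' @param noiseModel `"gaussian"` or `"poisson+gaussian"`.
#' @param seed RNG seed.
#' @return An [ArborSpec-class] object.
#' @examples
#' sp <- arborSpec(nSegments = 10, seed = 1)
#' sim <- simulateArbor(sp)
#' dim(sim$image)
#' @export
arborSpec <- function(imageSize = c(160L, 160L), pxSizeUm = 0.5,
                      nSegments = 20L,
                      mixture = data.frame(
                        mean_deg = c(-65, 65), kappa = c(6, 6),
                        weight = c(0.55, 0.45)),
                      segmentLengthUm = c(15, 45), tubeSigmaPx = 1.5,
                      minSeparationUm = 3, snr = 10,
                      noiseModel = "gaussian", seed = 1L) {
  new("ArborSpec", imageSize = as.integer(imageSize), pxSizeUm = pxSizeUm,
      nSegments = as.integer(nSegments), mixture = mixture,
      segmentLengthUm = as.numeric(segmentLengthUm),
      tubeSigmaPx = tubeSigmaPx, minSeparationUm = minSeparationUm,
      snr = snr, noiseModel = noiseModel, seed = as.integer(seed))
}

#' Specification of a synthetic particle movie
#'
#' Describes a 1D-path time-lapse containing moving puncta (EB3 comets or
#' Rab5 vesicles) with known kinetics. Rendering can produce either a
#' (distance x time) intensity profile or a 2D image stack with the path
#' along a horizontal line. Velocities are signed: positive = anterograde
#' (increasing distance from the cell body).
#'
#' @slot pathLengthUm numeric(1), traced path length in micrometres.
#' @slot pxSizeUm numeric(1), spatial sampling, micrometres per pixel.
#' @slot frameIntervalS numeric(1), seconds between frames (acquisition used
#'   2-5 s intervals).
#' @slot nFrames integer(1), number of frames.
#' @slot particles data.frame, one row per particle: `t_start_s`,
#'   `x_start_um`, `velocity_um_s` (signed), `run_length_um`, `intensity`.
#' @slot background numeric(1), constant background level.
#' @slot snr numeric(1), particle intensity over noise SD; `Inf` noise-free.
#' @slot seed integer(1), RNG seed.
#' @export
setClass("MovieSpec",
  representation(
    pathLengthUm = "numeric", pxSizeUm = "numeric", frameIntervalS = "numeric",
    nFrames = "integer", particles = "data.frame", background = "numeric",
    snr = "numeric", seed = "integer"
  )
)

setValidity("MovieSpec", function(object) {
  msg <- character()
  if (object@pathLengthUm <= 0) msg <- c(msg, "pathLengthUm must be > 0")
  if (object@pxSizeUm <= 0) msg <- c(msg, "pxSizeUm must be > 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  need <- c("t_start_s", "x_start_um", "velocity_um_s", "run_length_um",
            "intensity")
  if (!all(need %in% names(object@particles)))
    msg <- c(msg, paste("particles needs columns:", paste(need, collapse = ", ")))
  else if (nrow(object@particles) &&
           any(object@particles$run_length_um <= 0))
    msg <- c(msg, "run_length_um must be > 0")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MovieSpec
#'
#' @param pathLengthUm path length in micrometres.
#' @param pxSizeUm spatial sampling, micrometres per pixel.
#' @param frameIntervalS frame interval, seconds (2-5 s matches acquisition).
#' @param nFrames number of frames.
#' @param particles data.frame with `t_start_s`, `x_start_um`,
#'   `velocity_um_s`, `run_length_um`, `intensity`.
#' @param background constant background intensity.
#' @param snr particle peak over noise SD.
#' @param seed RNG seed.
#' @return A [MovieSpec-class] object.
#' @examples
#' mv <- movieSpec(particles = data.frame(t_start_s = 0, x_start_um = 5,
#'   velocity_um_s = 0.5, run_length_um = 10, intensity = 1))
#' sim <- simulateParticleMovie(mv)
#' sim$tracks$duration_s   # 20 s = 10 um / 0.5 um/s
#' @export
movieSpec <- function(pathLengthUm = 30, pxSizeUm = 0.2, frameIntervalS = 2.5,
                      nFrames = 80L,
                      particles = data.frame(t_start_s = numeric(),
                                             x_start_um = numeric(),
                                             velocity_um_s = numeric(),
                                             run_length_um = numeric(),
                                             intensity = numeric()),
                      background = 0.1, snr = Inf, seed = 1L) {
  new("MovieSpec", pathLengthUm = pathLengthUm, pxSizeUm = pxSizeUm,
      frameIntervalS = frameIntervalS, nFrames = as.integer(nFrames),
      particles = particles, background = background, snr = snr,
      seed = as.integer(seed))
}

#' Specification of a synthetic branch-event table
#'
#' Initiations are Poisson counts per neuron per branch type over the
#' observation window; retraction flags are Bernoulli draws with
#' type-specific loss probabilities, and retracted branches carry a
#' direction label (anterior/posterior).
#'
#' @slot nNeurons integer(1), number of neurons.
#' @slot durationH numeric(1), observation duration, hours.
#' @slot gcbRatePerH numeric(1), growth-cone-bifurcation initiations per
#'   neuron per hour.
#' @slot ibRatePerH numeric(1), interstitial-branch initiations per neuron
#'   per hour.
#' @slot gcbLossProb numeric(1), probability a GCB branch retracts.
#' @slot ibLossProb numeric(1), probability an IB branch retracts.
#' @slot anteriorFractionOfLost numeric(1), probability a retracted branch is
#'   anteriorly directed.
#' @slot seed integer(1), RNG seed.
#' @export
setClass("EventTableSpec",
  representation(
    nNeurons = "integer", durationH = "numeric", gcbRatePerH = "numeric",
    ibRatePerH = "numeric", gcbLossProb = "numeric", ibLossProb = "numeric",
    anteriorFractionOfLost = "numeric", seed = "integer"
  )
)

setValidity("EventTableSpec", function(object) {
  msg <- character()
  if (object@nNeurons < 1L) msg <- c(msg, "nNeurons must be >= 1")
  if (object@durationH <= 0) msg <- c(msg, "durationH must be > 0")
  if (object@gcbRatePerH < 0 || object@ibRatePerH < 0)
    msg <- c(msg, "rates must be >= 0")
  pr <- c(object@gcbLossProb, object@ibLossProb, object@anteriorFractionOfLost)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an EventTableSpec
#'
#' Defaults reflect wild-type dynamics: 2.22 GCB and 0.99 IB initiations per
#' neuron per hour with loss probabilities 0.13 (GCB) and 0.10 (IB).
#'
#' @param nNeurons number of neurons.
#' @param durationH observation duration in hours.
#' @param gcbRatePerH,ibRatePerH initiations per neuron per hour by type.
#' @param gcbLossProb,ibLossProb retraction probability by type.
#' @param anteriorFractionOfLost probability a retracted branch is anterior.
#' @param seed RNG seed.
#' @return An [EventTableSpec-class] object.
#' @export
eventTableSpec <- function(nNeurons = 10L, durationH = 2,
                           gcbRatePerH = 2.22, ibRatePerH = 0.99,
                           gcbLossProb = 0.13, ibLossProb = 0.10,
                           anteriorFractionOfLost = 0.5, seed = 1L) {
  new("EventTableSpec", nNeurons = as.integer(nNeurons), durationH = durationH,
      gcbRatePerH = gcbRatePerH, ibRatePerH = ibRatePerH,
      gcbLossProb = gcbLossProb, ibLossProb = ibLossProb,
      anteriorFractionOfLost = anteriorFractionOfLost, seed = as.integer(seed))
}

#' Specification of a synthetic swim trajectory
#'
#' A three-state (swim / pause / freeze) semi-Markov locomotion model
#' discretized at the camera frame rate inside a rectangular tank. Freeze
#' dwell times are `freezeMinS` plus an exponential tail so every labelled
#' freeze bout satisfies the minimum-duration definition; pause dwells are
#' truncated below `freezeMinS` (a pause that long would be a freeze by
#' definition). State is constant over each frame interval and the
#' displacement over interval i -> i+1 is governed by the state at frame i,
#' so frame-wise speed exactly reflects the state sequence.
#'
#' @slot fps numeric(1), frames per second.
#' @slot durationS numeric(1), session length, seconds (novel-tank sessions
#'   are 180 s, habituation sessions 600 s).
#' @slot tankSizeCm numeric(2), tank width and height, centimetres.
#' @slot dwellMeanS named numeric(3), mean dwell time (s) in
#'   `swim`, `pause`, `freeze`.
#' @slot pFreeze numeric(1), probability that a stop is a freeze rather than
#'   a pause.
#' @slot swimSpeedCmS numeric(1), swim speed, cm/s.
#' @slot freezeMinS numeric(1), minimum freeze duration, seconds.
#' @slot freezeJitterCmS numeric(1), sub-threshold speed jitter emitted while
#'   frozen (gill movement surrogate); 0 for exact immobility.
#' @slot upperZonePreference numeric(1) in [0, 1], probability that a swim
#'   bout targets the upper half of the tank (realized occupancy follows
#'   the bout targets loosely); 0 confines the fish to the lower zone.
#' @slot seed integer(1), RNG seed.
#' @export
setClass("TrajectorySpec",
  representation(
    fps = "numeric", durationS = "numeric", tankSizeCm = "numeric",
    dwellMeanS = "numeric", pFreeze = "numeric", swimSpeedCmS = "numeric",
    freezeMinS = "numeric", freezeJitterCmS = "numeric",
    upperZonePreference = "numeric", seed = "integer"
  )
)

setValidity("TrajectorySpec", function(object) {
  msg <- character()
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (length(object@tankSizeCm) != 2L || any(object@tankSizeCm <= 0))
    msg <- c(msg, "tankSizeCm must be two positive numbers")
  if (!all(c("swim", "pause", "freeze") %in% names(object@dwellMeanS)))
    msg <- c(msg, "dwellMeanS must be named swim, pause, freeze")
  else if (any(object@dwellMeanS <= 0))
    msg <- c(msg, "dwellMeanS must be > 0")
  if (object@pFreeze < 0 || object@pFreeze > 1)
    msg <- c(msg, "pFreeze must lie in [0, 1]")
  if (object@swimSpeedCmS < 0) msg <- c(msg, "swimSpeedCmS must be >= 0")
  if (object@freezeMinS < 0) msg <- c(msg, "freezeMinS must be >= 0")
  if (object@freezeJitterCmS < 0) msg <- c(msg, "freezeJitterCmS must be >= 0")
  if (object@upperZonePreference < 0 || object@upperZonePreference > 1)
    msg <- c(msg, "upperZonePreference must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a TrajectorySpec
#'
#' @param fps frames per second of the virtual camera.
#' @param durationS session length in seconds.
#' @param tankSizeCm tank width and height, cm.
#' @param dwellMeanS named mean dwell times (s) for swim, pause, freeze.
#' @param pFreeze probability a stop is a freeze (vs a brief pause).
#' @param swimSpeedCmS swim speed, cm/s.
#' @param freezeMinS minimum freeze duration, s.
#' @param freezeJitterCmS sub-threshold jitter speed while frozen, cm/s.
#' @param upperZonePreference target long-run upper-zone occupancy in [0, 1].
#' @param seed RNG seed.
#' @return A [TrajectorySpec-class] object.
#' @examples
#' tr <- simulateTrajectory(trajectorySpec(durationS = 30, seed = 2))
#' head(tr$trajectory)
#' @export
trajectorySpec <- function(fps = 10, durationS = 180, tankSizeCm = c(28, 18),
                           dwellMeanS = c(swim = 8, pause = 0.8, freeze = 6),
                           pFreeze = 0.25, swimSpeedCmS = 6, freezeMinS = 3,
                           freezeJitterCmS = 0, upperZonePreference = 0.2,
                           seed = 1L) {
  new("TrajectorySpec", fps = fps, durationS = durationS,
      tankSizeCm = as.numeric(tankSizeCm), dwellMeanS = dwellMeanS,
      pFreeze = pFreeze, swimSpeedCmS = swimSpeedCmS, freezeMinS = freezeMinS,
      freezeJitterCmS = freezeJitterCmS,
      upperZonePreference = upperZonePreference, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Analysis result classes
## ---------------------------------------------------------------------------

#' Orientation profile of one or more arbor images
#'
#' Per-1-degree-bin orientation-weighted fluorescence signal, one row per
#' image. Bins are right-closed over (-90, 90] with half-integer centers
#' (-89.5 ... 89.5 for 1-degree bins). Units are arbitrary fluorescence
#' signal (`"signal"`) or percent of per-image total (`"percent"`).
#'
#' @slot binCenters numeric, bin centers in degrees.
#' @slot values matrix, images x bins.
#' @slot units character(1), `"signal"` or `"percent"`.
#' @export
setClass("OrientationProfile",
  representation(binCenters = "numeric", values = "matrix",
                 units = "character"))

setValidity("OrientationProfile", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@binCenters))
    msg <- c(msg, "ncol(values) must equal length(binCenters)")
  w <- diff(object@binCenters)
  if (length(w) && max(abs(w - w[1])) > 1e-9)
    msg <- c(msg, "bin widths must be uniform")
  if (!object@units %in% c("signal", "percent"))
    msg <- c(msg, "units must be 'signal' or 'percent'")
  if (object@units == "percent" && nrow(object@values) &&
      any(abs(rowSums(object@values) - 100) > 1e-6))
    msg <- c(msg, "percent profiles must sum to 100 per image")
  if (length(msg)) msg else TRUE
})

#' Kymograph of a traced axon segment
#'
#' Distance x time intensity matrix sampled along a traced path at 1-pixel
#' steps. Row 1 is the cell-body end of the path; increasing distance is
#' anterograde.
#'
#' @slot intensity matrix, distance (rows) x time (cols).
#' @slot pxSizeUm numeric(1), micrometres per distance pixel.
#' @slot frameIntervalS numeric(1), seconds per time column.
#' @export
setClass("Kymograph",
  representation(intensity = "matrix", pxSizeUm = "numeric",
                 frameIntervalS = "numeric"))

setValidity("Kymograph", function(object) {
  msg <- character()
  if (object@pxSizeUm <= 0) msg <- c(msg, "pxSizeUm must be > 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (length(msg)) msg else TRUE
})

#' AUC comparison between two groups of profiles
#'
#' Per-sample trapezoidal areas under the curve over an angular (or ROI
#' index) range, compared with a two-sample t test (Welch by default).
#'
#' @slot range numeric(2), compared range (degrees or ROI index).
#' @slot aucA,aucB numeric, per-sample AUC values.
#' @slot statistic numeric(1), t statistic (group A minus group B).
#' @slot pValue numeric(1).
#' @slot method character(1), `"per_image"` (Welch t on per-sample AUCs) or
#'   `"summary"` (z test from group means and standard errors).
#' @export
setClass("AUCComparison",
  representation(range = "numeric", aucA = "numeric", aucB = "numeric",
                 statistic = "numeric", pValue = "numeric",
                 method = "character"))

setValidity("AUCComparison", function(object) {
  if (length(object@range) != 2L || object@range[1] >= object@range[2])
    "range must be (lo, hi) with lo < hi" else TRUE
})
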