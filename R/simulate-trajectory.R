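#' Simulate a swim trajectory with known state intervals
#'
#' Alternates swim bouts with stops; each stop is a freeze (probability
#' `pFreeze`) or a brief pause. Dwell times are exponential with the spec
#' means, except that freeze dwells are `freezeMinS` plus an exponential
#' tail (so labelled freezes always satisfy the minimum-duration
#' definition), pause dwells are truncated just below `freezeMinS`, and
#' swim dwells are truncated below two frame intervals so that state runs
#' remain resolvable at the camera frame rate. The continuous-time state
#' sequence is discretized at `fps`: the state at frame i governs the
#' displacement over the interval i -> i+1, so frame-wise forward-difference
#' speed reflects the state sequence exactly. Swimming follows a persistent
#' random walk at `swimSpeedCmS` with reflecting tank walls; frozen and
#' paused frames emit zero displacement plus, for freezes, the optional
#' sub-threshold jitter. `upperZonePreference = 0` confines the fish below
#' the half-height zone boundary.
#'
#' @param spec a [TrajectorySpec-class].
#' @return list with
#'   \describe{
#'     \item{trajectory}{data.frame `t_s`, `x_cm`, `y_cm`, `state`.}
#'     \item{bouts}{data.frame of all state runs: `state`, `start_frame`,
#'       `end_frame`, `start_s`, `duration_s` (= frames / fps).}
#'     \item{freezeBouts}{the freeze rows of `bouts`.}
#'     \item{upperFraction}{realized fraction of frames with y above the
#'       half-height zone boundary.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' tr <- simulateTrajectory(trajectorySpec(durationS = 60, seed = 7))
#' tr$upperFraction
#' @export
simulateTrajectory <- function(spec) {
  stopifnot(is(spec, "TrajectorySpec"))
  validObject(spec)
  set.seed(spec@seed)
  fps <- spec@fps
  n <- round(spec@durationS * fps)
  dt <- 1 / fps

  states <- .sampleStateFrames(spec, n)

  w <- spec@tankSizeCm[1]; h <- spec@tankSizeCm[2]
  ymax <- if (spec@upperZonePreference == 0) h / 2 else h
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, 0.1 * w, 0.9 * w)
  y[1] <- stats::runif(1, 0.05 * h, 0.95 * ymax)
  heading <- stats::runif(1, 0, 2 * pi)
  # vertical attractor per swim bout: upper half with prob = preference
  attractUpper <- stats::runif(1) < spec@upperZonePreference
  step <- spec@swimSpeedCmS * dt
  jstep <- spec@freezeJitterCmS * dt
  for (i in seq_len(n - 1)) {
    if (i > 1 && states[i] == "swim" && states[i - 1] != "swim")
      attractUpper <- stats::runif(1) < spec@upperZonePreference
    if (states[i] == "swim") {
      heading <- heading + stats::rnorm(1, 0, 0.45)
      ty <- if (attractUpper) 0.8 * h else 0.2 * h
      # vertical pull toward the bout's attractor zone, strengthening
      # with distance so bouts stay inside their zone
      pull <- 3.5 * (ty - y[i]) / h
      dxy <- c(cos(heading), sin(heading) + pull)
      dxy <- dxy / sqrt(sum(dxy^2)) * step
    } else if (states[i] == "freeze" && jstep > 0) {
      a <- stats::runif(1, 0, 2 * pi)
      dxy <- c(cos(a), sin(a)) * jstep
    } else {
      dxy <- c(0, 0)
    }
    nx <- x[i] + dxy[1]; ny <- y[i] + dxy[2]
    if (nx < 0) { nx <- -nx; heading <- pi - heading }
    if (nx > w) { nx <- 2 * w - nx; heading <- pi - heading }
    if (ny < 0) { ny <- -ny; heading <- -heading }
    if (ny > ymax) { ny <- 2 * ymax - ny; heading <- -heading }
    x[i + 1] <- nx; y[i + 1] <- ny
  }

  runs <- .runs(states == "freeze")
  allRuns <- .runs(states)
  bouts <- data.frame(
    state = allRuns$value,
    start_frame = allRuns$start, end_frame = allRuns$end,
    start_s = (allRuns$start - 1) / fps,
    duration_s = (allRuns$end - allRuns$start + 1) / fps)
  traj <- data.frame(t_s = (seq_len(n) - 1) / fps, x_cm = x, y_cm = y,
                     state = states)
  list(trajectory = traj, bouts = bouts,
       freezeBouts = bouts[bouts$state == "freeze", , drop = FALSE],
       upperFraction = mean(y > h / 2),
       spec = spec)
}

# continuous-time semi-Markov state sequence sampled at frame starts
.sampleStateFrames <- function(spec, n) {
  fps <- spec@fps
  total <- n / fps
  dwell <- spec@dwellMeanS
  minSwim <- 2 / fps
  t <- 0
  segStates <- character(); segDur <- numeric()
  cur <- "swim"
  while (t < total) {
    if (cur == "swim") {
      d <- max(minSwim, stats::rexp(1, 1 / dwell[["swim"]]))
      nxt <- if (stats::runif(1) < spec@pFreeze) "freeze" else "pause"
    } else if (cur == "freeze") {
      tailMean <- max(dwell[["freeze"]] - spec@freezeMinS, 0.5)
      d <- spec@freezeMinS + stats::rexp(1, 1 / tailMean)
      nxt <- "swim"
    } else {
      d <- min(stats::rexp(1, 1 / dwell[["pause"]]),
               max(spec@freezeMinS - 2 / fps, 1 / fps))
      nxt <- "swim"
    }
    segStates <- c(segStates, cur); segDur <- c(segDur, d)
    t <- t + d
    cur <- nxt
  }
  bounds <- cumsum(segDur)
  frameT <- (seq_len(n) - 1) / fps
  idx <- findInterval(frameT, c(0, bounds), rightmost.closed = FALSE,
                      left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(segStates)] <- length(segStates)
  segStates[idx]
}
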