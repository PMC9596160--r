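#' Larval touch-response metrics from a movement trace
#'
#' The response is measured from the first movement at or after the
#' stimulus frame to the cessation of movement for more than
#' `pauseFrames` frames (default 15): response time = (last moving frame
#' before that gap - first moving frame) / fps. Swim bouts within the
#' response are maximal moving runs separated by gaps longer than
#' `boutGapFrames` (default 5; inter-bout pauses last about 7-8 frames,
#' well below the 15-frame termination gap). A larva with no movement
#' after the stimulus did not respond and is excluded from summaries.
#'
#' @param trace logical (or 0/1) vector, one entry per frame: did the
#'   larva move in this frame.
#' @param stimFrame frame index of the touch.
#' @param fps frames per second (default 50).
#' @param pauseFrames response-termination gap, frames (movement must
#'   cease for more than this).
#' @param boutGapFrames gap separating swim bouts, frames.
#' @return list with `responded` (logical), `responseTimeS`, `nBouts`
#'   (both NA when not responded).
#' @examples
#' tr <- rep(FALSE, 1050); tr[10:60] <- TRUE
#' touchResponse(tr, stimFrame = 5)$responseTimeS  # 1 s
#' @export
touchResponse <- function(trace, stimFrame, fps = 50, pauseFrames = 15L,
                          boutGapFrames = 5L) {
  trace <- as.logical(trace)
  n <- length(trace)
  if (stimFrame < 1 || stimFrame > n)
    stop("stimFrame outside the trace")
  post <- which(trace & seq_len(n) >= stimFrame)
  if (!length(post))
    return(list(responded = FALSE, responseTimeS = NA_real_,
                nBouts = NA_integer_))
  first <- post[1]
  gaps <- diff(post)
  stopIdx <- which(gaps > pauseFrames)
  last <- if (length(stopIdx)) post[stopIdx[1]] else post[length(post)]
  moving <- post[post <= last]
  boutBreaks <- which(diff(moving) > boutGapFrames)
  nBouts <- length(boutBreaks) + 1L
  list(responded = TRUE, responseTimeS = (last - first) / fps,
       nBouts = nBouts)
}

#' Detect freezing bouts in a trajectory
#'
#' Instantaneous speed is the forward frame difference (the last frame
#' repeats the previous value) passed through a 3-frame running median to
#' suppress tracking jitter. Freezing bouts are maximal runs of frames
#' with speed below `speedEpsCmS` lasting at least `minFreezeS` seconds
#' (inclusive: an exactly 3.0 s immobile run is a bout); bouts are
#' separated by at least one supra-threshold frame.
#'
#' The operational speed threshold (default 0.2 cm/s) stands in for
#' "cessation of all movement except for gills": digitized tracks are
#' never exactly zero.
#'
#' @param traj data.frame with `t_s`, `x_cm`, `y_cm` at fixed frame rate.
#' @param fps frames per second; inferred from `t_s` when NULL.
#' @param speedEpsCmS immobility speed threshold, cm/s.
#' @param minFreezeS minimum bout duration, seconds (default 3).
#' @param medianFilter apply the 3-frame median filter (default TRUE).
#' @return data.frame of bouts: `start_frame`, `end_frame`, `start_s`,
#'   `end_s`, `duration_s` (= frames / fps).
#' @export
detectFreezing <- function(traj, fps = NULL, speedEpsCmS = 0.2,
                           minFreezeS = 3, medianFilter = TRUE) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(traj)))
  if (is.null(fps)) {
    dts <- diff(traj$t_s)
    if (!length(dts) || any(dts <= 0)) stop("t_s must strictly increase")
    fps <- 1 / stats::median(dts)
  }
  sp <- frameSpeed(traj, fps, medianFilter)
  runs <- .runs(sp < speedEpsCmS)
  runs <- runs[runs$value, , drop = FALSE]
  minFrames <- ceiling(minFreezeS * fps - 1e-9)
  runs <- runs[(runs$end - runs$start + 1L) >= minFrames, , drop = FALSE]
  data.frame(start_frame = runs$start, end_frame = runs$end,
             start_s = (runs$start - 1) / fps,
             end_s = runs$end / fps,
             duration_s = (runs$end - runs$start + 1L) / fps)
}

#' Frame-wise speed of a trajectory
#'
#' @param traj data.frame with `x_cm`, `y_cm`.
#' @param fps frames per second.
#' @param medianFilter apply a 3-frame running median.
#' @return numeric vector, cm/s, one value per frame (forward difference;
#'   last frame repeats the previous speed).
#' @export
frameSpeed <- function(traj, fps, medianFilter = TRUE) {
  step <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2) * fps
  sp <- c(step, step[length(step)])
  if (medianFilter) sp <- .median3(sp)
  sp
}

#' Novel-tank session summary for one fish
#'
#' Computes the upper-zone metrics (entered, latency to first crossing,
#' cumulative time and percent of session in the upper zone), freezing
#' (via [detectFreezing()]), and the two velocity readings: total
#' velocity = path length / session length, and mobile-only velocity
#' which excludes the time and displacement of sub-threshold (frozen /
#' paused) frames. Upper and lower zone split at half the tank height;
#' per frame, time in upper + time in lower equals the session length
#' exactly.
#'
#' @param traj data.frame `t_s`, `x_cm`, `y_cm`.
#' @param tankHeightCm tank (water column) height; the zone boundary is
#'   at half this height.
#' @param fps frames per second; inferred when NULL.
#' @param speedEpsCmS immobility threshold for freezing and for the
#'   mobile-velocity exclusion.
#' @param minFreezeS minimum freezing-bout duration, seconds.
#' @return list: `sessionLengthS`, `enteredUpper`, `latencyToUpperS` (NA
#'   when never entered), `timeInUpperS`, `timeInLowerS`, `pctTimeUpper`,
#'   `nFreezeBouts`, `totalFrozenS`, `totalVelocityCmS`,
#'   `mobileVelocityCmS` (NA when no mobile frames), `freezeBouts`.
#' @export
tankSession <- function(traj, tankHeightCm, fps = NULL, speedEpsCmS = 0.2,
                        minFreezeS = 3) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(traj)))
  if (is.null(fps)) fps <- 1 / stats::median(diff(traj$t_s))
  n <- nrow(traj)
  sessionS <- n / fps
  upper <- traj$y_cm > tankHeightCm / 2
  timeUpper <- sum(upper) / fps
  firstUp <- if (any(upper)) which(upper)[1] else NA_integer_
  bouts <- detectFreezing(traj, fps = fps, speedEpsCmS = speedEpsCmS,
                          minFreezeS = minFreezeS)
  sp <- frameSpeed(traj, fps, medianFilter = TRUE)
  stepDist <- sp / fps                       # per-frame path length
  total <- sum(stepDist) / sessionS
  mobile <- sp >= speedEpsCmS
  mobileV <- if (any(mobile)) sum(stepDist[mobile]) / (sum(mobile) / fps)
             else NA_real_
  list(sessionLengthS = sessionS,
       enteredUpper = !is.na(firstUp),
       latencyToUpperS = if (!is.na(firstUp)) (firstUp - 1) / fps
                         else NA_real_,
       timeInUpperS = timeUpper,
       timeInLowerS = sessionS - timeUpper,
       pctTimeUpper = 100 * timeUpper / sessionS,
       nFreezeBouts = nrow(bouts),
       totalFrozenS = sum(bouts$duration_s),
       totalVelocityCmS = total,
       mobileVelocityCmS = mobileV,
       freezeBouts = bouts)
}

#' Group-level novel-tank statistics
#'
#' Aggregates per-fish session summaries by group: percent of fish that
#' entered the upper zone, percent with at least one freezing bout, means
#' with SEM of the continuous metrics, and two-group tests - Fisher's
#' exact test for the binary outcomes, and [chooseTest()]
#' (normality-screened t vs Mann-Whitney) for the continuous ones. When a
#' `day` column is present, per-experiment-day percentages are also
#' emitted (each day one point, matching per-trial plotting).
#'
#' @param sessions data.frame with one row per fish: `group`, logical
#'   `entered_upper`, integer `n_freeze_bouts`, and optionally
#'   `total_frozen_s`, `pct_time_upper`, `latency_to_upper_s`,
#'   `total_velocity_cm_s`, `mobile_velocity_cm_s`, `day`.
#' @return list with `groupSummary`, `tests` (data.frame: metric, test,
#'   statistic, p, n), and `perDay` (NULL without a `day` column).
#' @export
groupSessionStats <- function(sessions) {
  stopifnot(all(c("group", "entered_upper", "n_freeze_bouts") %in%
                  names(sessions)))
  sessions$froze <- sessions$n_freeze_bouts > 0
  gs <- do.call(rbind, lapply(split(sessions, sessions$group), function(d) {
    out <- data.frame(group = d$group[1], n = nrow(d),
                      pct_entered_upper = 100 * mean(d$entered_upper),
                      pct_froze = 100 * mean(d$froze))
    for (m in c("total_frozen_s", "pct_time_upper", "total_velocity_cm_s",
                "mobile_velocity_cm_s"))
      if (m %in% names(d)) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
        out[[paste0(m, "_sem")]] <- stats::sd(d[[m]], na.rm = TRUE) /
          sqrt(sum(!is.na(d[[m]])))
      }
    out
  }))
  rownames(gs) <- NULL
  tests <- NULL
  grp <- split(sessions, sessions$group)
  if (length(grp) == 2) {
    a <- grp[[1]]; b <- grp[[2]]
    tests <- list()
    for (m in c("entered_upper", "froze")) {
      tab <- rbind(c(sum(a[[m]]), sum(!a[[m]])),
                   c(sum(b[[m]]), sum(!b[[m]])))
      ft <- stats::fisher.test(tab)
      tests[[m]] <- data.frame(metric = m, test = "fisher",
                               statistic = unname(ft$estimate),
                               p = ft$p.value, n = nrow(sessions))
    }
    for (m in c("total_frozen_s", "pct_time_upper", "total_velocity_cm_s",
                "mobile_velocity_cm_s", "latency_to_upper_s"))
      if (m %in% names(sessions)) {
        x <- a[[m]][!is.na(a[[m]])]; y <- b[[m]][!is.na(b[[m]])]
        if (length(x) >= 3 && length(y) >= 3) {
          ct <- chooseTest(list(x, y))
          tests[[m]] <- data.frame(metric = m, test = ct$test,
                                   statistic = ct$statistic, p = ct$p,
                                   n = length(x) + length(y))
        }
      }
    tests <- do.call(rbind, tests)
    rownames(tests) <- NULL
  }
  perDay <- NULL
  if ("day" %in% names(sessions)) {
    perDay <- do.call(rbind, lapply(
      split(sessions, sessions[c("group", "day")], drop = TRUE),
      function(d) data.frame(group = d$group[1], day = d$day[1],
                             n = nrow(d),
                             pct_entered_upper = 100 * mean(d$entered_upper),
                             pct_froze = 100 * mean(d$froze))))
    rownames(perDay) <- NULL
  }
  list(groupSummary = gs, tests = tests, perDay = perDay)
}

#' Habituation curves over repeated exposures
#'
#' Per exposure and group: percent of fish freezing, mean time frozen,
#' mean velocities, percent time upper and latency, each with SEM.
#' Sessions flagged untrackable are omitted and counted in
#' `omitted`. A group with no fish at an exposure yields NA (missing),
#' not zero.
#'
#' @param sessions data.frame with `group`, `exposure` (1-6), per-fish
#'   metrics as in [groupSessionStats()], optionally logical
#'   `untrackable`.
#' @param nExposures number of exposures in the series (default 6).
#' @return list with `curves` (data.frame group x exposure) and
#'   `omitted` (count per group).
#' @export
habituationSeries <- function(sessions, nExposures = 6L) {
  stopifnot(all(c("group", "exposure", "n_freeze_bouts") %in%
                  names(sessions)))
  om <- NULL
  if ("untrackable" %in% names(sessions)) {
    om <- tapply(sessions$untrackable, sessions$group, sum)
    sessions <- sessions[!sessions$untrackable, , drop = FALSE]
  }
  groups <- unique(sessions$group)
  rows <- list()
  for (g in groups) for (e in seq_len(nExposures)) {
    d <- sessions[sessions$group == g & sessions$exposure == e, ,
                  drop = FALSE]
    row <- data.frame(group = g, exposure = e, n = nrow(d))
    metr <- function(v) if (nrow(d)) mean(v, na.rm = TRUE) else NA_real_
    sem <- function(v) if (nrow(d) > 1)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else NA_real_
    row$pct_froze <- if (nrow(d)) 100 * mean(d$n_freeze_bouts > 0)
                     else NA_real_
    for (m in c("total_frozen_s", "total_velocity_cm_s",
                "mobile_velocity_cm_s", "pct_time_upper",
                "latency_to_upper_s"))
      if (m %in% names(sessions)) {
        row[[paste0(m, "_mean")]] <- metr(d[[m]])
        row[[paste0(m, "_sem")]] <- sem(d[[m]])
      }
    rows[[length(rows) + 1L]] <- row
  }
  list(curves = do.call(rbind, rows), omitted = om)
}
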