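#' Build a kymograph from a time-lapse stack along a traced path
#'
#' The path polyline is resampled at 1-pixel steps; at every frame the
#' intensity at each sample is the mean over a short line of `widthPx`
#' pixels perpendicular to the path (bilinear interpolation). The first
#' polyline vertex must be the cell-body end: increasing distance is
#' anterograde.
#'
#' @param stack numeric array (rows x cols x frames) - a single plane or a
#'   maximum projection per frame.
#' @param path matrix or data.frame of polyline vertices in pixels
#'   (columns x, y), at least 2 vertices, within the stack bounds.
#' @param pxSizeUm pixel size, micrometres.
#' @param frameIntervalS frame interval, seconds.
#' @param widthPx odd perpendicular averaging width (default 1).
#' @return a [Kymograph-class].
#' @export
buildKymograph <- function(stack, path, pxSizeUm, frameIntervalS,
                           widthPx = 1L) {
  stopifnot(length(dim(stack)) == 3)
  path <- as.matrix(path)[, 1:2, drop = FALSE]
  if (nrow(path) < 2) stop("path needs at least 2 vertices")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  bad <- which(path[, 1] < 1 | path[, 1] > nc |
               path[, 2] < 1 | path[, 2] > nr)
  if (length(bad))
    stop("path vertex ", bad[1], " (x = ", path[bad[1], 1], ", y = ",
         path[bad[1], 2], ") lies outside the image")
  if (widthPx %% 2 != 1) stop("widthPx must be odd")

  rs <- .resamplePolyline(path, step = 1)
  offs <- seq(-(widthPx - 1) / 2, (widthPx - 1) / 2)
  K <- matrix(0, nrow(rs$pts), nf)
  for (f in seq_len(nf)) {
    frame <- stack[, , f]
    acc <- 0
    for (o in offs) {
      xs <- rs$pts[, 1] + o * rs$normals[, 1]
      ys <- rs$pts[, 2] + o * rs$normals[, 2]
      acc <- acc + .bilinear(frame, xs, ys)
    }
    K[, f] <- acc / length(offs)
  }
  new("Kymograph", intensity = K, pxSizeUm = pxSizeUm,
      frameIntervalS = frameIntervalS)
}

#' Wrap a distance x time profile as a kymograph
#'
#' Convenience for movies emitted directly as intensity profiles (see
#' [simulateParticleMovie()]), bypassing path tracing.
#'
#' @param profile matrix distance x time.
#' @param pxSizeUm micrometres per row.
#' @param frameIntervalS seconds per column.
#' @return a [Kymograph-class].
#' @export
asKymograph <- function(profile, pxSizeUm, frameIntervalS) {
  new("Kymograph", intensity = as.matrix(profile), pxSizeUm = pxSizeUm,
      frameIntervalS = frameIntervalS)
}

# resample a polyline at fixed arc-length steps; returns points and unit
# normals
.resamplePolyline <- function(path, step = 1) {
  seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                          path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  px <- stats::approx(cum, path[, 1], xout = s)$y
  py <- stats::approx(cum, path[, 2], xout = s)$y
  # tangent by central difference
  n <- length(s)
  tx <- c(px[2] - px[1], (px[-(1:2)] - px[1:(n - 2)]) / 2,
          px[n] - px[n - 1])
  ty <- c(py[2] - py[1], (py[-(1:2)] - py[1:(n - 2)]) / 2,
          py[n] - py[n - 1])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  list(pts = cbind(px, py), normals = cbind(-ty / nrm, tx / nrm),
       distance = s)
}

.bilinear <- function(frame, xs, ys) {
  nr <- nrow(frame); nc <- ncol(frame)
  xs <- pmin(pmax(xs, 1), nc); ys <- pmin(pmax(ys, 1), nr)
  x0 <- pmin(floor(xs), nc - 1); y0 <- pmin(floor(ys), nr - 1)
  fx <- xs - x0; fy <- ys - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  frame[i00] * (1 - fx) * (1 - fy) + frame[i01] * fx * (1 - fy) +
    frame[i10] * (1 - fx) * fy + frame[i11] * fx * fy
}

#' Detect particle tracks in a kymograph
#'
#' Per-frame peak detection (local maxima above an adaptive
#' background + `kSigma` x noise threshold, with parabolic sub-pixel
#' refinement) followed by greedy nearest-neighbour linking with a maximum
#' per-frame displacement and short gap closing. Linked tracks are fitted
#' with a constant-velocity line; tracks shorter than `minFrames` frames
#' or `minRunUm` net displacement are discarded unless they clear the
#' motility floor check: a track with net displacement below
#' `motilityFloorUm` is kept but flagged non-motile (stationary vesicle).
#'
#' @param kymo a [Kymograph-class].
#' @param minRunUm minimum net run length for a motile track (default
#'   0.5).
#' @param minFrames minimum track length in frames (default 5).
#' @param maxStepUm maximum per-frame displacement used for linking
#'   (default 2.5 um/s x frame interval x 1.5 safety).
#' @param maxGapFrames frames a track may go undetected before being
#'   closed (default 2).
#' @param kSigma detection threshold in noise SDs above background.
#' @param smoothSigmaPx Gaussian presmoothing along the distance axis
#'   before peak detection (default 1.2 px; 0 disables). Matched-filter
#'   style smoothing roughly doubles the effective peak SNR.
#' @param motilityFloorUm net displacement below which a track is
#'   non-motile (default 0.5).
#' @return data.frame, one row per track: `track_id`, `t_start_s`,
#'   `t_end_s`, `x_start_um`, `x_end_um`, `velocity_um_s` (signed slope),
#'   `run_length_um` (net |displacement|), `duration_s`, `n_frames`,
#'   `direction` (anterograde/retrograde/static), `motile`.
#' @export
detectTracks <- function(kymo, minRunUm = 0.5, minFrames = 5L,
                         maxStepUm = NULL, maxGapFrames = 2L,
                         kSigma = 2.5, smoothSigmaPx = 1.2,
                         motilityFloorUm = 0.5) {
  stopifnot(is(kymo, "Kymograph"))
  K <- kymo@intensity
  px <- kymo@pxSizeUm; dt <- kymo@frameIntervalS
  if (is.null(maxStepUm)) maxStepUm <- 2.5 * dt * 1.5
  maxStepPx <- maxStepUm / px
  if (smoothSigmaPx > 0 && nrow(K) > 8)
    K <- .filterSep(K, .gaussK(smoothSigmaPx), 1)
  bg <- stats::median(K)
  noise <- stats::mad(K)
  # noise-free data: mad collapses to numerical dust; fall back to the
  # global sd so the threshold sits between background and signal
  if (noise <= 1e-6 * max(abs(K))) noise <- max(stats::sd(K), 1e-12)
  thr <- bg + kSigma * noise

  peaks <- lapply(seq_len(ncol(K)), function(f) .framePeaks(K[, f], thr))

  tracks <- list(); active <- list()
  for (f in seq_len(ncol(K))) {
    pk <- peaks[[f]]
    used <- rep(FALSE, length(pk))
    if (length(active) && length(pk)) {
      # globally resolved assignment: repeatedly link the closest
      # (track, peak) pair within its gate. Established tracks accept
      # only small innovations around the constant-velocity prediction;
      # newborn tracks (velocity still unknown) get the full per-frame
      # displacement gate.
      D <- matrix(Inf, length(active), length(pk))
      for (ai in seq_along(active)) {
        a <- active[[ai]]
        gap <- f - a$lastF
        pred <- a$x[length(a$x)] + a$vel * gap
        gate <- if (length(a$x) >= 2) (2 + 2 * gap) else maxStepPx * gap
        d <- abs(pk - pred)
        D[ai, d <= gate] <- d[d <= gate]
      }
      while (any(is.finite(D))) {
        ij <- arrayInd(which.min(D), dim(D))
        ai <- ij[1]; j <- ij[2]
        used[j] <- TRUE
        a <- active[[ai]]
        a$x <- c(a$x, pk[j]); a$f <- c(a$f, f); a$lastF <- f
        nlast <- length(a$x)
        if (nlast >= 2)   # endpoint slope: robust to per-frame jitter
          a$vel <- (a$x[nlast] - a$x[1]) / (a$f[nlast] - a$f[1])
        active[[ai]] <- a
        D[ai, ] <- Inf; D[, j] <- Inf
      }
    }
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(a) f - a$lastF > maxGapFrames,
                      logical(1))
      tracks <- c(tracks, active[stale])
      active <- active[!stale]
    }
    # new tracks from unmatched peaks
    for (p in pk[!used])
      active[[length(active) + 1L]] <- list(x = p, f = f, lastF = f,
                                            vel = 0)
  }
  tracks <- c(tracks, active)

  rows <- lapply(tracks, function(a) {
    if (length(a$f) < minFrames) return(NULL)
    tsec <- (a$f - 1) * dt
    xum <- a$x * px
    fit <- stats::lm.fit(cbind(1, tsec), xum)
    v <- fit$coefficients[2]
    net <- xum[length(xum)] - xum[1]
    motile <- abs(net) >= motilityFloorUm
    if (motile && abs(net) < minRunUm) return(NULL)
    data.frame(t_start_s = tsec[1], t_end_s = tsec[length(tsec)],
               x_start_um = xum[1], x_end_um = xum[length(xum)],
               velocity_um_s = unname(v), run_length_um = abs(net),
               duration_s = tsec[length(tsec)] - tsec[1],
               n_frames = length(a$f),
               direction = if (!motile) "static"
                           else if (net > 0) "anterograde" else "retrograde",
               motile = motile)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(track_id = integer(), t_start_s = numeric(),
                      t_end_s = numeric(), x_start_um = numeric(),
                      x_end_um = numeric(), velocity_um_s = numeric(),
                      run_length_um = numeric(), duration_s = numeric(),
                      n_frames = integer(), direction = character(),
                      motile = logical()))
  out <- do.call(rbind, rows)
  out <- cbind(track_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# local maxima above threshold with parabolic sub-pixel refinement
.framePeaks <- function(col, thr) {
  n <- length(col)
  if (n < 3) return(numeric())
  i <- which(col[2:(n - 1)] >= col[1:(n - 2)] &
             col[2:(n - 1)] >= col[3:n] &
             col[2:(n - 1)] > thr) + 1L
  if (!length(i)) return(numeric())
  # suppress plateaus: keep first of adjacent indices
  i <- i[c(TRUE, diff(i) > 1)]
  denom <- col[i - 1] - 2 * col[i] + col[i + 1]
  delta <- ifelse(abs(denom) > 1e-12,
                  0.5 * (col[i - 1] - col[i + 1]) / denom, 0)
  delta[abs(delta) > 1] <- 0
  i + delta
}

#' Import manually annotated tracks
#'
#' Reads a CSV of hand-traced kymograph tracks (columns `track_id`,
#' `distance_um`, `time_s`, one row per anchor point) and converts each to
#' the same per-track summary as [detectTracks()], fitting a
#' constant-velocity line through the anchors.
#'
#' @param file CSV path.
#' @param motilityFloorUm net displacement below which a track is
#'   non-motile.
#' @return data.frame in the [detectTracks()] layout.
#' @export
importTracks <- function(file, motilityFloorUm = 0.5) {
  d <- utils::read.csv(file)
  stopifnot(all(c("track_id", "distance_um", "time_s") %in% names(d)))
  rows <- lapply(split(d, d$track_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    if (nrow(tr) < 2) return(NULL)
    fit <- stats::lm.fit(cbind(1, tr$time_s), tr$distance_um)
    net <- tr$distance_um[nrow(tr)] - tr$distance_um[1]
    motile <- abs(net) >= motilityFloorUm
    data.frame(track_id = tr$track_id[1], t_start_s = tr$time_s[1],
               t_end_s = tr$time_s[nrow(tr)],
               x_start_um = tr$distance_um[1],
               x_end_um = tr$distance_um[nrow(tr)],
               velocity_um_s = unname(fit$coefficients[2]),
               run_length_um = abs(net),
               duration_s = tr$time_s[nrow(tr)] - tr$time_s[1],
               n_frames = nrow(tr),
               direction = if (!motile) "static"
                           else if (net > 0) "anterograde" else "retrograde",
               motile = motile)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Match detected tracks against ground truth
#'
#' Greedy one-to-one matching: each truth track is paired with the
#' unused detected track whose constant-velocity position at the truth's
#' temporal midpoint is closest, provided the detection overlaps that
#' midpoint within `slackS` seconds and the position error is below
#' `maxDistUm`. Reports detection precision, recall, F1 and the
#' direction agreement among matched pairs.
#'
#' @param detected track table from [detectTracks()].
#' @param truth ground-truth table from [simulateParticleMovie()].
#' @param maxDistUm maximum midpoint position error for a match.
#' @param slackS temporal slack around the detection's span.
#' @return list with `tp`, `precision`, `recall`, `f1`,
#'   `directionAccuracy`.
#' @export
matchTracks <- function(detected, truth, maxDistUm = 2, slackS = 5) {
  nd <- nrow(detected); nt <- nrow(truth)
  used <- rep(FALSE, max(nd, 1)); tp <- 0; dirok <- 0
  for (i in seq_len(nt)) {
    tm <- (truth$t_start_s[i] + truth$t_end_s[i]) / 2
    xm <- (truth$x_start_um[i] + truth$x_end_um[i]) / 2
    best <- NA; bd <- Inf
    for (j in seq_len(nd)) {
      if (used[j]) next
      if (tm < detected$t_start_s[j] - slackS ||
          tm > detected$t_end_s[j] + slackS) next
      xj <- detected$x_start_um[j] +
        detected$velocity_um_s[j] * (tm - detected$t_start_s[j])
      d <- abs(xj - xm)
      if (d < bd) { bd <- d; best <- j }
    }
    if (!is.na(best) && bd <= maxDistUm) {
      used[best] <- TRUE
      tp <- tp + 1
      if (detected$direction[best] == truth$direction[i])
        dirok <- dirok + 1
    }
  }
  precision <- tp / max(nd, 1)
  recall <- tp / max(nt, 1)
  list(tp = tp, precision = precision, recall = recall,
       f1 = 2 * precision * recall / max(precision + recall, 1e-12),
       directionAccuracy = if (tp) dirok / tp else NA_real_)
}

#' Transport summary statistics from a track table
#'
#' @param tracks track data.frame ([detectTracks()] layout or the
#'   ground-truth table from [simulateParticleMovie()]; a `motile` column
#'   is inferred from `direction` if absent).
#' @param segmentLengthUm analyzed segment length, micrometres.
#' @param durationMin observation duration, minutes.
#' @return list with `nTracks`, `frequencyPer10umPerMin`
#'   (tracks / min / 10 um), `pctRetrograde` (of all directional tracks),
#'   `pctAnterogradeOfMotile`, `meanRunLengthUm` and `maxRunLengthUm` by
#'   direction, `meanVelocityUmS` by direction (magnitudes),
#'   `meanDurationS`.
#' @examples
#' tr <- data.frame(velocity_um_s = c(0.5, -0.3), run_length_um = c(10, 6),
#'   duration_s = c(20, 20), direction = c("anterograde", "retrograde"))
#' transportSummary(tr, segmentLengthUm = 20, durationMin = 6)$frequencyPer10umPerMin
#' @export
transportSummary <- function(tracks, segmentLengthUm, durationMin) {
  if (segmentLengthUm <= 0 || durationMin <= 0)
    stop("segmentLengthUm and durationMin must be > 0")
  if (!"motile" %in% names(tracks))
    tracks$motile <- tracks$direction %in% c("anterograde", "retrograde")
  n <- nrow(tracks)
  mot <- tracks[tracks$motile, , drop = FALSE]
  dirTab <- function(dirn, fun, col)
    if (any(mot$direction == dirn))
      fun(mot[[col]][mot$direction == dirn]) else NA_real_
  ndir <- sum(mot$direction %in% c("anterograde", "retrograde"))
  list(
    nTracks = n,
    frequencyPer10umPerMin = n / durationMin / (segmentLengthUm / 10),
    pctRetrograde = if (ndir) 100 * sum(mot$direction == "retrograde") /
      ndir else NA_real_,
    pctAnterogradeOfMotile = if (nrow(mot)) 100 *
      mean(mot$direction == "anterograde") else NA_real_,
    meanRunLengthUm = c(
      anterograde = dirTab("anterograde", mean, "run_length_um"),
      retrograde = dirTab("retrograde", mean, "run_length_um"),
      all = if (nrow(mot)) mean(mot$run_length_um) else NA_real_),
    maxRunLengthUm = c(
      anterograde = dirTab("anterograde", max, "run_length_um"),
      retrograde = dirTab("retrograde", max, "run_length_um")),
    meanVelocityUmS = c(
      anterograde = dirTab("anterograde", function(x) mean(abs(x)),
                           "velocity_um_s"),
      retrograde = dirTab("retrograde", function(x) mean(abs(x)),
                          "velocity_um_s")),
    meanDurationS = if (n) mean(tracks$duration_s) else NA_real_)
}

#' Branch-point accumulation after photoactivation
#'
#' Frames after the activation frame are split into `nWindows` equal
#' spans; each window is maximum-projected over time and the mean
#' intensity in the branch-point ROI measured. The pre-activation
#' background (same statistic over the frames before activation) is
#' subtracted, values are divided by the corrected first window (t1) and
#' reported as percent of t1. The normalized series is invariant to
#' affine intensity rescaling of the whole stack.
#'
#' @param stack numeric array rows x cols x frames.
#' @param roi integer(4), `c(row0, row1, col0, col1)` branch-point ROI.
#' @param activationFrame index of the activation frame; windows start at
#'   the next frame.
#' @param nWindows number of time windows (default 4, the t1-t4 scheme).
#' @return list with `windowMeans` (raw), `background`, `normalizedPct`
#'   (t1 = 100), `valid` (FALSE when corrected t1 <= 0, in which case
#'   `normalizedPct` is NA).
#' @export
branchpointAccumulation <- function(stack, roi, activationFrame,
                                    nWindows = 4L) {
  stopifnot(length(dim(stack)) == 3, length(roi) == 4)
  nf <- dim(stack)[3]
  if (activationFrame < 1 || activationFrame >= nf)
    stop("activationFrame must lie within the stack, before its last frame")
  if (roi[1] < 1 || roi[2] > dim(stack)[1] || roi[3] < 1 ||
      roi[4] > dim(stack)[2] || roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi outside stack bounds")
  roiMeanMax <- function(frames) {
    sub <- stack[roi[1]:roi[2], roi[3]:roi[4], frames, drop = FALSE]
    mean(apply(sub, c(1, 2), max))
  }
  post <- (activationFrame + 1L):nf
  cuts <- floor(seq(0, length(post), length.out = nWindows + 1L))
  wm <- vapply(seq_len(nWindows), function(k)
    roiMeanMax(post[(cuts[k] + 1L):cuts[k + 1L]]), numeric(1))
  bgFrames <- seq_len(activationFrame)
  bg <- roiMeanMax(bgFrames)
  corr <- wm - bg
  if (corr[1] <= 0)
    return(list(windowMeans = wm, background = bg,
                normalizedPct = rep(NA_real_, nWindows), valid = FALSE))
  list(windowMeans = wm, background = bg,
       normalizedPct = 100 * corr / corr[1], valid = TRUE)
}
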