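#' Render a synthetic particle movie along a 1D path
#'
#' Each particle moves at constant signed velocity from its start time and
#' position until its run length is consumed (or it exits the path, in
#' which case the truncated run is what ground truth records). Positive
#' velocity is anterograde (increasing distance from the cell body).
#' Particles are rendered as Gaussian puncta (sigma `puncSigmaPx`) on a
#' constant background; `render = "profile"` emits the (distance x time)
#' intensity matrix directly (separating rendering from path-tracing
#' errors), `render = "stack"` emits a 2D+t array with the path along the
#' middle row.
#'
#' @param spec a [MovieSpec-class].
#' @param render `"profile"` or `"stack"`.
#' @param puncSigmaPx Gaussian punctum sigma in pixels.
#' @param stackHalfWidthPx for `render = "stack"`, half-width of the image
#'   perpendicular to the path.
#' @return list with
#'   \describe{
#'     \item{profile}{matrix distance x time (or `stack`: array y x x x t).}
#'     \item{tracks}{ground-truth data.frame, one row per particle:
#'       `t_start_s`, `t_end_s`, `x_start_um`, `x_end_um`,
#'       `velocity_um_s`, `run_length_um` (after truncation at the path
#'       ends), `duration_s`, `direction` (anterograde/retrograde/static).}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' mv <- movieSpec(particles = data.frame(t_start_s = 0, x_start_um = 2,
#'   velocity_um_s = -0.3, run_length_um = 6, intensity = 1))
#' simulateParticleMovie(mv)$tracks$direction  # "retrograde"
#' @export
simulateParticleMovie <- function(spec, render = c("profile", "stack"),
                                  puncSigmaPx = 1.5, stackHalfWidthPx = 4L) {
  stopifnot(is(spec, "MovieSpec"))
  validObject(spec)
  render <- match.arg(render)
  set.seed(spec@seed)

  npx <- max(2L, round(spec@pathLengthUm / spec@pxSizeUm))
  times <- (seq_len(spec@nFrames) - 1L) * spec@frameIntervalS
  p <- spec@particles

  gt <- .movieGroundTruth(p, spec@pathLengthUm)

  prof <- matrix(spec@background, npx, spec@nFrames)
  if (nrow(p)) {
    xs_px <- seq_len(npx)
    for (i in seq_len(nrow(p))) {
      for (f in seq_len(spec@nFrames)) {
        t <- times[f]
        if (t < gt$t_start_s[i] || t > gt$t_end_s[i]) next
        x_um <- p$x_start_um[i] + p$velocity_um_s[i] * (t - p$t_start_s[i])
        x_px <- x_um / spec@pxSizeUm + 0.5   # pixel j covers ((j-1)px, j*px]
        prof[, f] <- prof[, f] +
          p$intensity[i] * exp(-(xs_px - x_px)^2 / (2 * puncSigmaPx^2))
      }
    }
  }
  if (is.finite(spec@snr)) {
    amp <- if (nrow(p)) max(p$intensity) else 1
    prof <- prof + matrix(stats::rnorm(length(prof), 0, amp / spec@snr),
                          nrow(prof), ncol(prof))
  }

  out <- list(tracks = gt, spec = spec)
  if (render == "profile") {
    out$profile <- prof
  } else {
    ny <- 2L * stackHalfWidthPx + 1L
    stack <- array(spec@background, dim = c(ny, npx, spec@nFrames))
    lat <- exp(-((seq_len(ny) - (stackHalfWidthPx + 1L))^2) /
                 (2 * puncSigmaPx^2))
    for (f in seq_len(spec@nFrames)) {
      sig <- prof[, f] - spec@background
      stack[, , f] <- spec@background + outer(lat, sig)
    }
    out$stack <- stack
    out$pathRow <- stackHalfWidthPx + 1L
  }
  out
}

#' Standard benchmark movie specification
#'
#' A reproducible multi-particle movie used to benchmark track detection:
#' particles get signed velocities of 0.2-1.2 um/s, run durations of
#' 20-50 s (so every truth spans well over the detector's minimum track
#' length at 2.5 s frames) with run lengths capped at 25 um, start
#' positions placed so the full run fits on the 40 um path, and start
#' times spread over the movie.
#'
#' @param seed RNG seed (also seeds the rendering noise).
#' @param nParticles number of particles (default 20).
#' @param snr rendering SNR (default 3).
#' @return a [MovieSpec-class].
#' @export
movieBenchmarkSpec <- function(seed, nParticles = 20L, snr = 3) {
  set.seed(seed)
  np <- nParticles
  v <- sample(c(-1, 1), np, TRUE) * stats::runif(np, 0.2, 1.2)
  dur <- stats::runif(np, 20, 50)
  run <- pmin(abs(v) * dur, 25)
  x0 <- ifelse(v > 0, stats::runif(np, 2, 38 - run),
               stats::runif(np, 2 + run, 38))
  movieSpec(pathLengthUm = 40, pxSizeUm = 0.2, frameIntervalS = 2.5,
            nFrames = 100L,
            particles = data.frame(t_start_s = stats::runif(np, 0,
                                                            200 - dur),
                                   x_start_um = x0, velocity_um_s = v,
                                   run_length_um = run, intensity = 1),
            background = 0.1, snr = snr, seed = seed)
}

# Ground-truth kinetics with truncation at the path boundaries [0, L]
.movieGroundTruth <- function(p, L) {
  n <- nrow(p)
  if (!n)
    return(data.frame(t_start_s = numeric(), t_end_s = numeric(),
                      x_start_um = numeric(), x_end_um = numeric(),
                      velocity_um_s = numeric(), run_length_um = numeric(),
                      duration_s = numeric(), direction = character()))
  v <- p$velocity_um_s
  dur_full <- ifelse(v == 0, Inf, p$run_length_um / abs(v))
  # time until the particle exits [0, L]
  t_exit <- ifelse(v > 0, (L - p$x_start_um) / v,
            ifelse(v < 0, (0 - p$x_start_um) / v, Inf))
  dur <- pmin(dur_full, pmax(t_exit, 0))
  x_end <- p$x_start_um + v * dur
  data.frame(
    t_start_s = p$t_start_s,
    t_end_s = p$t_start_s + dur,
    x_start_um = p$x_start_um,
    x_end_um = x_end,
    velocity_um_s = v,
    run_length_um = abs(x_end - p$x_start_um),
    duration_s = dur,
    direction = ifelse(v > 0, "anterograde",
                ifelse(v < 0, "retrograde", "static"))
  )
}
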