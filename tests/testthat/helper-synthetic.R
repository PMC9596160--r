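# Shared synthetic fixtures built in code.

# noise-free single-orientation arbor spec
singleAngleSpec <- function(theta, seed, snr = Inf, nSegments = 15L) {
  arborSpec(nSegments = nSegments, snr = snr, seed = seed,
            mixture = data.frame(mean_deg = theta, kappa = Inf, weight = 1))
}

# full-field sinusoidal grating at a given axial angle (degrees);
# infinite parallel lines, no end caps
makeGrating <- function(theta, n = 128, freq = 0.12) {
  a <- theta * pi / 180
  outer(seq_len(n), seq_len(n), function(r, c)
    0.5 + 0.5 * cos(2 * pi * freq * (c * (-sin(a)) + (-r) * cos(a))))
}

# shortest axial distance between two angles in degrees
axialDiff <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  abs(ifelse(d <= -90, d + 180, d))
}

argmaxAngle <- function(profile) {
  binCenters(profile)[which.max(profileValues(profile)[1, ])]
}

# brute-force central-difference gradient orientation map (axial degrees)
bruteForceOrientation <- function(img) {
  gx <- (cbind(img[, -1], img[, ncol(img)]) -
         cbind(img[, 1], img[, -ncol(img)])) / 2
  gy <- -(rbind(img[-1, ], img[nrow(img), ]) -
          rbind(img[1, ], img[-nrow(img), ])) / 2
  ang <- atan2(gy, gx) * 180 / pi + 90
  ang <- (ang + 90) %% 180 - 90
  ang[ang <= -90] <- ang[ang <= -90] + 180
  list(angle = ang, magnitude = gx^2 + gy^2)
}

# simple constant-speed trajectory builder (cm, seconds)
makeTrajectory <- function(speeds, fps = 10, x0 = 5, y0 = 5, heading = 0) {
  n <- length(speeds) + 1L
  dx <- cos(heading) * speeds / fps
  dy <- sin(heading) * speeds / fps
  data.frame(t_s = (seq_len(n) - 1) / fps,
             x_cm = cumsum(c(x0, dx)),
             y_cm = cumsum(c(y0, dy)))
}
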