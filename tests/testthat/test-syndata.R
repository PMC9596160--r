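test_that("spec constructors validate their invariants", {
  expect_error(arborSpec(mixture = data.frame(mean_deg = 0, kappa = 1,
                                              weight = 0.7)),
               "weights")
  expect_error(arborSpec(pxSizeUm = 0), "pxSizeUm")
  expect_error(arborSpec(snr = 0), "snr")
  expect_error(eventTableSpec(gcbLossProb = 1.5), "probabilities")
  expect_error(trajectorySpec(fps = 0), "fps")
  expect_error(movieSpec(frameIntervalS = 0), "frameIntervalS")
})

test_that("arbor generator is seed-deterministic and closes over ground truth", {
  a <- simulateArbor(arborSpec(seed = 7))
  b <- simulateArbor(arborSpec(seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$segments, b$segments)
  expect_identical(a$bandCounts, b$bandCounts)
  # every rendered segment appears exactly once in ground truth
  expect_identical(nrow(a$segments), 20L)
  c2 <- simulateArbor(arborSpec(seed = 8))
  expect_false(identical(a$image, c2$image))
})

test_that("degenerate mixture pins every segment angle to the mean", {
  sim <- simulateArbor(arborSpec(nSegments = 50L, seed = 3, snr = Inf,
    minSeparationUm = 0,
    mixture = data.frame(mean_deg = -60, kappa = Inf, weight = 1)))
  expect_equal(sim$segments$angle_deg, rep(-60, 50))
})

test_that("two-component mixture proportions fall inside the binomial 99% CI", {
  sim <- simulateArbor(arborSpec(
    nSegments = 200L, seed = 22, imageSize = c(320L, 320L),
    minSeparationUm = 0, segmentLengthUm = c(10, 20),
    mixture = data.frame(mean_deg = c(0, 45), kappa = c(Inf, Inf),
                         weight = c(0.5, 0.5))))
  p0 <- mean(axialDiff(sim$segments$angle_deg, 0) < 1)
  ci <- qnorm(c(0.005, 0.995), 0.5, sqrt(0.25 / 200))
  expect_gt(p0, ci[1])
  expect_lt(p0, ci[2])
})

test_that("particle ground truth follows d = L/v and the sign convention", {
  mv <- movieSpec(particles = data.frame(
    t_start_s = c(0, 5), x_start_um = c(5, 20),
    velocity_um_s = c(0.5, -0.3), run_length_um = c(10, 6),
    intensity = 1))
  gt <- simulateParticleMovie(mv)$tracks
  expect_equal(gt$duration_s[1], 20)
  expect_equal(gt$direction, c("anterograde", "retrograde"))
  # particle exiting the path: run truncated, not an error
  mv2 <- movieSpec(pathLengthUm = 10, particles = data.frame(
    t_start_s = 0, x_start_um = 8, velocity_um_s = 1, run_length_um = 10,
    intensity = 1))
  gt2 <- simulateParticleMovie(mv2)$tracks
  expect_equal(gt2$run_length_um, 2)
  expect_equal(gt2$x_end_um, 10)
})

test_that("noise-free rendered puncta sit on the analytic positions within 0.5 px", {
  mv <- movieBenchmarkSpec(seed = 5, nParticles = 10L, snr = Inf)
  sim <- simulateParticleMovie(mv)
  prof <- sim$profile
  px <- mv@pxSizeUm; dt <- mv@frameIntervalS
  checked <- 0
  for (f in seq_len(ncol(prof))) {
    t <- (f - 1) * dt
    act <- which(sim$tracks$t_start_s <= t & sim$tracks$t_end_s >= t)
    if (!length(act)) next
    xs <- (sim$tracks$x_start_um[act] + sim$tracks$velocity_um_s[act] *
             (t - sim$tracks$t_start_s[act])) / px + 0.5
    pk <- arborquant:::.framePeaks(prof[, f], 0.5)
    for (k in seq_along(act)) {
      # peaks of near-coincident particles merge; only isolated puncta
      # must sit on the analytic position
      if (length(xs) > 1 && min(abs(xs[-k] - xs[k])) < 8) next
      expect_lt(min(abs(pk - xs[k])), 0.5)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 80)
})

test_that("event tables follow the Poisson/Bernoulli generative model", {
  expect_identical(
    nrow(simulateEventTable(eventTableSpec(gcbRatePerH = 0,
                                           ibRatePerH = 0))), 0L)
  ev <- simulateEventTable(eventTableSpec(nNeurons = 50L, gcbLossProb = 1,
                                          seed = 2))
  expect_true(all(ev$retracted[ev$type == "GCB"]))
  expect_true(all(ev$t_retract_min[ev$retracted] >=
                    ev$t_init_min[ev$retracted]))
  expect_true(all(is.na(ev$t_retract_min[!ev$retracted])))
  # Poisson moments: rate 2/h, 100 neurons, 2 h -> 400 +- 3*20
  ev2 <- simulateEventTable(eventTableSpec(nNeurons = 100L, durationH = 2,
                                           gcbRatePerH = 2, ibRatePerH = 0,
                                           seed = 5))
  expect_lt(abs(sum(ev2$type == "GCB") - 400), 3 * 20)
  expect_identical(simulateEventTable(eventTableSpec(seed = 9)),
                   simulateEventTable(eventTableSpec(seed = 9)))
})

test_that("trajectory generator honors zone confinement and bout labels", {
  tr <- simulateTrajectory(trajectorySpec(durationS = 60, seed = 4,
                                          upperZonePreference = 0))
  expect_identical(tr$upperFraction, 0)
  expect_true(all(tr$trajectory$y_cm <= 18 / 2))
  # all mass in freeze: one bout spanning the session
  tr2 <- simulateTrajectory(trajectorySpec(durationS = 30, seed = 4,
    pFreeze = 1, dwellMeanS = c(swim = 1e-9, pause = 0.5, freeze = 1e6)))
  expect_identical(nrow(tr2$freezeBouts), 1L)
  expect_equal(tr2$freezeBouts$duration_s, 30, tolerance = 0.1)
  # labelled freeze bouts satisfy the minimum duration (truncation aside)
  tr3 <- simulateTrajectory(trajectorySpec(durationS = 300, seed = 11,
                                           pFreeze = 0.5))
  full <- tr3$freezeBouts[tr3$freezeBouts$end_frame < 3000, , drop = FALSE]
  expect_true(all(full$duration_s >= 3))
  # state runs partition the session (ground-truth closure)
  expect_identical(sum(tr3$bouts$end_frame - tr3$bouts$start_frame + 1L),
                   3000L)
})

test_that("semi-Markov dwell parameters reproduce the expected freeze fraction", {
  # pFreeze = 1: cycle = swim dwell (Exp mean 14, floored at 2 frames)
  # then freeze dwell (3 + Exp mean 3). E[max(m, Exp(mu))] = m + mu e^(-m/mu).
  muS <- 14; m <- 0.2
  eSwim <- m + muS * exp(-m / muS)
  expected <- 6 / (6 + eSwim)
  fr <- vapply(1:50, function(s)
    sum(simulateTrajectory(trajectorySpec(durationS = 600, seed = 400 + s,
      pFreeze = 1, dwellMeanS = c(swim = muS, pause = 0.8, freeze = 6)
    ))$freezeBouts$duration_s) / 600, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se)
})
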