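test_that("touch response measures swim time and bouts operationally", {
  tr <- rep(FALSE, 1050); tr[10:60] <- TRUE
  r <- touchResponse(tr, stimFrame = 5)
  expect_true(r$responded)
  expect_equal(r$responseTimeS, 1)
  expect_identical(r$nBouts, 1L)
  # two runs separated by 8 frames: 2 bouts, response spans both
  tr2 <- rep(FALSE, 1050); tr2[10:40] <- TRUE; tr2[49:79] <- TRUE
  r2 <- touchResponse(tr2, stimFrame = 5)
  expect_identical(r2$nBouts, 2L)
  expect_equal(r2$responseTimeS, (79 - 10) / 50)
  # no movement: non-responder, excluded from summaries
  r3 <- touchResponse(rep(FALSE, 1050), stimFrame = 5)
  expect_false(r3$responded)
  expect_true(is.na(r3$responseTimeS))
})

test_that("bout counts equal a run-length-encoding oracle", {
  for (s in 1:20) {
    set.seed(s)
    tr <- runif(400) < 0.4
    tr[1:9] <- FALSE
    r <- touchResponse(tr, stimFrame = 10, pauseFrames = 15, boutGapFrames = 5)
    post <- which(tr & seq_along(tr) >= 10)
    if (!length(post)) { expect_false(r$responded); next }
    gaps <- diff(post)
    stopAt <- which(gaps > 15)
    last <- if (length(stopAt)) post[stopAt[1]] else post[length(post)]
    kept <- post[post <= last]
    oracleBouts <- 1L + sum(diff(kept) > 5)
    expect_identical(r$nBouts, oracleBouts)
    expect_equal(r$responseTimeS, (last - kept[1]) / 50)
  }
})

test_that("freezing bouts respect the 3 s boundary inclusively", {
  fps <- 10
  sp <- c(rep(2, 20), rep(0, 30), rep(2, 20))       # exactly 3.0 s immobile
  traj <- makeTrajectory(sp, fps = fps)
  b <- detectFreezing(traj, fps = fps)
  expect_identical(nrow(b), 1L)
  expect_equal(b$duration_s, 3)
  sp2 <- c(rep(2, 20), rep(0, 29), rep(2, 20))      # 2.9 s: below threshold
  expect_identical(nrow(detectFreezing(makeTrajectory(sp2, fps = fps),
                                       fps = fps)), 0L)
})

test_that("programmed bouts are recovered with frame-accurate endpoints", {
  for (s in 1:10) {
    tr <- simulateTrajectory(trajectorySpec(durationS = 300, seed = 200 + s,
                                            pFreeze = 0.5,
                                            freezeJitterCmS = 0.05))
    det <- detectFreezing(tr$trajectory, fps = 10)
    gt <- tr$freezeBouts[tr$freezeBouts$duration_s >= 3, , drop = FALSE]
    expect_identical(nrow(det), nrow(gt))
    if (nrow(gt)) {
      expect_true(all(abs(det$start_frame - gt$start_frame) <= 1))
      expect_true(all(abs(det$end_frame - gt$end_frame) <= 1))
    }
  }
})

test_that("tank sessions conserve zone time and order the velocities", {
  # constant swimming: total = mobile
  traj <- makeTrajectory(rep(2, 1799), fps = 10, x0 = 2, y0 = 4,
                         heading = pi / 2)
  traj$y_cm <- 4 + (traj$y_cm - 4) %% 10          # keep inside a 14-cm tank
  s <- tankSession(traj, tankHeightCm = 14, fps = 10)
  expect_equal(s$timeInUpperS + s$timeInLowerS, s$sessionLengthS)
  expect_equal(s$totalVelocityCmS, 2, tolerance = 0.05)
  expect_equal(s$mobileVelocityCmS, s$totalVelocityCmS, tolerance = 1e-9)
  # half swimming at 2 cm/s, half frozen: total 1, mobile 2
  sp <- c(rep(2, 900), rep(0, 899))
  s2 <- tankSession(makeTrajectory(sp, fps = 10, y0 = 2), tankHeightCm = 14,
                    fps = 10)
  expect_equal(s2$totalVelocityCmS, 1, tolerance = 0.01)
  expect_equal(s2$mobileVelocityCmS, 2, tolerance = 0.01)
  # never leaving the lower zone
  low <- makeTrajectory(rep(1, 599), fps = 10, x0 = 2, y0 = 2)
  low$y_cm <- pmin(low$y_cm, 6)
  s3 <- tankSession(low, tankHeightCm = 14, fps = 10)
  expect_false(s3$enteredUpper)
  expect_equal(s3$pctTimeUpper, 0)
  expect_true(is.na(s3$latencyToUpperS))
})

test_that("mobile velocity dominates total velocity across simulated fish", {
  for (s in 1:15) {
    tr <- simulateTrajectory(trajectorySpec(durationS = 120, seed = 300 + s))
    ss <- tankSession(tr$trajectory, tankHeightCm = 18, fps = 10)
    expect_equal(ss$timeInUpperS + ss$timeInLowerS, ss$sessionLengthS)
    if (!is.na(ss$mobileVelocityCmS))
      expect_gte(ss$mobileVelocityCmS, ss$totalVelocityCmS - 1e-9)
  }
})

test_that("group statistics aggregate entries, freezes and run the right tests", {
  sess <- data.frame(group = rep(c("wt", "mut"), c(11, 10)),
                     entered_upper = c(rep(TRUE, 10), FALSE,
                                       rep(FALSE, 8), TRUE, TRUE),
                     n_freeze_bouts = c(rep(0L, 11), rep(2L, 6),
                                        rep(0L, 4)))
  gs <- groupSessionStats(sess)
  wt <- gs$groupSummary[gs$groupSummary$group == "wt", ]
  expect_equal(wt$pct_entered_upper, 100 * 10 / 11, tolerance = 1e-6)
  expect_equal(wt$pct_froze, 0)
  expect_true(all(c("entered_upper", "froze") %in% gs$tests$metric))
  expect_true(all(!is.na(gs$tests$p)))
  # per-day percentages
  sess$day <- rep(1:3, length.out = nrow(sess))
  gs2 <- groupSessionStats(sess)
  expect_false(is.null(gs2$perDay))
  expect_true(all(gs2$perDay$n > 0))
})

test_that("habituation curves are flat for identical sessions and NA when absent", {
  base <- data.frame(group = "wt", exposure = rep(1:6, each = 4),
                     n_freeze_bouts = 1L, total_frozen_s = 10,
                     pct_time_upper = 20)
  hs <- habituationSeries(base)
  expect_true(all(hs$curves$pct_froze == 100))
  expect_true(all(hs$curves$total_frozen_s_mean == 10))
  # one exposure missing entirely: NA point, not zero
  gap <- base[base$exposure != 4, ]
  hs2 <- habituationSeries(gap)
  expect_true(is.na(hs2$curves$pct_froze[hs2$curves$exposure == 4]))
  # untrackable sessions are omitted and counted
  base$untrackable <- FALSE
  base$untrackable[1:3] <- TRUE
  hs3 <- habituationSeries(base)
  expect_identical(unname(hs3$omitted[["wt"]]), 3L)
})

test_that("declining freeze probability yields declining freeze curves", {
  rho <- vapply(1:100, function(r) {
    set.seed(r)
    p <- seq(0.6, 0.1, length.out = 6)
    sess <- do.call(rbind, lapply(1:6, function(e)
      data.frame(group = "mut", exposure = e,
                 n_freeze_bouts = rbinom(20, 1, p[e]))))
    cv <- habituationSeries(sess)$curves
    suppressWarnings(cor(cv$exposure, cv$pct_froze, method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rho < 0, na.rm = TRUE), 0.95)
})
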