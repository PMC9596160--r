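test_that("ROI grids are non-overlapping, ordered dorsal to ventral", {
  g <- roiGrid(spanUm = c(5, 75), nRois = 8, roiHeightUm = 3,
               xExtentUm = c(0, 80))
  expect_identical(nrow(g$bands), 8L)
  expect_true(all(diff(g$bands$y0_um) > 0))
  expect_true(all(g$bands$y0_um[-1] >= g$bands$y1_um[-8]))
  expect_error(roiGrid(c(0, 10), 8, 3, c(0, 80)), "overlap")
})

test_that("branch crossing counts: blank image, ground truth, scale invariance", {
  blank <- matrix(0, 160, 160)
  g <- roiGrid(c(0, 80), 8, 3, c(0, 80))
  expect_identical(countBranchCrossings(blank, g, 0.5), rep(0L, 8))
  for (s in c(1, 5, 9, 13, 17)) {
    sim <- simulateArbor(arborSpec(nSegments = 15L, snr = Inf, seed = s))
    cc <- countBranchCrossings(sim$image, sim$grid, 0.5)
    expect_identical(as.integer(cc), as.integer(sim$bandCounts))
    # global intensity scaling leaves Otsu-based counts unchanged
    cc3 <- countBranchCrossings(sim$image * 3, sim$grid, 0.5)
    expect_identical(cc3, cc)
  }
  gBad <- roiGrid(c(0, 100), 8, 3, c(0, 80))
  expect_error(countBranchCrossings(blank, gBad, 0.5),
               "band [0-9]+ lies outside")
})

test_that("density comparison mirrors the AUC machinery", {
  a <- matrix(rep(c(5, 7, 9, 9, 7, 5, 4, 3), each = 4), 4, 8, byrow = FALSE)
  a <- matrix(c(5, 7, 9, 9, 7, 5, 4, 3), 4, 8, byrow = TRUE)
  cmp <- compareDensity(a, a)
  expect_equal(cmp@pValue, 1)
  half <- a / 2
  cmp2 <- compareDensity(a, half)
  expect_equal(mean(cmp2@aucA) / mean(cmp2@aucB), 2)
})

test_that("initiation rate and loss ratio are exact recounts", {
  ev <- data.frame(neuron_id = 1, type = "GCB",
                   t_init_min = c(10, 30, 50, 70), retracted = FALSE)
  expect_equal(initiationRate(ev, 1, 2)$rate[["GCB"]], 2)
  empty <- ev[0, ]
  expect_equal(initiationRate(empty, 5, 2)$rate[["GCB"]], 0)
  ev2 <- data.frame(neuron_id = 1, type = "GCB",
                    retracted = c(rep(TRUE, 7), rep(FALSE, 5)))
  expect_equal(lossRatio(ev2)$ratio[["GCB"]], 7 / 12)
  ev3 <- data.frame(neuron_id = 1, type = "GCB", retracted = rep(FALSE, 6))
  expect_equal(lossRatio(ev3)$ratio[["GCB"]], 0)
  expect_true(is.na(lossRatio(ev3)$ratio[["IB"]]))   # undefined, not zero
  # against an independent recount on a simulated table
  sim <- simulateEventTable(eventTableSpec(nNeurons = 40L, seed = 31))
  ir <- initiationRate(sim, 40, 2)
  for (ty in c("GCB", "IB"))
    expect_equal(ir$rate[[ty]], sum(sim$type == ty) / 40 / 2)
  lr <- lossRatio(sim)
  for (ty in c("GCB", "IB"))
    expect_equal(lr$ratio[[ty]],
                 sum(sim$retracted & sim$type == ty) / sum(sim$type == ty))
})

test_that("retraction direction bias reports percentages and honest type I error", {
  ev <- data.frame(neuron_id = rep(1:2, each = 3), retracted = TRUE,
                   direction = "anterior")
  rb <- retractionDirectionBias(ev)
  expect_equal(rb$perNeuron$pct_anterior, c(100, 100))
  ev2 <- data.frame(neuron_id = 1, retracted = TRUE,
                    direction = rep(c("anterior", "posterior"), 4))
  expect_equal(retractionDirectionBias(ev2)$perNeuron$pct_anterior, 50)
  # unbiased directions: significant in few replicates
  sig <- vapply(1:100, function(r) {
    set.seed(r)
    d <- data.frame(neuron_id = rep(1:100, each = 4), retracted = TRUE,
                    direction = sample(c("anterior", "posterior"),
                                       400, TRUE))
    p <- retractionDirectionBias(d)$pValue
    !is.na(p) && p < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.10)
})

test_that("growth velocity is path length over time, direction-blind", {
  expect_equal(growthVelocity(data.frame(t_min = c(0, 5),
                                         x_um = c(0, 10), y_um = 0)), 2)
  expect_equal(growthVelocity(data.frame(t_min = 0:3, x_um = 1, y_um = 2)),
               0)
  # zig-zag: 20 equal 1-um steps in 10 min -> 2 um/min whatever the turns
  set.seed(3)
  ang <- runif(20, 0, 2 * pi)
  zz <- data.frame(t_min = seq(0, 10, length.out = 21),
                   x_um = cumsum(c(0, cos(ang))),
                   y_um = cumsum(c(0, sin(ang))))
  expect_equal(growthVelocity(zz), 2)
  # invariant under time reversal
  rev <- data.frame(t_min = zz$t_min, x_um = rev(zz$x_um),
                    y_um = rev(zz$y_um))
  expect_equal(growthVelocity(rev), growthVelocity(zz))
})

test_that("rose histograms count every step and split the half-planes", {
  post <- data.frame(t_min = 0:10, x_um = (0:10) * 2, y_um = 0)
  rh <- growthDirectionHistogram(post)
  expect_identical(sum(rh$counts), 10L)
  expect_equal(rh$posteriorFraction, 1)
  expect_equal(rh$anteriorFraction, 0)
  # anterior-ventral step lands in the expected quadrant sector
  av <- data.frame(t_min = 0:1, x_um = c(0, -1), y_um = c(0, 1))
  rha <- growthDirectionHistogram(av)
  expect_gte(rha$angles, 180); expect_lt(rha$angles, 270)
  # symmetric random walk: anterior share near 1/2 within 3 sigma
  set.seed(8)
  n <- 1e4
  steps <- complex(argument = runif(n, 0, 2 * pi))
  rw <- data.frame(t_min = 0:n, x_um = cumsum(c(0, Re(steps))),
                   y_um = cumsum(c(0, Im(steps))))
  rhw <- growthDirectionHistogram(rw)
  expect_lt(abs(rhw$anteriorFraction - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(rhw$anteriorFraction + rhw$posteriorFraction, 1)
})

test_that("sister branch angles are geometric, symmetric and null on retraction", {
  a <- data.frame(t_min = c(0, 15), x_um = c(0, 10), y_um = c(0, 0))
  b <- data.frame(t_min = c(0, 15), x_um = c(0, -8), y_um = c(0, 0))
  expect_equal(sisterBranchAngle(c(0, 0), a, b, 15)[["t15"]], 180)
  bp <- data.frame(t_min = c(0, 15), x_um = c(0, 0), y_um = c(0, 7))
  expect_equal(sisterBranchAngle(c(0, 0), a, bp, 15)[["t15"]], 90)
  # programmed separation recovered exactly on noise-free tracks
  half <- 96.5 / 2 * pi / 180
  up <- data.frame(t_min = c(0, 15, 75), x_um = c(0, 5, 20) * cos(half),
                   y_um = c(0, 5, 20) * sin(half))
  dn <- data.frame(t_min = c(0, 15, 75), x_um = c(0, 5, 20) * cos(half),
                   y_um = -c(0, 5, 20) * sin(half))
  got <- sisterBranchAngle(c(0, 0), up, dn)
  expect_equal(unname(got), c(96.5, 96.5))
  expect_equal(sisterBranchAngle(c(0, 0), dn, up), got)
  # branch gone before 75 min: that offset is NA
  short <- up[up$t_min <= 15, ]
  got2 <- sisterBranchAngle(c(0, 0), short, dn)
  expect_equal(got2[["t15"]], 96.5)
  expect_true(is.na(got2[["t75"]]))
})

test_that("fasciculation statistics summarize frequency, length and resolution", {
  none <- data.frame(neuron_id = integer(), class = character(),
                     length_um = numeric(), resolved = logical())
  fs0 <- fasciculationStats(none, 35)
  expect_equal(unname(fs0$frequency), c(0, 0, 0))
  expect_identical(length(fs0$lengths), 0L)
  ev <- data.frame(neuron_id = 1:19, class = rep(c("self", "non-self"),
                                                 c(12, 7)),
                   length_um = seq(8, 60, length.out = 19),
                   resolved = rep(c(TRUE, FALSE), c(9, 10)))
  fs <- fasciculationStats(ev, 37)
  expect_equal(unname(fs$frequency[["all"]]), 19 / 37, tolerance = 1e-12)
  expect_equal(fs$resolvedFraction, 9 / 19)
  # support check: lengths drawn on the observed 7.5-60.5 um range
  set.seed(5)
  draws <- runif(1e4, 7.5, 60.5)
  fs2 <- fasciculationStats(data.frame(neuron_id = 1, class = "self",
                                       length_um = draws, resolved = TRUE),
                            100)
  expect_gte(fs2$lengthSummary[["min"]], 7.5)
  expect_lte(fs2$lengthSummary[["max"]], 60.5)
})

test_that("midline crossing fractions per embryo and acetylation filter rule", {
  d <- data.frame(embryo_id = rep(1:2, each = 50),
                  crosses_midline = c(rep(FALSE, 50),
                                      rep(c(TRUE, FALSE), c(2, 48))))
  mf <- midlineCrossingFraction(d)
  expect_equal(mf$perEmbryo$pct, c(0, 4))
  br <- data.frame(length_um = c(4, 8, 12), signal_present = c(TRUE, FALSE,
                                                               TRUE))
  na <- nascentBranchAcetylation(br)
  expect_equal(na$pctPositive, 50)
  expect_identical(na$nRejected, 1L)
  many <- data.frame(length_um = rep(5, 132),
                     signal_present = rep(c(TRUE, FALSE), 66))
  expect_equal(nascentBranchAcetylation(many)$pctPositive, 50)
})
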