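test_that("tubeness suppresses flat regions and peaks on ridge centerlines", {
  expect_true(all(tubeness(matrix(1, 48, 48), 1, 0.5) == 0))
  img <- matrix(0, 64, 64)
  for (r in 1:64) img[r, ] <- exp(-(r - 32)^2 / (2 * 1.5^2))
  tb <- tubeness(img, scaleUm = 0.75, pxSizeUm = 0.5)
  inner <- 10:54
  expect_true(all(abs(apply(tb[, inner], 2, which.max) - 32) <= 1))
  expect_error(tubeness(img, scaleUm = 0.2, pxSizeUm = 0.5), "one pixel")
})

test_that("tubeness commutes with quarter-turn rotation", {
  sim <- simulateArbor(singleAngleSpec(-30, seed = 2))
  img <- sim$image
  tb <- tubeness(img, 0.75, 0.5)
  rot <- t(img)[ncol(img):1, ]              # 90 degree rotation
  tbr <- tubeness(rot, 0.75, 0.5)
  back <- t(tbr[nrow(tbr):1, ])             # rotate back
  expect_lt(max(abs(back - tb)), 1e-6 * max(tb))
})

test_that("orientation histogram recovers grating and arbor orientations", {
  op <- orientationHistogram(makeGrating(-60), 0.5)
  expect_lte(axialDiff(argmaxAngle(op), -60), 1)
  # arbor image with capsule segments
  sim <- simulateArbor(singleAngleSpec(25, seed = 6))
  expect_lte(axialDiff(argmaxAngle(orientationHistogram(sim$image, 0.5)),
                       25), 1)
})

test_that("rotating the image shifts the histogram argmax equivariantly", {
  sim <- simulateArbor(singleAngleSpec(-60, seed = 5))
  img <- sim$image
  for (theta in c(10, 20, 30)) {
    rot <- as.matrix(EBImage::rotate(img, theta, output.dim = dim(img),
                                     bg.col = 0))
    est <- argmaxAngle(orientationHistogram(rot, 0.5))
    expect_lte(axialDiff(est, -60 + theta), 1)
  }
})

test_that("histogram mass equals the summed per-pixel weights exactly", {
  sim <- simulateArbor(arborSpec(seed = 12, snr = 5))
  om <- orientationMap(sim$image, 0.5)
  w <- om$energy * om$coherency
  keep <- om$coherency >= 0.1 & om$energy > 0
  op <- orientationHistogram(sim$image, 0.5)
  expect_equal(sum(profileValues(op)), sum(w[keep]))
})

test_that("zero-gradient input is flagged empty rather than NaN", {
  op <- orientationHistogram(matrix(3, 32, 32), 0.5)
  expect_true(attr(op, "empty"))
  expect_true(all(profileValues(op) == 0))
  expect_false(any(is.nan(profileValues(op))))
})

test_that("structure tensor agrees with brute-force gradient orientation", {
  for (theta in c(-60, -20, 35, 80)) {
    img <- makeGrating(theta)
    om <- orientationMap(img, 0.5)
    bf <- bruteForceOrientation(img)
    inner <- matrix(FALSE, nrow(img), ncol(img))
    inner[11:(nrow(img) - 10), 11:(ncol(img) - 10)] <- TRUE
    sel <- inner & bf$magnitude > quantile(bf$magnitude[inner], 0.5)
    agree <- mean(axialDiff(bf$angle[sel], om$angle[sel]) <= 2)
    expect_gte(agree, 0.99)
  }
})

test_that("isotropic filtered noise yields a flat histogram across seeds", {
  shares <- vapply(1:50, function(s) {
    set.seed(s)
    n <- matrix(rnorm(128 * 128), 128, 128)
    k <- arborquant:::.gaussK(1.5)
    n <- as.matrix(EBImage::filter2(n, outer(k, k), boundary = "circular"))
    v <- profileValues(orientationHistogram(n, 0.5))[1, ]
    v / sum(v)
  }, numeric(180))
  m <- rowMeans(shares)
  se <- apply(shares, 1, sd) / sqrt(50)
  expect_true(all(abs(m - 1 / 180) <= 5 * se))
})

test_that("profile averaging reproduces means and calibrated intervals", {
  op1 <- orientationHistogram(makeGrating(-40), 0.5)
  same <- combineProfiles(rep(list(op1), 5))
  av <- averageProfiles(same)
  expect_equal(av$mean, profileValues(op1)[1, ], ignore_attr = TRUE)
  expect_true(all(av$ci_hi - av$ci_lo == 0))
  two <- new("OrientationProfile", binCenters = c(-0.5, 0.5),
             values = rbind(c(2, 2), c(4, 4)), units = "signal")
  expect_equal(averageProfiles(two)$mean, c(3, 3))
  # CI coverage on simulated Gaussian per-bin noise
  set.seed(99)
  nb <- 5; truth <- seq(10, 50, length.out = nb)
  hits <- replicate(400, {
    v <- matrix(rnorm(10 * nb, rep(truth, each = 10), 3), 10, nb)
    av <- averageProfiles(new("OrientationProfile",
                              binCenters = seq_len(nb), values = v,
                              units = "signal"))
    av$ci_lo <= truth & truth <= av$ci_hi
  })
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("normalization turns profiles into percentages summing to 100", {
  uni <- new("OrientationProfile", binCenters = seq(-89.5, 89.5),
             values = matrix(7, 1, 180), units = "signal")
  expect_equal(profileValues(normalizeProfile(uni))[1, ],
               rep(100 / 180, 180))
  one <- new("OrientationProfile", binCenters = seq(-89.5, 89.5),
             values = matrix(c(5, rep(0, 179)), 1), units = "signal")
  expect_equal(profileValues(normalizeProfile(one))[1, 1], 100)
  sim <- simulateArbor(arborSpec(seed = 3))
  np <- normalizeProfile(orientationHistogram(sim$image, 0.5))
  expect_equal(sum(profileValues(np)), 100, tolerance = 1e-6)
  zero <- new("OrientationProfile", binCenters = seq(-89.5, 89.5),
              values = matrix(0, 1, 180), units = "signal")
  expect_error(normalizeProfile(zero), "zero total")
})

test_that("AUC comparison handles identity, scaling and bad ranges", {
  sims <- lapply(1:4, function(s)
    orientationHistogram(simulateArbor(arborSpec(seed = s))$image, 0.5))
  A <- combineProfiles(sims[1:2])
  cmp <- compareAUC(A, A, range = c(-50.5, -20.5))
  expect_equal(cmp@statistic, 0)
  expect_equal(cmp@pValue, 1)
  B <- new("OrientationProfile", binCenters = binCenters(A),
           values = 2 * profileValues(A), units = "signal")
  cmp2 <- compareAUC(A, B, range = c(-89.5, 89.5))
  expect_equal(mean(cmp2@aucB) / mean(cmp2@aucA), 2)
  expect_error(compareAUC(A, B, range = c(-120, -95)), "outside")
  expect_error(compareAUC(A, B, range = c(10, 5)))
  # summary-statistic mode agrees in direction
  cmp3 <- compareAUC(A, B, range = c(-89.5, 89.5), method = "summary")
  expect_lt(cmp3@statistic, 0)
})
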