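#' Hessian tubeness filter for curvilinear structures
#'
#' Enhances bright line-like (tube-like) structures and suppresses blobs
#' and flat background, as used to clean non-axonal background before
#' orientation profiling. The image is convolved with scale-normalized
#' Gaussian second-derivative kernels (gamma = 2), the Hessian
#' eigenvalues are ordered by magnitude, and a Frangi-type vesselness is
#' composed from the blobness ratio and the structure norm; only pixels
#' whose larger-magnitude eigenvalue is negative (bright ridge) respond.
#'
#' @param image numeric matrix (rows = dorsoventral, cols =
#'   anteroposterior).
#' @param scaleUm filter scale (ridge half-width) in micrometres.
#' @param pxSizeUm pixel size in micrometres.
#' @param beta blobness sensitivity (Frangi beta), default 0.5.
#' @param c structure sensitivity; default half the maximum structure norm
#'   of the image (adaptive).
#' @return numeric matrix of the same size, >= 0.
#' @examples
#' img <- matrix(0, 64, 64); img[32, ] <- 1
#' tb <- tubeness(img, scaleUm = 1, pxSizeUm = 0.5)
#' which.max(tb[, 32]) # 32: maximal on the ridge centerline
#' @export
tubeness <- function(image, scaleUm, pxSizeUm, beta = 0.5, c = NULL) {
  stopifnot(is.matrix(image))
  if (scaleUm <= 0) stop("scaleUm must be > 0")
  sigma <- scaleUm / pxSizeUm
  if (sigma < 1) stop("tubeness scale is below one pixel; ",
                      "increase scaleUm or check pxSizeUm")
  g <- .gaussK(sigma); g1 <- .gaussKd1(sigma); g2 <- .gaussKd2(sigma)
  s2 <- sigma^2
  hxx <- s2 * .filterSep(image, g, g2)      # d2/dx2 (x = cols)
  hyy <- s2 * .filterSep(image, g2, g)      # d2/dy2 (y = rows)
  hxy <- s2 * .filterSep(image, g1, g1)
  # eigenvalues of [[hxx, hxy], [hxy, hyy]]
  tr <- hxx + hyy
  dd <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
  l1 <- (tr - dd) / 2
  l2 <- (tr + dd) / 2
  # order by |.|: lam2 = larger magnitude
  swap <- abs(l1) > abs(l2)
  lam1 <- ifelse(swap, l2, l1)
  lam2 <- ifelse(swap, l1, l2)
  rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
  s2n <- lam1^2 + lam2^2
  if (is.null(c)) c <- sqrt(max(s2n)) / 2
  v <- exp(-rb2 / (2 * beta^2)) *
       (if (c > 0) (1 - exp(-s2n / (2 * c^2))) else 0)
  v[lam2 >= 0] <- 0
  dim(v) <- dim(image)
  v
}

#' Structure-tensor orientation histogram of an arbor image
#'
#' Computes a per-pixel local orientation from the smoothed structure
#' tensor (Gaussian-derivative gradients, sigma `gradSigmaUm`; Gaussian
#' tensor smoothing, sigma `tensorSigmaUm`) and accumulates an
#' orientation-weighted signal histogram at `binDeg`-degree bins over
#' (-90, 90]. Orientation is axial (modulo 180 degrees) with 0 on the
#' anterior-posterior axis and negative angles descending toward
#' posterior. Each pixel contributes weight = gradient energy (tensor
#' trace) x coherency; pixels below the coherency floor are excluded as
#' isotropic background. The histogram total therefore equals the summed
#' weights of contributing pixels exactly.
#'
#' @param image numeric matrix.
#' @param pxSizeUm pixel size, micrometres.
#' @param binDeg bin width in degrees (default 1).
#' @param gradSigmaUm gradient derivative scale; default 1 pixel.
#' @param tensorSigmaUm tensor smoothing scale; default 2 pixels.
#' @param coherencyFloor minimum coherency for a pixel to contribute.
#' @param weighting `"energy_coherency"` (default) or `"energy"`.
#' @return an [OrientationProfile-class] with one image row. A
#'   zero-gradient image yields an all-zero profile carrying attribute
#'   `empty = TRUE`.
#' @examples
#' sim <- simulateArbor(arborSpec(nSegments = 15, snr = Inf, seed = 1,
#'   mixture = data.frame(mean_deg = -60, kappa = Inf, weight = 1)))
#' op <- orientationHistogram(sim$image, pxSizeUm = 0.5)
#' binCenters(op)[which.max(profileValues(op))]  # close to -60
#' @export
orientationHistogram <- function(image, pxSizeUm, binDeg = 1,
                                 gradSigmaUm = pxSizeUm,
                                 tensorSigmaUm = 2 * pxSizeUm,
                                 coherencyFloor = 0.1,
                                 weighting = c("energy_coherency",
                                               "energy")) {
  weighting <- match.arg(weighting)
  if (180 / binDeg != round(180 / binDeg))
    stop("binDeg must divide 180")
  om <- orientationMap(image, pxSizeUm, gradSigmaUm, tensorSigmaUm)
  energy <- om$energy; coherency <- om$coherency; ang <- om$angle

  centers <- seq(-90 + binDeg / 2, 90 - binDeg / 2, by = binDeg)
  nb <- length(centers)
  w <- switch(weighting, energy_coherency = energy * coherency,
              energy = energy)
  keep <- coherency >= coherencyFloor & energy > 0
  vals <- numeric(nb)
  empty <- !any(keep)
  if (!empty) {
    # right-closed bins over (-90, 90]
    idx <- ceiling((ang[keep] + 90) / binDeg)
    idx[idx < 1L] <- 1L; idx[idx > nb] <- nb
    tab <- rowsum(w[keep], idx)
    vals[as.integer(rownames(tab))] <- tab[, 1]
  }
  out <- new("OrientationProfile", binCenters = centers,
             values = matrix(vals, 1, nb), units = "signal")
  attr(out, "empty") <- empty
  out
}

#' Per-pixel structure-tensor orientation map
#'
#' The building block of [orientationHistogram()]: Gaussian-derivative
#' gradients (sigma `gradSigmaUm`) form the structure tensor, which is
#' smoothed with a Gaussian of sigma `tensorSigmaUm`; the local line
#' orientation is the minor-eigenvector angle (degrees, axial (-90, 90],
#' 0 = anterior-posterior), the energy is the tensor trace and the
#' coherency the normalized eigenvalue anisotropy in [0, 1].
#'
#' @inheritParams orientationHistogram
#' @return list of matrices `angle` (degrees), `energy`, `coherency`.
#' @export
orientationMap <- function(image, pxSizeUm, gradSigmaUm = pxSizeUm,
                           tensorSigmaUm = 2 * pxSizeUm) {
  stopifnot(is.matrix(image))
  if (gradSigmaUm <= 0 || tensorSigmaUm <= 0)
    stop("gradSigmaUm and tensorSigmaUm must be > 0")
  sg <- max(gradSigmaUm / pxSizeUm, 0.6)
  st <- max(tensorSigmaUm / pxSizeUm, 0.6)
  g <- .gaussK(sg); g1 <- .gaussKd1(sg)
  gx <- .filterSep(image, g, g1)            # d/dx, x = cols (posterior +)
  gy <- -.filterSep(image, g1, g)           # Cartesian y up (dorsal +)
  gs <- .gaussK(st)
  j11 <- .filterSep(gx * gx, gs, gs)
  j22 <- .filterSep(gy * gy, gs, gs)
  j12 <- .filterSep(gx * gy, gs, gs)
  energy <- j11 + j22
  dd <- sqrt(pmax((j11 - j22)^2 + 4 * j12^2, 0))
  coherency <- ifelse(energy > 0, dd / energy, 0)
  dim(coherency) <- dim(image)
  # line orientation = major tensor eigenvector (gradient direction) + 90
  ang <- .axialDeg(0.5 * atan2(2 * j12, j11 - j22) * 180 / pi + 90)
  dim(ang) <- dim(image)
  list(angle = ang, energy = energy, coherency = coherency)
}

#' Stack single-image profiles into one multi-image profile
#'
#' @param profiles list of [OrientationProfile-class] objects with
#'   identical binning and units.
#' @return an [OrientationProfile-class] with one row per input image.
#' @export
combineProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, is, logical(1), "OrientationProfile")))
  bc <- binCenters(profiles[[1]])
  un <- profiles[[1]]@units
  for (p in profiles) {
    if (!isTRUE(all.equal(binCenters(p), bc)))
      stop("profiles must share identical binning")
    if (p@units != un) stop("profiles must share units")
  }
  new("OrientationProfile", binCenters = bc,
      values = do.call(rbind, lapply(profiles, profileValues)), units = un)
}

#' @rdname normalizeProfile
#' @export
setMethod("normalizeProfile", "OrientationProfile", function(x) {
  tot <- rowSums(x@values)
  if (any(tot <= 0))
    stop("cannot normalize a profile with zero total signal")
  new("OrientationProfile", binCenters = x@binCenters,
      values = sweep(x@values, 1, tot / 100, "/"), units = "percent")
})

#' @rdname averageProfiles
#' @export
setMethod("averageProfiles", "OrientationProfile", function(x, conf = 0.95) {
  v <- x@values
  n <- nrow(v)
  m <- colMeans(v)
  if (n > 1) {
    se <- apply(v, 2, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    lo <- m - tq * se; hi <- m + tq * se
  } else {
    lo <- hi <- m
  }
  data.frame(angle_deg = x@binCenters, mean = m, ci_lo = lo, ci_hi = hi,
             n = n)
})

#' Compare two groups of profiles by area under the curve
#'
#' Computes, for every sample in each group, the trapezoidal area under
#' its profile over `range`, and compares the two sets of per-sample AUC
#' values. `method = "per_image"` (default) runs a Welch two-sample t test
#' on the per-sample AUCs; `method = "summary"` forms a z test from the
#' two group means and standard errors (the summary-statistic reading of
#' the same comparison).
#'
#' @param groupA,groupB [OrientationProfile-class] objects (multi-image)
#'   with identical binning, or matrices sample x position with a shared
#'   `x` coordinate vector given via `xCoords`.
#' @param range numeric(2) angular range (degrees) to integrate over; must
#'   lie within the bin support.
#' @param method `"per_image"` or `"summary"`.
#' @param xCoords optional x coordinates when matrices are supplied.
#' @return an [AUCComparison-class].
#' @examples
#' a <- simulateArbor(arborSpec(seed = 1)); b <- simulateArbor(arborSpec(seed = 2))
#' pa <- orientationHistogram(a$image, 0.5); pb <- orientationHistogram(b$image, 0.5)
#' compareAUC(combineProfiles(list(pa, pa)), combineProfiles(list(pb, pb)),
#'            range = c(-50.5, -20.5))
#' @export
compareAUC <- function(groupA, groupB, range,
                       method = c("per_image", "summary"), xCoords = NULL) {
  method <- match.arg(method)
  getm <- function(g) {
    if (is(g, "OrientationProfile"))
      list(x = binCenters(g), v = profileValues(g))
    else if (is.matrix(g)) {
      if (is.null(xCoords)) stop("xCoords required for matrix input")
      list(x = xCoords, v = g)
    } else stop("groups must be OrientationProfile or matrix")
  }
  A <- getm(groupA); B <- getm(groupB)
  if (!isTRUE(all.equal(A$x, B$x))) stop("groups must share binning")
  if (nrow(A$v) < 2 || nrow(B$v) < 2)
    stop("need at least 2 samples per group")
  if (length(range) != 2 || range[1] >= range[2])
    stop("range must be (lo, hi) with lo < hi")
  aucA <- apply(A$v, 1, function(y) .trapz(A$x, y, range[1], range[2]))
  aucB <- apply(B$v, 1, function(y) .trapz(B$x, y, range[1], range[2]))
  if (method == "per_image") {
    ts <- .welch(aucA, aucB)
    stat <- ts$statistic; p <- ts$p.value
  } else {
    seA <- stats::sd(aucA) / sqrt(length(aucA))
    seB <- stats::sd(aucB) / sqrt(length(aucB))
    se <- sqrt(seA^2 + seB^2)
    if (se == 0) {
      stat <- 0; p <- 1
    } else {
      stat <- (mean(aucA) - mean(aucB)) / se
      p <- 2 * stats::pnorm(-abs(stat))
    }
  }
  new("AUCComparison", range = as.numeric(range), aucA = aucA, aucB = aucB,
      statistic = stat, pValue = p, method = method)
}
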