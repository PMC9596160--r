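#' Render a synthetic arbor image with known ground truth
#'
#' Renders `nSegments` straight Gaussian-profile line segments whose
#' orientations are drawn from the spec's axial von Mises mixture, on a
#' zero background, then adds noise according to the spec. Segment
#' midpoints are uniform over the field and segments are rejection-sampled
#' to keep a minimum mutual separation, emulating the contact repulsion
#' ("tiling") of peripheral sensory arbors. Anterior is left, dorsal is up;
#' a segment at angle `a` (degrees, axial convention) advances
#' `(cos a, sin a)` in Cartesian coordinates with the y axis pointing
#' dorsally, so negative angles descend toward posterior.
#'
#' Ground truth contains every rendered segment exactly once (clipped to
#' the image bounds) together with its true orientation, plus the number of
#' distinct segments crossing each band of a dorsoventral ROI grid
#' (see [roiGrid()]): a segment crosses a band when its own analytic
#' noise-free footprint within the band strip - evaluated at the strip's
#' Otsu threshold, the same threshold definition the counting path uses -
#' covers at least 2 pixels. Because segments keep a minimum mutual
#' separation their footprints are disjoint, so this per-segment recount
#' is exact for the rendered image while remaining independent of
#' connected-component labelling.
#'
#' @param spec an [ArborSpec-class].
#' @param grid an ROI grid from [roiGrid()] used for the ground-truth
#'   band-crossing counts; defaults to an 8-band grid spanning the image.
#' @param bandCounts compute the ground-truth band-crossing counts
#'   (default TRUE); skip when only the image and angles are needed.
#' @return list with
#'   \describe{
#'     \item{image}{numeric matrix (rows = dorsoventral, cols =
#'       anteroposterior), noise added per spec.}
#'     \item{clean}{the noise-free render.}
#'     \item{segments}{data.frame, one row per segment: `angle_deg`,
#'       endpoints in pixels (`x0`,`y0`,`x1`,`y1`; matrix row/col
#'       convention, y = row) and in micrometres.}
#'     \item{bandCounts}{integer vector, distinct segments crossing each
#'       grid band.}
#'     \item{grid}{the grid used.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' sim <- simulateArbor(arborSpec(nSegments = 12, snr = Inf, seed = 3))
#' sim$bandCounts
#' @export
simulateArbor <- function(spec, grid = NULL, bandCounts = TRUE) {
  stopifnot(is(spec, "ArborSpec"))
  validObject(spec)
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  px <- spec@pxSizeUm
  if (is.null(grid))
    grid <- roiGrid(spanUm = c(0, nr * px), nRois = 8L,
                    roiHeightUm = 3, xExtentUm = c(0, nc * px))

  set.seed(spec@seed)
  segs <- .sampleSegments(spec)

  img <- matrix(0, nr, nc)
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      img <- img + .renderSegment(nr, nc, spec@tubeSigmaPx,
                                  c(segs$x0[i], segs$y0[i]),
                                  c(segs$x1[i], segs$y1[i]))
    }
  }
  clean <- img
  noisy <- .addImageNoise(clean, spec@snr, spec@noiseModel)

  counts <- if (bandCounts)
    .bandCrossings(segs, grid, px, clean, spec@tubeSigmaPx) else NULL

  list(image = noisy, clean = clean, segments = segs, bandCounts = counts,
       grid = grid, spec = spec)
}

# Sample segment geometry (pixel coordinates, matrix convention: x = col,
# y = row, row 1 dorsal). Rejection-samples placements violating the
# minimum mutual separation; gives up after a bounded number of proposals
# with an informative error (field too crowded).
.sampleSegments <- function(spec) {
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  px <- spec@pxSizeUm
  n <- spec@nSegments
  out <- data.frame(angle_deg = numeric(0), x0 = numeric(0), y0 = numeric(0),
                    x1 = numeric(0), y1 = numeric(0))
  if (n == 0L) return(out)
  m <- spec@mixture
  comp <- sample.int(nrow(m), n, replace = TRUE, prob = m$weight)
  angles <- numeric(n)
  for (k in seq_len(nrow(m))) {
    idx <- which(comp == k)
    angles[idx] <- .rvonmisesAxial(length(idx), m$mean_deg[k], m$kappa[k])
  }
  lens_um <- stats::runif(n, spec@segmentLengthUm[1], spec@segmentLengthUm[2])
  minSepPx <- spec@minSeparationUm / px
  kept <- matrix(numeric(0), 0, 4)   # x0 y0 x1 y1 per kept segment
  maxTries <- 500L
  for (i in seq_len(n)) {
    a <- angles[i] * pi / 180
    halfL <- lens_um[i] / px / 2
    # direction in matrix coords: x = cos a, y(row) = -sin a (dorsal up)
    dx <- cos(a) * halfL; dy <- -sin(a) * halfL
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
      p1 <- c(cx - dx, cy - dy); p2 <- c(cx + dx, cy + dy)
      cl <- .clipSegment(p1, p2, nc, nr)
      if (is.null(cl)) next
      if (minSepPx > 0 && nrow(kept)) {
        d <- vapply(seq_len(nrow(kept)), function(j)
          .segSegDist(cl$p1, cl$p2, kept[j, 1:2], kept[j, 3:4]), numeric(1))
        if (min(d) < minSepPx) next
      }
      kept <- rbind(kept, c(cl$p1, cl$p2))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place segment ", i,
           " with the requested minimum separation; ",
           "reduce nSegments or minSeparationUm")
  }
  data.frame(angle_deg = angles,
             x0 = kept[, 1], y0 = kept[, 2], x1 = kept[, 3], y1 = kept[, 4],
             x0_um = kept[, 1] * px, y0_um = kept[, 2] * px,
             x1_um = kept[, 3] * px, y1_um = kept[, 4] * px)
}

# Liang-Barsky clip of segment p1-p2 to [1, nc] x [1, nr]; NULL if outside
.clipSegment <- function(p1, p2, nc, nr) {
  d <- p2 - p1
  t0 <- 0; t1 <- 1
  for (side in 1:4) {
    p <- c(-d[1], d[1], -d[2], d[2])[side]
    q <- c(p1[1] - 1, nc - p1[1], p1[2] - 1, nr - p1[2])[side]
    if (abs(p) < 1e-12) { if (q < 0) return(NULL); next }
    r <- q / p
    if (p < 0) { if (r > t1) return(NULL); t0 <- max(t0, r) }
    else { if (r < t0) return(NULL); t1 <- min(t1, r) }
  }
  if (t0 >= t1) return(NULL)
  list(p1 = p1 + t0 * d, p2 = p1 + t1 * d)
}

# Render one Gaussian-profile capsule (peak 1) into an nr x nc canvas
.renderSegment <- function(nr, nc, sigma, p1, p2) {
  pad <- ceiling(4 * sigma)
  xmin <- max(1L, floor(min(p1[1], p2[1])) - pad)
  xmax <- min(nc, ceiling(max(p1[1], p2[1])) + pad)
  ymin <- max(1L, floor(min(p1[2], p2[2])) - pad)
  ymax <- min(nr, ceiling(max(p1[2], p2[2])) + pad)
  xs <- xmin:xmax; ys <- ymin:ymax
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  d <- .pointSegDist(gx, gy, p1, p2)
  v <- exp(-d^2 / (2 * sigma^2))
  out <- matrix(0, nr, nc)
  out[cbind(gy, gx)] <- v
  out
}

.addImageNoise <- function(clean, snr, noiseModel) {
  if (is.infinite(snr)) return(clean)
  peak <- max(clean, 1e-12)
  sd_n <- peak / snr
  img <- clean
  if (noiseModel == "poisson+gaussian") {
    # shot noise scaled so the peak has ~snr^2 expected counts
    counts <- snr^2
    img <- stats::rpois(length(clean), clean / peak * counts) / counts * peak
    dim(img) <- dim(clean)
    sd_n <- sd_n / 2           # split the budget between the two sources
  }
  img <- img + matrix(stats::rnorm(length(clean), 0, sd_n),
                      nrow(clean), ncol(clean))
  img
}

# Ground-truth distinct-segment crossings per grid band. A segment counts
# for a band when its analytic noise-free footprint - the pixels of the
# band strip where that segment alone renders above the strip's threshold
# (the same per-strip Otsu definition the counting path uses) - has at
# least minObjectPx pixels. The minimum mutual separation enforced at
# placement keeps footprints disjoint and non-adjacent, so this
# per-segment recount is exact for the rendered image while staying
# independent of connected-component labelling.
.bandCrossings <- function(segs, grid, pxSizeUm, clean, tubeSigmaPx,
                           minObjectPx = 2L) {
  nb <- nrow(grid$bands)
  counts <- integer(nb)
  if (!nrow(segs)) return(counts)
  for (b in seq_len(nb)) {
    ix <- .bandStripIndices(grid, b, pxSizeUm, dim(clean))
    strip <- clean[ix$rows, ix$cols, drop = FALSE]
    rng <- range(strip)
    if (diff(rng) <= 0) { counts[b] <- 0L; next }
    norm <- (strip - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thAbs <- rng[1] + th * diff(rng)
    gx <- rep(ix$cols, each = length(ix$rows))
    gy <- rep(ix$rows, times = length(ix$cols))
    counts[b] <- sum(vapply(seq_len(nrow(segs)), function(i) {
      d <- .pointSegDist(gx, gy, c(segs$x0[i], segs$y0[i]),
                         c(segs$x1[i], segs$y1[i]))
      sum(exp(-d^2 / (2 * tubeSigmaPx^2)) > thAbs) >= minObjectPx
    }, logical(1)))
  }
  counts
}

# pixel row/col index sets of a grid band; shared by the ground-truth
# recount and countBranchCrossings so both see the same strip
.bandStripIndices <- function(grid, b, pxSizeUm, dm) {
  r0 <- max(1L, floor(grid$bands$y0_um[b] / pxSizeUm) + 1L)
  r1 <- min(dm[1], ceiling(grid$bands$y1_um[b] / pxSizeUm))
  c0 <- max(1L, floor(grid$bands$x0_um[b] / pxSizeUm) + 1L)
  c1 <- min(dm[2], ceiling(grid$bands$x1_um[b] / pxSizeUm))
  if (grid$bands$y0_um[b] < 0 ||
      grid$bands$y1_um[b] > dm[1] * pxSizeUm + 1e-9 || r0 > r1 || c0 > c1)
    stop("ROI band ", b, " lies outside the image")
  list(rows = r0:r1, cols = c0:c1)
}
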