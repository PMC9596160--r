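## Internal numerical helpers shared across modules.

# 1D Gaussian kernel, unit sum
.gaussK <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D Gaussian first-derivative kernel, normalized so a unit ramp responds 1
.gaussKd1 <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  k <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  k / sum(-x * k)
}

# 1D Gaussian second-derivative kernel, normalized so x^2/2 responds 1
.gaussKd2 <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  k <- (x^2 / sigma^4 - 1 / sigma^2) * exp(-x^2 / (2 * sigma^2))
  k <- k - mean(k)                       # exact zero response to constants
  k / sum(x^2 / 2 * k)
}

# separable 2D filtering via EBImage; kr acts along rows, kc along columns
.filterSep <- function(img, kr, kc) {
  EBImage::filter2(img, outer(kr, kc), boundary = "replicate")
}

# trapezoidal area under y(x) over [lo, hi]; x strictly increasing.
# End points are linearly interpolated so the range need not hit a knot.
.trapz <- function(x, y, lo = min(x), hi = max(x)) {
  if (lo >= hi) stop("lo must be < hi")
  if (lo < min(x) || hi > max(x))
    stop(sprintf("range [%g, %g] outside support [%g, %g]", lo, hi,
                 min(x), max(x)))
  yi <- stats::approx(x, y, xout = c(lo, hi))$y
  keep <- x > lo & x < hi
  xx <- c(lo, x[keep], hi)
  yy <- c(yi[1], y[keep], yi[2])
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

# Welch two-sample t test returning (statistic, p, df); handles the
# degenerate zero-variance equal-means case as t = 0, p = 1.
.welch <- function(a, b) {
  if (stats::var(a) + stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, p.value = 1, df = NA_real_))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0,
                df = NA_real_))
  }
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}

# Axial von Mises sampler: draws line orientations in (-90, 90] whose
# doubled angles follow von Mises(2*mean, kappa). Best & Fisher (1979)
# rejection algorithm; kappa = Inf returns the mean exactly, kappa = 0 is
# uniform.
.rvonmisesAxial <- function(n, mean_deg, kappa) {
  if (n == 0L) return(numeric())
  if (is.infinite(kappa)) return(rep(mean_deg, n))
  mu <- 2 * mean_deg * pi / 180
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    i <- 1L
    while (i <= n) {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        th[i] <- sign(u[3] - 0.5) * acos(f)
        i <- i + 1L
      }
    }
  }
  ang <- (th + mu) / 2 * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  ang[ang <= -90] <- ang[ang <= -90] + 180
  ang
}

# map any angle (deg) to the axial range (-90, 90]
.axialDeg <- function(a) {
  a <- ((a + 90) %% 180) - 90
  a[a <= -90] <- a[a <= -90] + 180
  a
}

# minimum distance between two 2D segments p1-p2 and q1-q2 (each 2-vectors)
.segSegDist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    cc <- sum(d1 * r)
    if (e <= 1e-12) { t <- 0; s <- min(max(-cc / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-12) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (q1 + t * d2)
  sqrt(sum(v * v))
}

# distance from points (x, y) to segment p1-p2, vectorized over points
.pointSegDist <- function(x, y, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d * d)
  if (len2 < 1e-12) return(sqrt((x - p1[1])^2 + (y - p1[2])^2))
  t <- ((x - p1[1]) * d[1] + (y - p1[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p1[1] + t * d[1]))^2 + (y - (p1[2] + t * d[2]))^2)
}

# derive a child seed from a base seed and a stream index (kept < 2^31)
.childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

# run-length encoding of a logical vector -> data.frame(start, end, value)
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, value = r$values)
}

# running median of 3 with endpoints passed through
.median3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  a <- x[1:(n - 2)]; b <- x[2:(n - 1)]; cc <- x[3:n]
  out <- x
  # median(a, b, c) = max(min(a, b), min(max(a, b), c))
  out[2:(n - 1)] <- pmax(pmin(a, b), pmin(pmax(a, b), cc))
  out
}
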