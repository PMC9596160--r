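#' @include AllClasses.R
NULL

#' Bin centers of an orientation profile
#' @param x an object with angular bins.
#' @return numeric vector of bin centers (degrees).
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' Per-image profile values
#' @param x an [OrientationProfile-class].
#' @return matrix, images x bins.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Number of images contributing to a profile
#' @param x an [OrientationProfile-class].
#' @return integer(1).
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' Normalize a profile to percent of total signal
#'
#' Each image's bins are rescaled to `100 * bin / total`, so every row sums
#' to 100. Used to compare directional bias independently of overall signal
#' abundance.
#'
#' @param x an [OrientationProfile-class] in signal units.
#' @return an [OrientationProfile-class] with `units == "percent"`.
#' @export
setGeneric("normalizeProfile", function(x) standardGeneric("normalizeProfile"))

#' Average a multi-image profile with confidence intervals
#'
#' @param x an [OrientationProfile-class] with one or more images.
#' @param conf confidence level for the per-bin t-based interval.
#' @return data.frame with `angle_deg`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
setGeneric("averageProfiles",
           function(x, conf = 0.95) standardGeneric("averageProfiles"))

#' Spatial calibration of a kymograph
#' @param x a [Kymograph-class].
#' @return micrometres per pixel.
#' @export
setGeneric("pxSize", function(x) standardGeneric("pxSize"))

#' Frame interval of a kymograph
#' @param x a [Kymograph-class].
#' @return seconds per frame.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

## ---------------------------------------------------------------------------

#' @rdname binCenters
#' @export
setMethod("binCenters", "OrientationProfile", function(x) x@binCenters)

#' @rdname profileValues
#' @export
setMethod("profileValues", "OrientationProfile", function(x) x@values)

#' @rdname nImages
#' @export
setMethod("nImages", "OrientationProfile", function(x) nrow(x@values))

#' @rdname pxSize
#' @export
setMethod("pxSize", "Kymograph", function(x) x@pxSizeUm)

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "Kymograph", function(x) x@frameIntervalS)

#' Intensity matrix of a kymograph
#' @param x a [Kymograph-class].
#' @return matrix, distance x time.
#' @export
kymoIntensity <- function(x) {
  stopifnot(is(x, "Kymograph"))
  x@intensity
}

setMethod("show", "OrientationProfile", function(object) {
  cat(sprintf(
    "OrientationProfile: %d image(s), %d bins of %.2f deg (%s units)\n",
    nrow(object@values), length(object@binCenters),
    if (length(object@binCenters) > 1) diff(object@binCenters[1:2]) else NA,
    object@units))
  if (nrow(object@values)) {
    m <- colMeans(object@values)
    cat(sprintf("  peak bin: %.1f deg\n", object@binCenters[which.max(m)]))
  }
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf(
    "Kymograph: %d px (%.2f um) x %d frames (%.1f s interval)\n",
    nrow(object@intensity), nrow(object@intensity) * object@pxSizeUm,
    ncol(object@intensity), object@frameIntervalS))
})

setMethod("show", "AUCComparison", function(object) {
  cat(sprintf(
    "AUCComparison over [%.1f, %.1f]: meanA = %.4g, meanB = %.4g\n  t = %.3f, p = %.4g (%s)\n",
    object@range[1], object@range[2], mean(object@aucA), mean(object@aucB),
    object@statistic, object@pValue, object@method))
})

#' Per-group AUC values of a comparison
#' @param x an [AUCComparison-class].
#' @return list with `A` and `B` numeric vectors of per-sample AUCs.
#' @export
aucValues <- function(x) {
  stopifnot(is(x, "AUCComparison"))
  list(A = x@aucA, B = x@aucB)
}

#' p value of an AUC comparison
#' @param x an [AUCComparison-class].
#' @return numeric(1).
#' @export
aucPValue <- function(x) {
  stopifnot(is(x, "AUCComparison"))
  x@pValue
}
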