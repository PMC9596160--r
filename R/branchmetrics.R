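#' Dorsoventral ROI grid for branch-density counting
#'
#' Builds `nRois` horizontal bands of `roiHeightUm` height, regularly
#' spaced from dorsal to ventral over `spanUm` (the dorsoventral span to
#' cover, with the first band anchored at its top, e.g. the bottom of the
#' central axon fascicle). Bands never overlap.
#'
#' @param spanUm numeric(2), dorsoventral span (top, bottom) in
#'   micrometres measured from the image top.
#' @param nRois number of bands (default 8).
#' @param roiHeightUm band height in micrometres (default 3).
#' @param xExtentUm numeric(2), anteroposterior extent of every band.
#' @return list with `bands` (data.frame `y0_um`, `y1_um`, `x0_um`,
#'   `x1_um`, ordered dorsal to ventral) and the parameters.
#' @export
roiGrid <- function(spanUm, nRois = 8L, roiHeightUm = 3, xExtentUm) {
  stopifnot(length(spanUm) == 2, spanUm[2] > spanUm[1],
            nRois >= 1, roiHeightUm > 0,
            length(xExtentUm) == 2, xExtentUm[2] > xExtentUm[1])
  span <- diff(spanUm)
  if (nRois * roiHeightUm > span + 1e-9)
    stop("ROIs of ", roiHeightUm, " um cannot fit ", nRois,
         " times in a span of ", span, " um without overlap")
  gap <- if (nRois > 1) (span - nRois * roiHeightUm) / (nRois - 1) else 0
  y0 <- spanUm[1] + (seq_len(nRois) - 1) * (roiHeightUm + gap)
  list(bands = data.frame(y0_um = y0, y1_um = y0 + roiHeightUm,
                          x0_um = xExtentUm[1], x1_um = xExtentUm[2]),
       nRois = as.integer(nRois), roiHeightUm = roiHeightUm,
       spanUm = spanUm, xExtentUm = xExtentUm)
}

#' Count branch objects crossing each ROI band
#'
#' For every band of the grid the image strip is thresholded (Otsu by
#' default, computed per strip), binarized, and the number of connected
#' components of at least `minObjectPx` pixels is counted - the
#' particle-counting reading of "branches crossing the ROI". A strip with
#' no signal counts zero. Counts are invariant to global intensity
#' rescaling when `threshold = "otsu"`.
#'
#' @param image numeric matrix.
#' @param grid an [roiGrid()] result; must lie within the image.
#' @param pxSizeUm pixel size, micrometres.
#' @param threshold `"otsu"` or a numeric absolute threshold.
#' @param minObjectPx minimum object size in pixels (default 2, kills
#'   single-pixel noise).
#' @return integer vector of counts, one per band (dorsal to ventral).
#' @examples
#' sim <- simulateArbor(arborSpec(nSegments = 10, snr = Inf, seed = 2))
#' countBranchCrossings(sim$image, sim$grid, pxSizeUm = 0.5)
#' @export
countBranchCrossings <- function(image, grid, pxSizeUm, threshold = "otsu",
                                 minObjectPx = 2L) {
  stopifnot(is.matrix(image))
  counts <- integer(nrow(grid$bands))
  for (b in seq_len(nrow(grid$bands))) {
    ix <- .bandStripIndices(grid, b, pxSizeUm, dim(image))
    strip <- image[ix$rows, ix$cols, drop = FALSE]
    rng <- range(strip)
    if (diff(rng) <= 0) { counts[b] <- 0L; next }
    if (identical(threshold, "otsu")) {
      norm <- (strip - rng[1]) / diff(rng)
      th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
      bin <- norm > th
    } else {
      bin <- strip > threshold
    }
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    counts[b] <- sum(sizes >= minObjectPx)
  }
  counts
}

#' Compare branch-density profiles between groups
#'
#' Per-embryo trapezoidal AUC over the ROI index, compared with a Welch t
#' test - the density analogue of [compareAUC()].
#'
#' @param groupA,groupB matrices embryo x ROI of crossing counts.
#' @param roiSubset integer range of ROI indices to integrate over;
#'   default the full profile.
#' @return an [AUCComparison-class].
#' @export
compareDensity <- function(groupA, groupB,
                           roiSubset = c(1, ncol(groupA))) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            ncol(groupA) == ncol(groupB))
  compareAUC(groupA, groupB, range = roiSubset,
             xCoords = seq_len(ncol(groupA)))
}

#' Branch initiation rate per neuron per hour
#'
#' @param events branch-event data.frame (see [simulateEventTable()]).
#' @param nNeurons number of observed neurons (not all neurons need have
#'   events).
#' @param durationH observation duration, hours.
#' @return list with `rate` (named per type, branches/neuron/hour),
#'   `perNeuron` (data.frame neuron x type counts/duration) and `n`.
#' @examples
#' ev <- data.frame(neuron_id = 1, type = "GCB", t_init_min = c(1, 5, 9, 20),
#'                  retracted = FALSE)
#' initiationRate(ev, nNeurons = 1, durationH = 2)$rate  # GCB 2/h
#' @export
initiationRate <- function(events, nNeurons, durationH) {
  if (durationH <= 0) stop("durationH must be > 0")
  if (nNeurons < 1) stop("nNeurons must be >= 1")
  types <- c("GCB", "IB")
  rate <- vapply(types, function(ty)
    sum(events$type == ty) / nNeurons / durationH, numeric(1))
  per <- expand.grid(neuron_id = seq_len(nNeurons), type = types,
                     stringsAsFactors = FALSE)
  per$rate <- mapply(function(nid, ty)
    sum(events$neuron_id == nid & events$type == ty) / durationH,
    per$neuron_id, per$type)
  list(rate = rate, perNeuron = per, n = nrow(events))
}

#' Branch loss ratio (retracted / total events) per type
#'
#' @param events branch-event data.frame with `type` and `retracted`.
#' @return list with `ratio` (named per type; `NA` where a type has no
#'   events - undefined, not zero) and `perNeuron` per-neuron ratios.
#' @examples
#' ev <- data.frame(neuron_id = 1, type = "GCB",
#'                  retracted = c(rep(TRUE, 7), rep(FALSE, 5)))
#' lossRatio(ev)$ratio[["GCB"]]  # 7/12
#' @export
lossRatio <- function(events) {
  types <- c("GCB", "IB")
  ratio <- vapply(types, function(ty) {
    k <- events$type == ty
    if (!sum(k)) return(NA_real_)
    mean(events$retracted[k])
  }, numeric(1))
  per <- NULL
  if (nrow(events) && "neuron_id" %in% names(events)) {
    per <- do.call(rbind, lapply(split(events,
                                       events[c("neuron_id", "type")],
                                       drop = TRUE), function(d)
      data.frame(neuron_id = d$neuron_id[1], type = d$type[1],
                 ratio = mean(d$retracted), n = nrow(d))))
    rownames(per) <- NULL
  }
  list(ratio = ratio, perNeuron = per, n = nrow(events))
}

#' Direction bias among retracted branches
#'
#' Per-neuron percentage of retracted branches that were anteriorly vs
#' posteriorly directed, with a two-sided one-sample t test of the
#' per-neuron anterior percentage against 50%.
#'
#' @param events branch-event data.frame with `neuron_id`, `retracted`,
#'   `direction`.
#' @return list with `perNeuron` (`pct_anterior`, `pct_posterior`),
#'   `meanAnteriorPct`, `pValue` (NA when fewer than 2 neurons have
#'   retracted branches).
#' @export
retractionDirectionBias <- function(events) {
  d <- events[events$retracted & !is.na(events$direction), , drop = FALSE]
  if (!nrow(d))
    return(list(perNeuron = data.frame(neuron_id = integer(),
                                       pct_anterior = numeric(),
                                       pct_posterior = numeric()),
                meanAnteriorPct = NA_real_, pValue = NA_real_))
  per <- do.call(rbind, lapply(split(d, d$neuron_id), function(x)
    data.frame(neuron_id = x$neuron_id[1],
               pct_anterior = 100 * mean(x$direction == "anterior"),
               pct_posterior = 100 * mean(x$direction == "posterior"))))
  rownames(per) <- NULL
  p <- if (nrow(per) >= 2 && stats::sd(per$pct_anterior) > 0)
    stats::t.test(per$pct_anterior, mu = 50)$p.value else NA_real_
  list(perNeuron = per, meanAnteriorPct = mean(per$pct_anterior),
       pValue = p)
}

#' Axon growth velocity from a growth-cone track
#'
#' Total accumulated path length divided by elapsed time (the
#' migration-tool "velocity": turning does not reduce it).
#'
#' @param track data.frame with `t_min`, `x_um`, `y_um`, time strictly
#'   increasing, at least 2 samples.
#' @return velocity in micrometres per minute.
#' @examples
#' tr <- data.frame(t_min = 0:5, x_um = 2 * (0:5), y_um = 0)
#' growthVelocity(tr)  # 2 um/min
#' @export
growthVelocity <- function(track) {
  .checkTrack(track)
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  sum(steps) / (track$t_min[nrow(track)] - track$t_min[1])
}

.checkTrack <- function(track) {
  stopifnot(all(c("t_min", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2) stop("track needs at least 2 samples")
  if (any(diff(track$t_min) <= 0)) stop("track time must strictly increase")
}

#' Rose histogram of frame-to-frame growth directions
#'
#' The angle of each step (position in a frame relative to the preceding
#' frame) on [0, 360) degrees under the anterior-left convention: 0 =
#' posterior, 90 = dorsal, 180 = anterior, 270 = ventral. Zero-length
#' steps carry no direction and are dropped from the counts.
#'
#' @param track growth-cone track data.frame (`t_min`, `x_um`, `y_um`).
#' @param sectorDeg sector width in degrees (default 15; must divide 360).
#' @return list with `counts` (named by sector start), `sectorEdges`,
#'   `angles` (per-step degrees), `anteriorFraction`,
#'   `posteriorFraction` (halves split by the dorsoventral axis;
#'   fractions among steps with a nonzero anteroposterior component),
#'   `meanAngle` and `resultantLength` (circular statistics of the step
#'   directions).
#' @export
growthDirectionHistogram <- function(track, sectorDeg = 15) {
  .checkTrack(track)
  if (360 / sectorDeg != round(360 / sectorDeg))
    stop("sectorDeg must divide 360")
  dx <- diff(track$x_um); dy_img <- diff(track$y_um)
  dy <- -dy_img                       # dorsal up
  keep <- dx != 0 | dy != 0
  ang <- (atan2(dy[keep], dx[keep]) * 180 / pi) %% 360
  edges <- seq(0, 360, by = sectorDeg)
  idx <- findInterval(ang, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  names(counts) <- utils::head(edges, -1)
  ap <- dx[keep][dx[keep] != 0]
  z <- complex(argument = ang * pi / 180)
  list(counts = counts, sectorEdges = edges, angles = ang,
       anteriorFraction = if (length(ap)) mean(ap < 0) else NA_real_,
       posteriorFraction = if (length(ap)) mean(ap > 0) else NA_real_,
       meanAngle = (Arg(mean(z)) * 180 / pi) %% 360,
       resultantLength = Mod(mean(z)))
}

#' Angle between sister branches after bifurcation
#'
#' For each requested offset after branch creation, the angle (degrees,
#' [0, 180]) between the two vectors from the bifurcation node to each
#' sister-branch tip at that time. If either branch has no sample at or
#' beyond the offset (it retracted or the recording ended), that offset is
#' `NA` - no data is recorded, matching the measurement rule. The result
#' is symmetric in branch order.
#'
#' @param node numeric(2), bifurcation point (x_um, y_um).
#' @param branchA,branchB data.frames (`t_min`, `x_um`, `y_um`) of the two
#'   sister-branch tip tracks, times measured from branch creation.
#' @param offsetsMin numeric, offsets after creation at which to measure
#'   (default 15 and 75 min).
#' @return named numeric vector of angles, one per offset.
#' @examples
#' a <- data.frame(t_min = c(0, 15), x_um = c(0, 10), y_um = c(0, 0))
#' b <- data.frame(t_min = c(0, 15), x_um = c(0, 0),  y_um = c(0, 10))
#' sisterBranchAngle(c(0, 0), a, b, offsetsMin = 15)  # 90
#' @export
sisterBranchAngle <- function(node, branchA, branchB,
                              offsetsMin = c(15, 75)) {
  tipAt <- function(br, t) {
    if (nrow(br) == 0 || max(br$t_min) < t) return(NULL)
    i <- max(which(br$t_min <= t))
    if (br$t_min[i] == t || i == nrow(br)) {
      c(br$x_um[i], br$y_um[i])
    } else {
      f <- (t - br$t_min[i]) / (br$t_min[i + 1] - br$t_min[i])
      c(br$x_um[i] + f * (br$x_um[i + 1] - br$x_um[i]),
        br$y_um[i] + f * (br$y_um[i + 1] - br$y_um[i]))
    }
  }
  out <- vapply(offsetsMin, function(t) {
    pa <- tipAt(branchA, t); pb <- tipAt(branchB, t)
    if (is.null(pa) || is.null(pb)) return(NA_real_)
    va <- pa - node; vb <- pb - node
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
    if (na == 0 || nb == 0) return(NA_real_)
    acos(min(max(sum(va * vb) / (na * nb), -1), 1)) * 180 / pi
  }, numeric(1))
  names(out) <- paste0("t", offsetsMin)
  out
}

#' Fasciculation frequency and length statistics
#'
#' @param events data.frame with `neuron_id`, `class` (`self` /
#'   `non-self`), `length_um`, `resolved` (logical). Zero rows allowed.
#' @param nNeurons number of observed neurons.
#' @return list with `frequency` (events/neuron: self, non-self, all),
#'   `lengths` (numeric vector), `lengthSummary` (min/mean/max, NA when
#'   empty), `resolvedFraction`.
#' @export
fasciculationStats <- function(events, nNeurons) {
  if (nNeurons <= 0) stop("nNeurons must be > 0")
  freq <- c(self = sum(events$class == "self") / nNeurons,
            `non-self` = sum(events$class == "non-self") / nNeurons,
            all = nrow(events) / nNeurons)
  lens <- events$length_um
  list(frequency = freq, lengths = lens,
       lengthSummary = if (length(lens))
         c(min = min(lens), mean = mean(lens), max = max(lens))
       else c(min = NA_real_, mean = NA_real_, max = NA_real_),
       resolvedFraction = if (nrow(events)) mean(events$resolved)
       else NA_real_)
}

#' Midline-crossing percentage per embryo with group comparison
#'
#' @param neurons data.frame with `embryo_id`, `crosses_midline`
#'   (logical) and optionally `group`.
#' @return If a `group` column with 2 levels is present: list with
#'   `perEmbryo` (embryo percentages), `groupSummary` (mean/SEM per
#'   group) and `pValue` (Mann-Whitney on per-embryo percentages).
#'   Otherwise the per-embryo table and overall mean.
#' @export
midlineCrossingFraction <- function(neurons) {
  stopifnot(all(c("embryo_id", "crosses_midline") %in% names(neurons)))
  hasGroup <- "group" %in% names(neurons)
  key <- if (hasGroup) interaction(neurons$group, neurons$embryo_id,
                                   drop = TRUE) else neurons$embryo_id
  per <- do.call(rbind, lapply(split(neurons, key), function(d)
    data.frame(embryo_id = d$embryo_id[1],
               group = if (hasGroup) d$group[1] else NA,
               n_neurons = nrow(d),
               pct = 100 * mean(d$crosses_midline))))
  rownames(per) <- NULL
  if (hasGroup && length(unique(per$group)) == 2) {
    gs <- do.call(rbind, lapply(split(per, per$group), function(d)
      data.frame(group = d$group[1], mean_pct = mean(d$pct),
                 sem = stats::sd(d$pct) / sqrt(nrow(d)), n = nrow(d))))
    rownames(gs) <- NULL
    sp <- split(per$pct, per$group)
    p <- stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE)$p.value
    list(perEmbryo = per, groupSummary = gs, pValue = p)
  } else {
    list(perEmbryo = per, meanPct = mean(per$pct))
  }
}

#' Acetylated-tubulin scoring of nascent branches
#'
#' Admits only terminal branches up to `maxLengthUm` (default 10)
#' micrometres; longer branches are rejected by the filter and reported as
#' a count. Returns the percentage of admitted branches with visible
#' signal, with a per-embryo breakdown when `embryo_id` is present.
#'
#' @param branches data.frame with `length_um`, `signal_present`
#'   (logical) and optionally `embryo_id`.
#' @param maxLengthUm nascent-branch length ceiling, micrometres.
#' @return list with `pctPositive`, `nAdmitted`, `nRejected`,
#'   `perEmbryo` (or NULL).
#' @examples
#' br <- data.frame(length_um = c(4, 8, 12), signal_present = c(TRUE, FALSE, TRUE))
#' nascentBranchAcetylation(br)  # 12 um branch excluded; 50% positive
#' @export
nascentBranchAcetylation <- function(branches, maxLengthUm = 10) {
  stopifnot(all(c("length_um", "signal_present") %in% names(branches)))
  keep <- branches$length_um <= maxLengthUm
  adm <- branches[keep, , drop = FALSE]
  per <- NULL
  if ("embryo_id" %in% names(adm) && nrow(adm)) {
    per <- do.call(rbind, lapply(split(adm, adm$embryo_id), function(d)
      data.frame(embryo_id = d$embryo_id[1], n = nrow(d),
                 pct_positive = 100 * mean(d$signal_present))))
    rownames(per) <- NULL
  }
  list(pctPositive = if (nrow(adm)) 100 * mean(adm$signal_present)
       else NA_real_,
       nAdmitted = nrow(adm), nRejected = sum(!keep), perEmbryo = per)
}
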