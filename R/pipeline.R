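#' Choose and run a two-or-more-group test with a normality screen
#'
#' Each sample is screened with the Shapiro-Wilk test; when every sample
#' passes (p > `alpha`), a parametric test is used (Welch t for two
#' groups, one-way ANOVA otherwise), else the rank-based counterpart
#' (Mann-Whitney / Kruskal-Wallis). Constant samples are routed to the
#' rank branch. The choice is recorded in the result. The screen level
#' defaults to 0.01: a pre-test should abandon the parametric branch
#' only on clear evidence, and a 0.05 per-sample screen would reroute
#' almost one in ten genuinely Gaussian comparisons.
#'
#' @param samples list of numeric vectors, one per group (>= 2 groups).
#' @param alpha normality-screen level (default 0.01).
#' @return list with `test` (name), `statistic`, `p`, `normal` (logical
#'   per-sample screen results), `n` per group.
#' @examples
#' set.seed(1)
#' chooseTest(list(rnorm(30), rnorm(30, 1)))$test   # "welch_t"
#' @export
chooseTest <- function(samples, alpha = 0.01) {
  stopifnot(is.list(samples), length(samples) >= 2)
  normal <- vapply(samples, function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
    tryCatch(stats::shapiro.test(x)$p.value > alpha,
             error = function(e) FALSE)
  }, logical(1))
  k <- length(samples)
  if (all(normal)) {
    if (k == 2) {
      if (stats::sd(samples[[1]]) + stats::sd(samples[[2]]) == 0) {
        res <- list(test = "welch_t", statistic = 0, p = 1)
      } else {
        tt <- stats::t.test(samples[[1]], samples[[2]])
        res <- list(test = "welch_t", statistic = unname(tt$statistic),
                    p = tt$p.value)
      }
    } else {
      d <- data.frame(y = unlist(samples),
                      g = factor(rep(seq_len(k), lengths(samples))))
      av <- stats::anova(stats::aov(y ~ g, data = d))
      res <- list(test = "anova", statistic = av$`F value`[1],
                  p = av$`Pr(>F)`[1])
    }
  } else {
    if (k == 2) {
      if (identical(samples[[1]], samples[[2]])) {
        res <- list(test = "mann_whitney", statistic = NA_real_, p = 1)
      } else {
        wt <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
        res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                    p = wt$p.value)
      }
    } else {
      kt <- stats::kruskal.test(samples)
      res <- list(test = "kruskal_wallis",
                  statistic = unname(kt$statistic), p = kt$p.value)
    }
  }
  c(res, list(normal = normal, n = lengths(samples)))
}

#' Run a configured analysis pipeline
#'
#' Executes the stages of a YAML (or list) run configuration in order,
#' isolating per-sample failures: a missing or malformed input produces
#' an error record naming the file while the remaining samples complete.
#' All randomness is derived from the config seed, and the resolved
#' configuration is written beside the outputs so a rerun reproduces them
#' bit for bit.
#'
#' Supported stage types:
#' \describe{
#'   \item{simulate_arbors}{fields `group`, `n`, and any [arborSpec()]
#'     arguments; renders `n` seeded images for the group.}
#'   \item{orientation}{fields `groups` (named lists with either a
#'     simulated `group` reference or `files` + `pxSizeUm`); computes
#'     per-image orientation profiles, writes
#'     `profile_<group>.csv`.}
#'   \item{compare}{fields `groupA`, `groupB`, `range` (2 numbers),
#'     optional `normalized` (default TRUE); appends a row to
#'     `comparisons.csv`.}
#' }
#'
#' @param config path to a YAML file or an equivalent named list with
#'   `seed`, `out_dir` and `stages`.
#' @return invisibly, a list with `profiles` (per group), `comparisons`
#'   (data.frame), `errors` (data.frame) and `outDir`.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(!is.null(cfg$out_dir), !is.null(cfg$stages))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "log.jsonl")
  cat("", file = logFile)
  logRec <- function(...) {
    rec <- list(...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logFile,
        append = TRUE)
  }
  errors <- list()
  addError <- function(stage, what, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      stage = stage, input = what, message = conditionMessage2(message))
    logRec(level = "error", stage = stage, input = what,
           message = conditionMessage2(message))
  }
  conditionMessage2 <- function(m)
    if (inherits(m, "condition")) conditionMessage(m) else as.character(m)

  groups <- list()     # group name -> list(images = list of matrices, px)
  profiles <- list()   # group name -> OrientationProfile
  comparisons <- list()

  for (si in seq_along(cfg$stages)) {
    st <- cfg$stages[[si]]
    ty <- st$type
    if (identical(ty, "simulate_arbors")) {
      n <- st$n
      args <- st[setdiff(names(st), c("type", "group", "n"))]
      imgs <- vector("list", n)
      for (i in seq_len(n)) {
        args$seed <- .childSeed(seed, si * 1000L + i)
        sp <- do.call(arborSpec, args)
        imgs[[i]] <- simulateArbor(sp)$image
      }
      groups[[st$group]] <- list(images = imgs, pxSizeUm = sp@pxSizeUm)
      logRec(level = "info", stage = "simulate_arbors", group = st$group,
             n = n)
    } else if (identical(ty, "orientation")) {
      for (g in st$groups) {
        nm <- g$name
        imgs <- list(); px <- g$pxSizeUm
        if (!is.null(g$group)) {
          src <- groups[[g$group]]
          if (is.null(src)) {
            addError("orientation", g$group, "unknown simulated group")
            next
          }
          imgs <- src$images; px <- src$pxSizeUm
        } else {
          for (f in g$files) {
            res <- tryCatch(readImageTIFF(f), error = identity)
            if (inherits(res, "condition")) addError("orientation", f, res)
            else imgs[[length(imgs) + 1L]] <- res
          }
        }
        if (!length(imgs)) next
        pr <- combineProfiles(lapply(imgs, orientationHistogram,
                                     pxSizeUm = px))
        profiles[[nm]] <- pr
        writeProfileCSV(pr, file.path(outDir,
                                      paste0("profile_", nm, ".csv")))
        logRec(level = "info", stage = "orientation", group = nm,
               n = nImages(pr))
      }
    } else if (identical(ty, "compare")) {
      pa <- profiles[[st$groupA]]; pb <- profiles[[st$groupB]]
      if (is.null(pa) || is.null(pb)) {
        addError("compare", paste(st$groupA, st$groupB),
                 "profiles not available")
        next
      }
      if (!isFALSE(st$normalized)) {
        pa <- normalizeProfile(pa); pb <- normalizeProfile(pb)
      }
      cmp <- compareAUC(pa, pb, range = unlist(st$range))
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        groupA = st$groupA, groupB = st$groupB,
        range_lo = cmp@range[1], range_hi = cmp@range[2],
        mean_auc_A = mean(cmp@aucA), mean_auc_B = mean(cmp@aucB),
        statistic = cmp@statistic, p = cmp@pValue, test = "welch_t",
        nA = length(cmp@aucA), nB = length(cmp@aucB))
      logRec(level = "info", stage = "compare", groupA = st$groupA,
             groupB = st$groupB, p = cmp@pValue)
    } else {
      addError("config", if (is.null(ty)) "<missing type>" else ty,
               "unknown stage type")
    }
  }

  cmps <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()
  if (nrow(cmps))
    utils::write.csv(cmps, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE)
  errs <- if (length(errors)) do.call(rbind, errors) else
    data.frame(stage = character(), input = character(),
               message = character())
  utils::write.csv(errs, file.path(outDir, "errors.csv"),
                   row.names = FALSE)
  cfg$seed <- seed
  yaml::write_yaml(cfg, file.path(outDir, "resolved_config.yaml"))
  invisible(list(profiles = profiles, comparisons = cmps, errors = errs,
                 outDir = outDir))
}

## ---------------------------------------------------------------------------
## I/O helpers
## ---------------------------------------------------------------------------

#' Write an orientation profile to CSV
#'
#' One row per angular bin: `angle_deg`, the per-image columns
#' `signal_1..n` (or `percent_1..n`), the across-image `mean`, `ci_lo`
#' and `ci_hi`.
#'
#' @param profile an [OrientationProfile-class].
#' @param file output path.
#' @export
writeProfileCSV <- function(profile, file) {
  av <- averageProfiles(profile)
  v <- t(profileValues(profile))
  colnames(v) <- paste0(profile@units, "_", seq_len(ncol(v)))
  utils::write.csv(cbind(av[, c("angle_deg", "mean", "ci_lo", "ci_hi")], v),
                   file, row.names = FALSE)
}

#' Read an orientation profile written by [writeProfileCSV()]
#'
#' @param file CSV path.
#' @return an [OrientationProfile-class].
#' @export
readProfileCSV <- function(file) {
  d <- utils::read.csv(file)
  sig <- grep("^(signal|percent)_", names(d), value = TRUE)
  units <- if (length(sig) && startsWith(sig[1], "percent")) "percent"
           else "signal"
  new("OrientationProfile", binCenters = d$angle_deg,
      values = t(as.matrix(d[, sig, drop = FALSE])), units = units)
}

#' Read a trajectory CSV
#'
#' Expects columns `t_s`, `x_cm`, `y_cm` (extra columns such as a tracker
#' likelihood are preserved).
#'
#' @param file CSV path.
#' @return data.frame.
#' @export
readTrajectoryCSV <- function(file) {
  d <- utils::read.csv(file)
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  d
}

#' Read a grayscale TIFF with micrometre calibration
#'
#' Pixel size is taken from a `<file>.yaml` sidecar (key `px_size_um`)
#' when present and attached as attribute `pxSizeUm`.
#'
#' @param file TIFF path.
#' @return numeric matrix with attribute `pxSizeUm` (NA when unknown).
#' @export
readImageTIFF <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  img <- tiff::readTIFF(file)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- paste0(file, ".yaml")
  px <- NA_real_
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$px_size_um)) px <- meta$px_size_um
  }
  attr(img, "pxSizeUm") <- px
  img
}

#' Write a grayscale image as TIFF with a calibration sidecar
#'
#' Intensities are rescaled to [0, 1] for storage; the original range and
#' the pixel size go to the `<file>.yaml` sidecar.
#'
#' @param image numeric matrix.
#' @param file output TIFF path.
#' @param pxSizeUm pixel size, micrometres.
#' @export
writeImageTIFF <- function(image, file, pxSizeUm) {
  rng <- range(image)
  sc <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(sc, file, bits.per.sample = 16)
  yaml::write_yaml(list(px_size_um = pxSizeUm, range_min = rng[1],
                        range_max = rng[2]), paste0(file, ".yaml"))
  invisible(file)
}
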