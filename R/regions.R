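#' Region tables for region-level statistics
#'
#' Regions are plain data.frames with columns `name`, `start`, `end`
#' (0-based bp; `start > end` wraps through the origin) and `class`
#' (`"macrodomain"`, `"hemi_genome"` or `"signal_defined"`). Bins belong to
#' a region when their midpoint falls inside it, so a set of regions tiling
#' the genome partitions the bins exactly.
#'
#' `macrodomainRegions` exposes the macrodomains of a [GenomeConfig-class];
#' `hemiGenomeRegions` derives the four hemi-genome regions from oriC and
#' dif: the Ori- and Ter-centered halves, and the left and right arms
#' (replichores).
#'
#' @param config a [GenomeConfig-class].
#' @return a regions data.frame.
#' @export
macrodomainRegions <- function(config) {
  md <- config@macrodomains
  if (!nrow(md)) stop("genome configuration has no macrodomains")
  data.frame(name = md$name, start = md$start, end = md$end,
             class = "macrodomain")
}

#' @rdname macrodomainRegions
#' @export
hemiGenomeRegions <- function(config) {
  L <- config@genomeLength
  ori <- config@oriC
  dif <- config@difSite
  q <- L / 4
  data.frame(
    name = c("Ori-half", "Ter-half", "Right-arm", "Left-arm"),
    start = c((ori - q) %% L, (ori + q) %% L, ori, dif),
    end = c((ori + q) %% L, (ori - q) %% L, dif, ori),
    class = "hemi_genome"
  )
}

.regionBinIndex <- function(config, regions) {
  lapply(seq_len(nrow(regions)),
         function(i) .binsInRegion(config, regions$start[i], regions$end[i]))
}

.starsOf <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "NS"))
}

#' Region means across replicates with paired tests
#'
#' Computes, for every region, the mean track value over its unmasked bins
#' in each replicate, then compares regions pairwise across replicates: an
#' F test for equality of variances followed by a paired two-tailed t test
#' with `df = n_replicates - 1`. Significance stars mark p < 0.05 / 0.01 /
#' 0.001 / 0.0001. No multiple-testing correction is applied by default,
#' matching common practice for these panel comparisons; set
#' `correction` to a [stats::p.adjust()] method to adjust the t-test
#' p-values.
#'
#' @param replicates list of [BinnedTrack-class] replicate tracks on one
#'   binning.
#' @param regions regions data.frame (see [macrodomainRegions()]).
#' @param correction p-value adjustment method (default `"none"`).
#' @return list with `means` (per-region grand mean, sem and per-replicate
#'   means) and `comparisons` (pairwise F/t tests).
#' @export
regionMeansAndTests <- function(replicates, regions, correction = "none") {
  if (length(replicates) < 2) stop("need at least 2 replicates for tests")
  config <- replicates[[1]]@config
  binIdx <- .regionBinIndex(config, regions)
  if (any(vapply(binIdx, length, integer(1)) == 0))
    stop("a region contains no bins")
  perRep <- vapply(replicates, function(t) {
    vapply(binIdx, function(idx) {
      keep <- idx[!t@mask[idx] & is.finite(t@values[idx])]
      if (!length(keep)) return(NA_real_)
      mean(t@values[keep])
    }, numeric(1))
  }, numeric(nrow(regions)))
  perRep <- matrix(perRep, nrow = nrow(regions),
                   dimnames = list(regions$name, NULL))
  if (any(!is.finite(perRep))) stop("a region has no unmasked bins in some replicate")

  means <- data.frame(
    name = regions$name, class = regions$class,
    mean = rowMeans(perRep), sem = apply(perRep, 1, .sem)
  )
  means <- cbind(means, as.data.frame(perRep))
  names(means)[-(1:4)] <- paste0("rep", seq_along(replicates))

  pairs <- utils::combn(nrow(regions), 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- perRep[i1, ]; y <- perRep[i2, ]
    n <- length(x)
    constant <- function(v) stats::sd(v) < 1e-10 * max(1, abs(mean(v)))
    fP <- if (constant(x) && constant(y)) 1
          else if (constant(x) || constant(y)) 0
          else stats::var.test(x, y)$p.value
    d <- x - y
    if (constant(d)) {
      # constant differences: no evidence against equality when zero,
      # certain difference otherwise
      tStat <- NA_real_
      tP <- if (abs(mean(d)) < 1e-10) 1 else 0
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      tStat <- unname(tt$statistic)
      tP <- tt$p.value
    }
    data.frame(regionA = regions$name[i1], regionB = regions$name[i2],
               difference = mean(d),
               fP = fP, equalVariance = fP > 0.05,
               t = tStat, df = n - 1L, tP = tP)
  }))
  comparisons$tPAdjusted <- stats::p.adjust(comparisons$tP, method = correction)
  comparisons$stars <- as.character(.starsOf(comparisons$tPAdjusted))
  list(means = means, comparisons = comparisons)
}

#' Classify enriched and depleted supercoiling regions
#'
#' Smooths the track, converts it to z-scores and extracts maximal
#' contiguous runs of bins above `+thresholdSd` (psoralen enriched, more
#' negatively supercoiled) or below `-thresholdSd` (depleted, more
#' positively supercoiled), dropping runs shorter than `minLengthKb`. Runs
#' are computed on the circle, so a region may wrap through the origin.
#'
#' @param track a [BinnedTrack-class] (raw enrichment; smoothing and
#'   z-scoring are applied internally).
#' @param smoothingKb smoothing window, kb (default 100).
#' @param thresholdSd z-score threshold (default 0.5).
#' @param minLengthKb minimum region length, kb (default 20).
#' @return regions data.frame with columns `name`, `start`, `end`,
#'   `class = "signal_defined"` and `state` (`"enriched"`/`"depleted"`).
#' @export
classifySupercoiledRegions <- function(track, smoothingKb = 100,
                                       thresholdSd = 0.5, minLengthKb = 20) {
  config <- track@config
  sm <- if (smoothingKb > 0) circularMovingAverage(track, smoothingKb) else track
  z <- zscoreTrack(sm)@values
  state <- integer(length(z))
  state[is.finite(z) & z > thresholdSd] <- 1L
  state[is.finite(z) & z < -thresholdSd] <- -1L

  n <- length(state)
  runs <- rle(state)
  nr <- length(runs$lengths)
  startBin <- cumsum(c(1L, runs$lengths))[seq_len(nr)]
  df <- data.frame(state = runs$values, startBin = startBin,
                   len = runs$lengths)
  # merge the wrap-around run when first and last share a state
  if (nr > 1 && df$state[1] == df$state[nr]) {
    df$len[nr] <- df$len[nr] + df$len[1]
    df <- df[-1, , drop = FALSE]
  }
  minBins <- minLengthKb * 1000 / config@binSize
  df <- df[df$state != 0L & df$len >= minBins, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(name = character(), start = numeric(), end = numeric(),
                      class = character(), state = character()))
  start <- (df$startBin - 1) * config@binSize
  end <- ((df$startBin - 1 + df$len) * config@binSize) %% config@genomeLength
  end[end == 0] <- config@genomeLength
  state <- ifelse(df$state == 1L, "enriched", "depleted")
  idx <- stats::ave(seq_along(state), state, FUN = seq_along)
  data.frame(name = paste0(state, "_", idx), start = start, end = end,
             class = "signal_defined", state = state, row.names = NULL)
}

#' Association of a binding track with supercoiled regions
#'
#' Averages a z-scored binding track (e.g. a nucleoid protein or
#' topoisomerase ChIP profile) within each supplied region, then summarizes
#' each region class and tests whether its mean binding differs from zero
#' (one-sample two-tailed t over region means, `df = n_regions - 1`) or
#' between the two classes (`test = "two_sample"`).
#'
#' @param proteinZ a [BinnedTrack-class] of kind `"zscore"`.
#' @param regions regions data.frame with a `state` column (see
#'   [classifySupercoiledRegions()]).
#' @param test `"one_sample"` (default) or `"two_sample"`.
#' @return list with `regionMeans` (per-region mean z) and `classStats`
#'   (per class: n, mean, sem, t, df, p, stars; for `two_sample` a single
#'   between-class test is reported).
#' @export
trackAssociation <- function(proteinZ, regions, test = c("one_sample", "two_sample")) {
  test <- match.arg(test)
  if (!nrow(regions)) stop("no regions supplied")
  config <- proteinZ@config
  binIdx <- .regionBinIndex(config, regions)
  regionMean <- vapply(binIdx, function(idx) {
    v <- proteinZ@values[idx]
    mean(v[is.finite(v)])
  }, numeric(1))
  rm <- data.frame(name = regions$name, state = regions$state,
                   meanZ = regionMean)
  classes <- split(rm$meanZ, rm$state)
  if (any(vapply(classes, length, integer(1)) == 0)) stop("empty region class")
  if (identical(test, "one_sample")) {
    classStats <- do.call(rbind, lapply(names(classes), function(cl) {
      x <- classes[[cl]]
      if (length(x) < 2 || stats::sd(x) < 1e-10 * max(1, abs(mean(x)))) {
        # constant region means carry no within-class uncertainty
        tStat <- NA_real_
        p <- if (abs(mean(x)) < 1e-10) 1 else 0
      } else {
        tt <- stats::t.test(x, mu = 0)
        tStat <- unname(tt$statistic)
        p <- tt$p.value
      }
      data.frame(state = cl, n = length(x), mean = mean(x), sem = .sem(x),
                 t = tStat, df = length(x) - 1L, p = p)
    }))
  } else {
    if (length(classes) != 2) stop("two_sample test needs exactly two classes")
    dMean <- mean(classes[[1]]) - mean(classes[[2]])
    if (stats::sd(unlist(classes) - rep(vapply(classes, mean, numeric(1)),
                                        lengths(classes))) <
        1e-10 * max(1, abs(dMean))) {
      tStat <- NA_real_
      df <- length(unlist(classes)) - 2L
      p <- if (abs(dMean) < 1e-10) 1 else 0
    } else {
      tt <- stats::t.test(classes[[1]], classes[[2]], var.equal = TRUE)
      tStat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
    classStats <- data.frame(
      state = paste(names(classes), collapse = " vs "),
      n = length(unlist(classes)),
      mean = dMean, sem = NA_real_, t = tStat, df = df, p = p)
  }
  classStats$stars <- as.character(.starsOf(classStats$p))
  list(regionMeans = rm, classStats = classStats)
}
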