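#' Define a (possibly skewed) ori-ter symmetry axis
#'
#' The axis passes through a point displaced from oriC by `skewDeg` degrees
#' (1 degree = genome length / 360 bp) and through its antipode. Positive
#' skew is counterclockwise, i.e. toward decreasing genomic coordinate on
#' the conventional circular map drawn with coordinates increasing
#' clockwise.
#'
#' @param config a [GenomeConfig-class] (supplies oriC and genome length).
#' @param skewDeg axis skew in degrees (default 0 = natural ori-ter axis).
#' @return an [AxisSpec-class].
#' @export
axisSpec <- function(config, skewDeg = 0) {
  L <- config@genomeLength
  new("AxisSpec", oricBp = config@oriC, skewDeg = as.numeric(skewDeg),
      axisBp = (config@oriC - skewDeg * L / 360) %% L)
}

setMethod("show", "AxisSpec", function(object) {
  cat(sprintf("AxisSpec: oriC %.0f bp, skew %+.1f deg -> axis point %.0f bp\n",
              object@oricBp, object@skewDeg, object@axisBp))
  invisible(object)
})

#' Left and right chromosome-arm series about an axis
#'
#' Reads the (optionally smoothed) track outward from the axis point: the
#' left arm counterclockwise (decreasing coordinates), the right arm
#' clockwise, both out to half the genome truncated by the smoothing
#' half-window so only fully supported bins are compared.
#'
#' @param track a [BinnedTrack-class].
#' @param axis an [AxisSpec-class] (see [axisSpec()]).
#' @param smoothingKb moving-average smoothing applied first (kb); 0 = none.
#' @return list with equal-length numeric vectors `left`, `right` and
#'   `positionsKb` (distance from the axis point).
#' @export
armSeries <- function(track, axis, smoothingKb = 100) {
  if (smoothingKb > 0) track <- circularMovingAverage(track, smoothingKb)
  config <- track@config
  n <- length(track@values)
  halfWin <- (.oddBins(max(smoothingKb, 0), config) - 1L) %/% 2L
  len <- n %/% 2L - halfWin
  if (len < 3) stop("genome too small for arm comparison at this smoothing")
  a <- .binAt(axis@axisBp, config)
  i <- seq_len(len)
  list(left = track@values[.wrap1(a - i, n)],
       right = track@values[.wrap1(a + i, n)],
       positionsKb = i * config@binSize / 1000)
}

#' Replichore symmetry correlation
#'
#' Pearson correlation between the left- and right-arm series about an axis,
#' with invalid bins excluded pairwise.
#'
#' @inheritParams armSeries
#' @return Pearson r (numeric scalar).
#' @export
symmetryCorrelation <- function(track, axis, smoothingKb = 100) {
  arms <- armSeries(track, axis, smoothingKb)
  ok <- is.finite(arms$left) & is.finite(arms$right)
  if (sum(ok) < 3) stop("too few valid arm positions")
  if (.popSd(arms$left[ok]) == 0 || .popSd(arms$right[ok]) == 0)
    stop("degenerate arm variance")
  stats::cor(arms$left[ok], arms$right[ok])
}

#' Scan axis skews for maximal replichore symmetry
#'
#' Evaluates [symmetryCorrelation()] on a grid of axis skews and reports the
#' skew with the strongest correlation; ties are broken toward the smallest
#' absolute skew. The track is smoothed once before the scan.
#'
#' @param track a [BinnedTrack-class].
#' @param skewRangeDeg length-2 numeric, scan limits in degrees
#'   (default c(-90, 90)).
#' @param stepDeg grid step in degrees (default 1).
#' @param smoothingKb smoothing applied to the track before scanning (kb).
#' @return a [SkewScanResult-class].
#' @export
skewScan <- function(track, skewRangeDeg = c(-90, 90), stepDeg = 1,
                     smoothingKb = 100) {
  if (length(skewRangeDeg) != 2 || skewRangeDeg[2] < skewRangeDeg[1])
    stop("empty skew grid")
  grid <- seq(skewRangeDeg[1], skewRangeDeg[2], by = stepDeg)
  smoothed <- if (smoothingKb > 0) circularMovingAverage(track, smoothingKb)
              else track
  config <- track@config
  # arm truncation matches what symmetryCorrelation(track, ., smoothingKb)
  # would use; the smoothing itself is hoisted out of the loop
  halfWin <- (.oddBins(max(smoothingKb, 0), config) - 1L) %/% 2L
  n <- length(smoothed@values)
  len <- n %/% 2L - halfWin
  i <- seq_len(len)
  rs <- vapply(grid, function(sk) {
    a <- .binAt((config@oriC - sk * config@genomeLength / 360) %% config@genomeLength,
                config)
    left <- smoothed@values[.wrap1(a - i, n)]
    right <- smoothed@values[.wrap1(a + i, n)]
    ok <- is.finite(left) & is.finite(right)
    if (sum(ok) < 3 || .popSd(left[ok]) == 0 || .popSd(right[ok]) == 0)
      return(NA_real_)
    stats::cor(left[ok], right[ok])
  }, numeric(1))
  best <- which(rs == max(rs, na.rm = TRUE))
  best <- best[which.min(abs(grid[best]))]
  new("SkewScanResult", skewDeg = grid, r = rs,
      optSkewDeg = grid[best], optR = rs[best])
}

setMethod("show", "SkewScanResult", function(object) {
  cat(sprintf("SkewScanResult: %d skews in [%g, %g] deg; optimum %+g deg (r = %.3f)\n",
              length(object@skewDeg), min(object@skewDeg), max(object@skewDeg),
              object@optSkewDeg, object@optR))
  invisible(object)
})
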