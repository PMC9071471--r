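#' Bin aligned fragments into a count track
#'
#' Each fragment contributes exactly one count to the bin containing its
#' midpoint. Fragments that span the origin of the circular genome use the
#' circular midpoint: for a fragment `(start, end)` the length is
#' `(end - start) mod L` and the midpoint `(start + length/2) mod L`.
#'
#' Midpoint assignment is robust to fragment length (typical sonication size
#' ~500 bp) and to paired-end fragments; the total count is conserved exactly.
#'
#' @param fragments data.frame with `start`, `end` columns (0-based bp,
#'   half-open; `end < start` wraps through the origin), or a
#'   [GenomicRanges::GRanges] (1-based, converted internally).
#' @param config a [GenomeConfig-class].
#' @return a [BinnedTrack-class] of kind `"count"`.
#' @export
binFragments <- function(fragments, config) {
  if (methods::is(fragments, "GRanges")) {
    fragments <- data.frame(
      start = GenomicRanges::start(fragments) - 1,
      end = GenomicRanges::end(fragments)
    )
  }
  L <- config@genomeLength
  s <- as.numeric(fragments$start)
  e <- as.numeric(fragments$end)
  if (any(!is.finite(s)) || any(!is.finite(e)) ||
      any(s < 0) || any(s >= L) || any(e < 0) || any(e > L))
    stop("fragment coordinates outside [0, genome length)")
  len <- (e - s) %% L
  if (any(len == 0)) stop("zero-length fragment")
  mid <- (s + len / 2) %% L
  counts <- tabulate(.binAt(mid, config), nbins = nBins(config))
  binnedTrack(counts, config, kind = "count")
}

#' Mask unmappable intervals and impute from flanking bins
#'
#' Every bin overlapping a masked interval of the genome configuration is
#' replaced by the mean of the nearest `flankKb` unmasked bins on each side
#' (6 kb total at the defaults), and flagged in the track mask as imputed.
#' When the outward search runs into another masked interval it skips past it
#' and emits a warning.
#'
#' @param track a [BinnedTrack-class] of kind `"count"` or `"relative"`.
#' @param flankKb flank width per side in kb (default 3).
#' @return the imputed [BinnedTrack-class]; unmasked bins are unchanged.
#' @export
maskAndImpute <- function(track, flankKb = 3) {
  config <- track@config
  if (!track@kind %in% c("count", "relative"))
    stop("maskAndImpute expects a count or relative track")
  mi <- config@maskedIntervals
  if (!nrow(mi)) return(track)
  n <- length(track@values)
  maskedIdx <- sort(unique(unlist(
    lapply(seq_len(nrow(mi)),
           function(i) .binsOverlapping(config, mi$start[i], mi$end[i]))
  )))
  isMasked <- rep(FALSE, n)
  isMasked[maskedIdx] <- TRUE
  flankBins <- max(1L, as.integer(round(flankKb * 1000 / config@binSize)))
  values <- track@values
  skippedForeign <- FALSE

  collectFlank <- function(b, step) {
    got <- numeric(0)
    i <- b
    steps <- 0L
    inRun <- TRUE
    while (length(got) < flankBins && steps < n) {
      i <- .wrap1(i + step, n)
      steps <- steps + 1L
      if (isMasked[i]) {
        if (!inRun) skippedForeign <<- TRUE
      } else {
        inRun <- FALSE
        got <- c(got, track@values[i])
      }
    }
    got
  }

  for (b in maskedIdx) {
    flanks <- c(collectFlank(b, -1L), collectFlank(b, +1L))
    values[b] <- mean(flanks, na.rm = TRUE)
  }
  if (skippedForeign)
    warning("flank search extended past an adjacent masked interval")
  mask <- track@mask
  mask[maskedIdx] <- TRUE
  binnedTrack(values, config, kind = track@kind, mask = mask,
              metadata = track@metadata)
}

#' Normalize a count track to the genome average
#'
#' Divides every bin by the mean over unmasked bins, so that the resulting
#' relative track has mean 1 over its unmasked bins. Idempotent, and
#' invariant to rescaling of the input counts.
#'
#' @param track a [BinnedTrack-class] of kind `"count"` or `"relative"`.
#' @return a [BinnedTrack-class] of kind `"relative"`.
#' @export
normalizeRelative <- function(track) {
  if (!track@kind %in% c("count", "relative"))
    stop("normalizeRelative expects a count or relative track")
  keep <- !track@mask & is.finite(track@values)
  if (!any(keep) || sum(track@values[keep]) <= 0)
    stop("empty library: no counts in unmasked bins")
  m <- mean(track@values[keep])
  binnedTrack(track@values / m, track@config, kind = "relative",
              mask = track@mask, metadata = track@metadata)
}

#' Per-bin log2 pulldown/input enrichment
#'
#' Computes `log2(pulldown / input)` per bin from two relative tracks on the
#' same binning. Bins where either side is zero carry no information about
#' the ratio; they are set to `NA` and flagged in the mask (no pseudocount is
#' added). Imputed flags from both inputs are carried through.
#'
#' @param pulldown,input [BinnedTrack-class] objects of kind `"relative"`.
#' @return a [BinnedTrack-class] of kind `"log2_enrichment"`.
#' @export
log2Enrichment <- function(pulldown, input) {
  if (!identical(pulldown@kind, "relative") || !identical(input@kind, "relative"))
    stop("log2Enrichment expects two relative tracks (see normalizeRelative)")
  if (!.sameBinning(pulldown, input))
    stop("pulldown and input are on different genome binnings")
  p <- pulldown@values
  i <- input@values
  bad <- !is.finite(p) | !is.finite(i) | p <= 0 | i <= 0
  v <- rep(NA_real_, length(p))
  v[!bad] <- log2(p[!bad] / i[!bad])
  binnedTrack(v, pulldown@config, kind = "log2_enrichment",
              mask = pulldown@mask | input@mask | bad)
}

#' Standardize a track to z-scores
#'
#' Centers and scales by the mean and population standard deviation of the
#' unmasked bins, giving mean 0 and sd 1 over unmasked bins. Idempotent, and
#' invariant under positive affine transformations of the input.
#'
#' @param track a [BinnedTrack-class].
#' @return a [BinnedTrack-class] of kind `"zscore"`.
#' @export
zscoreTrack <- function(track) {
  keep <- !track@mask & is.finite(track@values)
  x <- track@values[keep]
  if (length(x) < 2) stop("need at least 2 unmasked bins")
  s <- .popSd(x)
  if (s == 0) stop("zero variance over unmasked bins")
  binnedTrack((track@values - mean(x)) / s, track@config, kind = "zscore",
              mask = track@mask, metadata = track@metadata)
}

#' Centered circular moving average
#'
#' Each bin becomes the mean of an odd-width window centered on it, with
#' circular wrap at the genome origin. Window widths given in kb are
#' converted to the nearest odd bin count. `NA` (invalid) bins are excluded
#' from the window means; imputed bins contribute their imputed values.
#'
#' @param track a [BinnedTrack-class].
#' @param windowKb window width in kb.
#' @return a smoothed [BinnedTrack-class] of the same kind.
#' @export
circularMovingAverage <- function(track, windowKb) {
  w <- .oddBins(windowKb, track@config)
  n <- length(track@values)
  if (w >= n) stop("smoothing window must be smaller than the genome")
  if (w == 1L) return(track)
  fin <- is.finite(track@values)
  v0 <- ifelse(fin, track@values, 0)
  kern <- rep(1, w)
  sums <- as.numeric(stats::filter(v0, kern, sides = 2, circular = TRUE))
  cnts <- as.numeric(stats::filter(as.numeric(fin), kern, sides = 2,
                                   circular = TRUE))
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  binnedTrack(out, track@config, kind = track@kind, mask = cnts == 0,
              metadata = track@metadata)
}

#' Distributional diagnostics for an enrichment track
#'
#' Reports the sample skewness (Excel-style, type 2), the correlation of the
#' ordered values with normal quantiles (q-q plot linearity), and, when a
#' per-bin GC content vector is supplied, the Pearson correlation between
#' enrichment and GC with its p-value. A well-behaved log2 enrichment track
#' is near-normal with slight positive skew; a strong GC correlation would
#' indicate composition bias requiring correction.
#'
#' @param track a [BinnedTrack-class] (typically kind `"log2_enrichment"`).
#' @param gcPerBin optional numeric vector of per-bin GC fractions.
#' @return a list with elements `n`, `skewness`, `qqCorrelation` and,
#'   if `gcPerBin` is given, `gcCorrelation` (`r`, `p`).
#' @export
trackDiagnostics <- function(track, gcPerBin = NULL) {
  x <- track@values[is.finite(track@values)]
  out <- list(
    n = length(x),
    skewness = e1071::skewness(x, type = 2),
    qqCorrelation = stats::cor(sort(x), stats::qnorm(stats::ppoints(length(x))))
  )
  if (!is.null(gcPerBin)) {
    if (length(gcPerBin) != length(track@values))
      stop("gcPerBin must have one value per bin")
    ok <- is.finite(track@values) & is.finite(gcPerBin)
    ct <- stats::cor.test(track@values[ok], gcPerBin[ok])
    out$gcCorrelation <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  out
}
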