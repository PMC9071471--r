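#' Extract a strand-oriented window around a transcription unit
#'
#' Takes the enrichment values in `[-halfWidthKb, +halfWidthKb]` around the
#' TU midpoint and flips minus-strand windows so that transcription always
#' runs left to right. Position 0 is the bin containing the midpoint;
#' negative positions are upstream (behind the polymerase, negatively
#' supercoiled), positive positions downstream. The window wraps freely
#' around the circular genome and masked bins are carried through.
#'
#' @param track a [BinnedTrack-class], typically kind `"log2_enrichment"`.
#' @param tu a single transcription unit (length-1 `GRanges` from
#'   [transcriptionUnits()]).
#' @param halfWidthKb half-width of the window in kb (default 40).
#' @return an [OrientedWindow-class].
#' @export
extractOrientedWindow <- function(track, tu, halfWidthKb = 40) {
  if (length(tu) != 1L) stop("tu must be a single transcription unit")
  config <- track@config
  hw <- as.integer(round(halfWidthKb * 1000 / config@binSize))
  n <- length(track@values)
  if (2L * hw + 1L > n) stop("window larger than the genome")
  midBin <- .binAt(.tuMidpointBp(tu, config), config)
  offsets <- seq.int(-hw, hw)
  strand <- .tuStrand(tu)
  idx <- if (identical(strand, "-")) {
    .wrap1(midBin - offsets, n)
  } else {
    .wrap1(midBin + offsets, n)
  }
  new("OrientedWindow",
      tuName = S4Vectors::mcols(tu)$name, strand = strand,
      halfWidthKb = as.numeric(halfWidthKb),
      positionsKb = offsets * config@binSize / 1000,
      values = track@values[idx], mask = track@mask[idx])
}

#' Consensus profile across oriented windows
#'
#' Mean-centers each window over its full range (so the mean log2 value over
#' the window is zero) and averages the windows position by position,
#' ignoring missing entries. The per-position standard error of the mean is
#' recorded.
#'
#' @param windows list of [OrientedWindow-class] objects of equal half-width.
#' @return a [ConsensusProfile-class].
#' @export
consensusProfile <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  pos <- windows[[1]]@positionsKb
  for (w in windows)
    if (!isTRUE(all.equal(w@positionsKb, pos)))
      stop("windows must share the same half-width and binning")
  mat <- vapply(windows, function(w) {
    v <- w@values
    v - mean(v[is.finite(v)])
  }, numeric(length(pos)))
  mat <- matrix(mat, nrow = length(pos))
  nAt <- as.integer(rowSums(is.finite(mat)))
  vals <- rowMeans(mat, na.rm = TRUE)
  vals[nAt == 0] <- NA_real_
  sem <- apply(mat, 1, .sem)
  new("ConsensusProfile", positionsKb = pos, values = vals, sem = sem,
      nWindows = length(windows), nAtPosition = nAt)
}

setMethod("show", "ConsensusProfile", function(object) {
  cat(sprintf("ConsensusProfile over %d windows, positions %g..%g kb\n",
              object@nWindows, min(object@positionsKb), max(object@positionsKb)))
  invisible(object)
})

# Pearson r of values against distance for the first k points; NA when
# degenerate.
.pearsonUpTo <- function(d, y, k) {
  sel <- d <= k
  if (sum(sel) < 3) return(NA_real_)
  yy <- y[sel]
  if (.popSd(yy) == 0 || .popSd(d[sel]) == 0) return(NA_real_)
  stats::cor(d[sel], yy)
}

#' Fit one side of a twin-domain by expanding-window regression
#'
#' Regresses the consensus profile against distance from the operon midpoint
#' on one side, starting with the first `startKb` kb and extending one kb at
#' a time; the window whose regression attains the maximal Pearson
#' correlation magnitude is retained. With `rule = "scan"` (default) all
#' candidate windows are evaluated and the global maximum of |r| taken
#' (ties broken toward the shortest window); `rule = "greedy"` stops at the
#' first decrease of |r|.
#'
#' The domain amplitude is the regression y-intercept (signed log2
#' fold-change at the midpoint) and the magnitude is the x-intercept
#' `-intercept/slope`, the distance at which the domain decays to baseline.
#' 95% ranges are the x- and y-intercepts of the pointwise 95% confidence
#' band of the fitted mean line. When the fitted line does not decay toward
#' baseline (slope and intercept of the same sign, or degenerate input) no
#' domain is detected and the magnitude is `NA`.
#'
#' @param profile a [ConsensusProfile-class] (or [OrientedWindow-class]).
#' @param side `"upstream"` (negative positions) or `"downstream"`.
#' @param startKb minimal window, kb from the midpoint (default 10).
#' @param rule `"scan"` or `"greedy"`.
#' @return a [DomainFit-class].
#' @export
fitDomainRegression <- function(profile, side = c("upstream", "downstream"),
                                startKb = 10, rule = c("scan", "greedy")) {
  side <- match.arg(side)
  rule <- match.arg(rule)
  pos <- profile@positionsKb
  val <- profile@values
  sel <- if (identical(side, "upstream")) pos < 0 else pos > 0
  d <- abs(pos[sel])
  y <- val[sel]
  o <- order(d)
  d <- d[o]; y <- y[o]
  keep <- is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (!length(d) || max(d) < startKb)
    stop(sprintf("profile extends less than %g kb on the %s side", startKb, side))

  ks <- seq.int(ceiling(startKb), floor(max(d)))
  rs <- vapply(ks, function(k) .pearsonUpTo(d, y, k), numeric(1))
  rScan <- data.frame(windowKb = ks, r = rs)

  noFit <- function() new("DomainFit",
    side = side, slope = NA_real_, intercept = NA_real_, windowKb = NA_real_,
    pearsonR = NA_real_, amplitude = NA_real_, magnitudeKb = NA_real_,
    amplitudeRange = c(NA_real_, NA_real_), magnitudeRange = c(NA_real_, NA_real_),
    nPoints = 0L, detected = FALSE, rScan = rScan)

  if (all(is.na(rs))) return(noFit())

  if (identical(rule, "scan")) {
    best <- which.max(abs(rs))   # first (= shortest window) among ties
  } else {
    best <- 1L
    while (best < length(ks) && !is.na(rs[best + 1L]) &&
           abs(rs[best + 1L]) > abs(rs[best]) + .Machine$double.eps^0.5)
      best <- best + 1L
  }
  k <- ks[best]
  sel2 <- d <= k
  dd <- d[sel2]; yy <- y[sel2]
  fit <- stats::lm(yy ~ dd)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  nPts <- length(dd)

  detected <- is.finite(b0) && is.finite(b1) && b1 != 0 && (b0 * b1 < 0)
  magnitude <- if (detected) -b0 / b1 else NA_real_

  # pointwise 95% confidence band of the mean line (sigma = 0 on an exactly
  # linear profile collapses the band onto the point estimates)
  s <- suppressWarnings(summary(fit)$sigma)
  xbar <- mean(dd)
  Sxx <- sum((dd - xbar)^2)
  tq <- stats::qt(0.975, nPts - 2)
  seY <- function(x) s * sqrt(1 / nPts + (x - xbar)^2 / Sxx)
  ampRange <- sort(b0 + c(-1, 1) * tq * seY(0))

  magRange <- c(NA_real_, NA_real_)
  if (detected) {
    bandRoot <- function(sgn) {
      f <- function(x) b0 + b1 * x + sgn * tq * seY(x)
      tryCatch(
        stats::uniroot(f, lower = 0, upper = max(10 * magnitude, k),
                       extendInt = "yes", tol = 1e-9)$root,
        error = function(e) NA_real_)
    }
    magRange <- sort(c(bandRoot(-1), bandRoot(1)))
  }

  new("DomainFit",
      side = side, slope = b1, intercept = b0, windowKb = as.numeric(k),
      pearsonR = rs[best], amplitude = b0, magnitudeKb = magnitude,
      amplitudeRange = ampRange, magnitudeRange = magRange,
      nPoints = as.integer(nPts), detected = detected, rScan = rScan)
}

setMethod("show", "DomainFit", function(object) {
  if (!object@detected) {
    cat(sprintf("DomainFit (%s): no domain detected\n", object@side))
  } else {
    cat(sprintf(
      "DomainFit (%s): amplitude %.3f [%.3f, %.3f], magnitude %.1f kb [%.1f, %.1f], window %g kb, r = %.3f (n = %d)\n",
      object@side, object@amplitude, object@amplitudeRange[1],
      object@amplitudeRange[2], object@magnitudeKb, object@magnitudeRange[1],
      object@magnitudeRange[2], object@windowKb, object@pearsonR,
      object@nPoints))
  }
  invisible(object)
})

#' Per-TU twin-domain amplitude from flanking enrichment
#'
#' For every transcription unit, the amplitude is the enrichment `offsetKb`
#' upstream of its 5' boundary minus the enrichment `offsetKb` downstream of
#' its 3' boundary, in transcription orientation. Canonical twin-domains
#' (negative supercoiling behind, positive ahead) therefore give positive
#' amplitudes, and inverting a unit flips the sign of its amplitude.
#'
#' @param track a [BinnedTrack-class] of kind `"log2_enrichment"`.
#' @param tus transcription units ([transcriptionUnits()]).
#' @param offsetKb flank offset in kb (default 5).
#' @return data.frame with columns `name`, `strand`, `expression`,
#'   `ribosomal`, `amplitude` (NA where a flanking bin is invalid) and
#'   `masked` (either flanking bin imputed/invalid).
#' @export
perTuAmplitude <- function(track, tus, offsetKb = 5) {
  config <- track@config
  L <- config@genomeLength
  off <- offsetKb * 1000
  s0 <- .tuStart0(tus)
  e0 <- .tuEnd0(tus)
  minus <- .tuStrand(tus) == "-"
  upPos <- ifelse(minus, e0 + off, s0 - off) %% L
  downPos <- ifelse(minus, s0 - off, e0 + off) %% L
  upBin <- .binAt(upPos, config)
  downBin <- .binAt(downPos, config)
  amp <- track@values[upBin] - track@values[downBin]
  data.frame(
    name = S4Vectors::mcols(tus)$name,
    strand = .tuStrand(tus),
    expression = tuExpression(tus),
    ribosomal = tuRibosomal(tus),
    amplitude = amp,
    masked = track@mask[upBin] | track@mask[downBin]
  )
}

#' Correlation between twin-domain amplitude and expression
#'
#' Pearson correlation between per-TU amplitudes and expression (converted
#' to z-score), over all TUs and over top-expression subsets chosen by
#' expression rank.
#'
#' @param amplitudes numeric amplitudes per TU (e.g. from
#'   [perTuAmplitude()]`$amplitude`).
#' @param expressions matched expression levels.
#' @param topFractions fractions defining top-expression subsets
#'   (default top 10% and top 1%).
#' @return data.frame with one row per subset: `subset`, `fraction`, `n`,
#'   `r`, `p`, `meanAmplitude`, `semAmplitude`. Subsets with fewer than 3
#'   TUs are skipped with a warning.
#' @export
amplitudeExpressionCorrelation <- function(amplitudes, expressions,
                                           topFractions = c(0.1, 0.01)) {
  if (length(amplitudes) != length(expressions))
    stop("amplitudes and expressions must be matched per TU")
  ok <- is.finite(amplitudes) & is.finite(expressions)
  amp <- amplitudes[ok]
  ez <- as.numeric(scale(expressions[ok]))
  rnk <- rank(-ez, ties.method = "first")
  subsets <- c(list(all = seq_along(amp)),
               stats::setNames(
                 lapply(topFractions, function(f) which(rnk <= ceiling(f * length(amp)))),
                 sprintf("top%g%%", topFractions * 100)))
  rows <- lapply(names(subsets), function(nm) {
    idx <- subsets[[nm]]
    if (length(idx) < 3) {
      warning("subset ", nm, " has fewer than 3 TUs; skipped")
      return(NULL)
    }
    ct <- stats::cor.test(ez[idx], amp[idx])
    data.frame(subset = nm,
               fraction = if (nm == "all") 1 else topFractions[match(nm, names(subsets)) - 1],
               n = length(idx), r = unname(ct$estimate), p = ct$p.value,
               meanAmplitude = mean(amp[idx]), semAmplitude = .sem(amp[idx]))
  })
  do.call(rbind, rows)
}

#' Percent change in domain amplitude between conditions
#'
#' `100 * (1 - amplitude_treated / amplitude_control)`: positive for a
#' reduction (e.g. transcription shutoff), negative for an increase.
#'
#' @param fitTreated,fitControl [DomainFit-class] objects for the same side.
#' @return percent reduction (numeric scalar).
#' @export
amplitudeChangePercent <- function(fitTreated, fitControl) {
  if (!identical(fitTreated@side, fitControl@side))
    stop("fits are for different domain sides")
  if (!is.finite(fitControl@amplitude) || fitControl@amplitude == 0)
    stop("control amplitude is zero or undefined")
  100 * (1 - fitTreated@amplitude / fitControl@amplitude)
}
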