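#' Construct twin-domain model parameters
#'
#' @param ampPerUnitExpression log2 fold-change for a unit transcribed at the
#'   mean ribosomal-operon rate (default 0.38).
#' @param negMagnitudeKb upstream (negative) domain magnitude, kb (default 23).
#' @param posMagnitudeKb downstream (positive) domain magnitude, kb
#'   (default 25).
#' @param referenceExpression expression level anchoring the amplitude scale;
#'   `NA` to derive it from ribosomal-flagged units at model time.
#' @return a [TwinDomainParams-class].
#' @export
twinDomainParams <- function(ampPerUnitExpression = 0.38,
                             negMagnitudeKb = 23, posMagnitudeKb = 25,
                             referenceExpression = NA_real_) {
  new("TwinDomainParams",
      ampPerUnitExpression = ampPerUnitExpression,
      negMagnitudeKb = negMagnitudeKb,
      posMagnitudeKb = posMagnitudeKb,
      referenceExpression = as.numeric(referenceExpression))
}

setMethod("show", "TwinDomainParams", function(object) {
  cat(sprintf(
    "TwinDomainParams: amplitude %.3g per reference expression (ref = %.4g), magnitudes %.3g/%.3g kb (neg/pos)\n",
    object@ampPerUnitExpression, object@referenceExpression,
    object@negMagnitudeKb, object@posMagnitudeKb))
  invisible(object)
})

# resolve the amplitude anchor: explicit referenceExpression, else the mean
# expression of ribosomal-flagged TUs
.resolveReference <- function(params, tus) {
  if (is.finite(params@referenceExpression)) return(params@referenceExpression)
  rib <- tuRibosomal(tus)
  if (is.null(rib) || !any(rib))
    stop("no ribosomal-flagged TUs and no explicit referenceExpression; ",
         "the amplitude scale is anchored to the mean ribosomal rate")
  mean(tuExpression(tus)[rib])
}

#' Twin-domain contribution of a single transcription unit
#'
#' Places a signed triangle around the TU midpoint: `+A` extrapolated at the
#' midpoint decaying linearly to 0 at `negMagnitudeKb` upstream (negative
#' supercoiling behind the polymerase), `-A` decaying to 0 at
#' `posMagnitudeKb` downstream, with `A = ampPerUnitExpression *
#' expression / referenceExpression`. With `shape = "ramp"` (default) the
#' midpoint bin sits at the zero crossing of a linear ramp between the two
#' peaks; `shape = "step"` puts the sign change as a step at the midpoint.
#' Orientation follows the strand; the contribution wraps around the
#' circular genome.
#'
#' @param tu a single transcription unit.
#' @param params [TwinDomainParams-class].
#' @param config [GenomeConfig-class].
#' @param shape `"ramp"` or `"step"` midpoint behaviour.
#' @param referenceExpression optional explicit anchor (otherwise taken from
#'   `params`).
#' @return data.frame with columns `bin` (1-based) and `value`; zero
#'   contributions are omitted.
#' @export
tuTwinDomainProfile <- function(tu, params, config,
                                shape = c("ramp", "step"),
                                referenceExpression = NULL) {
  shape <- match.arg(shape)
  if (length(tu) != 1L) stop("tu must be a single transcription unit")
  expr <- tuExpression(tu)
  if (expr == 0)
    return(data.frame(bin = integer(), value = numeric()))
  ref <- if (!is.null(referenceExpression)) referenceExpression
         else .resolveReference(params, tu)
  if (!is.finite(ref) || ref <= 0)
    stop("referenceExpression must be positive when any unit is expressed")
  A <- params@ampPerUnitExpression * expr / ref
  n <- nBins(config)
  kbPerBin <- config@binSize / 1000
  negBins <- floor(params@negMagnitudeKb / kbPerBin)
  posBins <- floor(params@posMagnitudeKb / kbPerBin)
  offsets <- seq.int(-negBins, posBins)
  dKb <- offsets * kbPerBin
  value <- ifelse(dKb < 0, A * (1 - (-dKb) / params@negMagnitudeKb),
           ifelse(dKb > 0, -A * (1 - dKb / params@posMagnitudeKb),
                  if (identical(shape, "step")) A else 0))
  midBin <- .binAt(.tuMidpointBp(tu, config), config)
  if (identical(.tuStrand(tu), "-")) offsets <- -offsets
  bins <- .wrap1(midBin + offsets, n)
  keep <- value != 0
  data.frame(bin = bins[keep], value = value[keep])
}

#' Compose a genome supercoiling model from a transcriptome
#'
#' Sums the twin-domain contributions of all transcription units on the
#' circular genome. The result is linear in the TU list and equivariant
#' under rotation of all coordinates.
#'
#' @param tus transcription units ([transcriptionUnits()]).
#' @param params [TwinDomainParams-class]; when its `referenceExpression` is
#'   `NA` the mean expression of ribosomal-flagged units is used.
#' @param config [GenomeConfig-class].
#' @param shape midpoint behaviour, see [tuTwinDomainProfile()].
#' @return a [BinnedTrack-class] of kind `"modeled"`, with the resolved
#'   parameters in its metadata.
#' @export
composeGenomeModel <- function(tus, params, config, shape = c("ramp", "step")) {
  shape <- match.arg(shape)
  if (!length(tus)) stop("at least one transcription unit is required")
  ref <- .resolveReference(params, tus)
  v <- numeric(nBins(config))
  for (i in seq_along(tus)) {
    contrib <- tuTwinDomainProfile(tus[i], params, config, shape = shape,
                                   referenceExpression = ref)
    if (nrow(contrib))
      v[contrib$bin] <- v[contrib$bin] + contrib$value
  }
  binnedTrack(v, config, kind = "modeled",
              metadata = list(params = params, referenceExpression = ref,
                              shape = shape))
}

#' Rescale a modeled profile to a reference track's range
#'
#' Affine rescaling of the model so its minimum and maximum match the
#' reference. Extrema are extracted after smoothing both tracks
#' (`smoothKb`, default 50 kb, matching the smoothing at which model and
#' measurement are compared); set `smoothKb = 0` to use the raw range. The
#' affine map is then applied to the unsmoothed model values, so all Pearson
#' correlations with other tracks are unchanged.
#'
#' @param model a [BinnedTrack-class] of kind `"modeled"`.
#' @param reference a [BinnedTrack-class] on the same binning.
#' @param smoothKb smoothing (kb) applied before extracting extrema.
#' @return the rescaled [BinnedTrack-class].
#' @export
scaleToReference <- function(model, reference, smoothKb = 50) {
  if (!.sameBinning(model, reference))
    stop("model and reference are on different binnings")
  sm <- if (smoothKb > 0) circularMovingAverage(model, smoothKb) else model
  sr <- if (smoothKb > 0) circularMovingAverage(reference, smoothKb) else reference
  mv <- sm@values[is.finite(sm@values)]
  rv <- sr@values[is.finite(sr@values)]
  if (diff(range(mv)) == 0) stop("constant model cannot be rescaled")
  a <- diff(range(rv)) / diff(range(mv))
  b <- min(rv) - a * min(mv)
  binnedTrack(a * model@values + b, model@config, kind = "modeled",
              mask = model@mask,
              metadata = c(model@metadata, list(scale = a, offset = b)))
}

#' Sliding-window Pearson correlation between two tracks
#'
#' Pearson correlation within a centered circular window around every
#' evaluated position. Bins where either track is invalid are excluded
#' pairwise; windows with fewer than 3 valid pairs (or degenerate variance)
#' yield `NA`.
#'
#' @param a,b [BinnedTrack-class] objects on the same binning.
#' @param windowKb window width, kb (default 300).
#' @param stepKb evaluation step, kb (default 1 = every bin); skipped
#'   positions are `NA`.
#' @return a [BinnedTrack-class] of kind `"correlation"`.
#' @export
slidingWindowCorrelation <- function(a, b, windowKb = 300, stepKb = 1) {
  if (!.sameBinning(a, b)) stop("tracks are on different binnings")
  config <- a@config
  w <- .oddBins(windowKb, config)
  n <- length(a@values)
  if (w < 3) stop("window must span at least 3 bins")
  if (w >= n) stop("window must be smaller than the genome")
  fin <- is.finite(a@values) & is.finite(b@values)
  ax <- ifelse(fin, a@values, 0)
  bx <- ifelse(fin, b@values, 0)
  kern <- rep(1, w)
  csum <- function(x) as.numeric(stats::filter(x, kern, sides = 2, circular = TRUE))
  m <- csum(as.numeric(fin))
  Sx <- csum(ax); Sy <- csum(bx)
  Sxx <- csum(ax^2); Syy <- csum(bx^2); Sxy <- csum(ax * bx)
  varx <- m * Sxx - Sx^2
  vary <- m * Syy - Sy^2
  r <- rep(NA_real_, n)
  ok <- m >= 3 & varx > 0 & vary > 0
  r[ok] <- (m[ok] * Sxy[ok] - Sx[ok] * Sy[ok]) / sqrt(varx[ok] * vary[ok])
  stepBins <- max(1L, as.integer(round(stepKb * 1000 / config@binSize)))
  if (stepBins > 1L) {
    skip <- rep(TRUE, n)
    skip[seq.int(1L, n, by = stepBins)] <- FALSE
    r[skip] <- NA_real_
  }
  binnedTrack(r, config, kind = "correlation")
}

#' Genome-wide model fitness against replicate measurements
#'
#' Pearson correlation of each replicate track with the model over all
#' valid bins, summarized as mean and standard error across replicates;
#' optionally also within supplied regions.
#'
#' @param model a [BinnedTrack-class] (kind `"modeled"`).
#' @param replicates list of [BinnedTrack-class] measurement replicates.
#' @param regions optional regions data.frame (`name`, `start`, `end`) for
#'   per-region fitness.
#' @return list with `perReplicate` (numeric vector), `meanR`, `semR` and,
#'   when regions are given, `regions` (data.frame of per-region mean/sem).
#' @export
modelFitnessSummary <- function(model, replicates, regions = NULL) {
  if (!length(replicates)) stop("at least one replicate is required")
  rOf <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || .popSd(x[ok]) == 0 || .popSd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  perRep <- vapply(replicates, function(t) rOf(model@values, t@values), numeric(1))
  out <- list(perReplicate = perRep, meanR = mean(perRep, na.rm = TRUE),
              semR = .sem(perRep))
  if (!is.null(regions)) {
    config <- model@config
    out$regions <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      idx <- .binsInRegion(config, regions$start[i], regions$end[i])
      rr <- vapply(replicates,
                   function(t) rOf(model@values[idx], t@values[idx]), numeric(1))
      data.frame(name = regions$name[i], meanR = mean(rr, na.rm = TRUE),
                 semR = .sem(rr))
    }))
  }
  out
}
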