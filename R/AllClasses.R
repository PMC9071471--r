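#' @import methods
NULL

.TRACK_KINDS <- c("count", "relative", "log2_enrichment", "zscore", "modeled",
                  "correlation")

#' Circular genome geometry
#'
#' A `GenomeConfig` describes the geometry of a circular bacterial chromosome
#' for binned-track analyses: total length, bin size, the replication origin
#' (oriC) and dimer-resolution site (dif), intervals to mask (e.g. unmappable
#' rRNA operons) and, optionally, macrodomain coordinates.
#'
#' Coordinates are 0-based, half-open base pairs and are reduced modulo the
#' genome length on construction. Intervals with `start > end` wrap through
#' the origin. Bin `i` covers `[i * binSize, (i + 1) * binSize)`; a final
#' partial bin is allowed and flagged by [nBins()] arithmetic.
#'
#' @slot genomeLength total genome length in bp.
#' @slot binSize bin width in bp (default 1000).
#' @slot oriC position of the replication origin, bp.
#' @slot difSite position of the dif site, bp.
#' @slot maskedIntervals data.frame with columns `start`, `end`, `label`.
#' @slot macrodomains data.frame with columns `name`, `start`, `end`;
#'   must tile the genome without overlap when non-empty.
#'
#' @seealso [genomeConfig()], [readGenomeConfig()]
#' @export
setClass("GenomeConfig",
  representation(
    genomeLength = "numeric",
    binSize = "numeric",
    oriC = "numeric",
    difSite = "numeric",
    maskedIntervals = "data.frame",
    macrodomains = "data.frame"
  )
)

setValidity("GenomeConfig", function(object) {
  msg <- character()
  L <- object@genomeLength
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    msg <- c(msg, "genomeLength must be a single positive number")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  for (pos in c(object@oriC, object@difSite))
    if (!is.finite(pos) || pos < 0 || pos >= L)
      msg <- c(msg, "oriC/difSite must lie in [0, genomeLength)")
  mi <- object@maskedIntervals
  if (nrow(mi) && !all(c("start", "end", "label") %in% names(mi)))
    msg <- c(msg, "maskedIntervals needs columns start, end, label")
  md <- object@macrodomains
  if (nrow(md)) {
    if (!all(c("name", "start", "end") %in% names(md))) {
      msg <- c(msg, "macrodomains needs columns name, start, end")
    } else {
      # macrodomains must tile the circle without overlap
      len <- (md$end - md$start) %% L
      len[len == 0] <- L
      if (abs(sum(len) - L) > 0.5)
        msg <- c(msg, "macrodomains must tile the genome exactly")
      starts <- sort(md$start %% L)
      ends <- sort(md$end %% L)
      if (!isTRUE(all.equal(starts, ends)))
        msg <- c(msg, "macrodomains must be contiguous and non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' One value per bin on a circular genome
#'
#' A `BinnedTrack` holds one numeric value per fixed-width bin around a
#' circular chromosome, together with the [GenomeConfig] it was computed on,
#' a `kind` label recording the processing stage, and a per-bin mask.
#'
#' Mask semantics: `mask = TRUE` marks bins that are imputed or invalid.
#' Imputed bins (e.g. unmappable rRNA bins replaced by flanking averages)
#' carry finite values and are used by value-consuming operations; invalid
#' bins carry `NA` and are skipped. Normalization statistics
#' ([normalizeRelative()], [zscoreTrack()]) are computed over unmasked bins
#' only, so a `relative` track has mean 1 and a `zscore` track mean 0 / sd 1
#' over its unmasked bins.
#'
#' @slot config the [GenomeConfig].
#' @slot values numeric vector, one per bin.
#' @slot kind one of `"count"`, `"relative"`, `"log2_enrichment"`,
#'   `"zscore"`, `"modeled"`, `"correlation"`.
#' @slot mask logical vector, `TRUE` = imputed or invalid.
#' @slot metadata free-form list (e.g. model parameters for modeled tracks).
#'
#' @seealso [binnedTrack()], [binFragments()], [log2Enrichment()]
#' @export
setClass("BinnedTrack",
  representation(
    config = "GenomeConfig",
    values = "numeric",
    kind = "character",
    mask = "logical",
    metadata = "list"
  )
)

setValidity("BinnedTrack", function(object) {
  msg <- character()
  n <- nBins(object@config)
  if (length(object@values) != n)
    msg <- c(msg, sprintf("values must have one entry per bin (%d)", n))
  if (length(object@mask) != length(object@values))
    msg <- c(msg, "mask must match values in length")
  if (length(object@kind) != 1L || !object@kind %in% .TRACK_KINDS)
    msg <- c(msg, paste("kind must be one of:", paste(.TRACK_KINDS, collapse = ", ")))
  if (identical(object@kind, "count")) {
    v <- object@values[!is.na(object@values)]
    if (any(v < 0)) msg <- c(msg, "count tracks must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Strand-oriented window around a transcription unit
#'
#' Per-kb track values over `[-halfWidthKb, +halfWidthKb]` relative to a
#' transcription unit midpoint, flipped so that transcription runs left to
#' right. Minus-strand windows are reversed copies of the genomic values.
#'
#' @slot tuName transcription unit name.
#' @slot strand `"+"` or `"-"`.
#' @slot halfWidthKb half-width in kb.
#' @slot positionsKb signed distances from the TU midpoint, kb.
#' @slot values track values at those positions.
#' @slot mask per-position imputed/invalid flags carried from the track.
#' @export
setClass("OrientedWindow",
  representation(
    tuName = "character",
    strand = "character",
    halfWidthKb = "numeric",
    positionsKb = "numeric",
    values = "numeric",
    mask = "logical"
  )
)

setValidity("OrientedWindow", function(object) {
  n <- length(object@positionsKb)
  if (length(object@values) != n || length(object@mask) != n)
    return("positionsKb, values and mask must have equal length")
  TRUE
})

#' Consensus (metagene) profile over oriented windows
#'
#' Mean per-position signal over a set of equally sized [OrientedWindow]s,
#' after each window has been mean-centered over its full range. The mean of
#' `values` is therefore zero up to averaging of missing positions.
#'
#' @slot positionsKb signed distances from the midpoint, kb.
#' @slot values per-position mean.
#' @slot sem per-position standard error of the mean.
#' @slot nWindows number of windows averaged.
#' @slot nAtPosition number of non-missing windows contributing per position.
#' @export
setClass("ConsensusProfile",
  representation(
    positionsKb = "numeric",
    values = "numeric",
    sem = "numeric",
    nWindows = "integer",
    nAtPosition = "integer"
  )
)

#' One side of a fitted supercoiling twin-domain
#'
#' Result of the expanding-window linear regression on one side of a
#' consensus twin-domain profile. The domain amplitude is the regression
#' y-intercept (log2 fold-change extrapolated to the operon midpoint) and the
#' magnitude is the x-intercept (distance, in kb from the midpoint, at which
#' the fitted line reaches baseline). 95% ranges come from the intercepts of
#' the pointwise 95% confidence band of the fitted mean line.
#'
#' @slot side `"upstream"` or `"downstream"`.
#' @slot slope,intercept fitted line (log2-units per kb, log2-units).
#' @slot windowKb extent of the window chosen by the |r| scan, kb.
#' @slot pearsonR Pearson correlation at the chosen window.
#' @slot amplitude y-intercept (signed; negative for the downstream,
#'   positively supercoiled domain).
#' @slot magnitudeKb x-intercept distance, kb (`NA` when no domain detected).
#' @slot amplitudeRange,magnitudeRange 95% intervals (length-2 numeric).
#' @slot nPoints number of points in the chosen regression.
#' @slot detected `FALSE` when the fitted line does not decay to baseline.
#' @slot rScan data.frame with the |r| value at every candidate window.
#' @export
setClass("DomainFit",
  representation(
    side = "character",
    slope = "numeric",
    intercept = "numeric",
    windowKb = "numeric",
    pearsonR = "numeric",
    amplitude = "numeric",
    magnitudeKb = "numeric",
    amplitudeRange = "numeric",
    magnitudeRange = "numeric",
    nPoints = "integer",
    detected = "logical",
    rScan = "data.frame"
  )
)

#' Generative parameters of the additive twin-domain model
#'
#' The triangle that the model places around every transcription unit:
#' the amplitude scale (log2 fold-change for a unit transcribed at the mean
#' ribosomal-operon rate) and the per-side magnitudes at which the negative
#' (upstream) and positive (downstream) domains decay to baseline.
#'
#' @slot ampPerUnitExpression log2 fold-change at reference expression
#'   (default 0.38).
#' @slot negMagnitudeKb upstream (negative-domain) magnitude, kb (default 23).
#' @slot posMagnitudeKb downstream (positive-domain) magnitude, kb (default 25).
#' @slot referenceExpression expression level, in the transcriptome's units,
#'   to which the amplitude scale is anchored (mean ribosomal-operon rate).
#' @export
setClass("TwinDomainParams",
  representation(
    ampPerUnitExpression = "numeric",
    negMagnitudeKb = "numeric",
    posMagnitudeKb = "numeric",
    referenceExpression = "numeric"
  )
)

setValidity("TwinDomainParams", function(object) {
  msg <- character()
  if (object@ampPerUnitExpression <= 0)
    msg <- c(msg, "ampPerUnitExpression must be > 0")
  if (object@negMagnitudeKb <= 0 || object@posMagnitudeKb <= 0)
    msg <- c(msg, "magnitudes must be > 0")
  if (!is.na(object@referenceExpression) && object@referenceExpression <= 0)
    msg <- c(msg, "referenceExpression must be > 0")
  if (length(msg)) msg else TRUE
})

#' Axis of replichore symmetry
#'
#' An ori-ter axis rotated by `skewDeg` degrees (positive = counterclockwise,
#' i.e. toward decreasing genomic coordinate on the conventional circular map).
#' The axis passes through `axisBp = (oriC - skew * L / 360) mod L` and its
#' antipode.
#'
#' @slot oricBp origin position, bp.
#' @slot skewDeg skew, degrees counterclockwise.
#' @slot axisBp derived axis point near oriC, bp.
#' @export
setClass("AxisSpec",
  representation(oricBp = "numeric", skewDeg = "numeric", axisBp = "numeric")
)

#' Result of a symmetry skew scan
#'
#' @slot skewDeg grid of axis skews tested, degrees.
#' @slot r left/right arm Pearson correlation at each skew.
#' @slot optSkewDeg skew attaining the maximum r (ties broken toward 0).
#' @slot optR correlation at the optimum.
#' @export
setClass("SkewScanResult",
  representation(
    skewDeg = "numeric", r = "numeric",
    optSkewDeg = "numeric", optR = "numeric"
  )
)

#' Specification of a synthetic Psora-seq study
#'
#' Everything needed to generate a ground-truthed synthetic dataset:
#' genome geometry, transcriptome law, twin-domain parameters, replication
#' copy-number gradient, sequencing depth and noise, replicate count, and a
#' mandatory RNG seed.
#'
#' @slot genomeLength genome length, bp.
#' @slot binSize bin width, bp.
#' @slot nTus number of transcription units to place.
#' @slot nRibosomal number of rrn-like units among them.
#' @slot expressionMeanlog,expressionSdlog log-normal expression law.
#' @slot twinParams [TwinDomainParams] used to build the true landscape.
#' @slot oriTerCopyRatio expected ori:ter coverage ratio (>= 1).
#' @slot readsPerSample expected total fragments per sample.
#' @slot binNoiseSd per-bin multiplicative noise on the log2 scale.
#' @slot nReplicates number of pulldown/input replicate pairs.
#' @slot symmetrySkewDeg if finite, generate a mirror-symmetric landscape
#'   about an axis skewed by this many degrees instead of a twin-domain field.
#' @slot rifampicinFactor scale applied to all twin-domain amplitudes
#'   (1 = untreated; 0.12 emulates transcription shutoff).
#' @slot rngSeed integer seed; every stochastic call derives from it.
#' @export
setClass("SyntheticGenomeSpec",
  representation(
    genomeLength = "numeric",
    binSize = "numeric",
    nTus = "integer",
    nRibosomal = "integer",
    expressionMeanlog = "numeric",
    expressionSdlog = "numeric",
    twinParams = "TwinDomainParams",
    oriTerCopyRatio = "numeric",
    readsPerSample = "numeric",
    binNoiseSd = "numeric",
    nReplicates = "integer",
    symmetrySkewDeg = "numeric",
    rifampicinFactor = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SyntheticGenomeSpec", function(object) {
  msg <- character()
  if (object@genomeLength <= 0 || object@binSize <= 0)
    msg <- c(msg, "genomeLength and binSize must be positive")
  if (object@nTus < 1L) msg <- c(msg, "nTus must be >= 1")
  if (object@nRibosomal < 0L || object@nRibosomal > object@nTus)
    msg <- c(msg, "nRibosomal must be in [0, nTus]")
  if (object@oriTerCopyRatio < 1) msg <- c(msg, "oriTerCopyRatio must be >= 1")
  if (object@readsPerSample <= 0) msg <- c(msg, "readsPerSample must be positive")
  if (object@binNoiseSd < 0) msg <- c(msg, "binNoiseSd must be >= 0")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@rifampicinFactor < 0) msg <- c(msg, "rifampicinFactor must be >= 0")
  if (length(object@rngSeed) != 1L || is.na(object@rngSeed))
    msg <- c(msg, "an explicit integer rngSeed is required")
  if (length(msg)) msg else TRUE
})
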