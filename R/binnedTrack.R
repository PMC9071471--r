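#' Construct a binned circular-genome track
#'
#' @param values numeric vector with one entry per bin of `config`.
#' @param config a [GenomeConfig-class].
#' @param kind track kind: `"count"`, `"relative"`, `"log2_enrichment"`,
#'   `"zscore"`, `"modeled"` or `"correlation"`.
#' @param mask logical per-bin flags (`TRUE` = imputed/invalid); recycled
#'   from `FALSE` when omitted. Bins with `NA` values are always flagged.
#' @param metadata optional list of free-form annotations.
#'
#' @return a [BinnedTrack-class].
#' @examples
#' cfg <- genomeConfig(10000, binSize = 1000)
#' binnedTrack(rep(1, 10), cfg, kind = "count")
#' @export
binnedTrack <- function(values, config, kind = "count", mask = NULL,
                        metadata = list()) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  mask <- as.logical(mask) | is.na(values)
  new("BinnedTrack", config = config, values = values, kind = kind,
      mask = mask, metadata = metadata)
}

#' @describeIn binnedTrack per-bin values.
#' @param x a `BinnedTrack`.
#' @export
trackValues <- function(x) x@values

#' @describeIn binnedTrack per-bin imputed/invalid flags.
#' @export
trackMask <- function(x) x@mask

#' @describeIn binnedTrack track kind.
#' @export
trackKind <- function(x) x@kind

#' @describeIn binnedTrack the underlying [GenomeConfig-class].
#' @export
trackConfig <- function(x) x@config

#' @describeIn binnedTrack metadata list.
#' @export
trackMetadata <- function(x) x@metadata

setMethod("show", "BinnedTrack", function(object) {
  v <- object@values[!object@mask & !is.na(object@values)]
  cat(sprintf("BinnedTrack(kind = %s): %d bins of %g bp, %d masked\n",
              object@kind, length(object@values), object@config@binSize,
              sum(object@mask)))
  if (length(v))
    cat(sprintf("  unmasked values: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
                mean(v), stats::sd(v), min(v), max(v)))
  invisible(object)
})

#' @describeIn binnedTrack length of the track (number of bins).
#' @export
setMethod("length", "BinnedTrack", function(x) length(x@values))

#' Rotate a track around the circular genome
#'
#' Moves the feature at bin `b` to bin `b + shiftBins` (modulo the genome),
#' i.e. a positive shift rotates the landscape toward increasing coordinates.
#'
#' @param track a [BinnedTrack-class].
#' @param shiftBins whole-bin offset (may be negative).
#' @return the rotated [BinnedTrack-class].
#' @export
rotateTrack <- function(track, shiftBins) {
  n <- length(track@values)
  idx <- .wrap1(seq_len(n) - as.integer(shiftBins), n)
  binnedTrack(track@values[idx], track@config, kind = track@kind,
              mask = track@mask[idx], metadata = track@metadata)
}

#' Simple base-graphics view of a track
#'
#' @param x a [BinnedTrack-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "BinnedTrack", y = "missing"),
  function(x, y, ...) {
    pos <- .binMidpoints(x@config) / 1e6
    graphics::plot(pos, x@values, type = "l", xlab = "position (Mb)",
                   ylab = x@kind, ...)
    invisible(NULL)
  })
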