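#' Read and write binned tracks
#'
#' Tracks are exchanged in two plain-text formats: 4-column bedGraph
#' (`chrom`, `start`, `end`, `value`) and 2-column TSV (`bin_index`,
#' `value`, 1-based bins). Values are written with 6 decimal places so a
#' write/read round trip is bit-stable at that precision; `NA` marks
#' invalid (masked, zero-coverage) bins.
#'
#' @param track a [BinnedTrack-class].
#' @param path file path.
#' @param config the [GenomeConfig-class] the file is binned on.
#' @param kind track kind to assign on read.
#' @param chrom chromosome name written to bedGraph (default `"genome"`).
#' @return readers return a [BinnedTrack-class]; writers return `path`
#'   invisibly.
#' @name track-io
NULL

.fmtVal <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))

#' @rdname track-io
#' @export
writeTrackBedGraph <- function(track, path, chrom = "genome") {
  n <- length(track@values)
  cfg <- track@config
  starts <- (seq_len(n) - 1) * cfg@binSize
  ends <- pmin(starts + cfg@binSize, cfg@genomeLength)
  df <- data.frame(chrom = chrom, start = format(starts, scientific = FALSE, trim = TRUE),
                   end = format(ends, scientific = FALSE, trim = TRUE),
                   value = .fmtVal(track@values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname track-io
#' @export
readTrackBedGraph <- function(path, config, kind = "log2_enrichment") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          comment.char = "#", na.strings = "NA")
  n <- nBins(config)
  values <- rep(NA_real_, n)
  idx <- .binAt(df$start, config)
  values[idx] <- df$value
  binnedTrack(values, config, kind = kind)
}

#' @rdname track-io
#' @export
writeTrackTSV <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#bin_index\tvalue", con)
  writeLines(paste(seq_along(track@values), .fmtVal(track@values), sep = "\t"), con)
  invisible(path)
}

#' @rdname track-io
#' @export
readTrackTSV <- function(path, config, kind = "count") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin_index", "value"),
                          comment.char = "#", na.strings = "NA")
  n <- nBins(config)
  values <- rep(NA_real_, n)
  values[df$bin_index] <- df$value
  binnedTrack(values, config, kind = kind)
}

#' Read aligned fragment intervals from BED3
#'
#' @param path BED3 file (0-based half-open intervals).
#' @return data.frame with `start`, `end` columns suitable for
#'   [binFragments()].
#' @export
readFragmentsBED <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(start = GenomicRanges::start(gr) - 1, end = GenomicRanges::end(gr))
}
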