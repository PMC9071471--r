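#' Transcription-unit annotation as GRanges
#'
#' Transcription units (operons or single genes) are represented as a
#' [GenomicRanges::GRanges] on a single circular sequence, with metadata
#' columns `name`, `expression` (relative transcription rate, arbitrary
#' units) and `ribosomal` (logical, marks rrn-like units whose mean
#' expression anchors the twin-domain amplitude scale).
#'
#' @param name character vector of unit names.
#' @param start,end 0-based half-open bp coordinates; `end` may exceed the
#'   genome length for units wrapping through the origin.
#' @param strand `"+"` or `"-"` per unit.
#' @param expression non-negative relative expression per unit.
#' @param genomeLength genome length in bp (or a [GenomeConfig-class]).
#' @param ribosomal logical per unit; defaults to names starting with "rrn".
#'
#' @return a `GRanges` with the metadata columns described above.
#' @export
transcriptionUnits <- function(name, start, end, strand, expression,
                               genomeLength,
                               ribosomal = grepl("^rrn", name, ignore.case = TRUE)) {
  if (methods::is(genomeLength, "GenomeConfig"))
    genomeLength <- genomeLength@genomeLength
  if (any(end <= start))
    stop("start must be < end (after circular unwrapping)")
  if (any(expression < 0)) stop("expression must be >= 0")
  si <- GenomeInfoDb::Seqinfo(seqnames = "genome",
                              seqlengths = as.integer(genomeLength),
                              isCircular = TRUE)
  gr <- GenomicRanges::GRanges(
    seqnames = "genome",
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    seqinfo = si
  )
  S4Vectors::mcols(gr)$name <- as.character(name)
  S4Vectors::mcols(gr)$expression <- as.numeric(expression)
  S4Vectors::mcols(gr)$ribosomal <- as.logical(ribosomal)
  names(gr) <- as.character(name)
  gr
}

# 0-based start / half-open end, and circular midpoint in bp
.tuStart0 <- function(tus) GenomicRanges::start(tus) - 1
.tuEnd0 <- function(tus) GenomicRanges::end(tus)
.tuMidpointBp <- function(tus, config) {
  mid <- (.tuStart0(tus) + .tuEnd0(tus)) / 2
  mid %% config@genomeLength
}
.tuStrand <- function(tus) as.character(BiocGenerics::strand(tus))

#' @describeIn transcriptionUnits expression vector accessor.
#' @param tus a transcription-unit `GRanges`.
#' @export
tuExpression <- function(tus) S4Vectors::mcols(tus)$expression

#' @describeIn transcriptionUnits ribosomal flag accessor.
#' @export
tuRibosomal <- function(tus) S4Vectors::mcols(tus)$ribosomal

#' Read / write transcription units as 6-column BED
#'
#' BED columns are (chrom, start, end, name, score, strand) with the
#' relative expression level in the score column. Units named `rrn*` are
#' flagged ribosomal on read.
#'
#' @param path BED file path.
#' @param config a [GenomeConfig-class] (provides the genome length).
#' @return `readTranscriptionUnits` returns a transcription-unit `GRanges`;
#'   the writer returns `path` invisibly.
#' @export
readTranscriptionUnits <- function(path, config) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  transcriptionUnits(name = df$name, start = df$start, end = df$end,
                     strand = df$strand, expression = df$score,
                     genomeLength = config)
}

#' @rdname readTranscriptionUnits
#' @param tus a transcription-unit `GRanges`.
#' @param chrom chromosome name to write.
#' @export
writeTranscriptionUnits <- function(tus, path, chrom = "genome") {
  df <- data.frame(
    chrom = chrom,
    start = format(.tuStart0(tus), scientific = FALSE, trim = TRUE),
    end = format(.tuEnd0(tus), scientific = FALSE, trim = TRUE),
    name = S4Vectors::mcols(tus)$name,
    score = sprintf("%.6f", tuExpression(tus)),
    strand = .tuStrand(tus)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
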