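#' Create a circular genome configuration
#'
#' @param genomeLength total genome length in bp.
#' @param binSize bin width in bp. Default 1000 (1-kb bins).
#' @param oriC,difSite positions of the replication origin and dif site, bp.
#'   Reduced modulo `genomeLength`.
#' @param maskedIntervals data.frame with columns `start`, `end`, `label`
#'   (bp; `start > end` wraps through the origin), or `NULL`.
#' @param macrodomains data.frame with columns `name`, `start`, `end`, or
#'   `NULL`. When provided, the macrodomains must tile the genome without
#'   overlap.
#'
#' @return a [GenomeConfig-class] object.
#' @examples
#' cfg <- genomeConfig(100000, binSize = 1000, oriC = 0, difSite = 50000)
#' nBins(cfg)
#' @export
genomeConfig <- function(genomeLength, binSize = 1000, oriC = 0, difSite = 0,
                         maskedIntervals = NULL, macrodomains = NULL) {
  L <- as.numeric(genomeLength)
  mi <- if (is.null(maskedIntervals)) {
    data.frame(start = numeric(), end = numeric(), label = character())
  } else {
    data.frame(start = as.numeric(maskedIntervals$start) %% L,
               end = as.numeric(maskedIntervals$end) %% L,
               label = as.character(maskedIntervals$label))
  }
  md <- if (is.null(macrodomains)) {
    data.frame(name = character(), start = numeric(), end = numeric())
  } else {
    data.frame(name = as.character(macrodomains$name),
               start = as.numeric(macrodomains$start) %% L,
               end = as.numeric(macrodomains$end) %% L)
  }
  new("GenomeConfig",
      genomeLength = L, binSize = as.numeric(binSize),
      oriC = as.numeric(oriC) %% L, difSite = as.numeric(difSite) %% L,
      maskedIntervals = mi, macrodomains = md)
}

#' @rdname genomeConfig
#' @param x,object a `GenomeConfig`.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @describeIn genomeConfig number of bins (`ceiling(genomeLength / binSize)`;
#'   a final partial bin is included).
#' @export
setMethod("nBins", "GenomeConfig", function(x)
  as.integer(ceiling(x@genomeLength / x@binSize)))

#' @describeIn genomeConfig genome length in bp.
#' @export
genomeLength <- function(x) x@genomeLength

#' @describeIn genomeConfig bin width in bp.
#' @export
binSize <- function(x) x@binSize

#' @describeIn genomeConfig oriC position in bp.
#' @export
oriCPosition <- function(x) x@oriC

#' @describeIn genomeConfig dif position in bp.
#' @export
difPosition <- function(x) x@difSite

#' @describeIn genomeConfig masked intervals data.frame.
#' @export
maskedIntervals <- function(x) x@maskedIntervals

#' @describeIn genomeConfig macrodomain data.frame.
#' @export
macrodomains <- function(x) x@macrodomains

#' @describeIn genomeConfig `TRUE` when the genome length is not an exact
#'   multiple of the bin size (last bin partial).
#' @export
hasPartialBin <- function(x) (x@genomeLength %% x@binSize) != 0

setMethod("show", "GenomeConfig", function(object) {
  cat("GenomeConfig: circular genome of", format(object@genomeLength, big.mark = ","),
      "bp in", nBins(object), "bins of", object@binSize, "bp\n")
  cat("  oriC:", format(object@oriC, big.mark = ","),
      " dif:", format(object@difSite, big.mark = ","), "\n")
  cat("  masked intervals:", nrow(object@maskedIntervals),
      " macrodomains:", nrow(object@macrodomains), "\n")
  invisible(object)
})

#' Read / write a genome configuration as YAML
#'
#' The YAML schema has top-level keys `genome_length_bp`, `bin_size_bp`,
#' `oric_bp`, `dif_bp`, `masked_intervals` (list of `{start, end, label}`)
#' and `macrodomains` (list of `{name, start, end}`).
#'
#' @param path file path.
#' @return `readGenomeConfig` returns a [GenomeConfig-class];
#'   `writeGenomeConfig` returns `path` invisibly.
#' @export
readGenomeConfig <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("genome_length_bp", "bin_size_bp", "oric_bp", "dif_bp")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("genome config is missing required keys: ", paste(miss, collapse = ", "))
  toDf <- function(lst, cols) {
    if (is.null(lst) || !length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(el) as.data.frame(el[cols])))
  }
  genomeConfig(
    genomeLength = y$genome_length_bp,
    binSize = y$bin_size_bp,
    oriC = y$oric_bp,
    difSite = y$dif_bp,
    maskedIntervals = toDf(y$masked_intervals, c("start", "end", "label")),
    macrodomains = toDf(y$macrodomains, c("name", "start", "end"))
  )
}

#' @rdname readGenomeConfig
#' @param config a [GenomeConfig-class].
#' @export
writeGenomeConfig <- function(config, path) {
  rowsOf <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  y <- list(
    genome_length_bp = config@genomeLength,
    bin_size_bp = config@binSize,
    oric_bp = config@oriC,
    dif_bp = config@difSite,
    masked_intervals = rowsOf(config@maskedIntervals),
    macrodomains = rowsOf(config@macrodomains)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Built-in E. coli MG1655 genome configuration
#'
#' Convenience loader for the MG1655 (NC_000913.3) geometry shipped with the
#' package: genome length 4,641,652 bp, 1-kb bins, oriC and dif positions,
#' the seven unmappable rRNA operon intervals (35 one-kb bins in total) as
#' masked intervals, and approximate macrodomain boundaries. The rRNA and
#' macrodomain coordinates are external annotation with approximate
#' boundaries; override them with your own [genomeConfig()] where precision
#' matters.
#'
#' @return a [GenomeConfig-class].
#' @export
mg1655Config <- function() {
  readGenomeConfig(system.file("extdata", "mg1655.yaml", package = "PsoraSeq",
                               mustWork = TRUE))
}
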