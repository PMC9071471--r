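# Shared fixtures built in code.

# small circular genome: 100 bins of 1 kb
smallConfig <- function(nbins = 100, binSize = 1000, ...) {
  genomeConfig(nbins * binSize, binSize = binSize, ...)
}

smallTrack <- function(values, config = smallConfig(length(values)),
                       kind = "log2_enrichment", ...) {
  binnedTrack(values, config, kind = kind, ...)
}

# noiseless triangular twin-domain consensus profile: +amp decaying to 0 at
# negMag kb upstream, -amp decaying to 0 at posMag kb downstream
triangleProfile <- function(amp = 0.38, negMag = 23, posMag = 25, hw = 40) {
  pos <- seq(-hw, hw)
  val <- ifelse(pos < 0, pmax(0, amp * (1 + pos / negMag)),
         ifelse(pos > 0, pmin(0, -amp * (1 - pos / posMag)), 0))
  new("ConsensusProfile", positionsKb = pos, values = val,
      sem = rep(0, length(pos)), nWindows = 1L,
      nAtPosition = rep(1L, length(pos)))
}

profileFromValues <- function(values, hw = (length(values) - 1) / 2) {
  new("ConsensusProfile", positionsKb = seq(-hw, hw), values = values,
      sem = rep(0, length(values)), nWindows = 1L,
      nAtPosition = rep(1L, length(values)))
}

# independent brute-force oracle for the expanding-window rule: Pearson r
# from first principles over every window, global max of |r|
bruteForceBestWindow <- function(profile, side, startKb = 10) {
  pos <- profile@positionsKb
  sel <- if (side == "upstream") pos < 0 else pos > 0
  d <- abs(pos[sel]); y <- profile@values[sel]
  o <- order(d); d <- d[o]; y <- y[o]
  ok <- is.finite(y); d <- d[ok]; y <- y[ok]
  ks <- seq(ceiling(startKb), floor(max(d)))
  rs <- sapply(ks, function(k) {
    dd <- d[d <= k]; yy <- y[d <= k]
    n <- length(dd)
    num <- n * sum(dd * yy) - sum(dd) * sum(yy)
    den <- sqrt(n * sum(dd^2) - sum(dd)^2) * sqrt(n * sum(yy^2) - sum(yy)^2)
    if (den == 0) NA_real_ else num / den
  })
  list(k = ks[which.max(abs(rs))], r = rs[which.max(abs(rs))])
}

# single-TU GRanges helper
oneTU <- function(start, end, strand = "+", expression = 1, config,
                  name = "tu1", ribosomal = FALSE) {
  transcriptionUnits(name = name, start = start, end = end, strand = strand,
                     expression = expression, genomeLength = config,
                     ribosomal = ribosomal)
}
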