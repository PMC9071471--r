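# Internal circular-coordinate helpers. All bin indices are 1-based inside
# the package; text output uses 1-based bins to match genomic convention.

.wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# bin containing a bp position (position reduced modulo genome length)
.binAt <- function(pos, config) {
  L <- config@genomeLength
  n <- nBins(config)
  idx <- floor((pos %% L) / config@binSize) + 1
  as.integer(pmin(idx, n))
}

# midpoints (bp) of all bins; the final partial bin's midpoint stays inside it
.binMidpoints <- function(config) {
  n <- nBins(config)
  starts <- (seq_len(n) - 1) * config@binSize
  ends <- pmin(starts + config@binSize, config@genomeLength)
  (starts + ends) / 2
}

# circular distance between bp positions
.circDist <- function(a, b, L) {
  d <- abs((a %% L) - (b %% L))
  pmin(d, L - d)
}

# does circular interval [start, end) contain position x?  start == end is
# treated as the full circle.
.inCircInterval <- function(x, start, end, L) {
  x <- x %% L; start <- start %% L; end <- end %% L
  if (start == end) rep(TRUE, length(x))
  else if (start < end) x >= start & x < end
  else x >= start | x < end
}

# 1-based indices of bins whose midpoint lies in circular [start, end)
.binsInRegion <- function(config, start, end) {
  which(.inCircInterval(.binMidpoints(config), start, end, config@genomeLength))
}

# 1-based indices of bins overlapping circular [start, end)
.binsOverlapping <- function(config, start, end) {
  L <- config@genomeLength
  n <- nBins(config)
  start <- start %% L; end <- end %% L
  first <- .binAt(start, config)
  lastPos <- (end - 1e-9) %% L
  last <- .binAt(lastPos, config)
  if (start < end || end == 0) {
    if (end == 0) last <- .binAt(L - 1e-9, config)
    seq.int(first, last)
  } else {
    c(seq.int(first, n), seq.int(1L, last))
  }
}

.sameBinning <- function(a, b) {
  isTRUE(all.equal(a@config@genomeLength, b@config@genomeLength)) &&
    isTRUE(all.equal(a@config@binSize, b@config@binSize))
}

# kb window width -> nearest odd number of bins (>= 1)
.oddBins <- function(windowKb, config) {
  w <- round(windowKb * 1000 / config@binSize)
  w <- max(1, w)
  if (w %% 2 == 0) w + 1 else w
}

# population standard deviation
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# standard error of the mean
.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
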