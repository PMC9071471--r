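#' Specify a synthetic Psora-seq study
#'
#' The defaults describe the reference study conditions used throughout the
#' package's tests: a 4,641,652 bp circular genome in 1-kb bins, seven
#' rrn-like ribosomal operons pinned at the reference expression (so the
#' generative twin-domain amplitude equals `ampPerUnitExpression` exactly),
#' six pulldown/input replicate pairs of 1 million fragments each, a 4:1
#' ori:ter replication copy-number gradient, and a small multiplicative
#' per-bin noise of 0.05 on the log2 scale. Expressions follow a log-normal
#' law (meanlog 0, sdlog 2) with ribosomal units pinned at
#' `exp(meanlog + 2 * sdlog)`, about fifty-fold the median unit.
#'
#' @param genomeLength,binSize genome geometry, bp.
#' @param nTus,nRibosomal number of transcription units / rrn-like units.
#' @param expressionMeanlog,expressionSdlog log-normal expression law.
#' @param twinParams [TwinDomainParams-class] of the generative landscape;
#'   a `NA` reference expression is pinned to `exp(meanlog + 2 * sdlog)`.
#' @param oriTerCopyRatio expected ori:ter coverage ratio (>= 1).
#' @param readsPerSample expected fragments per sample.
#' @param binNoiseSd per-bin log2-scale noise sd.
#' @param nReplicates pulldown/input pairs to simulate.
#' @param symmetrySkewDeg when finite, generate a mirror-symmetric smooth
#'   landscape about an axis skewed by this many degrees instead of the
#'   twin-domain field (for symmetry-analysis tests).
#' @param rifampicinFactor scale applied to the generative landscape
#'   (1 = untreated; e.g. 0.12 emulates transcription shutoff).
#' @param rngSeed mandatory integer seed.
#' @return a [SyntheticGenomeSpec-class].
#' @export
syntheticGenomeSpec <- function(rngSeed,
                                genomeLength = 4641652, binSize = 1000,
                                nTus = 7L, nRibosomal = 7L,
                                expressionMeanlog = 0, expressionSdlog = 2,
                                twinParams = twinDomainParams(),
                                oriTerCopyRatio = 4,
                                readsPerSample = 1e6,
                                binNoiseSd = 0.05,
                                nReplicates = 6L,
                                symmetrySkewDeg = NA_real_,
                                rifampicinFactor = 1) {
  if (missing(rngSeed)) stop("an explicit rngSeed is required")
  if (!is.finite(twinParams@referenceExpression)) {
    twinParams@referenceExpression <-
      exp(expressionMeanlog + 2 * expressionSdlog)
  }
  new("SyntheticGenomeSpec",
      genomeLength = genomeLength, binSize = binSize,
      nTus = as.integer(nTus), nRibosomal = as.integer(nRibosomal),
      expressionMeanlog = expressionMeanlog, expressionSdlog = expressionSdlog,
      twinParams = twinParams, oriTerCopyRatio = oriTerCopyRatio,
      readsPerSample = readsPerSample, binNoiseSd = binNoiseSd,
      nReplicates = as.integer(nReplicates),
      symmetrySkewDeg = as.numeric(symmetrySkewDeg),
      rifampicinFactor = rifampicinFactor,
      rngSeed = as.integer(rngSeed))
}

#' @describeIn syntheticGenomeSpec the [GenomeConfig-class] implied by the
#'   spec: oriC at coordinate 0, dif at the antipode, no masked intervals.
#' @param spec a `SyntheticGenomeSpec`.
#' @export
specConfig <- function(spec) {
  genomeConfig(spec@genomeLength, binSize = spec@binSize,
               oriC = 0, difSite = floor(spec@genomeLength / 2))
}

.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Sample a synthetic transcriptome
#'
#' Places `nTus` non-overlapping transcription units on the circle with
#' random strands. Ribosomal units are 5.5 kb (rrn-like); the rest draw
#' lengths from 1 kb plus an exponential tail truncated at 6 kb (gene-dense
#' bacterial genome; at 2,598 units on 4.64 Mb the mean inter-unit gap is
#' under 1 kb). Expressions are log-normal with ribosomal units pinned at
#' the reference expression. Layouts are resampled until ribosomal units are
#' at least 100 kb apart (dispersed, as rrn operons are), so their
#' twin-domains do not overlap in consensus windows.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @param seed RNG seed (defaults to the spec seed).
#' @return a transcription-unit `GRanges` (see [transcriptionUnits()]).
#' @export
sampleTranscriptome <- function(spec, seed = spec@rngSeed) {
  set.seed(seed)
  L <- spec@genomeLength
  n <- spec@nTus
  nRib <- spec@nRibosomal
  layoutOnce <- function() {
    ribosomal <- c(rep(TRUE, nRib), rep(FALSE, n - nRib))[sample.int(n)]
    len <- round(ifelse(ribosomal, 5500,
                        pmin(1000 + stats::rexp(n, 1 / 700), 6000)))
    free <- L - sum(len)
    if (free <= 0) stop("genome too small to place ", n, " transcription units")
    u <- stats::runif(n)
    gaps <- free * u / sum(u)
    # integer lengths + floored starts keep consecutive units non-overlapping
    starts <- floor((round(stats::runif(1, 0, L)) +
                     cumsum(c(0, (len + gaps)[-n]))) %% L)
    list(start = starts, len = len, ribosomal = ribosomal)
  }
  # keep rrn-like twin-domains from overlapping: 100 kb where the genome
  # allows it, otherwise as dispersed as the circle permits
  minRibSpacing <- min(1e5, floor(L / max(1, nRib) / 2))
  for (try in seq_len(500)) {
    lay <- layoutOnce()
    if (nRib < 2) break
    mids <- (lay$start + lay$len / 2)[lay$ribosomal]
    dmin <- min(apply(utils::combn(mids, 2), 2,
                      function(p) .circDist(p[1], p[2], L)))
    if (dmin >= minRibSpacing) break
    if (try == 500)
      warning("could not satisfy ribosomal spacing; using last layout")
  }
  ribosomal <- lay$ribosomal
  expr <- stats::rlnorm(n, spec@expressionMeanlog, spec@expressionSdlog)
  expr[ribosomal] <- spec@twinParams@referenceExpression
  name <- character(n)
  name[ribosomal] <- paste0("rrn", seq_len(sum(ribosomal)))
  name[!ribosomal] <- sprintf("tu%04d", seq_len(sum(!ribosomal)))
  transcriptionUnits(name = name, start = lay$start,
                     end = lay$start + lay$len,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     expression = expr, genomeLength = L,
                     ribosomal = ribosomal)
}

#' Deterministic true supercoiling landscape for a transcriptome
#'
#' Thin wrapper over [composeGenomeModel()]: the ground-truth per-bin log2
#' supercoiling signal implied by the transcription units and twin-domain
#' parameters.
#'
#' @param tus transcription units.
#' @param twinParams [TwinDomainParams-class].
#' @param config [GenomeConfig-class].
#' @return a [BinnedTrack-class] of kind `"modeled"`.
#' @export
trueSupercoilingProfile <- function(tus, twinParams, config) {
  composeGenomeModel(tus, twinParams, config)
}

.copyNumberWeights <- function(spec, config) {
  mids <- .binMidpoints(config)
  d <- .circDist(mids, config@oriC, config@genomeLength) /
    (config@genomeLength / 2)
  spec@oriTerCopyRatio^(-d)
}

#' Simulate an input (copy-number) count track
#'
#' Expected coverage decays exponentially with distance from oriC so that
#' the expected ori:ter coverage ratio equals `oriTerCopyRatio`
#' (exponential-phase replication gradient); per-bin counts are Poisson with
#' total close to `readsPerSample`.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @param config the [GenomeConfig-class] (see [specConfig()]).
#' @param seed RNG seed.
#' @return a [BinnedTrack-class] of kind `"count"`; the Poisson expectation
#'   is stored in `trackMetadata(.)$expectation`.
#' @export
simulateInputCounts <- function(spec, config = specConfig(spec),
                                seed = spec@rngSeed) {
  set.seed(seed)
  w <- .copyNumberWeights(spec, config)
  lambda <- spec@readsPerSample * w / sum(w)
  binnedTrack(stats::rpois(length(lambda), lambda), config, kind = "count",
              metadata = list(expectation = lambda))
}

#' Simulate a pulldown count track given a true landscape
#'
#' Psoralen binds in proportion to helical tension, so pulldown coverage is
#' modeled as the input (copy-number) expectation modulated by
#' `2^(s + eps)`, where `s` is the true per-bin log2 supercoiling signal and
#' `eps` is per-bin Gaussian noise on the log2 scale (`binNoiseSd`); counts
#' are then Poisson. With this construction the enrichment pipeline
#' estimates `s + eps` directly (up to its genome-average normalization).
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @param trueProfile [BinnedTrack-class] with the per-bin log2 signal `s`.
#' @param inputExpectation per-bin input Poisson expectation (from
#'   [simulateInputCounts()] metadata).
#' @param seed RNG seed.
#' @return a [BinnedTrack-class] of kind `"count"`; the drawn `eps` is in
#'   `trackMetadata(.)$epsilon`.
#' @export
simulatePulldownCounts <- function(spec, trueProfile, inputExpectation,
                                   seed = spec@rngSeed) {
  if (length(inputExpectation) != length(trueProfile@values))
    stop("inputExpectation must match the profile binning")
  set.seed(seed)
  eps <- stats::rnorm(length(inputExpectation), 0, spec@binNoiseSd)
  w <- inputExpectation * 2^(trueProfile@values + eps)
  lambda <- spec@readsPerSample * w / sum(w)
  binnedTrack(stats::rpois(length(lambda), lambda), trueProfile@config,
              kind = "count", metadata = list(epsilon = eps))
}

# mirror-symmetric smooth landscape about an axis skewed by skewDeg
.symmetricLandscape <- function(spec, config, skewDeg, sdTarget = 0.3) {
  n <- nBins(config)
  noise <- binnedTrack(stats::rnorm(n), config, kind = "modeled")
  smoothKb <- min(50, max(1, floor(n / 10)) * config@binSize / 1000)
  f <- circularMovingAverage(noise, smoothKb)@values
  f <- circularMovingAverage(binnedTrack(f, config, "modeled"), smoothKb)@values
  a <- .binAt((config@oriC - skewDeg * config@genomeLength / 360) %%
                config@genomeLength, config)
  v <- f
  for (i in seq_len((n - 1) %/% 2))
    v[.wrap1(a + i, n)] <- v[.wrap1(a - i, n)]
  v <- v - mean(v)
  v * sdTarget / .popSd(v)
}

#' Generate a complete ground-truthed synthetic dataset
#'
#' Draws a transcriptome, builds the deterministic true supercoiling
#' landscape (a twin-domain field, or a mirror-symmetric smooth landscape
#' when `symmetrySkewDeg` is set), scales it by `rifampicinFactor`, and
#' simulates `nReplicates` pulldown/input count pairs. Everything is a pure
#' function of the spec and its seed.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @return list with elements `spec`, `config`, `tus`, `groundTruth`
#'   (list: `profile`, `tuAmplitudes`, `twinParams`, `copyNumber`,
#'   `skewDeg`, `rifampicinFactor`) and `replicates` (list of
#'   `list(pulldown, input)` count-track pairs).
#' @export
generateDataset <- function(spec) {
  config <- specConfig(spec)
  tus <- sampleTranscriptome(spec, seed = spec@rngSeed)
  params <- spec@twinParams
  if (is.finite(spec@symmetrySkewDeg)) {
    set.seed(.deriveSeed(spec@rngSeed, 500))
    s <- .symmetricLandscape(spec, config, spec@symmetrySkewDeg) *
      spec@rifampicinFactor
    profile <- binnedTrack(s, config, kind = "modeled",
                           metadata = list(skewDeg = spec@symmetrySkewDeg))
  } else {
    base <- composeGenomeModel(tus, params, config)
    profile <- binnedTrack(base@values * spec@rifampicinFactor, config,
                           kind = "modeled", metadata = base@metadata)
  }
  ref <- params@referenceExpression
  tuAmp <- data.frame(
    name = S4Vectors::mcols(tus)$name,
    trueAmplitude = params@ampPerUnitExpression * tuExpression(tus) / ref *
      spec@rifampicinFactor
  )
  replicates <- lapply(seq_len(spec@nReplicates), function(k) {
    input <- simulateInputCounts(spec, config,
                                 seed = .deriveSeed(spec@rngSeed, 1000 + k))
    pulldown <- simulatePulldownCounts(
      spec, profile, trackMetadata(input)$expectation,
      seed = .deriveSeed(spec@rngSeed, 2000 + k))
    list(pulldown = pulldown, input = input)
  })
  list(spec = spec, config = config, tus = tus,
       groundTruth = list(profile = profile, tuAmplitudes = tuAmp,
                          twinParams = params,
                          copyNumber = .copyNumberWeights(spec, config),
                          skewDeg = spec@symmetrySkewDeg,
                          rifampicinFactor = spec@rifampicinFactor),
       replicates = replicates)
}

#' Standard enrichment pipeline for one pulldown/input pair
#'
#' Mask-and-impute both count tracks, normalize each to its genome average,
#' and take the per-bin log2 pulldown/input ratio.
#'
#' @param pulldown,input count [BinnedTrack-class] pairs on one binning.
#' @param flankKb imputation flank per side, kb.
#' @return a [BinnedTrack-class] of kind `"log2_enrichment"`.
#' @export
psoraEnrichment <- function(pulldown, input, flankKb = 3) {
  log2Enrichment(normalizeRelative(maskAndImpute(pulldown, flankKb)),
                 normalizeRelative(maskAndImpute(input, flankKb)))
}

#' Average replicate tracks bin by bin
#'
#' @param tracks list of [BinnedTrack-class] objects on one binning.
#' @return a [BinnedTrack-class] of the same kind with per-bin means over
#'   finite replicate values.
#' @export
averageTracks <- function(tracks) {
  if (!length(tracks)) stop("no tracks supplied")
  mat <- vapply(tracks, trackValues, numeric(length(tracks[[1]]@values)))
  mat <- matrix(mat, nrow = length(tracks[[1]]@values))
  nAt <- rowSums(is.finite(mat))
  v <- rowMeans(mat, na.rm = TRUE)
  v[nAt == 0] <- NA_real_
  binnedTrack(v, tracks[[1]]@config, kind = tracks[[1]]@kind)
}

#' Re-estimate the ori:ter copy ratio from an input track
#'
#' Fits log2 coverage against normalized circular distance from oriC and
#' returns the implied ori:ter ratio `2^(-slope)`.
#'
#' @param track an input count [BinnedTrack-class].
#' @return estimated ori:ter ratio (numeric scalar).
#' @export
estimateOriTerRatio <- function(track) {
  config <- track@config
  d <- .circDist(.binMidpoints(config), config@oriC, config@genomeLength) /
    (config@genomeLength / 2)
  ok <- is.finite(track@values) & track@values > 0 & !track@mask
  fit <- stats::lm(log2(track@values[ok]) ~ d[ok])
  2^(-unname(stats::coef(fit)[2]))
}
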