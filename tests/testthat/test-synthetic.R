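test_that("transcriptome sampling is seeded, non-overlapping and gene-dense", {
  spec <- syntheticGenomeSpec(rngSeed = 5)
  tus <- sampleTranscriptome(spec)
  expect_length(tus, 7L)
  expect_true(all(tuRibosomal(tus)))
  # pinned rrn expression equals the reference anchor exactly
  expect_true(all(tuExpression(tus) == spec@twinParams@referenceExpression))

  # determinism under the seed
  tus2 <- sampleTranscriptome(spec)
  expect_identical(PsoraSeq:::.tuStart0(tus), PsoraSeq:::.tuStart0(tus2))
  expect_identical(tuExpression(tus), tuExpression(tus2))

  # genome-scale transcriptome: no overlaps, mean inter-TU gap < 1 kb,
  # ribosomal units at least 100 kb apart
  big <- syntheticGenomeSpec(rngSeed = 6, nTus = 2598L, nRibosomal = 7L)
  btus <- sampleTranscriptome(big)
  expect_length(btus, 2598L)
  s0 <- sort(PsoraSeq:::.tuStart0(btus) %% genomeLength(specConfig(big)))
  ends <- PsoraSeq:::.tuEnd0(btus)[order(PsoraSeq:::.tuStart0(btus) %% genomeLength(specConfig(big)))]
  gaps <- c(s0[-1], s0[1] + genomeLength(specConfig(big))) - ends
  expect_true(all(gaps >= 0))          # no overlap around the circle
  expect_lt(mean(gaps), 1000)
  mids <- PsoraSeq:::.tuMidpointBp(btus[tuRibosomal(btus)], specConfig(big))
  dd <- apply(utils::combn(mids, 2), 2,
              function(p) PsoraSeq:::.circDist(p[1], p[2], genomeLength(specConfig(big))))
  expect_gte(min(dd), 1e5)
  expect_error(sampleTranscriptome(syntheticGenomeSpec(rngSeed = 1,
                                                       genomeLength = 1e4,
                                                       nTus = 10L,
                                                       nRibosomal = 0L)),
               "genome too small")
})

test_that("input counts follow the ori-ter copy gradient with Poisson dispersion", {
  specFlat <- syntheticGenomeSpec(rngSeed = 7, oriTerCopyRatio = 1,
                                  readsPerSample = 1e6)
  cfg <- specConfig(specFlat)
  flat <- simulateInputCounts(specFlat, cfg)
  lam <- trackMetadata(flat)$expectation
  expect_lt(diff(range(lam)), 1e-9)        # uniform expectation

  spec4 <- syntheticGenomeSpec(rngSeed = 7, oriTerCopyRatio = 4)
  grad <- simulateInputCounts(spec4, cfg)
  lam4 <- trackMetadata(grad)$expectation
  oriBin <- PsoraSeq:::.binAt(oriCPosition(cfg), cfg)
  terBin <- PsoraSeq:::.binAt(difPosition(cfg), cfg)
  expect_equal(lam4[oriBin] / lam4[terBin], 4, tolerance = 0.01)
  expect_equal(sum(trackValues(grad)), 1e6, tolerance = 0.01)

  # per-bin variance/mean across replicate draws is ~1 (Poisson)
  reps <- sapply(1:30, function(k)
    trackValues(simulateInputCounts(spec4, cfg, seed = 1000 + k))[1:500])
  vmr <- apply(reps, 1, var) / rowMeans(reps)
  expect_equal(mean(vmr), 1, tolerance = 0.1)

  # generative ori:ter ratio is recovered by the exponential re-fit
  expect_equal(estimateOriTerRatio(grad), 4, tolerance = 0.4)
})

test_that("pulldown counts encode the supercoiling signal in the enrichment", {
  spec <- syntheticGenomeSpec(rngSeed = 8, binNoiseSd = 0,
                              readsPerSample = 5e6)
  cfg <- specConfig(spec)
  input <- simulateInputCounts(spec, cfg)
  lam <- trackMetadata(input)$expectation

  # s = 0: pulldown is statistically identical to input; enrichment ~ 0
  zero <- binnedTrack(rep(0, nBins(cfg)), cfg, "modeled")
  pd0 <- simulatePulldownCounts(spec, zero, lam, seed = 9)
  enr0 <- psoraEnrichment(pd0, input)
  expect_lt(abs(mean(trackValues(enr0), na.rm = TRUE)), 0.02)
  expect_lt(sd(trackValues(enr0), na.rm = TRUE), 0.15)

  # a +1 block is recovered at high depth
  s <- rep(0, nBins(cfg)); s[100:200] <- 1
  pd1 <- simulatePulldownCounts(spec, binnedTrack(s, cfg, "modeled"), lam,
                                seed = 10)
  enr1 <- psoraEnrichment(pd1, input)
  inBlock <- mean(trackValues(enr1)[100:200], na.rm = TRUE)
  outBlock <- mean(trackValues(enr1)[-(100:200)], na.rm = TRUE)
  expect_equal(inBlock - outBlock, 1, tolerance = 0.05)

  # doubling the depth roughly halves the per-bin enrichment sampling variance
  varAt <- function(reads, seedOff) {
    sp <- syntheticGenomeSpec(rngSeed = 8, binNoiseSd = 0, readsPerSample = reads)
    ip <- simulateInputCounts(sp, cfg, seed = 20 + seedOff)
    pd <- simulatePulldownCounts(sp, zero, trackMetadata(ip)$expectation,
                                 seed = 30 + seedOff)
    var(trackValues(psoraEnrichment(pd, ip)), na.rm = TRUE)
  }
  v1 <- mean(sapply(1:3, function(k) varAt(1e6, k)))
  v2 <- mean(sapply(1:3, function(k) varAt(2e6, 10 + k)))
  expect_equal(v1 / v2, 2, tolerance = 0.35)
})

test_that("generated datasets are deterministic and honor the rifampicin factor", {
  spec <- syntheticGenomeSpec(rngSeed = 9, nReplicates = 2L,
                              genomeLength = 5e5, nTus = 3L, nRibosomal = 3L)
  d1 <- generateDataset(spec)
  d2 <- generateDataset(spec)
  expect_identical(trackValues(d1$groundTruth$profile),
                   trackValues(d2$groundTruth$profile))
  expect_identical(trackValues(d1$replicates[[1]]$pulldown),
                   trackValues(d2$replicates[[1]]$pulldown))
  expect_identical(trackValues(d1$replicates[[2]]$input),
                   trackValues(d2$replicates[[2]]$input))
  # replicates differ from each other
  expect_false(identical(trackValues(d1$replicates[[1]]$input),
                         trackValues(d1$replicates[[2]]$input)))

  # written files are byte-identical across reruns
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeTrackTSV(d1$replicates[[1]]$pulldown, f1)
  writeTrackTSV(d2$replicates[[1]]$pulldown, f2)
  expect_identical(readLines(f1), readLines(f2))

  # transcription shutoff: zero factor gives a flat ground truth
  rif <- syntheticGenomeSpec(rngSeed = 9, nReplicates = 1L, genomeLength = 5e5,
                             nTus = 3L, nRibosomal = 3L, rifampicinFactor = 0)
  expect_equal(trackValues(generateDataset(rif)$groundTruth$profile),
               rep(0, 500))

  # symmetric-landscape variant is mirror-symmetric about the requested axis
  symSpec <- syntheticGenomeSpec(rngSeed = 10, nReplicates = 1L,
                                 genomeLength = 7.2e5, symmetrySkewDeg = 14)
  sym <- generateDataset(symSpec)
  expect_equal(sym$groundTruth$skewDeg, 14)
  tr <- sym$groundTruth$profile
  expect_equal(symmetryCorrelation(tr, axisSpec(sym$config, 14), smoothingKb = 0),
               1, tolerance = 1e-9)
})

test_that("the enrichment pipeline converges to the ground truth with depth", {
  rs <- sapply(c(3e5, 3e6), function(depth) {
    spec <- syntheticGenomeSpec(rngSeed = 11, nTus = 200L, nRibosomal = 5L,
                                genomeLength = 1e6, nReplicates = 1L,
                                readsPerSample = depth, binNoiseSd = 0)
    ds <- generateDataset(spec)
    enr <- psoraEnrichment(ds$replicates[[1]]$pulldown, ds$replicates[[1]]$input)
    cor(trackValues(enr), trackValues(ds$groundTruth$profile),
        use = "complete.obs")
  })
  expect_gt(rs[2], rs[1])
  expect_gt(rs[2], 0.9)
})
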