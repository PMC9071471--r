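# build a track that is exactly mirror-symmetric about an axis skewed by
# skewDeg (uses the generator internals so the test controls the truth)
mirrorTrack <- function(cfg, skewDeg, sd = 0.3, seed = 1) {
  set.seed(seed)
  v <- PsoraSeq:::.symmetricLandscape(
    syntheticGenomeSpec(rngSeed = seed, genomeLength = genomeLength(cfg),
                        binSize = binSize(cfg)),
    cfg, skewDeg, sdTarget = sd)
  binnedTrack(v, cfg, "log2_enrichment")
}

test_that("arm series read outward from the axis and respect rotation", {
  cfg <- smallConfig(100, oriC = 0)
  const <- smallTrack(rep(2, 100), cfg)
  arms <- armSeries(const, axisSpec(cfg, 0), smoothingKb = 0)
  expect_equal(arms$left, arms$right)
  expect_equal(length(arms$left), 50)

  # a track symmetric about oriC has identical arms at skew 0
  sym <- mirrorTrack(cfg, 0, seed = 3)
  a0 <- armSeries(sym, axisSpec(cfg, 0), smoothingKb = 0)
  expect_equal(a0$left, a0$right, tolerance = 1e-12)

  # arms at skew s equal arms of the counter-rotated track at skew 0
  set.seed(6)
  tr <- smallTrack(rnorm(100), cfg)
  skewDeg <- 36   # = 10 bins on a 100-bin circle
  armsSkew <- armSeries(tr, axisSpec(cfg, skewDeg), smoothingKb = 0)
  rot <- rotateTrack(tr, +10)   # positive skew points at decreasing coords
  armsRot <- armSeries(rot, axisSpec(cfg, 0), smoothingKb = 0)
  expect_equal(armsSkew$left, armsRot$left)
  expect_equal(armsSkew$right, armsRot$right)

  # smoothing half-window is trimmed from the arm length
  expect_equal(length(armSeries(tr, axisSpec(cfg, 0), smoothingKb = 9)$left),
               50 - 4)
})

test_that("symmetry correlation is 1 for mirror tracks and -1 for antisymmetric", {
  cfg <- smallConfig(200, oriC = 0)
  sym <- mirrorTrack(cfg, 0, seed = 9)
  expect_equal(symmetryCorrelation(sym, axisSpec(cfg, 0), smoothingKb = 0), 1,
               tolerance = 1e-12)

  # antisymmetric: right arm = -left arm (the shared antipode bin must be 0)
  v <- trackValues(sym)
  a <- PsoraSeq:::.binAt(0, cfg)
  v[PsoraSeq:::.wrap1(a + 100, 200)] <- 0
  for (i in 1:99) v[PsoraSeq:::.wrap1(a + i, 200)] <- -v[PsoraSeq:::.wrap1(a - i, 200)]
  anti <- binnedTrack(v, cfg, "log2_enrichment")
  expect_equal(symmetryCorrelation(anti, axisSpec(cfg, 0), smoothingKb = 0), -1,
               tolerance = 1e-12)

  # white noise: no symmetry at genome scale
  cfgBig <- smallConfig(4642, oriC = 0)
  set.seed(10)
  noise <- binnedTrack(rnorm(4642), cfgBig, "log2_enrichment")
  expect_lt(abs(symmetryCorrelation(noise, axisSpec(cfgBig, 0), smoothingKb = 0)),
            0.1)
  expect_error(symmetryCorrelation(smallTrack(rep(1, 100)), axisSpec(smallConfig(100), 0), 0),
               "degenerate")
})

test_that("the skew scan recovers the generative axis and is rotation-equivariant", {
  cfg <- smallConfig(720, oriC = 0)   # 1 bin = 0.5 degrees
  sym <- mirrorTrack(cfg, 14, seed = 11)
  scan <- skewScan(sym, c(-90, 90), stepDeg = 1, smoothingKb = 0)
  expect_equal(scan@optSkewDeg, 14, tolerance = 1)
  expect_gt(scan@optR, 0.99)

  sym0 <- mirrorTrack(cfg, 0, seed = 12)
  expect_equal(skewScan(sym0, c(-90, 90), 1, 0)@optSkewDeg, 0, tolerance = 1)

  # rotating the track counterclockwise by d degrees shifts the optimum by +d
  d <- 10
  rot <- rotateTrack(sym0, -as.integer(d / 360 * 720))
  expect_equal(skewScan(rot, c(-90, 90), 1, 0)@optSkewDeg, d, tolerance = 1)

  # ties break toward the smallest |skew|
  const <- skewScan(mirrorTrack(cfg, 0, seed = 13), c(-5, 5), 1, 0)
  expect_equal(const@optSkewDeg, 0, tolerance = 1)
  expect_error(skewScan(sym0, c(10, 0), 1, 0), "empty skew grid")
})

test_that("region means and paired tests behave like the t distribution", {
  cfg <- smallConfig(100)
  regions <- data.frame(name = c("A", "B"), start = c(0, 50000),
                        end = c(50000, 100000), class = "hemi_genome")
  # identical per-replicate means: difference 0, p = 1
  set.seed(17)
  reps <- lapply(1:6, function(i) {
    half <- rnorm(50)
    smallTrack(c(half, half), cfg)   # both regions identical within replicate
  })
  out <- regionMeansAndTests(reps, regions)
  expect_equal(out$comparisons$difference, 0, tolerance = 1e-12)
  expect_equal(out$comparisons$tP, 1)
  expect_equal(out$means$mean[1], out$means$mean[2])

  # a constant shift much larger than the sem is significant with df = n-1
  reps2 <- lapply(1:6, function(i) {
    x <- rnorm(50, 0, 0.05)
    smallTrack(c(x, x + 1), cfg)
  })
  out2 <- regionMeansAndTests(reps2, regions)
  expect_equal(out2$comparisons$df, 5)
  expect_lt(out2$comparisons$tP, 0.05)
  expect_equal(out2$comparisons$difference, -1, tolerance = 0.1)
  expect_true(out2$comparisons$stars != "NS")

  # left vs right arms of a mirror-symmetric landscape: no significant difference
  cfgS <- smallConfig(200, oriC = 0, difSite = 100000)
  repsSym <- lapply(1:6, function(i) {
    tr <- mirrorTrack(cfgS, 0, seed = 100 + i)
    binnedTrack(trackValues(tr) + rnorm(200, 0, 0.05), cfgS, "log2_enrichment")
  })
  hemi <- hemiGenomeRegions(cfgS)
  outS <- regionMeansAndTests(repsSym, hemi)
  lr <- subset(outS$comparisons, regionA == "Right-arm" & regionB == "Left-arm")
  expect_gt(lr$tP, 0.05)

  # a partition's length-weighted grand mean equals the genome mean
  m <- out2$means
  lens <- c(50, 50)
  expect_equal(sum(m$mean * lens) / sum(lens),
               mean(sapply(reps2, function(t) mean(trackValues(t)))),
               tolerance = 1e-9)
  expect_error(regionMeansAndTests(reps2[1], regions), "at least 2")
})

test_that("supercoiled region classification recovers constructed blocks", {
  cfg <- smallConfig(100)
  v <- rep(0, 100)
  v[11:40] <- 1     # enriched block
  v[61:80] <- -1.5  # depleted block
  tr <- smallTrack(v, cfg)
  regions <- classifySupercoiledRegions(tr, smoothingKb = 0, thresholdSd = 0.5,
                                        minLengthKb = 5)
  expect_equal(nrow(regions), 2L)
  enr <- regions[regions$state == "enriched", ]
  expect_equal(enr$start, 10000)
  expect_equal(enr$end, 40000)
  dep <- regions[regions$state == "depleted", ]
  expect_equal(c(dep$start, dep$end), c(60000, 80000))

  # near-flat track with no excursions beyond threshold -> no regions
  set.seed(20)
  flat <- smallTrack(rnorm(100, 0, 1), cfg)
  none <- classifySupercoiledRegions(flat, smoothingKb = 0, thresholdSd = 5,
                                     minLengthKb = 1)
  expect_equal(nrow(none), 0L)

  # threshold 0: enriched and depleted regions tile the genome
  part <- classifySupercoiledRegions(flat, smoothingKb = 0, thresholdSd = 0,
                                     minLengthKb = 0)
  lens <- (part$end - part$start) %% 1e5
  lens[lens == 0] <- 1e5
  expect_equal(sum(lens), 1e5)

  # classes are disjoint: no bin is both enriched and depleted
  binsOf <- function(df) unlist(lapply(seq_len(nrow(df)), function(i)
    PsoraSeq:::.binsInRegion(cfg, df$start[i], df$end[i])))
  expect_length(intersect(binsOf(part[part$state == "enriched", , drop = FALSE]),
                          binsOf(part[part$state == "depleted", , drop = FALSE])),
                0)

  # a run crossing the origin is reported as one wrapped region
  vw <- rep(0, 100); vw[c(95:100, 1:8)] <- 2
  wrap <- classifySupercoiledRegions(smallTrack(vw, cfg), 0, 0.5, 5)
  expect_equal(nrow(wrap), 1L)
  expect_gt(wrap$start, wrap$end)
})

test_that("track association separates enriched and depleted classes", {
  cfg <- smallConfig(100)
  v <- rep(0, 100); v[11:40] <- 1; v[61:80] <- -1.5
  psora <- smallTrack(v, cfg)
  regions <- classifySupercoiledRegions(psora, 0, 0.5, 2)
  # split each block so each class has several regions for the t test
  regions <- data.frame(
    name = paste0("r", 1:6),
    start = c(10000, 20000, 30000, 60000, 67000, 74000),
    end = c(20000, 30000, 40000, 67000, 74000, 80000),
    class = "signal_defined",
    state = rep(c("enriched", "depleted"), each = 3))

  z <- zscoreTrack(psora)
  assoc <- trackAssociation(z, regions)
  enr <- assoc$classStats[assoc$classStats$state == "enriched", ]
  dep <- assoc$classStats[assoc$classStats$state == "depleted", ]
  expect_gt(enr$mean, 0)
  expect_lt(dep$mean, 0)
  expect_equal(enr$df, 2)

  # sign antisymmetry under track negation
  zNeg <- binnedTrack(-trackValues(z), cfg, "zscore")
  assocNeg <- trackAssociation(zNeg, regions)
  expect_equal(assocNeg$classStats$mean, -assoc$classStats$mean)

  # an independent track shows no association
  set.seed(25)
  indep <- zscoreTrack(smallTrack(rnorm(100), cfg))
  assocI <- trackAssociation(indep, regions)
  expect_true(all(assocI$classStats$p > 0.05))

  two <- trackAssociation(z, regions, test = "two_sample")
  expect_equal(nrow(two$classStats), 1L)
  expect_error(trackAssociation(z, regions[0, ]), "no regions")
})
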