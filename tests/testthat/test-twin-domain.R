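test_that("oriented windows follow strand, wrap the origin and mirror on inversion", {
  cfg <- smallConfig(100)
  set.seed(5)
  v <- rnorm(100)
  tr <- smallTrack(v, cfg)

  plus <- oneTU(49500, 50500, "+", config = cfg)   # midpoint bin 51
  w <- extractOrientedWindow(tr, plus, halfWidthKb = 10)
  expect_equal(w@values, v[41:61])
  expect_equal(w@positionsKb, -10:10)

  minus <- oneTU(49500, 50500, "-", config = cfg)
  wm <- extractOrientedWindow(tr, minus, halfWidthKb = 10)
  expect_equal(wm@values, rev(w@values))

  # orientation equivariance: flipping the strand and mirroring the genome
  # about the TU midpoint gives the identical window
  mirrored <- v[PsoraSeq:::.wrap1(2 * 51 - seq_len(100), 100)]
  wMir <- extractOrientedWindow(smallTrack(mirrored, cfg), plus, 10)
  expect_equal(wMir@values, wm@values)

  # window across the origin
  nearOri <- oneTU(500, 1500, "+", config = cfg)    # midpoint bin 2
  wo <- extractOrientedWindow(tr, nearOri, halfWidthKb = 10)
  expect_equal(wo@values, v[PsoraSeq:::.wrap1(2 + (-10:10), 100)])
})

test_that("consensus profiles center windows and average with cancellation", {
  cfg <- smallConfig(100)
  tr <- smallTrack(seq(0.01, 1, by = 0.01), cfg)
  tu <- oneTU(49500, 50500, "+", config = cfg)
  w <- extractOrientedWindow(tr, tu, 10)
  single <- consensusProfile(list(w))
  expect_equal(single@values, w@values - mean(w@values), tolerance = 1e-12)
  expect_equal(mean(single@values), 0, tolerance = 1e-9)

  w2 <- w; w2@values <- -w@values
  both <- consensusProfile(list(w, w2))
  expect_equal(both@values, rep(0, 21), tolerance = 1e-12)
  expect_error(consensusProfile(list()), "no windows")

  # 42 noisy copies of a triangle: consensus within 3 sem of the truth
  set.seed(8)
  tri <- triangleProfile(amp = 0.38, hw = 40)
  wins <- lapply(1:42, function(i)
    new("OrientedWindow", tuName = "t", strand = "+", halfWidthKb = 40,
        positionsKb = tri@positionsKb,
        values = tri@values + rnorm(81, 0, 0.2), mask = rep(FALSE, 81)))
  cons <- consensusProfile(wins)
  centered <- tri@values - mean(tri@values)
  expect_true(all(abs(cons@values - centered) < 3 * cons@sem))
  expect_equal(cons@nWindows, 42L)
})

test_that("domain regression recovers a noiseless triangle exactly", {
  prof <- triangleProfile(amp = 0.38, negMag = 23, posMag = 25)
  up <- fitDomainRegression(prof, "upstream")
  dn <- fitDomainRegression(prof, "downstream")
  expect_true(up@detected && dn@detected)
  expect_equal(up@amplitude, 0.38, tolerance = 1e-6)
  expect_equal(up@magnitudeKb, 23, tolerance = 1e-6)
  expect_equal(dn@amplitude, -0.38, tolerance = 1e-6)
  expect_equal(dn@magnitudeKb, 25, tolerance = 1e-6)
  # degenerate confidence band collapses onto the point estimates
  expect_equal(up@amplitudeRange, c(0.38, 0.38), tolerance = 1e-6)
  expect_equal(up@magnitudeRange, c(23, 23), tolerance = 1e-4)

  flat <- profileFromValues(rep(0, 81))
  expect_false(fitDomainRegression(flat, "upstream")@detected)
  expect_true(is.na(fitDomainRegression(flat, "upstream")@magnitudeKb))

  # a rising (wrong-sign) profile is not a decaying domain
  rising <- profileFromValues(seq(-0.4, 0.4, length.out = 81))
  expect_false(fitDomainRegression(rising, "upstream")@detected)
  expect_error(fitDomainRegression(triangleProfile(hw = 8), "upstream"),
               "extends less than")
})

test_that("the expanding-window rule equals a brute-force max-|r| scan", {
  set.seed(21)
  for (i in 1:50) {
    amp <- runif(1, 0.1, 0.6)
    mag <- runif(1, 12, 35)
    tri <- triangleProfile(amp = amp, negMag = mag, posMag = mag)
    noisy <- profileFromValues(tri@values + rnorm(81, 0, runif(1, 0.01, 0.15)))
    for (side in c("upstream", "downstream")) {
      fit <- fitDomainRegression(noisy, side)
      oracle <- bruteForceBestWindow(noisy, side)
      expect_equal(fit@windowKb, oracle$k)
      expect_equal(fit@pearsonR, oracle$r, tolerance = 1e-12)
    }
  }
})

test_that("greedy stopping stops at the first local maximum of |r|", {
  # construct a profile with an early local max of |r| and a later global max
  set.seed(4)
  tri <- triangleProfile(amp = 0.4, negMag = 30, posMag = 30)
  noisy <- profileFromValues(tri@values + rnorm(81, 0, 0.05))
  greedy <- fitDomainRegression(noisy, "upstream", rule = "greedy")
  scan <- fitDomainRegression(noisy, "upstream", rule = "scan")
  expect_lte(greedy@windowKb, scan@windowKb)
  expect_lte(abs(greedy@pearsonR), abs(scan@pearsonR) + 1e-12)
})

test_that("per-TU amplitudes are signed by orientation and flip under inversion", {
  cfg <- smallConfig(100)
  # canonical twin-domain around a TU at bins 49-52 (48000..51000):
  # +0.3 upstream of the 5' end, -0.3 downstream of the 3' end
  v <- rep(0, 100)
  tu <- oneTU(48000, 51000, "+", config = cfg)
  v[PsoraSeq:::.binAt(48000 - 5000, cfg)] <- 0.3
  v[PsoraSeq:::.binAt(51000 + 5000, cfg)] <- -0.3
  amp <- perTuAmplitude(smallTrack(v, cfg), tu, offsetKb = 5)
  expect_equal(amp$amplitude, 0.6)

  # flat track -> zero amplitude
  expect_equal(perTuAmplitude(smallTrack(rep(0, 100), cfg), tu)$amplitude, 0)

  # inverting the TU flips the sign on the same landscape
  inv <- oneTU(48000, 51000, "-", config = cfg)
  expect_equal(perTuAmplitude(smallTrack(v, cfg), inv, 5)$amplitude, -0.6)

  # masked flank -> NA amplitude
  v2 <- v; v2[PsoraSeq:::.binAt(43000, cfg)] <- NA
  expect_true(is.na(perTuAmplitude(smallTrack(v2, cfg), tu, 5)$amplitude))
})

test_that("amplitude-expression correlations rank top-expression subsets", {
  set.seed(31)
  n <- 2598
  expression <- rlnorm(n, 0, 2)
  # amplitudes exactly proportional to expression: r = 1 for all subsets
  tab <- amplitudeExpressionCorrelation(0.01 * expression, expression)
  expect_equal(tab$r, rep(1, 3), tolerance = 1e-9)

  # permuted amplitudes: no correlation at this n
  perm <- amplitudeExpressionCorrelation(0.01 * sample(expression), expression,
                                         topFractions = numeric())
  expect_lt(abs(perm$r[perm$subset == "all"]), 0.05)

  # only the top decile's twin-domains exceed noise: top subset correlates
  # better than the bulk
  amp <- ifelse(rank(-expression) <= n / 10, 0.3 * scale(expression), 0) +
    rnorm(n, 0, 0.1)
  tab2 <- amplitudeExpressionCorrelation(amp, expression)
  expect_gt(tab2$r[tab2$subset == "top10%"], tab2$r[tab2$subset == "all"])
  expect_warning(
    amplitudeExpressionCorrelation(rnorm(50), rlnorm(50), topFractions = 0.01),
    "fewer than 3")
})

test_that("amplitude change percent is the relative reduction", {
  mk <- function(amp) new("DomainFit", side = "upstream", slope = -amp / 23,
                          intercept = amp, windowKb = 23, pearsonR = -1,
                          amplitude = amp, magnitudeKb = 23,
                          amplitudeRange = c(amp, amp),
                          magnitudeRange = c(23, 23), nPoints = 23L,
                          detected = TRUE, rScan = data.frame())
  expect_equal(amplitudeChangePercent(mk(0.05), mk(0.38)), 86.8, tolerance = 0.1)
  expect_equal(amplitudeChangePercent(mk(0.38), mk(0.38)), 0)
  # an increase gives a negative reduction
  expect_lt(amplitudeChangePercent(mk(0.47), mk(0.38)), 0)
  expect_error(amplitudeChangePercent(mk(0.1), mk(0)), "zero")
  bad <- mk(0.1); bad@side <- "downstream"
  expect_error(amplitudeChangePercent(bad, mk(0.2)), "different domain sides")
})
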