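test_that("FSC of identical and negated volumes is +1 / -1", {
  set.seed(7)
  v <- volumeGrid3D(array(rnorm(32^3), c(32, 32, 32)), 1.34)
  neg <- volumeGrid3D(-voxels(v), 1.34)
  up <- fscCurve(v, v)
  dn <- fscCurve(v, neg)
  expect_true(all(abs(fscValues(up) - 1) < 1e-12))
  expect_true(all(abs(fscValues(dn) + 1) < 1e-12))
})

test_that("FSC of independent noise volumes is bounded by sampling error", {
  # |FSC| <= 4/sqrt(n_k) on well-populated shells, checked over seeds
  worst <- 0
  for (seed in 1:8) {
    set.seed(seed + 100)
    a <- volumeGrid3D(array(rnorm(32^3), c(32, 32, 32)), 1)
    b <- volumeGrid3D(array(rnorm(32^3), c(32, 32, 32)), 1)
    fc <- fscCurve(a, b)
    nk <- fc@shells@nVoxels
    big <- nk > 100
    worst <- max(worst, max(abs(fscValues(fc)[big]) * sqrt(nk[big])))
  }
  expect_lt(worst, 4)
})

test_that("SNR follows FSC/(1-FSC) with clamping at zero", {
  expect_identical(snrFromFsc(0.5), 1)
  expect_identical(snrFromFsc(0), 0)
  expect_identical(snrFromFsc(-0.3), 0)
  expect_equal(snrFromFsc(0.143), 0.143 / 0.857, tolerance = 1e-12)
  expect_error(snrFromFsc(1), "infinite")
})

test_that("threshold crossing is interpolated and clamped as documented", {
  exact <- makeFscAt(c(0.01, 0.02, 0.03, 0.04), c(1, 1, 0.143, 0.1))
  hit <- thresholdFrequency(exact, 0.143)
  expect_equal(hit$frequency, 0.03)
  expect_false(hit$flagged)
  flat <- makeFscCurve(0.9, boxSize = 32, pixelSize = 1)
  top <- thresholdFrequency(flat, 0.143)
  expect_equal(top$frequency, 0.5)   # Nyquist at 1 A/px
  expect_true(top$flagged)
  short <- makeFscAt(c(0.1, 0.2), c(0.8, 0.4))
  clamped <- thresholdFrequency(short, 0.143)
  expect_equal(clamped$frequency, 0.2)   # extrapolation clamps to last shell
  expect_true(clamped$flagged)
  low <- makeFscAt(c(0.1, 0.2), c(0.1, 0.05))
  first <- thresholdFrequency(low, 0.143)
  expect_equal(first$frequency, 0.1)
  expect_true(first$flagged)
})

test_that("amplitude ratio is the square root of the SNR ratio", {
  same <- makeFscCurve(0.6)
  ar <- amplitudeRatio(same, same)
  expect_true(all(abs(ratioValues(ar)[validShells(ar)] - 1) < 1e-12))
  f5 <- makeFscCurve(0.5); a8 <- makeFscCurve(0.8)
  ar2 <- amplitudeRatio(f5, a8)
  expect_true(all(abs(ratioValues(ar2)[validShells(ar2)] - 0.5) < 1e-12))
  zero <- makeFscCurve(0)
  ar3 <- amplitudeRatio(zero, a8)
  expect_true(all(ratioValues(ar3) == 0))
  expect_false(any(validShells(ar3)))
})

test_that("relative Guinier fit recovers exact exponential data", {
  sh <- frequencyShells(64, 1.34)
  nu <- shellFrequencies(sh)
  ratio <- new("AmplitudeRatioCurve", shells = sh,
               ratio = exp(0.2 - 25 * nu^2), valid = rep(TRUE, length(nu)))
  fsc <- makeFscCurve(0.9, 64, 1.34)
  cfg <- polishConfig(pixelSize = 1.34, maxShift = 8)
  m <- fitRelativeGuinier(ratio, fsc, cfg)
  expect_equal(bFactor(m), -100, tolerance = 1e-10)
  expect_equal(cIntercept(m), 0.2, tolerance = 1e-12)
  flat <- new("AmplitudeRatioCurve", shells = sh,
              ratio = rep(1, length(nu)), valid = rep(TRUE, length(nu)))
  m0 <- fitRelativeGuinier(flat, fsc, cfg)
  expect_equal(bFactor(m0), 0, tolerance = 1e-12)
  expect_equal(cIntercept(m0), 0, tolerance = 1e-12)
})

test_that("noisy Guinier fits match a closed-form OLS oracle", {
  sh <- frequencyShells(64, 1.34)
  nu <- shellFrequencies(sh)
  cfg <- polishConfig(pixelSize = 1.34, maxShift = 8)
  fsc <- makeFscCurve(0.9, 64, 1.34)
  set.seed(77)
  for (rep in 1:5) {
    logr <- 0.1 - 20 * nu^2 + rnorm(length(nu), sd = 0.05)
    ratio <- new("AmplitudeRatioCurve", shells = sh, ratio = exp(logr),
                 valid = rep(TRUE, length(nu)))
    m <- fitRelativeGuinier(ratio, fsc, cfg)
    keep <- sh@shell >= 1 & nu >= cfg@fscFitMinFreq
    fit <- stats::lm(logr[keep] ~ I(nu[keep]^2))
    expect_equal(bFactor(m), unname(4 * coef(fit)[2]), tolerance = 1e-8)
    expect_equal(cIntercept(m), unname(coef(fit)[1]), tolerance = 1e-8)
  }
})

test_that("frame weights are normalised, stable and dominance-ordered", {
  # identical models -> uniform 1/F weights
  wtU <- makeWeightTable(rep(-50, 4), rep(0.3, 4))
  expect_true(all(abs(weightMatrix(wtU) - 0.25) < 1e-12))
  # arbitrary models: every shell column sums to 1
  set.seed(8)
  B <- runif(6, -200, 0); C <- runif(6, -0.3, 0.3)
  wt <- makeWeightTable(B, C)
  expect_true(all(abs(colSums(weightMatrix(wt)) - 1) < 1e-10))
  # at nu = 0 weights are proportional to exp(C) regardless of B
  expect_equal(weightMatrix(wt)[, 1], exp(C) / sum(exp(C)),
               tolerance = 1e-12)
  # two-frame hand example at nu = 0.1
  sh2 <- new("FrequencyShells", shell = 0:1, nu = c(0, 0.1),
             nVoxels = c(1L, 1L))
  w2 <- frameWeights(list(makeDamageModel(1, 0, 0),
                          makeDamageModel(2, -100, 0)), sh2)
  expect_equal(weightMatrix(w2)[2, 2], exp(-0.25) / (1 + exp(-0.25)),
               tolerance = 1e-12)
  # shift invariance in C and in B
  wtC <- makeWeightTable(B, C + 1.7)
  wtB <- makeWeightTable(B - 80, C)
  expect_equal(weightMatrix(wtC), weightMatrix(wt), tolerance = 1e-12)
  expect_equal(weightMatrix(wtB), weightMatrix(wt), tolerance = 1e-12)
  # monotone dominance: larger B with equal C gains weight with frequency
  wtD <- makeWeightTable(c(-20, -120), c(0.1, 0.1))
  ratio <- weightMatrix(wtD)[1, ] / weightMatrix(wtD)[2, ]
  expect_true(all(diff(ratio) > 0))
})

test_that("unfittable frames inherit parameters from the nearest frame", {
  cfg <- polishConfig(pixelSize = 1.34, maxShift = 8)
  sc <- simulationConfig(nFrames = 3, boxSize = 32,
                         bSchedule = c(-30, -10, -60),
                         cSchedule = c(0, 0, 0), noiseSd = 0.1, seed = 3)
  hs <- simulateHalfmapSeries(sc)
  # degenerate frame 3: zero-power halves give flagged FSC 0 on every
  # shell, so no shell enters the Guinier fit and the frame is unfittable
  blank <- volumeGrid3D(array(0, c(32, 32, 32)), 1.34)
  hs$framePairs[[3]] <- list(blank, blank)
  expect_warning(est <- estimateFrameWeights(hs$framePairs, hs$allPair, cfg),
                 "unfittable")
  expect_false(est$models[[3]]@fittable)
  expect_equal(bFactor(est$models[[3]]), bFactor(est$models[[2]]))
  expect_true(all(abs(colSums(weightMatrix(est$weights)) - 1) < 1e-10))
})
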