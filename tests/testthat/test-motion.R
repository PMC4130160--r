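test_that("running averages use truncated symmetric windows", {
  set.seed(3)
  fr <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  mp <- movieParticle(fr, 1.34)
  expect_identical(frames(runningAverages(mp, 1)), fr)
  expect_error(runningAverages(mp, 4), "odd")
  avg <- frames(runningAverages(mp, 5))
  # frame 1: window truncated to frames 1-3; frame 8: full window 6-10
  expect_equal(avg[, , 1], apply(fr[, , 1:3], c(1, 2), mean))
  expect_equal(avg[, , 8], apply(fr[, , 6:10], c(1, 2), mean))
  expect_equal(avg[, , 16], apply(fr[, , 14:16], c(1, 2), mean))
  # explicit loop oracle over every frame
  for (f in 1:16) {
    win <- max(1, f - 2):min(16, f + 2)
    expect_equal(avg[, , f], apply(fr[, , win, drop = FALSE], c(1, 2), mean))
  }
})

test_that("translational alignment returns the correcting shift", {
  ref <- syntheticReference(64, 1.34, seed = 4)
  # integer circular shift constructed with Fourier phases
  img <- applyShift(ref, 3, -2)
  expect_equal(unname(alignTranslation(img, ref, 8)), c(-3, 2),
               tolerance = 1e-6)
  expect_equal(unname(alignTranslation(ref, ref, 8)), c(0, 0),
               tolerance = 1e-9)
  flat <- imageGrid2D(matrix(1, 64, 64), 1.34)
  expect_error(alignTranslation(flat, ref, 8), "zero-variance|constant")
  expect_error(alignTranslation(ref, ref, 20), "side/4")
})

test_that("sub-pixel shifts are recovered against a dense grid-search oracle", {
  ref <- syntheticReference(64, 1.34, seed = 5)
  shifts <- list(c(0.5, 0), c(-1.3, 2.7), c(0.25, -0.75))
  refPx <- pixels(ref)
  for (s in shifts) {
    img <- applyShift(ref, s[1], s[2])
    got <- alignTranslation(img, ref, 8)
    # oracle: real-space correlation maximised over a 0.01 px grid around
    # the known neighbourhood, using Fourier-interpolated candidates
    cand <- seq(-0.06, 0.06, by = 0.01)
    best <- c(NA, NA); bestC <- -Inf
    for (ddx in cand) for (ddy in cand) {
      test <- applyShift(img, -s[1] + ddx, -s[2] + ddy)
      cc <- sum(pixels(test) * refPx)
      if (cc > bestC) { bestC <- cc; best <- c(-s[1] + ddx, -s[2] + ddy) }
    }
    expect_lt(max(abs(unname(got) - best)), 0.05)
  }
})

test_that("Gaussian neighbour weights follow exp(-d^2 / 2 sigma^2)", {
  coords <- rbind(c(0, 0), c(0, 0), c(200, 0), c(0, 100), c(5000, 5000))
  w <- neighborWeights(coords, 1, 100)
  expect_equal(w[1], 1)                      # self-weight
  expect_equal(w[2], 1)                      # co-located particle
  expect_equal(w[3], exp(-2), tolerance = 1e-12)   # d = 2 sigma
  expect_equal(w[4], exp(-0.5), tolerance = 1e-12) # d = sigma -> 0.6065
  expect_lt(w[5], 1e-100)                    # distant particles underflow
})

test_that("exact linear observations are interpolated to machine precision", {
  f <- 1:16
  obs <- frameShiftObservations("p1", 1 + 0.5 * f, -2 + 0.25 * f)
  tr <- fitLinearTracks(list(obs), matrix(0, 1, 2), 100)[[1]]
  expect_equal(unname(trackParams(tr)), c(1, 0.5, -2, 0.25),
               tolerance = 1e-12)
  expect_equal(unname(evaluateTrack(tr, 1)), c(1.5, -1.75), tolerance = 1e-12)
  expect_equal(unname(evaluateTrack(tr, 4))[1], 3, tolerance = 1e-12)
  expect_error(evaluateTrack(tr, 0), "out of range")
  expect_error(evaluateTrack(tr, 17), "out of range")
})

test_that("co-located particles with identical observations share one track", {
  f <- 1:8
  mk <- function(id) frameShiftObservations(id, 0.3 * f - 1, -0.2 * f + 2)
  trs <- fitLinearTracks(list(mk("a"), mk("b")),
                         rbind(c(10, 10), c(10, 10)), 150)
  expect_equal(trackParams(trs[[1]]), trackParams(trs[[2]]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fitted tracks match an independent weighted-regression oracle", {
  for (seed in c(11, 23, 37)) {
    inst <- randomInstance(seed, maxParticles = 10, maxFrames = 16)
    got <- fitLinearTracks(inst$obs, inst$coords, inst$sigmaNB)
    want <- lmTrackOracle(inst$obs, inst$coords, inst$sigmaNB)
    for (p in seq_along(got))
      expect_equal(unname(trackParams(got[[p]])), unname(want[[p]]),
                   tolerance = 1e-8)
  }
})

test_that("invalid frames are excluded from the fit", {
  f <- 1:10
  dx <- 1 + 0.5 * f
  dx[4] <- 100  # gross outlier, flagged invalid
  valid <- rep(TRUE, 10); valid[4] <- FALSE
  obs <- frameShiftObservations("p1", dx, -0.1 * f, valid = valid)
  tr <- fitLinearTracks(list(obs), matrix(0, 1, 2), 100)[[1]]
  expect_equal(unname(trackParams(tr))[1:2], c(1, 0.5), tolerance = 1e-10)
})

test_that("axis independence: permuting Y observations never changes X", {
  set.seed(41)
  inst <- randomInstance(99, maxParticles = 5, maxFrames = 8)
  got1 <- fitLinearTracks(inst$obs, inst$coords, inst$sigmaNB)
  permuted <- lapply(inst$obs, function(o)
    frameShiftObservations(particleId(o), shiftX(o), sample(shiftY(o)),
                           validFrames(o)))
  got2 <- fitLinearTracks(permuted, inst$coords, inst$sigmaNB)
  for (p in seq_along(got1)) {
    expect_identical(trackParams(got1[[p]])[c("alphaX", "betaX")],
                     trackParams(got2[[p]])[c("alphaX", "betaX")])
  }
})

test_that("as sigmaNB shrinks each fit approaches the per-particle regression", {
  set.seed(55)
  n <- 6
  coords <- matrix(runif(2 * n, 0, 1000), n, 2)
  f <- 1:12
  obs <- lapply(seq_len(n), function(p)
    frameShiftObservations(paste0("p", p), rnorm(12), rnorm(12)))
  tiny <- fitLinearTracks(obs, coords, 1e-6)
  for (p in seq_len(n)) {
    own <- stats::lm(shiftX(obs[[p]]) ~ f)
    expect_equal(unname(trackParams(tiny[[p]])[c("alphaX", "betaX")]),
                 unname(coef(own)), tolerance = 1e-8)
  }
})

test_that("noiseless synthetic movies close the loop with alignment", {
  cfg <- polishConfig(pixelSize = 1.34, maxShift = 6, runningAvgWidth = 1)
  ref <- syntheticReference(48, 1.34, seed = 2)
  tr <- linearTrack("p1", 1.2, -0.3, -0.8, 0.2, nFrames = 8)
  sc <- simulationConfig(nFrames = 8, boxSize = 48, bSchedule = rep(0, 8),
                         cSchedule = rep(0, 8), noiseSd = 0, seed = 1)
  mv <- simulateMovie(ref, tr, sc)
  obs <- observeFrameShifts(mv, ref, cfg)
  expect_true(all(validFrames(obs)))
  f <- 1:8
  expect_lt(max(abs(shiftX(obs) - (1.2 - 0.3 * f))), 0.05)
  expect_lt(max(abs(shiftY(obs) - (-0.8 + 0.2 * f))), 0.05)
  # all frames identical to the reference -> all observations (0, 0)
  still <- stillMovie(ref, 8)
  obs0 <- observeFrameShifts(still, ref, cfg)
  expect_lt(max(abs(c(shiftX(obs0), shiftY(obs0)))), 1e-6)
})
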