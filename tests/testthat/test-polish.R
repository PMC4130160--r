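test_that("applyShift matches circular rolls and inverts cleanly", {
  ref <- syntheticReference(32, 1.34, seed = 11)
  expect_identical(pixels(applyShift(ref, 0, 0)), pixels(ref))
  rolled <- pixels(ref)[c(30:32, 1:29), c(3:32, 1:2)]  # roll by (+3, -2)
  got <- applyShift(ref, 3, -2)
  expect_lt(max(abs(pixels(got) - rolled)), 1e-6)
  # round trip within 1e-6 relative error
  back <- applyShift(applyShift(ref, 1.7, -2.3), -1.7, 2.3)
  expect_lt(max(abs(pixels(back) - pixels(ref))) / max(abs(pixels(ref))),
            1e-6)
  expect_error(applyShift(ref, NA, 0), "finite")
  expect_error(applyShift(ref, 9, 0), "side/4")
})

test_that("sub-pixel shift moves a blob peak as an oversampling oracle says", {
  # centred Gaussian blob; peak position checked on a 10x-oversampled grid
  n <- 32
  xy <- seq_len(n) - (n / 2 + 1)
  blob <- exp(-outer(xy^2, xy^2, "+") / (2 * 3^2))
  img <- imageGrid2D(blob, 1)
  sh <- applyShift(img, 0.5, 0)
  fine <- seq(-2, 2, by = 0.01)
  prof <- vapply(fine, function(d) {
    # Fourier-interpolated sample of the shifted blob along x at the centre
    sum(Re(cryopolish:::ifft2(fft(pixels(sh)) *
                              cryopolish:::phaseRamp2D(n, -d, 0)))[n / 2 + 1,
                                                                   n / 2 + 1])
  }, numeric(1))
  peakAt <- fine[which.max(prof)]
  expect_equal(peakAt, 0.5, tolerance = 0.05)
})

test_that("polishing with uniform weights and zero track is a plain average", {
  set.seed(12)
  fr <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  mp <- movieParticle(fr, 1.34)
  wt <- makeWeightTable(rep(0, 5), rep(0, 5))
  pp <- polishParticle(mp, zeroTrack(5), wt)
  expect_lt(max(abs(pixels(pp@image) - apply(fr, c(1, 2), mean))), 1e-6)
})

test_that("a selector weight table reproduces the selected frame", {
  set.seed(13)
  fr <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  mp <- movieParticle(fr, 1.34)
  sh <- frequencyShells(32, 1.34, dims = 2L)
  W <- matrix(0, 5, length(shellFrequencies(sh)))
  W[3, ] <- 1
  wt <- new("FrameWeightTable", weights = W, shells = sh)
  pp <- polishParticle(mp, zeroTrack(5), wt)
  expect_lt(max(abs(pixels(pp@image) - fr[, , 3])), 1e-6)
})

test_that("identical frames survive any valid weight table unchanged", {
  ref <- syntheticReference(48, 1.34, seed = 14)
  still <- stillMovie(ref, 8)
  set.seed(15)
  wt <- makeWeightTable(runif(8, -150, 0), runif(8, -0.2, 0.2),
                        boxSize = 48, pixelSize = 1.34)
  pp <- polishParticle(still, zeroTrack(8), wt)
  expect_lt(max(abs(pixels(pp@image) - pixels(ref))), 1e-6)
})

test_that("polishParticle is linear in the frame images", {
  set.seed(16)
  frA <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  frB <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  wt <- makeWeightTable(c(-20, -60, -90, -120), rep(0, 4))
  tr <- linearTrack("p", 0.4, -0.1, -0.2, 0.05, nFrames = 4)
  pol <- function(fr) pixels(polishParticle(movieParticle(fr, 1.34), tr,
                                            wt)@image)
  lhs <- pol(2 * frA + 3 * frB)
  rhs <- 2 * pol(frA) + 3 * pol(frB)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("shift consistency: correcting a moving particle equals the still case", {
  ref <- syntheticReference(48, 1.34, seed = 17)
  tr <- linearTrack("p", 0.9, -0.25, -0.6, 0.15, nFrames = 6)
  sc <- simulationConfig(nFrames = 6, boxSize = 48, bSchedule = rep(0, 6),
                         cSchedule = rep(0, 6), noiseSd = 0, seed = 1)
  moving <- simulateMovie(ref, tr, sc)
  set.seed(18)
  wt <- makeWeightTable(runif(6, -100, 0), rep(0, 6),
                        boxSize = 48, pixelSize = 1.34)
  polMoving <- polishParticle(moving, tr, wt)
  polStill <- polishParticle(stillMovie(ref, 6), zeroTrack(6), wt)
  relErr <- max(abs(pixels(polMoving@image) - pixels(polStill@image))) /
    max(abs(pixels(polStill@image)))
  expect_lt(relErr, 1e-3)
})

test_that("polishDataset preserves order and reports missing tracks", {
  ref <- syntheticReference(32, 1.34, seed = 19)
  sc <- simulationConfig(nFrames = 4, boxSize = 32, bSchedule = rep(0, 4),
                         cSchedule = rep(0, 4), noiseSd = 0.2, seed = 2)
  particles <- lapply(1:3, function(p)
    simulateMovie(ref, zeroTrack(4), initialize(sc, seed = sc@seed + p),
                  particleId = paste0("p", p)))
  tracks <- lapply(1:3, function(p)
    linearTrack(paste0("p", p), 0, 0, 0, 0, nFrames = 4))
  wt <- makeWeightTable(rep(0, 4), rep(0, 4))
  res <- polishDataset(particles, tracks, wt)
  expect_length(res$polished, 3)
  expect_identical(res$table$particleId, c("p1", "p2", "p3"))
  expect_error(polishDataset(particles, tracks[1:2], wt), "p3")
  partial <- polishDataset(particles, tracks[1:2], wt, skipMissing = TRUE)
  expect_length(partial$polished, 2)
  expect_identical(partial$skipped, "p3")
})

test_that("polished particles beat the naive average on a synthetic micrograph", {
  sc <- simulationConfig(nParticles = 12, nFrames = 8, boxSize = 32,
                         fieldSize = 1024, meanDrift = 0.4,
                         corrLength = 300, heterogeneity = 0.02,
                         noiseSd = 0.6, seed = 11)
  mic <- simulateMicrograph(sc)
  truthPx <- pixels(mic$reference)
  wt <- makeWeightTable(sc@bSchedule, sc@cSchedule,
                        boxSize = 32, pixelSize = sc@pixelSize)
  corPol <- corNaive <- numeric(length(mic$particles))
  for (p in seq_along(mic$particles)) {
    pol <- polishParticle(mic$particles[[p]], mic$tracks[[p]], wt)
    corPol[p] <- cor(as.vector(pixels(pol@image)), as.vector(truthPx))
    naive <- apply(frames(mic$particles[[p]]), c(1, 2), mean)
    corNaive[p] <- cor(as.vector(naive), as.vector(truthPx))
  }
  expect_gt(mean(corPol), mean(corNaive))
})
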