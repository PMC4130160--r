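## Synthetic fixtures with the statistical structure the method assumes:
## spatially smooth linear motion fields, dose-dependent Gaussian signal
## decay, and half-map pairs with equal noise power. Everything is
## deterministic given the config seed; the caller's RNG state is preserved.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default dose-dependent damage schedule
#'
#' A per-frame relative B-factor schedule shaped like experimentally
#' observed curves: depressed values for the first frames (large initial
#' beam-induced movement), the least negative value near frame 3, then a
#' decline with accumulating dose down to about -150 Angstrom^2; the
#' intercepts C_f decline mildly with dose.
#'
#' @param nFrames number of movie frames F.
#' @return list with numeric vectors `B` (Angstrom^2) and `C`.
#' @export
defaultDamageSchedule <- function(nFrames) {
  f <- seq_len(nFrames)
  peak <- min(3L, nFrames)
  B <- numeric(nFrames)
  B[f >= peak] <- -10 - 140 * ((f[f >= peak] - peak) / max(nFrames - peak, 1))^1.5
  if (peak > 1L) B[seq_len(peak - 1L)] <- seq(-40, -20,
                                              length.out = peak - 1L)
  C <- seq(0.1, -0.1, length.out = nFrames)
  list(B = B, C = C)
}

#' Simulate a spatially smooth motion field
#'
#' Places particles uniformly over the field of view and assigns each a true
#' straight track whose slope is a smooth function of position: a low-order
#' polynomial in (x, y) plus a few random Gaussian bumps of width
#' `corrLength`, scaled to the configured mean drift, plus i.i.d.
#' per-particle heterogeneity. Intercepts are chosen so each track's mean
#' over frames is zero (the average particle position is the frame-mean
#' position). Deterministic given the config seed.
#'
#' @param config a [SimulationConfig-class] object.
#' @return list with `coords` (n x 2 matrix, pixels) and `tracks` (list of
#'   [LinearTrack-class] with the true per-particle parameters, in the
#'   correcting-shift convention used throughout).
#' @export
simulateMotionField <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config@seed, {
    n <- config@nParticles
    L <- config@fieldSize
    coords <- cbind(x = stats::runif(n, 0, L), y = stats::runif(n, 0, L))
    u <- coords[, 1] / L
    v <- coords[, 2] / L
    smoothField <- function() {
      a <- stats::rnorm(4, sd = config@meanDrift)
      val <- a[1] + a[2] * u + a[3] * v + a[4] * u * v
      nb <- 3L
      cx <- stats::runif(nb, 0, L); cy <- stats::runif(nb, 0, L)
      amp <- stats::rnorm(nb, sd = config@meanDrift / 2)
      for (m in seq_len(nb)) {
        d2 <- (coords[, 1] - cx[m])^2 + (coords[, 2] - cy[m])^2
        val <- val + amp[m] * exp(-d2 / (2 * config@corrLength^2))
      }
      val
    }
    driftX <- smoothField() + stats::rnorm(n, sd = config@heterogeneity)
    driftY <- smoothField() + stats::rnorm(n, sd = config@heterogeneity)
    fmid <- (config@nFrames + 1) / 2
    tracks <- lapply(seq_len(n), function(p) {
      betaX <- -driftX[p]; betaY <- -driftY[p]
      linearTrack(sprintf("sim%04d", p),
                  alphaX = -betaX * fmid, betaX = betaX,
                  alphaY = -betaY * fmid, betaY = betaY,
                  nFrames = config@nFrames)
    })
    list(coords = coords, tracks = tracks)
  })
}

#' Band-limited random reference image
#'
#' Smooth random blobs: white noise low-pass filtered with a Gaussian
#' envelope, normalised to zero mean and unit variance. Spectrally rich yet
#' smooth enough for accurate sub-pixel alignment; no structural data
#' required.
#'
#' @param boxSize even side length in pixels.
#' @param pixelSize Angstrom per pixel.
#' @param cutoff Gaussian envelope standard deviation as a fraction of
#'   Nyquist (default 0.4).
#' @param seed integer seed.
#' @return an [ImageGrid2D-class] object.
#' @export
syntheticReference <- function(boxSize, pixelSize, cutoff = 0.4, seed = 1L) {
  withSeed(seed, {
    raw <- matrix(stats::rnorm(boxSize^2), boxSize, boxSize)
    nu <- radialFreqGrid2D(boxSize, pixelSize)
    nyq <- 1 / (2 * pixelSize)
    env <- exp(-nu^2 / (2 * (cutoff * nyq)^2))
    env[nu >= nyq] <- 0   # band-limit below Nyquist: Fourier shifts of the
                          # reference are then exactly invertible real maps
    img <- Re(ifft2(fft(raw) * env))
    img <- (img - mean(img)) / stats::sd(img)
    imageGrid2D(img, pixelSize)
  })
}

#' Simulate a particle movie from a reference and a true track
#'
#' Frame f is the reference filtered by the frame's damage envelope
#' `exp(B_f nu^2 / 4 + C_f)`, displaced so that the correcting shift equals
#' the track evaluated at f, plus white Gaussian noise of the configured
#' standard deviation. With a zero schedule, zero track and zero noise every
#' frame equals the reference.
#'
#' @param reference an [ImageGrid2D-class] object.
#' @param track the particle's true [LinearTrack-class] (correcting-shift
#'   convention).
#' @param config a [SimulationConfig-class]; uses nFrames, bSchedule,
#'   cSchedule, noiseSd and seed.
#' @param particleId,micrographId,coordX,coordY metadata for the result.
#' @return a [MovieParticle-class] object.
#' @export
simulateMovie <- function(reference, track, config, particleId = "sim",
                          micrographId = "simMic", coordX = 0, coordY = 0) {
  stopifnot(is(reference, "ImageGrid2D"), is(track, "LinearTrack"),
            is(config, "SimulationConfig"))
  n <- nrow(pixels(reference))
  withSeed(config@seed, {
    nu <- radialFreqGrid2D(n, pixelSize(reference))
    Fref <- fft(pixels(reference))
    fr <- array(0, dim = c(n, n, config@nFrames))
    for (f in seq_len(config@nFrames)) {
      filt <- exp(config@bSchedule[f] * nu^2 / 4 + config@cSchedule[f])
      sh <- evaluateTrack(track, f)
      ## the frame sits displaced by -track(f); applying +track(f) corrects it
      ramp <- phaseRamp2D(n, -sh[1], -sh[2])
      frame <- Re(ifft2(Fref * filt * ramp))
      if (config@noiseSd > 0)
        frame <- frame + matrix(stats::rnorm(n^2, sd = config@noiseSd), n, n)
      fr[, , f] <- frame
    }
    movieParticle(fr, pixelSize(reference), particleId, micrographId,
                  coordX, coordY)
  })
}

#' Simulate direct per-frame shift observations
#'
#' Observation-level shortcut for track-fitting experiments: each
#' particle's per-frame observation is its true track evaluated at f plus
#' i.i.d. Gaussian observation noise, bypassing image formation.
#'
#' @param tracks list of true [LinearTrack-class] objects.
#' @param nFrames number of frames F.
#' @param noiseSd observation noise standard deviation (pixels).
#' @param seed integer seed.
#' @return list of [FrameShiftObservations-class], parallel to `tracks`.
#' @export
simulateShiftObservations <- function(tracks, nFrames, noiseSd, seed = 1L) {
  withSeed(seed, {
    f <- seq_len(nFrames)
    lapply(tracks, function(tr) {
      p <- trackParams(tr)
      frameShiftObservations(particleId(tr),
        p["alphaX"] + p["betaX"] * f + stats::rnorm(nFrames, sd = noiseSd),
        p["alphaY"] + p["betaY"] * f + stats::rnorm(nFrames, sd = noiseSd),
        valid = rep(TRUE, nFrames))
    })
  })
}

## apply a radial amplitude filter exp(B nu^2/4 + C) to a cubic volume
filterVolumeByShell <- function(vox, pixelSize, B, C) {
  n <- dim(vox)[1]
  k <- signedFreqIndex(n)
  k2 <- k^2
  nu2 <- outer(outer(k2, k2, "+"), k2, "+") / (n * pixelSize)^2
  Re(ifft3(fft(vox) * exp(B * nu2 / 4 + C)))
}

#' Simulate a per-frame half-map series with known damage parameters
#'
#' A common band-limited random signal volume S is generated once. The
#' frame-f half maps are S filtered by the injected damage envelope
#' `exp(B_f nu^2 / 4 + C_f)` plus independent Gaussian noise; the all-frame
#' half pair is S itself plus fresh noise of the same power. All halves and
#' frames share one noise power (the method's equal-noise-power
#' assumption). Relative B-factors are identifiable only up to the
#' reference reconstruction's own fall-off, so the unfiltered signal serves
#' as the all-frame reference: the injected `(B_f, C_f)` are then exactly
#' the relative quantities the Guinier analysis estimates.
#'
#' @param config a [SimulationConfig-class]; uses boxSize, pixelSize,
#'   nFrames, bSchedule, cSchedule, noiseSd and seed. `noiseSd` is the
#'   half-map noise standard deviation relative to unit signal variance.
#' @return list with `framePairs` (per-frame list of `list(half1, half2)`),
#'   `allPair`, and `truth` (data.frame frame, B, C).
#' @export
simulateHalfmapSeries <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@boxSize
  ps <- config@pixelSize
  withSeed(config@seed, {
    raw <- array(stats::rnorm(n^3), dim = c(n, n, n))
    k <- signedFreqIndex(n)
    k2 <- k^2
    nu <- sqrt(outer(outer(k2, k2, "+"), k2, "+")) / (n * ps)
    nyq <- 1 / (2 * ps)
    env <- exp(-nu^2 / (2 * (0.7 * nyq)^2))   # mild band limit: smooth blobs
    S <- Re(ifft3(fft(raw) * env))
    S <- (S - mean(S)) / stats::sd(S)
    noiseVol <- function() array(stats::rnorm(n^3, sd = config@noiseSd),
                                 dim = c(n, n, n))
    framePairs <- lapply(seq_len(config@nFrames), function(f) {
      Sf <- filterVolumeByShell(S, ps, config@bSchedule[f],
                                config@cSchedule[f])
      list(volumeGrid3D(Sf + noiseVol(), ps),
           volumeGrid3D(Sf + noiseVol(), ps))
    })
    allPair <- list(volumeGrid3D(S + noiseVol(), ps),
                    volumeGrid3D(S + noiseVol(), ps))
    list(framePairs = framePairs, allPair = allPair,
         truth = data.frame(frame = seq_len(config@nFrames),
                            B = config@bSchedule, C = config@cSchedule))
  })
}

#' Simulate a complete micrograph of particle movies
#'
#' Combines [simulateMotionField()] and [simulateMovie()]: one shared
#' reference image, per-particle true tracks from the smooth motion field,
#' and per-particle movies with the configured damage schedule and image
#' noise.
#'
#' @param config a [SimulationConfig-class] object.
#' @return list with `reference`, `coords`, `tracks` (truth) and
#'   `particles` (list of [MovieParticle-class]).
#' @export
simulateMicrograph <- function(config) {
  field <- simulateMotionField(config)
  reference <- syntheticReference(config@boxSize, config@pixelSize,
                                  seed = config@seed + 1L)
  particles <- lapply(seq_along(field$tracks), function(p) {
    cfgP <- initialize(config, seed = config@seed + 100L + p)
    simulateMovie(reference, field$tracks[[p]], cfgP,
                  particleId = particleId(field$tracks[[p]]),
                  micrographId = "simMic",
                  coordX = field$coords[p, 1], coordY = field$coords[p, 2])
  })
  list(reference = reference, coords = field$coords, tracks = field$tracks,
       particles = particles)
}
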