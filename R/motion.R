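#' Running averages of movie frames
#'
#' Replaces each movie frame by the unweighted mean of an odd-width window
#' of consecutive frames, truncated symmetrically at the movie ends so every
#' frame yields one output. Averaging boosts the per-frame SNR before
#' translational alignment at the cost of temporal resolution.
#'
#' @param particle a [MovieParticle-class] object with F frames.
#' @param width odd window width, 1 <= width <= 2F-1.
#' @return a [MovieParticle-class] object with the same F; output frame f is
#'   the mean of input frames in `[f-(width-1)/2, f+(width-1)/2]`
#'   intersected with `[1, F]`.
#' @export
runningAverages <- function(particle, width) {
  stopifnot(is(particle, "MovieParticle"))
  width <- as.integer(width)
  if (width %% 2L == 0L)
    stop("running-average width must be odd (the number of frames in a running average can only be an odd number); got ", width)
  nf <- nFrames(particle)
  if (width < 1L || width > 2L * nf - 1L)
    stop("running-average width must lie in [1, 2F-1]")
  if (width == 1L) return(particle)
  h <- (width - 1L) %/% 2L
  fr <- frames(particle)
  out <- fr
  for (f in seq_len(nf)) {
    win <- max(1L, f - h):min(nf, f + h)
    out[, , f] <- rowMeans(fr[, , win, drop = FALSE], dims = 2)
  }
  initialize(particle, frames = out)
}

#' Sub-pixel translational alignment of an image against a reference
#'
#' Finds the shift maximising the circular cross-correlation between image
#' and reference, searched within `+/- maxShift` pixels: integer-pixel peak
#' via FFT cross-correlation, refined by 3-point parabolic interpolation per
#' axis. Rotations are never searched.
#'
#' @param image,reference [ImageGrid2D-class] objects of the same shape.
#' @param maxShift search bound in pixels, below side/4.
#' @return numeric(2) `c(dx, dy)`: the correcting shift, i.e.
#'   `applyShift(image, dx, dy)` brings the image into register with the
#'   reference.
#' @export
alignTranslation <- function(image, reference, maxShift) {
  stopifnot(is(image, "ImageGrid2D"), is(reference, "ImageGrid2D"))
  a <- pixels(image); b <- pixels(reference)
  if (!all(dim(a) == dim(b)))
    stop("image and reference must have the same shape")
  n <- nrow(a)
  if (maxShift >= n / 4)
    stop("maxShift must be below side/4 = ", n / 4)
  if (stats::var(as.vector(a)) == 0 || stats::var(as.vector(b)) == 0)
    stop("cannot align a constant (zero-variance) image")
  cc <- Re(ifft2(fft(a) * Conj(fft(b))))
  lag <- signedFreqIndex(n)
  allowed <- abs(lag) <= ceiling(maxShift)
  mask <- outer(allowed, allowed)
  ccm <- cc
  ccm[!mask] <- -Inf
  peak <- arrayInd(which.max(ccm), dim(ccm))
  sub <- vapply(1:2, function(ax) {
    i <- peak[ax]
    im1 <- if (i == 1L) n else i - 1L
    ip1 <- if (i == n) 1L else i + 1L
    c0 <- if (ax == 1L) cc[i, peak[2]] else cc[peak[1], i]
    cm <- if (ax == 1L) cc[im1, peak[2]] else cc[peak[1], im1]
    cp <- if (ax == 1L) cc[ip1, peak[2]] else cc[peak[1], ip1]
    ## the correlation peak of band-limited images is close to Gaussian, so
    ## the parabola is fitted in the log domain where all three samples are
    ## positive (falling back to the raw values otherwise)
    v <- c(cm, c0, cp)
    if (all(v > 0)) v <- log(v)
    den <- v[1] - 2 * v[2] + v[3]
    delta <- if (abs(den) < .Machine$double.eps * max(abs(v), 1))
      0 else 0.5 * (v[1] - v[3]) / den
    lag[i] + max(-0.5, min(0.5, delta))
  }, numeric(1))
  found <- pmax(-maxShift, pmin(maxShift, sub))
  -c(dx = found[1], dy = found[2])
}

#' Per-frame shift observations for one particle
#'
#' Forms running averages of the particle's movie frames and aligns each
#' averaged frame translationally against the reference. The observation
#' for frame f is attributed to f, the window centre. Frames that fail
#' alignment are flagged invalid, never fabricated.
#'
#' @param particle a [MovieParticle-class] object.
#' @param reference an [ImageGrid2D-class] object matching the frame shape.
#' @param config a [PolishConfig-class] object supplying the running-average
#'   width and the shift search bound.
#' @return a [FrameShiftObservations-class] object with F entries.
#' @export
observeFrameShifts <- function(particle, reference, config) {
  stopifnot(is(particle, "MovieParticle"), is(config, "PolishConfig"))
  avg <- runningAverages(particle, config@runningAvgWidth)
  nf <- nFrames(avg)
  dx <- dy <- rep(NA_real_, nf)
  ok <- logical(nf)
  fr <- frames(avg)
  ps <- pixelSize(avg)
  for (f in seq_len(nf)) {
    sh <- tryCatch(
      alignTranslation(imageGrid2D(fr[, , f], ps), reference, config@maxShift),
      error = function(e) NULL)
    if (!is.null(sh)) {
      dx[f] <- sh[1]; dy[f] <- sh[2]; ok[f] <- TRUE
    }
  }
  if (!any(ok))
    stop("no movie frame of particle '", particleId(particle),
         "' could be aligned")
  frameShiftObservations(particleId(particle), dx, dy, ok)
}

#' Gaussian neighbour weights
#'
#' Weight of particle p' when fitting the track of a target particle:
#' `exp(-d^2 / (2 sigmaNB^2))` with d the Euclidean distance between the
#' two particles in the field of view. The self-weight is 1; weights for
#' distant particles underflow to 0. The kernel is deliberately
#' unnormalised: a common scale factor cancels in the least-squares
#' minimiser.
#'
#' @param coords numeric matrix (n x 2) of particle positions in pixels.
#' @param target index of the target particle (row of `coords`).
#' @param sigmaNB kernel standard deviation in pixels, > 0.
#' @return numeric(n) of weights in `[0, 1]`.
#' @export
neighborWeights <- function(coords, target, sigmaNB) {
  coords <- as.matrix(coords)
  if (sigmaNB <= 0) stop("sigmaNB must be > 0")
  d2 <- (coords[, 1] - coords[target, 1])^2 +
        (coords[, 2] - coords[target, 2])^2
  exp(-d2 / (2 * sigmaNB^2))
}

#' Fit straight movement tracks by neighbour-weighted least squares
#'
#' For each particle p and each axis independently, finds the intercept and
#' slope `(alpha_p, beta_p)` minimising
#' `sum_{p'} w_{p'} sum_f (dx_{p',f} - alpha_p - beta_p f)^2`,
#' where the outer sum runs over all particles on the micrograph (including
#' p itself) with Gaussian neighbour weights, f runs 1..F, and invalid
#' frames are excluded from the inner sum. The solution is the exact
#' weighted-least-squares minimiser from the 2x2 normal equations.
#'
#' @param observations list of [FrameShiftObservations-class], one per
#'   particle on one micrograph.
#' @param coords numeric matrix (n x 2) of the particles' field-of-view
#'   positions (pixels), rows parallel to `observations`.
#' @param sigmaNB Gaussian neighbour kernel standard deviation (pixels).
#' @return a list of [LinearTrack-class] objects, one per particle, in
#'   input order.
#' @export
fitLinearTracks <- function(observations, coords, sigmaNB) {
  coords <- as.matrix(coords)
  n <- length(observations)
  if (n == 0L) stop("no observations supplied")
  if (nrow(coords) != n)
    stop("coords must have one row per set of observations")
  nf <- nFrames(observations[[1]])
  fIdx <- seq_len(nf)
  ## per-particle sufficient statistics over valid frames
  stats <- lapply(observations, function(o) {
    v <- validFrames(o)
    f <- fIdx[v]
    list(n = length(f), sf = sum(f), sf2 = sum(f^2),
         sx = sum(shiftX(o)[v]), sfx = sum(f * shiftX(o)[v]),
         sy = sum(shiftY(o)[v]), sfy = sum(f * shiftY(o)[v]))
  })
  lapply(seq_len(n), function(p) {
    w <- neighborWeights(coords, p, sigmaNB)
    S <- c(n = 0, sf = 0, sf2 = 0, sx = 0, sfx = 0, sy = 0, sfy = 0)
    for (q in seq_len(n)) {
      if (w[q] == 0) next
      S <- S + w[q] * unlist(stats[[q]])
    }
    A <- matrix(c(S["n"], S["sf"], S["sf"], S["sf2"]), 2, 2)
    det <- A[1, 1] * A[2, 2] - A[1, 2]^2
    if (!is.finite(det) || det <= .Machine$double.eps * max(S["sf2"], 1))
      stop("track fit is degenerate for particle '",
           particleId(observations[[p]]),
           "': fewer than 2 distinct valid frames in its neighbourhood")
    solX <- solve(A, c(S["sx"], S["sfx"]))
    solY <- solve(A, c(S["sy"], S["sfy"]))
    linearTrack(particleId(observations[[p]]), solX[1], solX[2],
                solY[1], solY[2], nFrames = nf)
  })
}

#' Evaluate a fitted track at a frame index
#'
#' @param track a [LinearTrack-class] object.
#' @param f frame index, 1 <= f <= F.
#' @return numeric(2) `c(x, y)` correcting shift at frame f, in pixels:
#'   `alpha + beta * f` per axis.
#' @export
evaluateTrack <- function(track, f) {
  stopifnot(is(track, "LinearTrack"))
  if (!is.finite(f) || f < 1 ||
      (!is.na(track@nFrames) && f > track@nFrames))
    stop("frame index f = ", f, " out of range")
  c(x = track@alphaX + track@betaX * f,
    y = track@alphaY + track@betaY * f)
}
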