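# Shared fixture builders. All fixtures are generated in code; no binary
# files ship with the package.

# FSC curve with prescribed values on the shells of an N-box
makeFscCurve <- function(fsc, boxSize = 32, pixelSize = 1.34) {
  sh <- frequencyShells(boxSize, pixelSize)
  n <- length(shellFrequencies(sh))
  vals <- rep_len(fsc, n)
  new("FSCCurve", shells = sh, fsc = vals, zeroPower = rep(FALSE, n))
}

# FSC curve over explicit frequencies (shell indices 1..n, no DC)
makeFscAt <- function(nu, fsc) {
  sh <- new("FrequencyShells", shell = seq_along(nu), nu = nu,
            nVoxels = rep(1L, length(nu)))
  new("FSCCurve", shells = sh, fsc = fsc, zeroPower = rep(FALSE, length(nu)))
}

makeDamageModel <- function(frame, B, C) {
  new("FrameDamageModel", frame = as.integer(frame), bFactor = B,
      cIntercept = C, fitRange = c(0, 1), residual = 0, fittable = TRUE)
}

makeWeightTable <- function(B, C, boxSize = 32, pixelSize = 1.34) {
  ms <- lapply(seq_along(B), function(f) makeDamageModel(f, B[f], C[f]))
  frameWeights(ms, frequencyShells(boxSize, pixelSize, dims = 2L))
}

# movie whose every frame is the same image
stillMovie <- function(image, nFrames) {
  n <- nrow(pixels(image))
  movieParticle(array(rep(pixels(image), nFrames), c(n, n, nFrames)),
                pixelSize(image))
}

zeroTrack <- function(nFrames = NA_integer_)
  linearTrack("p", 0, 0, 0, 0, nFrames = nFrames)

# independent weighted-least-squares oracle: per-particle stats::lm fit with
# neighbour weights expanded per observation
lmTrackOracle <- function(observations, coords, sigmaNB) {
  n <- length(observations)
  lapply(seq_len(n), function(p) {
    w <- neighborWeights(coords, p, sigmaNB)
    rows <- do.call(rbind, lapply(seq_len(n), function(q) {
      o <- observations[[q]]
      v <- validFrames(o)
      f <- seq_len(nFrames(o))[v]
      data.frame(f = f, x = shiftX(o)[v], y = shiftY(o)[v], w = w[q])
    }))
    rows <- rows[rows$w > 0, ]
    fx <- stats::lm(x ~ f, data = rows, weights = rows$w)
    fy <- stats::lm(y ~ f, data = rows, weights = rows$w)
    c(alphaX = unname(coef(fx)[1]), betaX = unname(coef(fx)[2]),
      alphaY = unname(coef(fy)[1]), betaY = unname(coef(fy)[2]))
  })
}

# brute-force oracle: staged dense grid search minimising the weighted
# least-squares target for one particle and axis. The search runs in the
# decorrelated basis (mu, beta) with mu the predicted value at the weighted
# mean frame index, where the quadratic target is axis-aligned and the grid
# minimiser converges to the continuous one; returns c(alpha, beta).
gridTrackOracle <- function(observations, coords, sigmaNB, p, axis = "x",
                            span = 6, resolution = 0.001) {
  w <- neighborWeights(coords, p, sigmaNB)
  sw <- swf <- 0
  for (q in seq_along(observations)) {
    v <- validFrames(observations[[q]])
    f <- seq_len(nFrames(observations[[q]]))[v]
    sw <- sw + w[q] * length(f)
    swf <- swf + w[q] * sum(f)
  }
  fbar <- swf / sw
  target <- function(mu, beta) {
    s <- 0
    for (q in seq_along(observations)) {
      if (w[q] == 0) next
      o <- observations[[q]]
      v <- validFrames(o)
      f <- seq_len(nFrames(o))[v]
      d <- if (axis == "x") shiftX(o)[v] else shiftY(o)[v]
      s <- s + w[q] * sum((d - mu - beta * (f - fbar))^2)
    }
    s
  }
  best <- c(0, 0)
  step <- span / 20
  repeat {
    mus <- seq(best[1] - 20 * step, best[1] + 20 * step, by = step)
    betas <- seq(best[2] - 20 * step, best[2] + 20 * step, by = step)
    vals <- outer(mus, betas, Vectorize(target))
    ij <- arrayInd(which.min(vals), dim(vals))
    best <- c(mus[ij[1]], betas[ij[2]])
    if (step < resolution) break
    step <- step / 5
  }
  c(best[1] - best[2] * fbar, best[2])
}

# random small fitting instance for oracle-equivalence checks
randomInstance <- function(seed, maxParticles = 5, maxFrames = 8) {
  set.seed(seed)
  n <- sample(1:maxParticles, 1)
  nf <- sample(2:maxFrames, 1)
  coords <- matrix(runif(2 * n, 0, 500), n, 2)
  obs <- lapply(seq_len(n), function(p)
    frameShiftObservations(paste0("p", p),
                           rnorm(nf, sd = 1.5), rnorm(nf, sd = 1.5)))
  list(obs = obs, coords = coords, sigmaNB = runif(1, 50, 300), nf = nf)
}
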