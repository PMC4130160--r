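#' Create a 2-D image grid
#'
#' @param pixels square numeric matrix with even side length >= 16.
#' @param pixelSize pixel size in Angstrom per pixel.
#' @return an [ImageGrid2D-class] object.
#' @export
imageGrid2D <- function(pixels, pixelSize) {
  new("ImageGrid2D", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Create a 3-D volume grid
#'
#' @param voxels cubic numeric array with even side.
#' @param pixelSize voxel size in Angstrom.
#' @return a [VolumeGrid3D-class] object.
#' @export
volumeGrid3D <- function(voxels, pixelSize) {
  new("VolumeGrid3D", voxels = voxels, pixelSize = as.numeric(pixelSize))
}

#' Create a per-particle movie
#'
#' @param frames numeric array c(side, side, F) or list of square matrices of
#'   identical shape.
#' @param pixelSize Angstrom per pixel.
#' @param particleId,micrographId identifiers.
#' @param coordX,coordY particle position in the micrograph (pixels, 0-based).
#' @return a [MovieParticle-class] object.
#' @export
movieParticle <- function(frames, pixelSize, particleId = "particle",
                          micrographId = "micrograph",
                          coordX = 0, coordY = 0) {
  if (is.list(frames)) {
    side <- unique(vapply(frames, nrow, integer(1)))
    if (length(side) != 1L || any(vapply(frames, ncol, integer(1)) != side))
      stop("all frames must have the same square shape")
    frames <- array(unlist(frames), dim = c(side, side, length(frames)))
  }
  new("MovieParticle", particleId = as.character(particleId),
      micrographId = as.character(micrographId),
      coordX = as.numeric(coordX), coordY = as.numeric(coordY),
      frames = frames, pixelSize = as.numeric(pixelSize))
}

#' Create a polishing configuration
#'
#' @param sigmaNB standard deviation of the Gaussian neighbour kernel, in
#'   pixels. Smaller values let fewer neighbours contribute (more flexible,
#'   noisier tracks); typical values are 100-300 px.
#' @param runningAvgWidth odd number of movie frames per running average.
#' @param pixelSize Angstrom per pixel.
#' @param maxShift translational search bound in pixels.
#' @param fscFitMinFreq inclusive lower frequency bound of the relative
#'   Guinier fit (1/Angstrom); default 1/20.
#' @param fscThreshold FSC threshold defining the upper fit bound; default
#'   0.143.
#' @param randomSeed integer seed recorded for provenance.
#' @return a [PolishConfig-class] object.
#' @export
polishConfig <- function(sigmaNB = 300, runningAvgWidth = 7, pixelSize = 1,
                         maxShift = 10, fscFitMinFreq = 1 / 20,
                         fscThreshold = 0.143, randomSeed = 1L) {
  if (runningAvgWidth %% 2 == 0)
    stop("runningAvgWidth must be odd: the number of frames in a running average can only be an odd number")
  new("PolishConfig", sigmaNB = as.numeric(sigmaNB),
      runningAvgWidth = as.integer(runningAvgWidth),
      pixelSize = as.numeric(pixelSize), maxShift = as.numeric(maxShift),
      fscFitMinFreq = as.numeric(fscFitMinFreq),
      fscThreshold = as.numeric(fscThreshold),
      randomSeed = as.integer(randomSeed))
}

#' Create per-frame shift observations
#'
#' @param particleId identifier.
#' @param dx,dy per-frame correcting shifts (pixels).
#' @param valid logical per frame; defaults to all finite entries.
#' @return a [FrameShiftObservations-class] object.
#' @export
frameShiftObservations <- function(particleId, dx, dy,
                                   valid = is.finite(dx) & is.finite(dy)) {
  new("FrameShiftObservations", particleId = as.character(particleId),
      dx = as.numeric(dx), dy = as.numeric(dy), valid = as.logical(valid))
}

#' Create a linear movement track
#'
#' @param particleId identifier.
#' @param alphaX,alphaY intercepts (pixels; value extrapolated at frame 0).
#' @param betaX,betaY slopes (pixels/frame).
#' @param nFrames number of movie frames the track spans (NA if unknown).
#' @return a [LinearTrack-class] object.
#' @export
linearTrack <- function(particleId, alphaX, betaX, alphaY, betaY,
                        nFrames = NA_integer_) {
  new("LinearTrack", particleId = as.character(particleId),
      alphaX = as.numeric(alphaX), betaX = as.numeric(betaX),
      alphaY = as.numeric(alphaY), betaY = as.numeric(betaY),
      nFrames = as.integer(nFrames))
}

#' Frequency shells of an N-box Fourier grid
#'
#' @param boxSize box side length N (even).
#' @param pixelSize Angstrom per pixel/voxel.
#' @param nVoxels optional voxel counts per shell (computed lazily otherwise).
#' @param dims 2 or 3: dimensionality used for the default voxel counts.
#' @return a [FrequencyShells-class] object with shells k = 0..N/2 and
#'   nu_k = k/(N * pixelSize).
#' @export
frequencyShells <- function(boxSize, pixelSize, nVoxels = NULL, dims = 3L) {
  k <- 0:(boxSize %/% 2L)
  if (is.null(nVoxels)) {
    idx <- shellIndexGrid(boxSize, dims)
    nVoxels <- tabulate(idx + 1L, nbins = length(k))
  }
  new("FrequencyShells", shell = as.integer(k),
      nu = k / (boxSize * pixelSize), nVoxels = as.integer(nVoxels))
}

#' Create a synthetic-data configuration
#'
#' Defaults describe a realistic single field of view from a direct-electron
#' detector exposure: a 4096 px micrograph with 50 particles, 16 movie
#' frames, a smooth motion field drifting ~0.6 px/frame with 600 px spatial
#' correlation and mild per-particle heterogeneity, and a dose-dependent
#' damage schedule with depressed B-factors for the first frames, a peak
#' near frame 3 and a decline at high dose.
#'
#' @param nParticles number of particles in the field of view.
#' @param fieldSize micrograph side (pixels).
#' @param nFrames movie frames F.
#' @param boxSize particle box side (even, pixels).
#' @param pixelSize Angstrom per pixel.
#' @param meanDrift typical drift magnitude (px/frame) of the smooth field.
#' @param corrLength spatial correlation length of the motion field (px).
#' @param heterogeneity per-particle slope scatter (px/frame).
#' @param noiseSd observation/image noise standard deviation (px for direct
#'   shift observations; grey values for simulated images, relative to unit
#'   signal variance).
#' @param bSchedule,cSchedule injected per-frame relative B-factors
#'   (Angstrom^2) and intercepts; defaults from [defaultDamageSchedule()].
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nParticles = 50, fieldSize = 4096, nFrames = 16,
                             boxSize = 64, pixelSize = 1.34,
                             meanDrift = 0.6, corrLength = 600,
                             heterogeneity = 0.05, noiseSd = 0.1,
                             bSchedule = NULL, cSchedule = NULL, seed = 1L) {
  if (is.null(bSchedule) || is.null(cSchedule)) {
    sched <- defaultDamageSchedule(nFrames)
    if (is.null(bSchedule)) bSchedule <- sched$B
    if (is.null(cSchedule)) cSchedule <- sched$C
  }
  new("SimulationConfig", nParticles = as.integer(nParticles),
      fieldSize = as.numeric(fieldSize), nFrames = as.integer(nFrames),
      boxSize = as.integer(boxSize), pixelSize = as.numeric(pixelSize),
      meanDrift = as.numeric(meanDrift), corrLength = as.numeric(corrLength),
      heterogeneity = as.numeric(heterogeneity), noiseSd = as.numeric(noiseSd),
      bSchedule = as.numeric(bSchedule), cSchedule = as.numeric(cSchedule),
      seed = as.integer(seed))
}
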