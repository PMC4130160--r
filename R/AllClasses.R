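#' @import methods
NULL

## Central data containers. These are deliberately thin wrappers around base
## arrays: dense pixel/voxel grids with an attached physical pixel size, plus
## the bookkeeping objects of the polishing pipeline (shift observations,
## fitted tracks, FSC curves, damage models, weight tables).

#' Square 2-D image with a physical pixel size
#'
#' Carrier for micrograph-extracted particle images, references and averaged
#' movie frames. The side length must be even (and at least 16 for any image
#' that enters Fourier-space operations); all pixel values must be finite.
#'
#' @slot pixels numeric matrix, square.
#' @slot pixelSize numeric(1), Angstrom per pixel, > 0.
#' @export
setClass("ImageGrid2D",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) != ncol(p)) return("image must be square")
    if (nrow(p) %% 2L != 0L) return("image side length must be even")
    if (nrow(p) < 16L) return("image side length must be >= 16")
    if (!all(is.finite(p))) return("all pixel values must be finite")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) return("pixelSize must be a single positive number")
    TRUE
  })

#' Cubic 3-D volume with a physical voxel size
#'
#' Carrier for half-set reconstructions used in FSC and relative-Guinier
#' analysis.
#'
#' @slot voxels numeric 3-D array, cubic with even side.
#' @slot pixelSize numeric(1), Angstrom per voxel, > 0.
#' @export
setClass("VolumeGrid3D",
  representation(voxels = "array", pixelSize = "numeric"),
  validity = function(object) {
    v <- object@voxels
    d <- dim(v)
    if (length(d) != 3L) return("voxels must be a 3-D array")
    if (d[1] != d[2] || d[2] != d[3]) return("volume must be cubic")
    if (d[1] %% 2L != 0L) return("volume side length must be even")
    if (!all(is.finite(v))) return("all voxel values must be finite")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) return("pixelSize must be a single positive number")
    TRUE
  })

#' Per-particle movie: a stack of F frame images plus field-of-view position
#'
#' @slot particleId character(1) identifier.
#' @slot micrographId character(1) identifier of the field of view.
#' @slot coordX,coordY numeric(1), particle position in the micrograph
#'   (pixels, 0-based, origin at the first stored pixel).
#' @slot frames numeric array of dimension c(side, side, F), F >= 2.
#' @slot pixelSize numeric(1), Angstrom per pixel.
#' @export
setClass("MovieParticle",
  representation(particleId = "character", micrographId = "character",
                 coordX = "numeric", coordY = "numeric",
                 frames = "array", pixelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L) return("frames must be a 3-D array (side, side, F)")
    if (d[1] != d[2]) return("frames must be square")
    if (d[3] < 2L) return("a movie needs at least 2 frames")
    if (!all(is.finite(object@frames))) return("frame values must be finite")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  })

#' Polishing configuration
#'
#' Holds the user-tunable parameters of the pipeline: the neighbour kernel
#' width sigma_NB (pixels), the running-average window (odd frame count), the
#' pixel size, the translational search bound, and the relative-Guinier fit
#' range (lower frequency bound, default 1/20 per Angstrom) and FSC threshold
#' (default 0.143, the gold-standard resolution criterion).
#'
#' @export
setClass("PolishConfig",
  representation(sigmaNB = "numeric", runningAvgWidth = "integer",
                 pixelSize = "numeric", maxShift = "numeric",
                 fscFitMinFreq = "numeric", fscThreshold = "numeric",
                 randomSeed = "integer"),
  validity = function(object) {
    if (object@sigmaNB <= 0) return("sigmaNB must be > 0 (pixels)")
    if (object@runningAvgWidth %% 2L == 0L || object@runningAvgWidth < 1L)
      return("runningAvgWidth must be an odd frame count >= 1 (the number of frames in a running average can only be an odd number)")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    if (object@maxShift <= 0) return("maxShift must be positive")
    if (object@fscThreshold <= 0 || object@fscThreshold >= 1)
      return("fscThreshold must lie in (0, 1)")
    if (object@fscFitMinFreq >= 1 / (2 * object@pixelSize))
      return("fscFitMinFreq must be below the Nyquist frequency")
    TRUE
  })

#' Per-frame translation observations for one particle
#'
#' dx/dy are the differences (pixels) between the refined position of the
#' average particle and the refined position of movie frame f; equivalently
#' the correcting shift that registers frame f onto the average position.
#'
#' @slot particleId character(1).
#' @slot dx,dy numeric(F).
#' @slot valid logical(F); frames that failed alignment are flagged, never
#'   fabricated.
#' @export
setClass("FrameShiftObservations",
  representation(particleId = "character", dx = "numeric", dy = "numeric",
                 valid = "logical"),
  validity = function(object) {
    f <- length(object@dx)
    if (length(object@dy) != f || length(object@valid) != f)
      return("dx, dy and valid must have one entry per frame")
    if (f < 2L) return("need at least 2 frames of observations")
    if (any(!is.finite(object@dx[object@valid])) ||
        any(!is.finite(object@dy[object@valid])))
      return("valid observations must be finite")
    TRUE
  })

#' Fitted straight movement track for one particle
#'
#' The predicted correcting shift at frame f is alpha + beta * f per axis,
#' with f running 1..F; the intercept alpha is therefore the extrapolated
#' value at f = 0.
#'
#' @slot particleId character(1).
#' @slot alphaX,alphaY numeric(1), intercepts (pixels).
#' @slot betaX,betaY numeric(1), slopes (pixels/frame).
#' @slot nFrames integer(1), number of frames the track spans (NA if unknown).
#' @export
setClass("LinearTrack",
  representation(particleId = "character", alphaX = "numeric",
                 betaX = "numeric", alphaY = "numeric", betaY = "numeric",
                 nFrames = "integer"),
  validity = function(object) {
    if (!all(is.finite(c(object@alphaX, object@betaX,
                         object@alphaY, object@betaY))))
      return("track parameters must be finite")
    TRUE
  })

#' Radial frequency shells of a Fourier grid
#'
#' Integer-radius shells on the FFT grid of an N-box at a given pixel size;
#' shell k has centre frequency nu_k = k / (N * pixelSize) (1/Angstrom) and
#' nu_max equals the Nyquist frequency 1/(2 * pixelSize).
#'
#' @slot shell integer vector of shell indices (0 = DC).
#' @slot nu numeric vector of centre frequencies (1/Angstrom), strictly
#'   increasing.
#' @slot nVoxels integer vector, voxels per shell.
#' @export
setClass("FrequencyShells",
  representation(shell = "integer", nu = "numeric", nVoxels = "integer"),
  validity = function(object) {
    if (length(object@nu) == 0) return("shells must be non-empty")
    if (any(diff(object@nu) <= 0)) return("nu must be strictly increasing")
    if (length(object@shell) != length(object@nu) ||
        length(object@nVoxels) != length(object@nu))
      return("shell, nu and nVoxels must be parallel")
    TRUE
  })

#' Fourier shell correlation curve between two half-set volumes
#'
#' @slot shells FrequencyShells.
#' @slot fsc numeric per shell, in [-1, 1]. The DC shell is carried but
#'   excluded from all fits.
#' @slot zeroPower logical per shell; TRUE where a shell had zero power and
#'   FSC was defined as 0.
#' @export
setClass("FSCCurve",
  representation(shells = "FrequencyShells", fsc = "numeric",
                 zeroPower = "logical"),
  validity = function(object) {
    if (length(object@fsc) != length(object@shells@nu))
      return("one FSC value per shell required")
    if (any(object@fsc < -1 - 1e-9 | object@fsc > 1 + 1e-9))
      return("FSC values must lie in [-1, 1]")
    TRUE
  })

#' Frame-to-average signal amplitude ratio curve, tau_f(nu)/tau_a(nu)
#'
#' @slot shells FrequencyShells.
#' @slot ratio numeric per shell, >= 0 where valid.
#' @slot valid logical per shell; shells where either FSC is outside (0, 1)
#'   are flagged invalid (the ratio is undefined or at a boundary there).
#' @export
setClass("AmplitudeRatioCurve",
  representation(shells = "FrequencyShells", ratio = "numeric",
                 valid = "logical"),
  validity = function(object) {
    if (length(object@ratio) != length(object@shells@nu) ||
        length(object@valid) != length(object@shells@nu))
      return("ratio and valid must be parallel to shells")
    if (any(object@ratio[object@valid] < 0))
      return("ratio must be >= 0 where valid")
    TRUE
  })

#' Relative damage model for one movie frame
#'
#' Relative Guinier fit of ln(tau_f/tau_a) against nu^2: the relative
#' B-factor is 4 times the slope (Angstrom^2; negative when the frame's
#' signal falls off faster than the all-frame average) and C is the
#' intercept (frequency-independent relative signal).
#'
#' @slot frame integer(1) frame index.
#' @slot bFactor numeric(1), Angstrom^2.
#' @slot cIntercept numeric(1), unitless.
#' @slot fitRange numeric(2), frequency range (1/Angstrom) actually used.
#' @slot residual numeric(1), RMS residual of the fit in log-amplitude units.
#' @slot fittable logical(1).
#' @export
setClass("FrameDamageModel",
  representation(frame = "integer", bFactor = "numeric",
                 cIntercept = "numeric", fitRange = "numeric",
                 residual = "numeric", fittable = "logical"))

#' Normalised per-shell, per-frame weights w_f(nu)
#'
#' Rows are movie frames, columns are frequency shells; every column sums to
#' one, so re-weighting never sharpens or dampens the data overall.
#'
#' @slot weights numeric matrix, frames x shells, non-negative.
#' @slot shells FrequencyShells.
#' @export
setClass("FrameWeightTable",
  representation(weights = "matrix", shells = "FrequencyShells"),
  validity = function(object) {
    w <- object@weights
    if (ncol(w) != length(object@shells@nu))
      return("one weight column per frequency shell required")
    if (any(w < 0)) return("weights must be non-negative")
    cs <- colSums(w)
    if (any(abs(cs - 1) > 1e-10))
      return("each shell column must sum to 1 (within 1e-10)")
    TRUE
  })

#' A polished (shift-corrected, damage-weighted) average particle
#'
#' @slot particleId character(1).
#' @slot image ImageGrid2D.
#' @slot trackUsed character(1) provenance: id of the track applied.
#' @slot weightTableId character(1) provenance: identifier of the weight
#'   table applied.
#' @export
setClass("PolishedParticle",
  representation(particleId = "character", image = "ImageGrid2D",
                 trackUsed = "character", weightTableId = "character"))

#' Configuration of the synthetic-data generator
#'
#' Defines a simulated micrograph: particle count and field size, movie
#' length and box size, the smooth motion field (mean drift in px/frame,
#' spatial correlation length in px, per-particle heterogeneity in
#' px/frame), the observation/image noise level, and the injected per-frame
#' damage schedule (B_f in Angstrom^2, C_f unitless).
#'
#' @export
setClass("SimulationConfig",
  representation(nParticles = "integer", fieldSize = "numeric",
                 nFrames = "integer", boxSize = "integer",
                 pixelSize = "numeric", meanDrift = "numeric",
                 corrLength = "numeric", heterogeneity = "numeric",
                 noiseSd = "numeric", bSchedule = "numeric",
                 cSchedule = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nParticles < 1L) return("nParticles must be >= 1")
    if (object@nFrames < 2L) return("nFrames must be >= 2")
    if (object@boxSize %% 2L != 0L) return("boxSize must be even")
    if (object@fieldSize <= 0 || object@pixelSize <= 0)
      return("fieldSize and pixelSize must be positive")
    if (object@meanDrift < 0 || object@corrLength <= 0 ||
        object@heterogeneity < 0 || object@noiseSd < 0)
      return("motion/noise parameters must be non-negative (corrLength > 0)")
    if (length(object@bSchedule) != object@nFrames ||
        length(object@cSchedule) != object@nFrames)
      return("bSchedule and cSchedule must have one value per frame")
    TRUE
  })
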