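#' Accessors for cryopolish data classes
#'
#' Slot access for the package's S4 containers. Use these rather than `@`.
#'
#' @param x an object of the documented class.
#' @return the corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
setMethod("pixelSize", "ImageGrid2D", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "VolumeGrid3D", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "MovieParticle", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixels", "ImageGrid2D", function(x) x@pixels)
#' @rdname accessors
setMethod("voxels", "VolumeGrid3D", function(x) x@voxels)

#' @rdname accessors
setMethod("nFrames", "MovieParticle", function(x) dim(x@frames)[3])
#' @rdname accessors
setMethod("nFrames", "FrameShiftObservations", function(x) length(x@dx))
#' @rdname accessors
setMethod("nFrames", "FrameWeightTable", function(x) nrow(x@weights))

#' @rdname accessors
setMethod("particleId", "MovieParticle", function(x) x@particleId)
#' @rdname accessors
setMethod("particleId", "FrameShiftObservations", function(x) x@particleId)
#' @rdname accessors
setMethod("particleId", "LinearTrack", function(x) x@particleId)
#' @rdname accessors
setMethod("particleId", "PolishedParticle", function(x) x@particleId)

#' @rdname accessors
setMethod("coords", "MovieParticle", function(x) c(x = x@coordX, y = x@coordY))

#' @rdname accessors
setMethod("frames", "MovieParticle", function(x) x@frames)

#' @rdname accessors
setMethod("shiftX", "FrameShiftObservations", function(x) x@dx)
#' @rdname accessors
setMethod("shiftY", "FrameShiftObservations", function(x) x@dy)
#' @rdname accessors
setMethod("validFrames", "FrameShiftObservations", function(x) x@valid)

#' @rdname accessors
setMethod("trackParams", "LinearTrack", function(x)
  c(alphaX = x@alphaX, betaX = x@betaX, alphaY = x@alphaY, betaY = x@betaY))

#' @rdname accessors
setMethod("shellFrequencies", "FrequencyShells", function(x) x@nu)
#' @rdname accessors
setMethod("shellFrequencies", "FSCCurve", function(x) x@shells@nu)
#' @rdname accessors
setMethod("shellFrequencies", "AmplitudeRatioCurve", function(x) x@shells@nu)
#' @rdname accessors
setMethod("shellFrequencies", "FrameWeightTable", function(x) x@shells@nu)

#' @rdname accessors
setMethod("fscValues", "FSCCurve", function(x) x@fsc)
#' @rdname accessors
setMethod("ratioValues", "AmplitudeRatioCurve", function(x) x@ratio)
#' @rdname accessors
setMethod("validShells", "AmplitudeRatioCurve", function(x) x@valid)

#' @rdname accessors
setMethod("bFactor", "FrameDamageModel", function(x) x@bFactor)
#' @rdname accessors
setMethod("cIntercept", "FrameDamageModel", function(x) x@cIntercept)

#' @rdname accessors
setMethod("weightMatrix", "FrameWeightTable", function(x) x@weights)

setMethod("show", "ImageGrid2D", function(object) {
  cat(sprintf("ImageGrid2D: %d x %d px, %.4g A/px\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize))
})

setMethod("show", "VolumeGrid3D", function(object) {
  cat(sprintf("VolumeGrid3D: %d^3 voxels, %.4g A/voxel\n",
              dim(object@voxels)[1], object@pixelSize))
})

setMethod("show", "MovieParticle", function(object) {
  d <- dim(object@frames)
  cat(sprintf("MovieParticle '%s' on '%s': %d frames of %d x %d px (%.4g A/px) at (%.1f, %.1f)\n",
              object@particleId, object@micrographId, d[3], d[1], d[2],
              object@pixelSize, object@coordX, object@coordY))
})

setMethod("show", "FrameShiftObservations", function(object) {
  cat(sprintf("FrameShiftObservations '%s': %d frames (%d valid)\n",
              object@particleId, length(object@dx), sum(object@valid)))
})

setMethod("show", "LinearTrack", function(object) {
  cat(sprintf("LinearTrack '%s': x = %.3f %+.3f f, y = %.3f %+.3f f (px)\n",
              object@particleId, object@alphaX, object@betaX,
              object@alphaY, object@betaY))
})

setMethod("show", "FSCCurve", function(object) {
  cat(sprintf("FSCCurve: %d shells, nu in [%.4g, %.4g] 1/A\n",
              length(object@fsc), min(object@shells@nu), max(object@shells@nu)))
})

setMethod("show", "FrameDamageModel", function(object) {
  cat(sprintf("FrameDamageModel frame %d: B = %.2f A^2, C = %.4f%s\n",
              object@frame, object@bFactor, object@cIntercept,
              if (object@fittable) "" else " (unfittable)"))
})

setMethod("show", "FrameWeightTable", function(object) {
  cat(sprintf("FrameWeightTable: %d frames x %d shells (columns sum to 1)\n",
              nrow(object@weights), ncol(object@weights)))
})

setMethod("show", "PolishConfig", function(object) {
  cat(sprintf(paste0("PolishConfig: sigmaNB = %g px, running average width = %d, ",
                     "pixel size = %g A, max shift = %g px,\n  Guinier fit from %g 1/A ",
                     "to the FSC = %g crossing\n"),
              object@sigmaNB, object@runningAvgWidth, object@pixelSize,
              object@maxShift, object@fscFitMinFreq, object@fscThreshold))
})
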