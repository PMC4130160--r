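#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("particleId", function(x) standardGeneric("particleId"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("shiftX", function(x) standardGeneric("shiftX"))

#' @rdname accessors
#' @export
setGeneric("shiftY", function(x) standardGeneric("shiftY"))

#' @rdname accessors
#' @export
setGeneric("validFrames", function(x) standardGeneric("validFrames"))

#' @rdname accessors
#' @export
setGeneric("trackParams", function(x) standardGeneric("trackParams"))

#' @rdname accessors
#' @export
setGeneric("shellFrequencies", function(x) standardGeneric("shellFrequencies"))

#' @rdname accessors
#' @export
setGeneric("fscValues", function(x) standardGeneric("fscValues"))

#' @rdname accessors
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))

#' @rdname accessors
#' @export
setGeneric("validShells", function(x) standardGeneric("validShells"))

#' @rdname accessors
#' @export
setGeneric("bFactor", function(x) standardGeneric("bFactor"))

#' @rdname accessors
#' @export
setGeneric("cIntercept", function(x) standardGeneric("cIntercept"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
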