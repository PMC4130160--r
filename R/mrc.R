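## MRC2014 image/volume/stack I/O.
## Little-endian, 1024-byte header; data modes 0 (int8), 1 (int16), 2
## (float32) and 6 (uint16) are accepted on read, with conversion to double;
## mode 2 only is written. The pixel size lives in the cell dimensions
## (CELLA / MX etc.). Stacks (.mrcs) are written with MZ = 1 and ISPG = 0,
## volumes with MZ = NZ and ISPG = 1, following common single-particle usage.

.mrcHeaderSize <- 1024L

readMRCRaw <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 88)                           # skip cell angles, axis order, stats
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, .mrcHeaderSize + nsymbt)
  n <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode ", mode, " in ", path,
         " (modes 0, 1, 2 and 6 are supported)"))
  if (length(data) != n) stop("truncated MRC data block in ", path)
  px <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  list(data = array(data, dim = c(nx, ny, nz)), pixelSize = px,
       mode = mode, ispg = ispg, mz = mz)
}

writeMRCRaw <- function(data, pixelSize, path, asStack = FALSE) {
  d <- dim(data)
  if (length(d) == 2L) d <- c(d, 1L)
  dim(data) <- d
  mz <- if (asStack) 1L else d[3]
  ispg <- if (asStack) 0L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L, d[1], d[2], mz)),
           con, size = 4, endian = "little")
  cell <- c(d[1], d[2], mz) * pixelSize
  writeBin(as.numeric(c(cell, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(data), max(data), mean(data))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(ispg, 0L)), con, size = 4, endian = "little")
  writeBin(raw(100), con)                 # EXTRA (words 26-50)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")  # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  writeBin(as.numeric(stats::sd(data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")      # NLABL
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a cubic MRC volume
#'
#' @param path path to an MRC file holding a cubic data block (modes 0, 1, 2
#'   or 6; converted to real on read).
#' @return a [VolumeGrid3D-class] object.
#' @export
readVolume <- function(path) {
  raw <- readMRCRaw(path)
  d <- dim(raw$data)
  if (d[1] != d[2] || d[2] != d[3])
    stop("volume in ", path, " is not cubic (", paste(d, collapse = "x"), ")")
  volumeGrid3D(raw$data, raw$pixelSize)
}

#' Write a volume as 32-bit real MRC
#'
#' Values and pixel size round-trip bit-exactly for 32-bit input.
#'
#' @param volume a [VolumeGrid3D-class] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeGrid3D"))
  writeMRCRaw(voxels(volume), pixelSize(volume), path, asStack = FALSE)
}

#' Write a stack of images as an MRCS particle stack
#'
#' @param images list of [ImageGrid2D-class] objects of identical shape and
#'   pixel size.
#' @param path output path (conventionally .mrcs).
#' @return the path, invisibly; slice k of the stack is `images[[k]]`.
#' @export
writeParticleStack <- function(images, path) {
  if (length(images) == 0L) stop("cannot write an empty particle stack")
  sides <- vapply(images, function(im) nrow(pixels(im)), integer(1))
  ps <- vapply(images, pixelSize, numeric(1))
  if (length(unique(sides)) != 1L)
    stop("all images in a stack must have the same shape")
  if (length(unique(ps)) != 1L)
    stop("all images in a stack must share one pixel size")
  data <- array(unlist(lapply(images, pixels)),
                dim = c(sides[1], sides[1], length(images)))
  writeMRCRaw(data, ps[1], path, asStack = TRUE)
}

#' Read an MRCS particle stack
#'
#' @param path path to an MRC/MRCS file; slices are returned in file order.
#' @return a list of [ImageGrid2D-class] objects.
#' @export
readParticleStack <- function(path) {
  raw <- readMRCRaw(path)
  d <- dim(raw$data)
  if (d[1] != d[2]) stop("stack slices in ", path, " are not square")
  lapply(seq_len(d[3]), function(k)
    imageGrid2D(raw$data[, , k], raw$pixelSize))
}

## frame count of a stack without reading the data block
stackDepth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  ints[3]
}
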