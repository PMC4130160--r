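#' Translate an image by a sub-pixel shift
#'
#' Fourier phase modulation with circular boundary handling: shifting by
#' `(dx, dy)` then `(-dx, -dy)` recovers the input to high accuracy.
#' Circular wrap-around is acceptable for particle boxes windowed with
#' margins.
#'
#' @param image an [ImageGrid2D-class] object.
#' @param dx,dy shift in pixels, finite, `|dx|, |dy| < side/4`.
#' @return the translated [ImageGrid2D-class]; content moves towards larger
#'   indices for positive shifts.
#' @export
applyShift <- function(image, dx, dy) {
  stopifnot(is(image, "ImageGrid2D"))
  if (!is.finite(dx) || !is.finite(dy))
    stop("shift components must be finite")
  n <- nrow(pixels(image))
  if (abs(dx) >= n / 4 || abs(dy) >= n / 4)
    stop("|shift| must be below side/4 = ", n / 4)
  if (dx == 0 && dy == 0) return(image)
  shifted <- Re(ifft2(fft(pixels(image)) * phaseRamp2D(n, dx, dy)))
  imageGrid2D(shifted, pixelSize(image))
}

#' Polish one particle: shift-corrected, damage-weighted frame average
#'
#' Each movie frame f is translated by the fitted track evaluated at f (the
#' correcting shift registering the frame onto the refined average
#' position), transformed to Fourier space, multiplied per Fourier pixel by
#' the frame's weight at that pixel's radial frequency (linear interpolation
#' between shell centres; constant beyond the last shell), and accumulated;
#' the inverse transform gives the polished average. Because the weights sum
#' to one per shell, identical frames reproduce themselves exactly: there is
#' no overall sharpening or dampening.
#'
#' @param particle a [MovieParticle-class] object with F frames.
#' @param track the particle's [LinearTrack-class].
#' @param weights a [FrameWeightTable-class] with F rows.
#' @param shells optional [FrequencyShells-class]; defaults to the table's
#'   own shells.
#' @param weightTableId provenance string stored on the result.
#' @return a [PolishedParticle-class] object.
#' @export
polishParticle <- function(particle, track, weights, shells = NULL,
                           weightTableId = "weights") {
  stopifnot(is(particle, "MovieParticle"), is(track, "LinearTrack"),
            is(weights, "FrameWeightTable"))
  if (is.null(shells)) shells <- weights@shells
  nf <- nFrames(particle)
  if (nrow(weights@weights) != nf)
    stop("weight table has ", nrow(weights@weights),
         " frames but the particle has ", nf)
  n <- dim(frames(particle))[1]
  nuGrid <- radialFreqGrid2D(n, pixelSize(particle))
  nuShell <- shells@nu
  fr <- frames(particle)
  acc <- matrix(0 + 0i, n, n)
  for (f in seq_len(nf)) {
    sh <- evaluateTrack(track, f)
    wMap <- matrix(stats::approx(nuShell, weights@weights[f, ],
                                 xout = as.vector(nuGrid), rule = 2)$y, n, n)
    acc <- acc + fft(fr[, , f]) * phaseRamp2D(n, sh[1], sh[2]) * wMap
  }
  img <- imageGrid2D(Re(ifft2(acc)), pixelSize(particle))
  new("PolishedParticle", particleId = particleId(particle), image = img,
      trackUsed = particleId(track), weightTableId = weightTableId)
}

#' Polish a set of particles
#'
#' Matches particles to tracks by particle id, polishes each with the shared
#' weight table, and returns the polished images plus an updated metadata
#' table, order preserved. Particles lacking a track are collected into an
#' error report; the run aborts unless `skipMissing = TRUE`.
#'
#' @param particles list of [MovieParticle-class] objects.
#' @param tracks list of [LinearTrack-class] objects (any order; matched by
#'   id).
#' @param weights a [FrameWeightTable-class].
#' @param config a [PolishConfig-class] (recorded for provenance; not
#'   otherwise used here).
#' @param skipMissing logical; skip (rather than abort on) particles without
#'   a track.
#' @return list with `polished` (list of [PolishedParticle-class]), `table`
#'   (data.frame: particleId, polishedIndex) and `skipped` (character ids).
#' @export
polishDataset <- function(particles, tracks, weights, config = NULL,
                          skipMissing = FALSE) {
  trackIds <- vapply(tracks, particleId, character(1))
  ids <- vapply(particles, particleId, character(1))
  missing <- ids[!(ids %in% trackIds)]
  if (length(missing) && !skipMissing)
    stop("no fitted track for particle(s): ", paste(missing, collapse = ", "),
         " (use skipMissing = TRUE to polish the rest)")
  polished <- list()
  rows <- list()
  for (i in seq_along(particles)) {
    id <- ids[i]
    if (id %in% missing) next
    pp <- polishParticle(particles[[i]], tracks[[match(id, trackIds)]],
                         weights)
    polished[[length(polished) + 1L]] <- pp
    rows[[length(rows) + 1L]] <- data.frame(particleId = id,
                                            polishedIndex = length(polished),
                                            stringsAsFactors = FALSE)
  }
  list(polished = polished, table = do.call(rbind, rows), skipped = missing)
}
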