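#' Fourier shell correlation between two half-set volumes
#'
#' Per integer-radius shell k on the FFT grid,
#' `FSC_k = Re(sum F1 F2*) / sqrt(sum |F1|^2 * sum |F2|^2)` over voxels whose
#' radius rounds to k. FSC between two independently refined half-set
#' reconstructions estimates the signal content of each resolution shell.
#'
#' @param half1,half2 [VolumeGrid3D-class] objects of identical shape and
#'   pixel size.
#' @return an [FSCCurve-class] object over shells 0..N/2; shells with zero
#'   power get FSC 0 and a `zeroPower` flag.
#' @export
fscCurve <- function(half1, half2) {
  stopifnot(is(half1, "VolumeGrid3D"), is(half2, "VolumeGrid3D"))
  if (!all(dim(voxels(half1)) == dim(voxels(half2))))
    stop("half volumes must have the same shape")
  if (pixelSize(half1) != pixelSize(half2))
    stop("half volumes must share one pixel size")
  n <- dim(voxels(half1))[1]
  F1 <- fft(voxels(half1))
  F2 <- fft(voxels(half2))
  idx <- shellIndexGrid(n, 3L)
  nShells <- n %/% 2L + 1L
  num <- shellSum(Re(F1 * Conj(F2)), idx, nShells)
  p1 <- shellSum(Mod(F1)^2, idx, nShells)
  p2 <- shellSum(Mod(F2)^2, idx, nShells)
  den <- sqrt(p1 * p2)
  zero <- den == 0
  fsc <- ifelse(zero, 0, num / ifelse(zero, 1, den))
  fsc <- pmin(1, pmax(-1, fsc))
  shells <- frequencyShells(n, pixelSize(half1), dims = 3L)
  new("FSCCurve", shells = shells, fsc = fsc, zeroPower = zero)
}

#' Spectral signal-to-noise ratio from FSC
#'
#' Assuming equal noise power spectra in the two halves,
#' `SNR = FSC / (1 - FSC)`; negative FSC values clamp to SNR 0.
#'
#' @param fsc numeric FSC value(s), < 1.
#' @return SNR value(s), >= 0.
#' @export
snrFromFsc <- function(fsc) {
  if (any(fsc >= 1)) stop("FSC = 1 implies infinite SNR")
  pmax(fsc, 0) / (1 - fsc)
}

#' Frequency of the first downward FSC threshold crossing
#'
#' Scans the curve (DC shell excluded) for the first shell pair bracketing a
#' downward crossing of the threshold and interpolates linearly between the
#' two shell frequencies. A curve that never drops below the threshold
#' returns the last shell frequency (Nyquist for a full-range curve),
#' flagged; a curve already below the threshold at its first shell returns
#' the first shell frequency, flagged.
#'
#' @param curve an [FSCCurve-class] object.
#' @param threshold FSC threshold in (0, 1), conventionally 0.143.
#' @return list with `frequency` (1/Angstrom) and `flagged` (logical; TRUE
#'   when no genuine crossing existed).
#' @export
thresholdFrequency <- function(curve, threshold = 0.143) {
  stopifnot(is(curve, "FSCCurve"))
  keep <- curve@shells@shell >= 1L
  nu <- curve@shells@nu[keep]
  fsc <- curve@fsc[keep]
  if (length(nu) == 0L) stop("FSC curve has no non-DC shells")
  if (fsc[1] < threshold)
    return(list(frequency = nu[1], flagged = TRUE))
  below <- which(fsc < threshold)
  if (length(below) == 0L)
    return(list(frequency = nu[length(nu)], flagged = TRUE))
  i <- below[1] - 1L
  frac <- (fsc[i] - threshold) / (fsc[i] - fsc[i + 1L])
  list(frequency = nu[i] + frac * (nu[i + 1L] - nu[i]), flagged = FALSE)
}

#' Frame-to-average signal amplitude ratio from two FSC curves
#'
#' Computes per shell
#' `tau_f/tau_a = sqrt((FSC_f - FSC_f FSC_a) / (FSC_a - FSC_f FSC_a))`,
#' i.e. the square root of SNR_f/SNR_a under the equal-noise-power
#' assumption (amplitudes are square roots of power). Shells where either
#' FSC is outside (0, 1) are flagged invalid: the log-ratio used by the
#' Guinier fit is undefined there.
#'
#' @param fscF FSC curve of a single-frame reconstruction pair.
#' @param fscA FSC curve of the all-frame reconstruction pair.
#' @return an [AmplitudeRatioCurve-class] object on the shared shells.
#' @export
amplitudeRatio <- function(fscF, fscA) {
  stopifnot(is(fscF, "FSCCurve"), is(fscA, "FSCCurve"))
  if (length(fscF@fsc) != length(fscA@fsc) ||
      any(abs(fscF@shells@nu - fscA@shells@nu) > 1e-12))
    stop("the two FSC curves must share the same frequency shells")
  ff <- fscF@fsc
  fa <- fscA@fsc
  ## the ratio is undefined where the reference FSC is outside (0, 1) or
  ## either curve saturates at 1 (infinite SNR, incl. rounding to ~1); it is
  ## 0 (a flagged boundary) where the frame FSC is <= 0
  defined <- fa > 0 & fa < 1 - 1e-9 & ff < 1 - 1e-9
  valid <- defined & ff > 0
  num <- ff - ff * fa
  den <- fa - ff * fa
  ratio <- numeric(length(ff))
  ratio[valid] <- sqrt(num[valid] / den[valid])
  if (!any(defined))
    stop("no shell has a defined amplitude ratio (FSC at or beyond the (0, 1) boundaries everywhere)")
  new("AmplitudeRatioCurve", shells = fscF@shells, ratio = ratio,
      valid = valid)
}

#' Relative Guinier fit: per-frame relative B-factor and intercept
#'
#' Ordinary least squares of `ln(tau_f/tau_a)` against `nu^2` over the valid
#' shells between the configured lower frequency bound (about 1/20 per
#' Angstrom) and the frequency where the frame's FSC crosses the threshold
#' (0.143). The relative B-factor is 4 times the slope, so that
#' `ratio ~ exp(B_f nu^2 / 4 + C_f)`; B_f is negative when the frame's
#' signal falls off faster than the all-frame average. When fewer than 3
#' valid shells fall inside the range, the fit extends to all valid shells
#' above the lower bound; if still fewer than 3, the frame is reported
#' unfittable via an error.
#'
#' @param ratio an [AmplitudeRatioCurve-class] for the frame.
#' @param fscF the frame's [FSCCurve-class] (defines the upper fit bound).
#' @param config a [PolishConfig-class] object (fit bounds).
#' @param frame frame index recorded in the result.
#' @return a [FrameDamageModel-class] object.
#' @export
fitRelativeGuinier <- function(ratio, fscF, config, frame = 1L) {
  stopifnot(is(ratio, "AmplitudeRatioCurve"), is(fscF, "FSCCurve"),
            is(config, "PolishConfig"))
  nu <- ratio@shells@nu
  usable <- ratio@valid & ratio@ratio > 0 & ratio@shells@shell >= 1L
  upper <- thresholdFrequency(fscF, config@fscThreshold)$frequency
  inRange <- usable & nu >= config@fscFitMinFreq & nu <= upper
  if (sum(inRange) < 3L)
    inRange <- usable & nu >= config@fscFitMinFreq
  if (sum(inRange) < 3L)
    stop("frame ", frame, " is unfittable: fewer than 3 valid shells above ",
         signif(config@fscFitMinFreq, 3), " 1/A")
  x <- nu[inRange]^2
  y <- log(ratio@ratio[inRange])
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  new("FrameDamageModel", frame = as.integer(frame),
      bFactor = 4 * slope, cIntercept = intercept,
      fitRange = range(nu[inRange]), residual = sqrt(mean(res^2)),
      fittable = TRUE)
}

#' Normalised frequency-dependent frame weights
#'
#' `w_f(nu) = exp(B_f nu^2 / 4 + C_f) / sum_f' exp(B_f' nu^2 / 4 + C_f')`
#' per frequency shell, numerically stabilised by subtracting the per-shell
#' maximum exponent before exponentiation. Every shell column sums to one,
#' so the re-weighting redistributes information between frames without any
#' overall sharpening or dampening; only differences between the `(B_f,
#' C_f)` matter.
#'
#' @param models list of [FrameDamageModel-class], one per movie frame
#'   f = 1..F (resolve unfittable frames first, e.g. via
#'   [estimateFrameWeights()]'s nearest-frame fallback).
#' @param shells a [FrequencyShells-class] object.
#' @return a [FrameWeightTable-class] object (F x shells).
#' @export
frameWeights <- function(models, shells) {
  stopifnot(is(shells, "FrequencyShells"))
  B <- vapply(models, bFactor, numeric(1))
  C <- vapply(models, cIntercept, numeric(1))
  if (any(!is.finite(B)) || any(!is.finite(C)))
    stop("all frames need finite fitted (B, C) before weighting")
  nu2 <- shells@nu^2
  E <- outer(B / 4, nu2) + C            # F x K exponents
  E <- sweep(E, 2L, apply(E, 2L, max))
  W <- exp(E)
  W <- sweep(W, 2L, colSums(W), "/")
  new("FrameWeightTable", weights = W, shells = shells)
}

#' Estimate per-frame damage weights from half-map series
#'
#' Convenience pipeline: computes the all-frame FSC, each frame's FSC and
#' amplitude-ratio curve, fits the relative Guinier line per frame, and
#' returns the normalised weight table. Frames whose Guinier fit fails
#' (e.g. FSC never usable) copy `(B_f, C_f)` from the nearest fittable
#' frame by index (ties resolve to the earlier frame), with a loud warning;
#' this preserves the unity-sum contract without inventing damage
#' parameters.
#'
#' @param framePairs list of `list(half1, half2)` [VolumeGrid3D-class]
#'   pairs, one per movie frame.
#' @param allPair `list(half1, half2)` for the all-frame reconstruction.
#' @param config a [PolishConfig-class] object.
#' @return list with `models` (per-frame [FrameDamageModel-class]),
#'   `weights` (a [FrameWeightTable-class]) and `fscAll` (the all-frame
#'   [FSCCurve-class]).
#' @export
estimateFrameWeights <- function(framePairs, allPair, config) {
  fscA <- fscCurve(allPair[[1]], allPair[[2]])
  nF <- length(framePairs)
  models <- vector("list", nF)
  for (f in seq_len(nF)) {
    models[[f]] <- tryCatch({
      fscF <- fscCurve(framePairs[[f]][[1]], framePairs[[f]][[2]])
      fitRelativeGuinier(amplitudeRatio(fscF, fscA), fscF, config, frame = f)
    }, error = function(e) {
      new("FrameDamageModel", frame = as.integer(f), bFactor = NA_real_,
          cIntercept = NA_real_, fitRange = c(NA_real_, NA_real_),
          residual = NA_real_, fittable = FALSE)
    })
  }
  bad <- which(!vapply(models, function(m) m@fittable, logical(1)))
  good <- setdiff(seq_len(nF), bad)
  if (length(good) == 0L)
    stop("no movie frame yielded a fittable relative Guinier plot")
  for (f in bad) {
    src <- good[order(abs(good - f), good)][1]
    warning("frame ", f, " was unfittable; copying (B, C) from frame ", src,
            call. = FALSE)
    models[[f]] <- new("FrameDamageModel", frame = as.integer(f),
                       bFactor = models[[src]]@bFactor,
                       cIntercept = models[[src]]@cIntercept,
                       fitRange = models[[src]]@fitRange,
                       residual = NA_real_, fittable = FALSE)
  }
  list(models = models,
       weights = frameWeights(models, fscA@shells),
       fscAll = fscA)
}
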