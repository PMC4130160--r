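#' @importFrom stats fft
NULL

## Internal Fourier-grid helpers shared by alignment, FSC and weighting.
## Conventions: the first array index is X, the second Y (third Z); signed
## frequency indices follow the usual FFT layout, 0..N/2 then -(N/2-1)..-1.

signedFreqIndex <- function(n) {
  k <- 0:(n - 1L)
  k[k > n %/% 2L] <- k[k > n %/% 2L] - n
  k
}

## cache of integer shell-index grids, keyed by "n.dims"
.shellCache <- new.env(parent = emptyenv())

shellIndexGrid <- function(n, dims = 3L) {
  key <- paste0(n, ".", dims)
  if (!is.null(.shellCache[[key]])) return(.shellCache[[key]])
  k <- signedFreqIndex(n)
  k2 <- k^2
  if (dims == 2L) {
    r2 <- outer(k2, k2, "+")
  } else {
    r2 <- outer(outer(k2, k2, "+"), k2, "+")
  }
  idx <- as.integer(round(sqrt(r2)))
  idx[idx > n %/% 2L] <- -1L  # corner voxels beyond Nyquist belong to no shell
  dim(idx) <- dim(r2)
  .shellCache[[key]] <- idx
  idx
}

## radius grid in 1/Angstrom for a 2-D box
radialFreqGrid2D <- function(n, pixelSize) {
  k <- signedFreqIndex(n)
  sqrt(outer(k^2, k^2, "+")) / (n * pixelSize)
}

## phase ramp implementing a translation by (dx, dy) pixels: multiplying the
## image FFT by this ramp moves content to larger indices for positive shifts
phaseRamp2D <- function(n, dx, dy) {
  k <- signedFreqIndex(n)
  ex <- exp(-2i * pi * k * dx / n)
  ey <- exp(-2i * pi * k * dy / n)
  outer(ex, ey)
}

ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)
ifft3 <- function(x) fft(x, inverse = TRUE) / length(x)

## per-shell sums of a real-valued quantity on the full FFT grid; voxels
## beyond Nyquist (shell index -1) are dropped
shellSum <- function(values, idx, nShells) {
  v <- as.vector(values)
  g <- as.vector(idx)
  keep <- g >= 0L
  out <- rowsum(v[keep], g[keep], reorder = TRUE)
  full <- numeric(nShells)
  full[as.integer(rownames(out)) + 1L] <- out[, 1L]
  full
}
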