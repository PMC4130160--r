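---
title: "Particle polishing: models, parameters and design choices"
author: "cryopolish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle polishing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopolish)
```

## The problem

During a cryo-EM exposure the electron beam moves the frozen-hydrated
particles, blurring the recorded images, and progressively destroys
high-resolution signal through radiation damage. Fast direct-electron
detectors record the exposure as a movie of F short frames, which makes
both effects correctable in software: the per-frame particle positions can
be estimated and undone, and the per-frame information content can be
weighted by frequency before averaging. `cryopolish` implements this
two-part correction — straight-track motion estimation with spatial
borrowing of strength, and dose-dependent frequency weighting from
half-set FSC curves — and emits "polished" average particles suitable for
downstream 2D/3D classification and refinement.

## Motion model

For each particle, running averages of an odd number of consecutive movie
frames are aligned, translationally only, against a reference image. The
per-frame observation for frame $f$ is the correcting shift
$(\Delta x_f, \Delta y_f)$: the difference between the refined position of
the average particle and the refined position of frame $f$. These
observations are noisy for small particles, so a straight track is fitted
per particle, borrowing the observations of every other particle on the
same field of view. Independently per axis, the fit minimises

$$\min_{\alpha_p,\beta_p}\;\sum_{p'} w_{p'} \sum_{f=1}^{F}
  \left(\Delta x_{p',f} - \alpha_p - \beta_p f\right)^2 ,$$

with Gaussian neighbour weights
$w_{p'} = \exp\!\left(-d_{pp'}^2 / 2\sigma_{NB}^2\right)$, $d_{pp'}$ the
distance between particles $p$ and $p'$ in the field of view. The
minimiser is the exact solution of the pooled 2×2 weighted normal
equations. Assumptions worth keeping in mind:

* **Tracks are straight.** Bent or zig-zag motion is not modelled; for
  long exposures with large early drift, pre-align whole frames with an
  external tool and polish the residual motion here.
* **Rotations are ignored.** Beam-induced rotations are comparable to the
  orientation-estimation error for all but the largest particles.
* **Neighbouring particles move alike.** $\sigma_{NB}$ sets how far that
  assumption is stretched; heterogeneous local motion calls for smaller
  values.

### Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `sigmaNB` | px | 300 | neighbour kernel width; smaller = more flexible, noisier tracks. Typical 100–300 (smaller for larger particles). |
| `runningAvgWidth` | frames (odd) | 7 | SNR vs temporal resolution of the shift observations. Pick the width whose accumulated dose is ~5 e⁻/Å² for large particles, more (7–17 e⁻/Å²) for small ones. |
| `maxShift` | px | 10 | translational search bound; must be below box/4. |
| `fscFitMinFreq` | 1/Å | 1/20 | lower bound of the relative Guinier fit (inclusive). |
| `fscThreshold` | — | 0.143 | gold-standard FSC criterion bounding the fit range per frame. |

`sigmaNB` is interpreted in pixels throughout; all shift bookkeeping is in
pixels and all frequencies in 1/Å derived from the pixel size. The frame
index runs $f = 1,\dots,F$, so the intercept $\alpha$ is the extrapolated
shift at $f = 0$ — pure bookkeeping, since only the evaluated track
$\alpha + \beta f$ is ever applied.

## Damage model

Reconstructions from single movie frames lose high-frequency signal at
different rates. With half-set reconstructions per frame and for all
frames pooled, the spectral SNR of each follows from its FSC,
$\mathrm{SNR} = \mathrm{FSC}/(1-\mathrm{FSC})$, and — assuming equal noise
power in all single-frame reconstructions — the frame-to-average signal
amplitude ratio per shell is

$$\frac{\tau_f(\nu)}{\tau_a(\nu)} =
  \sqrt{\frac{\mathrm{FSC}_f - \mathrm{FSC}_f\,\mathrm{FSC}_a}
             {\mathrm{FSC}_a - \mathrm{FSC}_f\,\mathrm{FSC}_a}} .$$

The square root is forced by amplitudes being square roots of power.
Plotting $\ln(\tau_f/\tau_a)$ against $\nu^2$ gives a *relative Guinier
plot*; an ordinary least-squares line through it yields the relative
B-factor $B_f$ (4× the slope, in Å²; negative when the frame decays
faster than the average) and the intercept $C_f$ (frequency-independent
relative signal). The fitted parameters weight each frame per frequency
shell:

$$w_f(\nu) = \frac{\exp(B_f \nu^2/4 + C_f)}
                 {\sum_{f'} \exp(B_{f'} \nu^2/4 + C_{f'})} .$$

The shell columns sum to one, so re-weighting redistributes information
between frames without net sharpening or dampening, and only *differences*
between the $(B_f, C_f)$ matter — the weight table is invariant to adding
a constant to all $B_f$ or all $C_f$.

### Numerical choices

* **Fit range.** Shells from `fscFitMinFreq` (inclusive) up to the first
  downward crossing of `fscThreshold` by the frame's FSC, linearly
  interpolated between shells. Curves that never cross return the last
  shell frequency, flagged; curves already below threshold return the
  first shell, flagged. If fewer than 3 valid shells remain in range the
  fit extends to all valid shells above the lower bound before declaring
  the frame unfittable.
* **Log-domain validity.** Shells where either FSC is ≤ 0, or saturated
  at 1 (within 1e−9, absorbing floating-point rounding of identical
  halves), are excluded from the fit rather than clamped; a frame FSC of
  exactly 0 gives a flagged zero ratio.
* **Unfittable frames** copy $(B_f, C_f)$ from the nearest fittable frame
  by index (ties to the earlier frame), with a loud warning. This
  preserves the unity-sum contract without inventing damage parameters.
* **Weighting is unweighted OLS** on $(\nu^2, \ln \text{ratio})$;
  per-shell variance weighting was considered and rejected as
  under-determined by the data at hand.
* **Stabilisation.** Weight exponents subtract the per-shell maximum
  before exponentiation, so extreme B-factors cannot overflow.
* **Shell geometry.** Integer-radius shells on the FFT grid,
  $\nu_k = k/(N\,\Delta)$ with $\Delta$ the pixel size; the DC shell is
  carried but never fitted; voxels beyond Nyquist belong to no shell.

## Polishing

Each frame is translated by its fitted track value (Fourier phase
modulation, circular boundary), multiplied in Fourier space by
$w_f(|\nu|)$ — the 1-D shell weights interpolated linearly between shell
centres, constant beyond the last shell — and accumulated; the inverse
transform is the polished particle. Linear interpolation was preferred
over nearest-shell for smoothness. The operation is linear in the frame
images, and with identical frames it reproduces the frame exactly
(conservation). Polished images are not re-normalised in real space.

Two caveats are inherent to the Fourier implementation. Circular
wrap-around is acceptable because particle boxes are windowed with
margins. And the self-conjugate Nyquist frequency lines of an even-sized
real image cannot be phase-shifted by fractional amounts within a
real-to-real map; shift round-trips are exact only on content band-limited
below Nyquist (the synthetic reference generator enforces this), and on
real data the effect is confined to the Nyquist shell.

## Sub-pixel alignment

Alignment computes the FFT cross-correlation, takes the integer-pixel peak
within ±`maxShift`, and refines it per axis with a 3-point parabola fitted
to the *logarithm* of the three correlation samples (falling back to the
raw values if any is non-positive). The correlation peak of band-limited
images is close to Gaussian, for which the log-parabola is exact; in
practice this reduces the interpolation bias from ~0.04 px to under
1e−3 px while remaining deterministic and O(1). Iterative Fourier
upsampling was rejected as slower with no accuracy benefit at the 0.05 px
level the pipeline targets. The reference is used as given — no CTF
modulation is applied to it, a documented fidelity limitation since CTF
handling is out of scope.

## What the synthetic data emulate — and what they do not

The generator produces the statistical structure the method assumes, not
photorealistic micrographs:

* **Motion fields**: particle coordinates uniform over the field; slopes a
  low-order polynomial of position plus Gaussian bumps of width
  `corrLength` plus i.i.d. per-particle heterogeneity — spatially smooth,
  locally correlated motion. Intercepts centre each track so the average
  position is the frame-mean position.
* **Movies**: a band-limited random reference (filtered white noise —
  smooth blobs, no atomic model) filtered per frame by
  $\exp(B_f\nu^2/4 + C_f)$, displaced along the true track, plus white
  Gaussian noise.
* **Half-map series**: a common random signal volume, per-frame filtered
  copies plus independent noise of equal power in every half and frame —
  the method's stated noise assumption holds by construction (verified to
  2% in the tests). The *unfiltered* signal serves as the all-frame
  reference pair. This is a deliberate identifiability choice: relative
  B-factors are defined only up to the reference reconstruction's own
  fall-off, so anchoring the reference at $B = 0$ makes the injected
  schedule exactly the truth the Guinier analysis should recover. The
  default schedule mimics experimental curves: depressed $B_f$ for the
  first frames (large initial beam-induced motion), a peak near frame 3,
  then a dose-driven decline to about −150 Å².

Not modelled: CTF, detector MTF, ice background, dose-rate physics,
non-straight motion. Passing tests therefore demonstrate the estimators'
correctness and statistical behaviour under the model's assumptions, not
performance on pathological real data (e.g. charging, strong local motion
discontinuities).

### Problem sizes used in the tests

The shipped tests run at desk scale by design: boxes of 32–64 px, 8–16
frames, fields of up to 50 particles, 5–40 seeded replicates per
statistical claim. These sizes are large enough for the shell statistics
and small enough that the whole suite runs in about a minute.

## Worked example

```{r example}
cfg <- polishConfig(sigmaNB = 300, runningAvgWidth = 1, pixelSize = 1.34,
                    maxShift = 6)
sc <- simulationConfig(nParticles = 8, nFrames = 8, boxSize = 32,
                       fieldSize = 1024, noiseSd = 0.4, seed = 2)
mic <- simulateMicrograph(sc)
obs <- lapply(mic$particles, observeFrameShifts, reference = mic$reference,
              config = cfg)
tracks <- fitLinearTracks(obs, mic$coords, cfg@sigmaNB)
tracks[[1]]

hs <- simulateHalfmapSeries(simulationConfig(nFrames = 8, boxSize = 64,
                                             noiseSd = 0.1, seed = 3))
est <- estimateFrameWeights(hs$framePairs, hs$allPair, cfg)
round(cbind(truth = hs$truth$B,
            fitted = sapply(est$models, bFactor)), 1)

pol <- polishParticle(mic$particles[[1]], tracks[[1]], est$weights)
pol@image
```

## Known limitations

* Straight tracks only; use hybrid pre-alignment for bent motion.
* References are taken as-is (no CTF/projection matching).
* Relative B-factors need usable FSC between 1/20 Å⁻¹ and the 0.143
  crossing; very damaged late frames fall back to neighbouring frames'
  parameters.
* MRC I/O covers modes 0/1/2/6 and writes mode 2; compressed detector
  formats (TIFF/EER) and gain references are out of scope.
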