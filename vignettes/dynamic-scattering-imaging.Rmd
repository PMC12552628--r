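---
title: "Imaging through dynamic scattering media from frame-stack covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging through dynamic scattering media from frame-stack covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

## The imaging model

Within an isoplanatic patch, imaging through a thin scatterer is a
convolution: the camera frame is the object `O` convolved with a point
spread function `P`. When the scatterer is *static* and the illumination
varies between acquisitions, each frame is `I_m = P * O_m` — the model that
reflection-matrix methods decompose to undo scattering. When instead the
*medium* varies rapidly while the object stays fixed, each short-exposure
frame is

    I_m(r) = P_m(r) * O(r) = O(r) * P_m(r),

and because convolution commutes, the two situations are mathematically the
same problem with the roles of object and PSF exchanged. dynscatter
implements both sides of this equivalence: a forward simulator that renders
frame stacks through a time-varying scatterer, and a reconstruction engine
that applies the matrix decomposition developed for static media to the
dynamic case, recovering the hidden object *and* the per-frame PSFs.

Arranging the 2-D Fourier transforms of the frames as columns of a matrix
`A`, the model factorizes per spatial frequency: column `m` is
`a_m(k) = O~(k) p_m(k)`. If the PSF realizations are mutually uncorrelated
(the pixelwise covariance of the centered PSF ensemble is diagonal), the
covariance `C = A A^H / (M - 1)` converges to

    C(k1, k2) = O~(k1) T(k1 - k2) O~*(k2),

with `T` a Toeplitz kernel in the frequency difference — the Fourier
transform of the diagonal PSF covariance. The object's Fourier *phase* is
recoverable from the phases of `C` up to a constant and a linear ramp (an
unobservable image shift, plus, for real objects, a point-reflected twin);
its Fourier *amplitude* is recoverable from the diagonal, up to the global
factor `sqrt(T(0))`.

## The reconstruction algorithm

`class_phase_retrieval()` alternates two closed-form updates until the mean
absolute phase update drops below `tol` (default `1e-6` rad) or the
iteration budget is reached (default 1000, the standard protocol):

1. kernel: `t(q) = sum_k C(k+q, k) exp(-i psi(k+q)) exp(+i psi(k))`
2. phase: `psi(k1) = arg( sum_k2 C(k1, k2) exp(+i psi(k2)) t*(k1 - k2) )`

Both are computed in the frame domain — `t` as the summed cyclic
autocorrelation of the phase-corrected columns, the phase update as one
cyclic convolution per frame — so the dense `N_k x N_k` covariance is never
formed. This is what makes high pixel counts tractable: the cost per
iteration is a handful of FFTs per frame. The literal dense-matrix form is
retained (`class_phase_retrieval_cov()`) as the independent oracle; the two
implementations agree to `1e-8` on small problems, and on covariances
synthesized exactly from the factorized model the phase is recovered to
machine precision (the closed-form limit).

Numerical choices, all deterministic given the input:

* phase initialized at zero; `arg(0)` defined as 0;
* gauge fixed after convergence by removing the best-fit *integer* linear
  ramp (estimated from cyclic neighbor phase differences, so the removed
  ramp is an exact cyclic shift) and zeroing the phase at `k = 0`;
* amplitude estimated as `sqrt(max(diag C, 0))` — the moment estimator
  under the model — rather than by an iterative amplitude update; the
  unknown `T(0)` is absorbed into the global scale;
* in incoherent mode the temporal mean frame is subtracted before the
  transform (it carries the dominant DC term), so the zero-frequency
  coefficient is lost: the image offset is fixed by non-negativity (the
  minimum pixel is placed at zero — equivalent to choosing the missing DC)
  and the global scale by matching the image total to the mean-frame total,
  which equals the object total for unit-sum PSFs. Any remaining negative
  pixels are clipped and their pre-fix fraction is reported
  (`neg_fraction`). Registration-invariant Pearson metrics are unaffected
  by this affine fix;
* coherent fields are zero-mean across realizations, so no mean is
  subtracted there.

## The synthetic scatterer

The generator models a thin dynamic diffuser as a random phase screen in
the pupil plane. A screen is white Gaussian noise filtered to a Gaussian
autocorrelation and rescaled to the requested RMS phase (`rms_rad`).
`corr_len_px` is defined as the correlation length of the screen *phasor*
`exp(i phase)` — the quantity that sets the speckle-PSF envelope — so the
underlying phase correlation is internally scaled by `max(1, rms_rad)`.
The amplitude PSF is the centered Fourier transform of the pupil-masked
phasor, normalized to unit energy; the intensity PSF is its squared
modulus, normalized to unit sum. Frames are rendered by *circular*
convolution via products of 2-D DFTs, so the forward model matches the
reconstruction's Fourier factorization exactly and oracle tests are exact;
a `pad` flag provides linear convolution for realism checks. Temporal
correlation between consecutive screens is available by mixing the
underlying Gaussians (`frame_correlation`), which lets tests probe the
uncorrelated-PSF requirement; shot and read noise are optional and off by
default (reference runs are noiseless).

Defaults mirror the reference study conditions: `M = 150` realizations
(incoherent; `M = 180` coherent), phase-only screens with `rms_rad = 3*pi`
and `corr_len_px = 4` on a 64 x 64 grid, and a pupil at half the sampling
Nyquist in incoherent mode — the Nyquist-sampled diffraction-limited
system; phase-only screens conserve energy for any pupil. The
64 x 64 / M = 150 problem size keeps a full 1000-iteration reconstruction
around a minute on one CPU; the model is scale-free, so behavior at larger
grids differs only in the amount of averaging per kernel lag.

One scale caveat: speckle statistics are fully developed only when many
independent phase cells fit in the aperture, i.e. when
`corr_len_px * rms_rad` is small compared with the grid. The reference
screen parameters on a 64-pixel grid sit below that regime (the PSF is a
compact cluster of a few speckle lobes — a mild-diffuser blur), which is
the realistic condition for the reconstruction experiments; the
speckle-statistics tests (contrast, cross-frame decorrelation) use
smaller `corr_len_px` where the asymptotics apply, and the cross-frame
correlation bound is expressed through the effective number of speckle
modes (the variance participation ratio) rather than the raw pixel count,
which an envelope-free idealization would use.

What the simulator does *not* emulate: volumetric (thick-medium)
scattering, anisoplanatism, polarization, spectrally broadband speckle,
camera nonlinearity. Passing tests therefore demonstrate correctness of
the algorithmic chain under the isoplanatic convolution model, not
performance on arbitrary real media.

## Energy conservation and intensity modulation

A phase-only screen transmits all energy, so every intensity PSF has unit
sum and every noiseless frame has exactly the same total. This constraint
couples the PSF pixels (their centered ensemble cannot be uncorrelated:
each frame's PSF deviations must sum to zero), which leaks a structured
background haze into the reconstruction. The mitigation implemented here —
multiplying frame `m` by a fixed scalar rising linearly from 1 to 2 across
the stack (`apply_intensity_modulation()`) — breaks the exact constraint at
the cost of a rank-one, modulation-correlated component in the covariance.
In the packaged experiments the modulated reconstruction is dramatically
better than the unmodulated one (the acceptance suite measures the haze
metric both ways), which is why `run_experiment()` enables modulation by
default in incoherent mode; `iclass_reconstruct()` itself leaves it off
unless requested, since non-energy-conserving (noisy or amplitude-masked)
data do not need it. At very large `M` the rank-one component, which does
not average away, can become the dominant error — one reason fidelity is
not monotone in `M` without end: the reference conditions sit well inside
the regime where modulation helps.

## Fourier-domain cropping

`frames_to_spectral_matrix(lowpass_frac = f)` keeps the centered `f`
fraction of the spectrum before reconstruction — the Fourier-domain
cropping protocol of the reference experiments (captures were routinely
cropped to a few hundred pixels per side before processing). Cropping
concentrates the information of `M` frames on fewer unknown phases and
discards the lowest-amplitude frequencies; the reconstruction is then
band-limited but returned on the acquisition grid (zero-padded spectrum).
The default is no crop.

## Coherent mode and holography

Under focused illumination of the scattering layer (spot smaller than the
layer's correlation length) the object-plane illumination is effectively
constant across realizations and the measured field obeys
`E_m = Pcoh_m * O_eff` with `O_eff = O . E_ill` — the same factorized
model with complex quantities. The packaged coherent pipeline gives the
reflective mask a weak random phase (a diffusive backing, emulating a
diffusely reflecting target) so that its spectrum fills the system pupil —
without it the per-frame scatterer phase is unobservable at the object's
spectral zeros. It then simulates the object field a distance `dz` behind
the layer, propagates it to the layer
plane with the Fresnel transfer function

    H(fx, fy; dz) = exp(i 2 pi dz / lambda) exp(-i pi lambda dz (fx^2 + fy^2)),

scatters it with per-realization amplitude PSFs, records off-axis holograms
against a tilted plane-wave reference, demodulates them (Fourier sideband
crop and recenter; integer carriers so recentering is exact), reconstructs
`E_CLASS` at the layer plane, and back-propagates to the object plane by
flipping the sign of `dz`. The constant phase factor in `H` is retained so
propagation composes exactly (`H(dz1) H(dz2) = H(dz1 + dz2)`); `|H| = 1`
makes propagation unitary. A sampling guard warns when
`lambda |dz| / (N pitch^2) > 1`, where the discrete chirp aliases; the
default geometry (128 x 128, 5.5 um pitch, dz = 4 mm, 632.8 nm) sits
inside the limit. The default grid, pupil fraction (0.25 of Nyquist) and
carrier (38 cycles diagonal) are chosen together: off-axis recording
sacrifices bandwidth to the carrier, and on a 64-pixel grid the usable
band is so narrow that even a perfect band-limited reconstruction
correlates only ~0.8 with a sharp mask — at 128 pixels the same physical
band fraction leaves a ceiling above 0.93.

Per-frame scatterer estimation inverts the model once the object is known.
In incoherent mode, `estimate_frame_psfs()` Wiener-deconvolves each raw
frame with the reconstructed object (regularization `reg_eps` relative to
the peak spectral power, default `1e-6`), clips to non-negative and
renormalizes to unit sum. In coherent mode the scatterer acts
multiplicatively in the plane conjugate to the camera, so
`estimate_apsfs()` takes the phase of the ratio between each measured
field's spectrum and the reconstructed object's spectrum, on the support
where the object spectrum carries energy (threshold a fraction of the peak,
default 0.05), and Fourier-transforms the resulting phasor back into an
amplitude PSF. With the true object supplied, both round-trip against the
simulator's ground-truth PSF stacks.

## Evaluation conventions

Fourier-phase reconstructions are defined up to an integer cyclic shift
and, for real objects, a point-reflected twin. `registered_correlation()`
therefore maximizes the Pearson correlation over all cyclic shifts (via
FFT cross-correlation) and over reflection — this inflates its null
distribution slightly relative to a plain Pearson correlation, which the
tests account for. `haze_metric()` reports the median normalized intensity
outside the registered object support, the quantity the intensity
modulation is designed to suppress. `psf_diagonality()` scores how
diagonal the centered PSF ensemble covariance is; note it approaches 1
only when `sqrt(M)` is large compared to the pixel count, so it is used as
a *relative* ordering (e.g. correlated vs uncorrelated screens at matched
`M`) rather than an absolute score on large grids.

## Known limitations

* Fidelity under the reference incoherent conditions plateaus below unity
  even noiselessly (registered correlation ~0.84 with a sharp binary
  target), and the plateau is bias-limited rather than sampling-limited:
  it is essentially flat in the number of frames over `M = 10..150` and
  can *decrease* at much larger `M`, consistent with the residual
  correlations of energy-conserving PSFs and the modulation's rank-one
  term dominating once sampling noise is small. The acceptance suite
  records the achieved values.
* The diagonal amplitude estimator inherits a smooth low-frequency bias
  from residual PSF speckle correlations and from the modulation's
  rank-one term; an iterative amplitude update (as in the original
  incoherent-algorithm literature) might be more noise-robust and is noted
  as an open alternative.
* Coherent imaging assumes strictly constant illumination; thick media and
  varying illumination are out of scope.
* All spatial statistics assume the cyclic (torus) geometry of the DFT;
  objects approaching the frame edge wrap around rather than vignette.
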