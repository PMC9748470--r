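---
title: "SFD Mueller matrix imaging: models, conventions and design choices"
author: "sfdmueller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SFD Mueller matrix imaging: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdmueller)
```

## The measurement model

A scattering surface's polarized response is described by a Mueller-matrix
BSSRDF `S(x - x', y - y')`: the Stokes radiance leaving at `x` when Stokes
irradiance falls at `x'`, assumed laterally uniform in its statistics.
Under sinusoidal Stokes irradiance `E_0 [1 + cos(2 pi f x' + phi)]` the
emitted radiance separates into an unmodulated term, governed by the
ordinary Mueller BRDF `f_r = F_r(0)`, and a modulated term governed by the
Fourier transform of the line-spread function `S_1` (the BSSRDF with the
transverse coordinate integrated out):

`F_r(f) = \int S_1(u) exp(2 pi i f u) du.`

Stepping the illumination phase through `phi_j = 2 pi j / N` and summing
`(1/N) sum_j L_j exp(i 2 pi j / N)` recovers the complex modulation
amplitude per pixel; doing so for 16 generator/analyzer polarization
states and applying the data-reduction matrices `R_k` gives the per-pixel
complex SFD Mueller matrix.  Two properties make this object different
from an ordinary Mueller matrix, and both are exercised deliberately by
the test fixtures:

* **Complex values.**  If `S_1` is asymmetric (more light carried one way
  than the other, e.g. internal reflection along a fiber bundle), the
  transform acquires an imaginary part.  Phase from topography or from
  the illumination carrier is removed by forcing `M11` real
  (`normalize_phase()`), so surviving imaginary structure is a genuine
  material signature; reversing the transport direction conjugates it.
* **Nonrealizability.**  `F_r(f)` is a *signed* superposition of
  elementary responses, not a convex one, so the Cloude covariance
  eigenvalues may go negative and the purity indices can exceed 1.  At
  `f = 0` the superposition is convex again and realizability must hold —
  a pipeline invariant the tests assert on every simulated scene.

## Core algebra and its conventions

* **Covariance basis.**  `cloude_covariance()` uses the Pauli
  construction `H = (1/4) sum m_ij (sigma_i kron conj(sigma_j))`,
  normalized so `trace(H) = M11`.  Realizability and the purity indices
  are invariant to this normalization; it is fixed so that eigenvalue
  tolerances can be stated relative to `|trace(H)|`.
* **Eigenvalue ordering.**  Hermitian input (real matrices) sorts real
  eigenvalues descending.  The non-Hermitian covariance of a complex SFD
  matrix can have complex eigenvalues; these sort by descending real
  part, ties by descending imaginary part, because only real parts enter
  the purity formulas while imaginary residues are reported as
  diagnostics.
* **Purity on images** is computed from the real part of the SFD matrix;
  the imaginary part is displayed separately rather than folded in.
* **Realizability tolerance** defaults to `1e-6` relative to
  `|trace(H)|` — loose enough to absorb demodulation round-off at
  16-bit signal levels, tight enough that the deliberately nonrealizable
  fixtures fail it by orders of magnitude.  Overridable everywhere.
* **Lu-Chipman.**  Applied only where the matrix is realizable and
  `max|Im m| / M11 < 0.05` (the default negligibility threshold; the
  choice of 5% reflects the instrument-level reproducibility one can
  expect from a calibrated LC polarimeter, and is a parameter).
  Degenerate branches use limiting forms: a perfect polarizer
  (`1 - D^2` below 1e-12) is returned entirely as the diattenuator
  factor; a vanished polarized part yields a zero depolarizer block with
  identity retarder; singular depolarizers complete the retarder to the
  nearest proper rotation by SVD.  Orientation angles are reported in
  (-90, 90] degrees.

## The instrument model

The generator (and, mirrored, the analyzer) is a polarizer followed by
two switchable liquid-crystal retarders with fast axes at 27.4 and 72.4
degrees from the polarizer.  Each LC toggles between two retardance
states, giving 4 states per arm and 16 combinations (analyzer index
fastest — the manifest ordering is fixed and documented so acquisitions
are reproducible).  The reduction matrices come from inverting the 16x16
design matrix whose rows are Kronecker products of analyzer and generator
vectors; a condition-number guard rejects degenerate configurations such
as duplicated LC states.

The retardance states themselves are not dictated by the axis geometry,
so the package must choose defaults.  We use (135, 315) degrees for both
LCs: with those states the 27.4/72.4-degree axes give a design-matrix
condition number of 3.0096 (arm condition 1.7348, essentially the
theoretical optimum sqrt(3)), and a 1-degree grid search over both axis
angles finds nothing better — i.e. the published axis choice is optimal
*given* these states.  Candidate states of the (90, 180) class were
examined and rejected: they condition far worse at these axes (arm
condition 7.4) and their grid optimum sits at entirely different axes.
Externally calibrated reduction matrices can be loaded from a documented
16x16 CSV layout (`read_reduction_csv()`), bypassing the ideal model; the
eigenvalue-calibration procedure itself is out of scope.

The period-to-frequency helper uses an effective projector pitch of 1/30
cm at the sample plane, which reproduces the canonical fringe-period
table (periods Inf, 24, 18, 12, 9, 6 px giving approximately 0, 1.2, 1.7,
2.5, 3.3, 5.0 1/cm; 24 px gives exactly 1.25).

## The synthetic-data generator

Scenes are region maps whose pixels carry sums of kernel components, each
a Mueller weight attached to a 1-D line-spread kernel along the
modulation axis:

| kernel | transform | emulates |
|---|---|---|
| local | flat | single scatter |
| gaussian (sigma, cm) | `exp(-2 pi^2 sigma^2 f^2)` | broad diffusive halo |
| exponential (l, cm) | `1 / (1 + (2 pi f l)^2)` | diffusive transport tail |
| displaced (Delta, cm, axis) | `exp(2 pi i f Delta)` | directional double scatter |

The convolution is 1-D along the modulation axis because the transverse
coordinate is already integrated out of `S_1`; this keeps the oracle
closed-form and exactly matches what the reduction measures.  The 20-degree
oblique illumination of a real bench is not ray-traced; its polarimetric
signature is emulated as a weak fixed diattenuator (D = 0.05 at 90
degrees) composed into background weights.  Diffuse backgrounds default
to `diag(1, 0.1, 0.1, 0.05)`-type depolarizing weights — plausible for a
strongly scattering medium, and configuration rather than claims.  The
camera model applies Poisson shot noise on photoelectrons, Gaussian read
noise (default 2 e- RMS), integer quantization and clipping at a
saturation level (default 99% of 16-bit full scale); with noise off the
renderer is exact floating-point radiometry, which is what makes
sub-1e-10 round-trip assertions meaningful.

Three phantom presets (`phantom_preset()`) reproduce the qualitative
contrast mechanisms of interest: a buried anisotropic fiber sheet
(`fiber_gradient`), an internally reflecting fiber bundle
(`fiber_bundle`), and a bright anisotropic band flanked by
oppositely-displaced scatter (`two_region_brain`), the last including a
saturating specular hot spot to exercise masking.  Their kernel
parameters are illustrative, not fits to any measured sample.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: multiple-scattering radiative transport
(kernels are analytic stand-ins), wavelength dependence, projector pixel
geometry and synchronization artifacts, surface topography phase beyond a
uniform carrier, and instrument polarization errors (the ideal model is
exactly invertible; real reductions inherit calibration error instead).

## Pipeline conventions and numerics

* **Demodulation convention.**  `Lhat = (1/N) sum_j L_j exp(i 2 pi j/N)`
  maps a frame sequence `A + B cos(phi_j + theta)` to `(B/2)
  exp(-i theta)`; a scene component displaced by `Delta` along the
  modulation axis therefore shows `arg F_r = +2 pi f Delta` after M11
  phase normalization.  The factor B/2 and the ignored carrier
  `exp(2 pi i f x)` cancel between sample and mirror reference, so no
  absolute-phase or absolute-gain knowledge is needed.  For `N = 6`,
  roots-of-unity orthogonality rejects DC and the second harmonic
  exactly; `N = 3` is the admissible minimum and `N >= 6` adds noise
  averaging, not model capacity.
* **f = 0.**  The demodulation sum annihilates unmodulated signal, so the
  zero-frequency channel is reduced by averaging the phase frames
  (`dc_reduce()`), recovering the ordinary Mueller BRDF.
* **Orientation vocabulary.**  "Modulation along x" means irradiance
  varying along image *columns*; the manifest stores the axis tag
  explicitly rather than relying on horizontal/vertical wording.  Pixels
  are 0-based (row, col), rows increasing downward, physical pitch in
  cm/pixel carried in the manifest.
* **BRDF scale.**  The scaling applies, per pixel,
  `F_r = M(f) (f_r^d pi / M11^d(0)) (M11^r(0) / M11^r(f))` with spatial
  means of the flat reference images.  As printed, the diffuse
  reference's own scaled M11 is the dimensionless `f_r^d pi` (unity for a
  perfect Lambertian), so outputs are pi times a BRDF in 1/sr; we follow
  the formula as stated and note the convention here, since only ratios
  matter downstream.
* **Masking.**  A pixel saturates for a frequency if any contributing
  frame reaches the clip level; phase normalization flags pixels with
  `|M11|` below 1e-8 of the image maximum as undefined.  Masked pixels
  propagate as NA through every later stage and render as white
  (saturated) or blue (nonrealizable) in the figure products.

## Storage formats

The canonical container is a multi-page TIFF plus a JSON manifest: raw
stacks as 16-bit integer counts (lossless for camera data; noise-free
analytic renders fall back to 32-bit float pages), reduced images as
32-page float TIFF (Re/Im per element) with an 8-bit PNG mask, scenes and
reference sets as JSON.  Everything round-trips losslessly at its native
precision, and a rendered stack is indistinguishable from a measured one
to the reduction code.  A single-file HDF5 container was considered and
set aside: it adds a heavyweight dependency for no capability the
TIFF+JSON pair lacks at these data sizes.

## Problem sizes

The shipped verification uses: 20 random mixed-kernel scenes at 128x128
pixels and frequencies {0, 1.2, 2.5, 5} 1/cm for the analytic round trip
(noise-free, max |error| < 1e-10); 1000 random convex Jones sums for the
purity inequality; 500 random factor products for Lu-Chipman recovery
(< 1e-6); 200 seeded repetitions for shot-noise propagation (within 10%
of prediction); and a full 1-degree grid for the conditioning scan.
These sizes were chosen so the whole suite verifies the claimed exactness
bounds with comfortable margin while remaining quick to run on a laptop.

## Known limitations

Decomposition of *complex* SFD matrices is deliberately not offered —
there is no established framework for depolarization once covariance
eigenvalues leave the nonnegative reals, so the package reports purity
indices and realizability instead and restricts Lu-Chipman to the
negligible-imaginary, realizable subset.  Differential/logarithmic and
reverse-order decompositions are out of scope.  The analytic kernel
family spans the behaviors the pipeline must distinguish (flat, low-pass,
phase-carrying), but it is a model of convenience: quantitative inversion
of real tissue data would require transport-based kernels and a measured
instrument calibration.
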