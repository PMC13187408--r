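---
title: "Co-designing an extended depth-of-field meta-optic and its reconstruction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-designing an extended depth-of-field meta-optic and its reconstruction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edofco)
```

## The problem

A high-NA wide-field fluorescence microscope resolves subcellular detail but
keeps only a micron-scale axial slice in focus: the depth of field scales as
$\mathrm{DoF} \propto \lambda / \mathrm{NA}^2$. Multispectral imaging makes
this worse, because residual chromatic aberration shifts the best-focus plane
per emission channel. One route out is wavefront coding: place a phase
element in a plane conjugate to the objective pupil, deliberately aberrate
the system so that the measurement stays informative over a large depth
range, and restore the image computationally. `edofco` implements this
co-design loop end to end for a meta-optic phase element — an array of
subwavelength dielectric nanopillars whose local width sets a
wavelength-dependent phase delay — jointly optimized with a convolutional
reconstruction network.

## Forward model

The simulator uses scalar Fourier optics. The pupil is discretized on an
$n \times n$ grid with pitch $\Delta s$ (µm); the field after a phase-only
pupil is $P = m\,e^{i\phi}$ with binary aperture mask $m$, and the
incoherent point spread function is the squared magnitude of the centered
discrete Fourier transform of $P$, normalized to unit sum. The total pupil
phase at depth $z$ and wavelength $\lambda$ is

$$\phi_{z,\lambda} = \psi_z(\lambda)\,\rho^2 + \phi^M_\lambda, \qquad
\psi_z = \frac{\pi}{\lambda}\Big(\frac{1}{z} - \frac{1}{z_0}\Big)
\Big(\frac{D}{2}\Big)^2,$$

where $\rho$ is the normalized pupil radius ($\rho = 1$ at the aperture
edge, so the edge phase equals the defocus coefficient $\psi_z$ exactly),
$z_0$ the nominal focus and $D$ the pupil diameter. The sensor image is the
full linear convolution of the depth-independent ground truth with the
unit-sum PSF, center-cropped to the working patch size so convolution
boundary artifacts never reach the network, plus additive sensor noise:
$SI_{z,\lambda} = GT_\lambda * PSF_{z,\lambda} + \eta$.

Three modeling choices worth stating:

* **Scalar, single-transform PSF model.** Vectorial high-NA corrections and
  apodization are out of scope; the pupil-phase model captures what the
  design loop acts on (defocus and the learned modulation).
* **Noise model.** The distribution of $\eta$ is a configuration choice:
  additive Gaussian with $\sigma = 0.01$ in normalized intensity units by
  default, with an optional Poisson–Gaussian mode. Values are not clipped
  after noise; the network input normalization absorbs the range.
* **Depth convention.** A target DoF of, say, 50 µm means the symmetric
  range $z_0 \pm 25$ µm. Depth planes are spaced uniformly in diopters
  (reciprocal distance), matching the linearity of $\psi_z$ in $1/z$.

## Sizing the simulation

`plan_sampling()` sizes the pupil grid from two constraints: the
space-bandwidth product per wavelength,
$SBP(\lambda) = (2 L_x f_\mathrm{pass})(2 L_y f_\mathrm{pass})$ with
$f_\mathrm{pass} = \min(2\,\mathrm{NA}/\lambda,\ M/2p)$, and a bound on the
Fourier-plane pitch from the worst-case pupil phase slope,
$\Delta s_\mathrm{crit} = \pi (D/2) / (8\,\psi_\mathrm{max})$ evaluated at
the shortest wavelength, with $\psi_\mathrm{max} =
\max(|\psi_{z_0-\Delta}|, |\psi_{z_0+\Delta}|)$ (the near edge always
dominates). The working pitch oversamples this by a factor $\alpha$
(default 4). $\alpha$ is deliberately an independent configuration scalar:
the ratio $SBP_\mathrm{total}/SBP(\lambda_\mathrm{min})$ is reported as a
diagnostic alongside, and the two need not coincide. `fit_defocus_model()`
inverts the worst-case relation
$\psi_\mathrm{max}(\Delta) = C\Delta/(z_0(z_0-\Delta))$ from two operating
points in closed form, which lets published (DoF, $\psi_\mathrm{max}$)
pairs be cross-checked for mutual consistency and extrapolated:

```{r}
m <- fit_defocus_model(rbind(c(12.5, 110.20), c(25, 221.32)))
predict(m, dof_halfwidth = 37.5)
```

## The meta-optic parameterization

The element is a radial vector of nanopillar widths
$\gamma = \gamma_\mathrm{init} + \Delta\gamma$, clamped to the width bounds,
azimuthally replicated onto the pupil by nearest radial-bin assignment (a
fixed linear operator), and mapped to a per-wavelength phase through a
piecewise-linear lookup in a unit-cell library. Piecewise-linear
interpolation is the simplest differentiable choice whose gradient is the
exact segment slope; phases are kept unwrapped so the lookup stays smooth,
and wrapping is applied only on export. Out-of-range widths are clamped
rather than rejected during optimization so gradients stay defined (the
clamp's subgradient is zero outside the bounds, which is exactly the
saturation behavior wanted).

Because no electromagnetic solver ships with the package, the default
library is an explicit surrogate: a fill-factor effective-index model
$\phi(w, \lambda) = (2\pi/\lambda)\,h\,(n_\mathrm{eff}(w,\lambda) - 1)$ with
$n_\mathrm{eff} = 1 + (n_\mathrm{pillar}(\lambda) - 1)(w/\mathrm{period})^2$
and a Cauchy pillar index with TiO₂-like coefficients (A = 2.23,
B = 0.07 µm², height 700 nm, period 350 nm). The defaults span more than
$2\pi$ at each of 433/521/601/681 nm, which is the property the design loop
needs; tabulated libraries from full-wave solvers load from delimited text
with `load_library()`. The replication operator is read as fully
rotationally symmetric (a pure radius vector); sectorized non-symmetric
variants are intentionally not modeled.

The initialization is *flat-π*: the tabulated width whose phase at the
reference wavelength (shortest channel by default) is closest to π,
replicated over all radii — asserted at construction to land within one
lookup quantum of π. A cubic-phase start is available (`cubic_init()`) as an
untuned baseline; under the strong defocus this package targets it produces
heavily blurred sensor images and is not recommended.

## MTF-guided pre-optimization

Before joint training, the meta-optic alone is optimized for 30 epochs
against a frequency-domain objective. For each depth and wavelength the
DC-normalized radial MTF $M_\lambda(\rho, z)$ is compared to a target
passband $T(\rho) = \mathbf{1}[\rho \le \rho_\mathrm{cut}]$; per-depth
errors $\lVert M - T\rVert_1$ (averaged over radial bins so the loss scale
is grid-independent) aggregate across depth with a log-sum-exp,

$$\mathcal{L}_\lambda = \frac{1}{\beta}\log\sum_z
\exp\big(\alpha \lVert M_\lambda(\cdot,z) - T\rVert_1\big),$$

and across channels with a focus-weighted log-sum-exp that places extra
weight $\lambda_\mathrm{focus}$ on the currently limiting wavelength. The
numeric values $\rho_\mathrm{cut} = 0.5$, $\alpha = \beta = 50$,
$\eta = 10$, $\lambda_\mathrm{focus} = 0.5$ are declared package defaults —
chosen so the depth aggregation operates in its soft-max (worst-case-depth)
regime — not values taken from any reference; with $\alpha = \beta$ the
operator is the standard soft-max and its mean/max limits are unit-tested.
The Adam step size on the width perturbation defaults to 2 nm per epoch,
small against the ~275 nm width span of the library.

On the normalized frequency axis, $\rho = 1$ is the incoherent cutoff
$2\,\mathrm{NA}/\lambda$. On the discrete grid the OTF support equals the
pupil autocorrelation support, so one frequency sample corresponds to a
pupil displacement of $\Delta s$ and the radial bins are one sample wide —
no interpolation enters the loss.

## The reconstruction network

`build_reconstructor()` assembles a three-level encoder–decoder:
per-channel instance normalization of the input; a 1×1 cross-channel mixing
convolution initialized to the identity; a Fourier-domain channel-attention
block; double 3×3 convolutions with batch normalization and ReLU at widths
32→64→128 (2×2 max pooling between levels); a mirrored decoder with
factor-2 bilinear upsampling and skip connections; and a 1×1 head whose
tanh output is added to the input and clamped to $[0,1]$.

Two under-specified details are resolved as follows and asserted in tests:

* **Head initialization.** The residual head is zero-initialized, so the
  network is exactly the identity map `clamp(input)` at the start of
  training. Training therefore begins from the raw (coded) sensor image and
  can only improve on it.
* **Attention realization.** Each channel's gate is computed from the mean
  of its magnitude spectrum through a *shared* two-layer bottleneck and a
  sigmoid. Sharing the bottleneck across channels makes the block
  channel-symmetric — identical channels receive identical gates — while
  still letting the gate depend on each channel's spectral content. An
  epsilon inside the magnitude keeps all-zero channels finite.

The single-wavelength variant (`channels = 1`) omits the attention block,
since no cross-channel reweighting is possible.

Because no automatic-differentiation framework is available to R at this
tier, the package carries its own reverse-mode tape (`ad_param()`,
`ad_backward()`) with hand-derived vector-Jacobian products for the FFT
primitives (pupil→PSF intensity, magnitude spectra, FFT convolution) and
the network layers. Every adjoint is validated against central finite
differences in the test suite; the end-to-end gradient of the
reconstruction loss with respect to the width perturbation matches finite
differences to well below the 10⁻³ relative level.

## Joint training

`train_end_to_end()` runs the two-optimizer loop: per step it samples a
ground-truth patch (optionally augmented with right-angle rotations, flips
and brightness scaling in [0.8, 1.25] — right angles avoid interpolation
artifacts in the [0,1] bound), assigns a depth from the diopter-uniform
schedule, simulates the per-channel PSFs from the current widths, renders
noisy sensor images, reconstructs, and accumulates the multi-term loss

$$\mathcal{L} = w_\mathrm{RMSE}\,\mathrm{RMSE}
 + w_\mathrm{SSIM}(1 - \mathrm{SSIM})
 + w_\mathrm{grad}\,\ell_\mathrm{grad}
 + w_\mathrm{LP}\,\mathrm{MSE}(\phi_\mathrm{LP}(OI), \phi_\mathrm{LP}(GT))$$

averaged over the sampled depth/channel set. The weights
$(1.0, 0.2, 0.1, 0.1)$ keep RMSE the dominant signal; $\ell_\mathrm{grad}$
matches horizontal and vertical finite differences, and
$\phi_\mathrm{LP}$ is a fixed 9×9 Gaussian low-pass (σ = k/6). SSIM uses
the conventional 11×11 Gaussian window (σ = 1.5) with the standard
stabilizing constants at data range 1; the similarity map's border of half
a window is cropped before averaging so padding never enters the score
(this matches the reference implementation the tests compare against to
10⁻⁶). The RMSE term carries a 10⁻²⁴ epsilon inside the square root
(subtracted back out) so its gradient stays finite at `oi == gt` while the
loss remains exactly zero there.

The total objective is $\mathcal{J} = \mathcal{L} + \beta_\mathrm{wd}
\lVert\theta_\mathrm{net}\rVert_2^2$: the L2 penalty (gradient
$2\beta_\mathrm{wd}\theta$) touches network parameters only; the optical
widths are never regularized. Defaults follow the published recipe — Adam
at 10⁻² for the optics, 10⁻⁴ with weight decay 10⁻³ for the network.
Effective widths are re-clamped to the design bounds after every optical
step. Depth-plane counts default to K = 5 for 25/50 µm targets and K = 7
for 75 µm; evaluation sweeps use 41 diopter-uniform planes.

## The synthetic phantoms, and what they do not show

`generate_phantom()` renders four channel archetypes in $[0,1]$: soft-edged
elliptical blobs (nuclei-like), curvilinear filament networks, elliptical
membrane rings, and sparse diffraction-scale puncta. They emulate the one
property the co-design loop needs from data — channel-distinct spatial
statistics at cellular length scales (the archetypes are statistically
separable: filament channels carry at least twice the gradient energy of
nuclei channels across seeds) — and none of the photometric properties of
real stained cells: no autofluorescent background, no bleed-through, no
intensity statistics matched to any dye. Green tests on phantoms therefore
demonstrate that the optimization machinery behaves as designed, not that
any particular fidelity level transfers to real acquisitions. Loaders for
real multichannel TIFF stacks are provided for that purpose.

## The desk-scale experiment

`toy_codesign()` runs the whole pipeline at sizes where every stage takes
seconds to minutes on one CPU core: a 64×64 pupil grid, two emission
channels (433 and 681 nm), an 8-bin radial width vector, three training
depths over a ±50 µm range around a 3 mm focus with a 1.4 mm pupil — a
worst-case defocus coefficient near 20 rad, the regime of moderate
wavefront-coding designs — 64×64 phantom patches (6 training, 3 held out),
30 pre-optimization epochs, 250 end-to-end steps per trained arm, and a
5-plane diopter-uniform evaluation sweep. The toy network uses widths
8→16→32 and a network learning rate of 2×10⁻³, scaled up from the
full-size default because the schedule is two orders of magnitude shorter.
These sizes are the package's declared study conditions for its own
acceptance checks.

The experiment reproduces, at this scale, the qualitative findings the
method is built on: the pre-optimization lowers the EDoF objective and
flattens the across-depth MTF deviation relative to the flat-π start; the
full co-designed system beats both single-component ablations
(conventional optics + network; meta-optic without network) in
depth-averaged PSNR; and the full system's PSNR varies substantially less
with depth than the conventional system's. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch.

## Numerical notes and limitations

* All FFTs are unnormalized R `fft()` calls; PSF slices are normalized to
  unit sum explicitly, which is what makes sensor-image energy match
  ground-truth energy in the valid crop to 10⁻⁶.
* The PSF grid is shared across wavelengths; the object-space pixel pitch
  recorded per wavelength, $(\lambda/2\mathrm{NA})\,D/(n\Delta s)$, differs
  across channels. For image simulation the pixel grid is treated as
  common — the standard single-FFT approximation; resampling to a common
  physical pitch is left to the caller when physical registration across
  channels matters.
* Max-pooling breaks ties toward the first operand (deterministic);
  `clamp` passes gradients on the closed interval.
* The 2-D Gaussian PSF fit (`fwhm_gaussian_fit()`) uses
  Levenberg–Marquardt least squares with moment-based starts;
  non-convergence is flagged, not silently dropped.
* Pure-R training is CPU-bound: the full-width network on 512×512 patches
  is functional but slow; the package's own experiments run at the toy
  scale above. The module boundaries (PSF chain, loss, optimizer) are
  what a compiled or GPU backend would replace.
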