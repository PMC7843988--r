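---
title: "TEOIM models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEOIM models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teoim)
```

This vignette documents the physical models, numerical choices and design
decisions behind the package, in the spirit of a methods section: what is
modelled, what is assumed, and what passing the test suite does and does
not demonstrate about real measurements.

## The measurement being modelled

A thermo-elastic optical indicator microscope visualizes the magnetic
microwave near field around a sample. A glass indicator carrying a thin
conductive film sits in the field; surface currents induced by the
alternating magnetic field heat the film, heat diffuses into the glass,
and thermoelastic stress makes the glass birefringent. Circularly
polarized probe light reflected through the stressed glass becomes
elliptical, and two camera frames taken through an analyzer at 0° and 45°
encode the shear and normal-stress-difference channels respectively. The
sample of interest is a thin tube (1 mm bore) of NaCl or glucose solution:
the solution couples to and attenuates the field, so the imaged intensity
decreases with solute concentration, saturating at high concentration.

## Dielectric model

Solutions are described by a single-Debye relaxation plus an ionic
conductivity term,

$$\varepsilon'(c,\omega) = \varepsilon_\infty +
  \frac{\varepsilon_s(c)-\varepsilon_\infty}{1+(\omega\tau(c))^2},\qquad
\varepsilon''(c,\omega) =
  \frac{(\varepsilon_s(c)-\varepsilon_\infty)\,\omega\tau(c)}
       {1+(\omega\tau(c))^2} + \frac{\sigma(c)}{\omega\varepsilon_0},$$

with linear concentration laws $\varepsilon_s(c) = \varepsilon_{s0} - d\,c$,
$\tau(c) = \tau_0(1 + t\,c)$, $\sigma(c) = s\,c$. The water backbone uses
the standard 25 °C values $\varepsilon_{s0} = 78.4$,
$\varepsilon_\infty = 5.2$, $\tau_0 = 8.27$ ps. Measured permittivity
curves for these specific solutions are not tabulated in any accessible
form, so the solute slopes are phenomenological and user-adjustable:

* **NaCl** (`static_decrement = 0.15`, `conductivity_slope = 0.25` S/m per
  mg/ml, `tau_slope = -0.001`): dissociated ions bind water dipoles
  (static decrement) and carry ionic current. The conductivity slope is
  deliberately above the DC value of saline (≈ 13 S/m at 1.7 M) — it
  stands in for the total ionic loss at 12 GHz, and is chosen so that the
  attenuation exponent $2L/D_p(c)$ reaches its sublinear
  $\sqrt{\sigma c}$ regime within 0–100 mg/ml. That is what makes the
  NaCl response both *stronger* and *faster-saturating* than glucose, the
  qualitative behaviour this instrument class reports. At slopes below
  about 0.12 the NaCl response is nearly linear in $c$ and the fitted
  decay-scale ordering between the solutes inverts.
* **Glucose** (`static_decrement = 0.05`, `conductivity_slope = 0`,
  `tau_slope = 0.004`): a non-electrolyte; its loss grows only through a
  viscosity-driven increase of the relaxation time, so the response is
  much weaker. With $\omega\tau_0 \approx 0.62$ at 12 GHz, increasing
  $\tau$ moves the Debye loss peak toward the operating frequency, so
  $D_p(c)$ still decreases monotonically over the range (verified as a
  design check across 0–100 mg/ml).

Single-Debye only: no Cole–Cole or multi-Debye terms, no temperature
dependence, and no mixture model — the underlying measurement cannot
separate co-dissolved solutes, and neither does the package.

Penetration depth implements
$D_p = c/(\omega\sqrt{2\varepsilon'}\sqrt{\sqrt{1+(\varepsilon''/\varepsilon')^2}-1})$
with the inner square root evaluated as $r^2/(\sqrt{1+r^2}+1)$, which is
exact and avoids cancellation for small loss; the small-loss closed form
$c\sqrt{\varepsilon'}/(\omega\varepsilon'')$ is then reproduced to
rounding error. A lossless medium returns `Inf` rather than an error so
sanity cases compose downstream. The attenuation law is implemented as
printed in the field's convention for *power* density,
$P_l = P_0 e^{-2l/D_p}$; note the factor 2 is the field-vs-power
convention choice and is applied consistently everywhere (including the
tube-mode amplitude below).

## Forward model

The full-wave electromagnetic problem is out of scope. The near-field
intensity is parametric, chosen to reproduce the qualitative measured
patterns:

* a circular background lobe (isotropic 2-D Gaussian, peak
  `background_amplitude = 0.5`, width 3 mm) standing for the waveguide
  aperture mode seen with an empty tube;
* a tube-localized mode elongated along the tube axis (Gaussian, length
  scale 6 mm along x, half the 1 mm bore across), with peak amplitude

$$A = A_0\; g(f)\; S_{pol}\; e^{-2 L_{\mathrm{eff}}/D_p(\varepsilon(c,f))},$$

  where $g(f)$ is a Lorentzian of width 1 GHz centred at 12 GHz (the
  resonant coupling between tube and source), $S_{pol}$ is 1 for E-field
  parallel to the tube and 0.02 for perpendicular (the liquid barely
  perturbs the pattern in that orientation), and $L_{\mathrm{eff}}$
  defaults to the bore diameter (1 mm). Concentration enters *only*
  through $D_p(c)$ — the calibration fit downstream then discovers a
  saturating exponential rather than having one injected.

The resonance width matters: with the Debye water model $D_p(f)$ falls
across 7–15 GHz, so a broad resonance would drag the water-minus-background
contrast peak below the configured centre. The 1 GHz default keeps the
product $g(f)\,e^{-2L/D_p(f)}$ peaked at 12 GHz on an integer sweep grid.
The default amplitudes (0.5 background, 8.0 tube coupling) put the
tube-mode contribution in charge of the ROI signal, so the concentration
response dominates replicate drift at the default noise level.

**Heat source.** The film absorbs the magnetic field through surface
currents, so the deposited sheet power is pixelwise proportional to the
field intensity: $q = k\,|H|^2$.

**Thermoelastic stress.** Stress derives from a potential obeying a
biharmonic equation, $\nabla^4\phi = -\kappa\,q$, solved spectrally on a
periodic domain ($\hat\phi = -\kappa\hat q/|k|^4$, zero mode removed; the
subtracted mean of $q$ is reported), with
$\sigma_{xx} = -s\,\phi_{yy}$, $\sigma_{yy} = -s\,\phi_{xx}$,
$\sigma_{xy} = s\,\phi_{xy}$. Periodic boundaries are a modelling choice,
not physics: they make the reconstruction operator an exact discrete
inverse of the forward model and admit an analytic single-mode solution
and a dense-matrix oracle. Realistic (clamped/free) boundaries are out of
scope. On even grids, odd-order spectral derivatives zero the unpaired
Nyquist wavenumber — the standard spectral-differentiation convention
that keeps the multipliers Hermitian; without it the shear channel of a
generic rough field is silently symmetrized by the real part of the
inverse transform.

**Polarimetric rendering.** With circular input and analyzer angle $A$,
the Mueller chain gives
$I(A) = \tfrac{I_{full}}{2}(1 + \sin\delta\,\sin 2(A-\theta))$ with
retardance
$\delta = k_{pe}\sqrt{(\sigma_{xx}-\sigma_{yy})^2 + (2\sigma_{xy})^2}$ and
$\tan 2\theta = 2\sigma_{xy}/(\sigma_{xx}-\sigma_{yy})$. The channel
convention is fixed here and pinned by the round-trip test: the 45° frame
carries the normal-stress-difference channel and the 0° frame the shear
channel (with a sign flip on extraction). The default photoelastic
coefficient (0.06) keeps peak retardance near 0.2 rad under default
amplitudes; a warning fires beyond 0.3 rad, where the linearized
extraction degrades.

**Noise.** Additive Gaussian read noise per frame, i.i.d. across pixels,
averaged over `n_frames` (default 3000, matching the acquisition
protocol), plus one multiplicative illumination-drift factor per
replicate (sd 0.5 %) to produce replicate scatter for the sensitivity
analysis. The average of $n$ i.i.d. Gaussian frames is itself Gaussian
with sd $\sigma/\sqrt{n}$, so the averaged frame is sampled in a single
draw — an exact distributional identity, not an approximation. Every
simulated measurement is a pure function of its configuration and seed;
dataset generators derive per-cell seeds deterministically from the base
seed. What the generator does **not** emulate: camera optics (PSF,
vignetting), heat diffusion transients, spatially correlated or
non-Gaussian noise, drift within a replicate, and any full-wave field
structure. Tests passing on this generator therefore validate the
*analysis chain* — inversion, statistics, calibration — not the fidelity
of any parametric field shape to a particular instrument.

## Reconstruction

$\hat q = C(\partial_x^2\beta_1 - \partial_y^2\beta_1 +
2\,\partial_x\partial_y\beta_2)$, with derivatives in physical units from
the pixel pitch. Choices:

* **C is a single scalar** (default 1): it bundles the probe wavelength
  and indicator constants, which are not separately recoverable;
  `roundtrip_scale()` supplies the value that returns simulated data to
  heat-source units, playing the role of an absolute calibration.
* **Stencils**: second-order central differences by default (mixed
  derivative as composed central first differences, symmetric in x/y);
  spectral derivatives optionally, exact against the periodic forward
  model. No one-sided boundary stencils — a crop margin (default 2 px) is
  removed instead, because boundary artifacts otherwise dominate ROI
  statistics. Cropped maps carry their origin offset so physical
  coordinates survive.
* **Pre-smoothing**: the operator amplifies high-frequency noise
  quadratically, so a Gaussian pre-filter (periodic, spectral transfer
  $e^{-k^2\sigma^2/2}$) is applied identically to both channels; default
  1 px for noisy inputs, 0 for noise-free.

ROI statistics use half-open rectangles $[x_0,x_1)\times[y_0,y_1)$ in mm
over pixel centres, 0-based indexing, stated once and enforced
everywhere.

## Calibration and sensitivity

Replicate statistics are the plotted quantities: per-concentration mean
and $n-1$ standard deviation. The calibration model
$I(c) = B + A e^{-c/c_0}$ is fitted to the per-concentration *means*
(mirroring how such curves are presented; pooled fitting over all
replicates and $1/\mathrm{sd}^2$ weighting are options — whether the
original curve fits were weighted is not stated, so unweighted is the
default). The fit is deterministic: fixed initialization
($B_0 = \min$ mean, $A_0 = $ range, $c_{00} = $ half the concentration
span) and a Levenberg–Marquardt solve driven directly through
`minpack.lm::nls.lm`. Internally the decay scale is parametrized as
$\log c_0$: positivity holds by construction and the degenerate boundary
$c_0 \to 0$ (a step-function local minimum whose $c_0$-gradient
vanishes) is removed. Covariances come from the analytic Jacobian at the
solution. Non-convergence and degenerate (constant) data raise explicit
errors.

The sensitivity limit uses the analytic derivative of the *fitted* model,
$C_{min}(c) = |\Delta E_{max}\,(dI/dc)^{-1}| =
(\Delta E_{max} c_0/A)e^{c/c_0}$ — the formula is stated on the fitted
intensity function, so finite differences on raw data are not used (they
appear only as an independent oracle in the tests). Because the
margin-of-error definition of $\Delta E_{max}$ is ambiguous, two rules are
implemented and the choice is recorded in every output: `max_sd` (default,
largest replicate sd over concentrations) and `max_half_range` (largest
half-range). For any saturating decreasing fit ($A > 0$), $C_{min}$ rises
monotonically with concentration: sensitivity is best at low
concentration.

The frequency analysis is the elementwise sample-minus-background ROI
difference across the sweep; the argmax is the optimal operating
frequency, with ties broken toward the lowest frequency (documented and
tested).

## Problem sizes and verification

Unit and acceptance tests run at sizes chosen for sharp oracles: the
dense biharmonic comparison materializes the operator as a 256 × 256
matrix (16 × 16 grid) via explicit DFT Kronecker products and an SVD
pseudo-inverse; the forward/inverse round trip runs noise-free at
256 × 256 with a small photoelastic coefficient so the Mueller
linearization error ($\approx\delta^2/6$) sits below the $10^{-6}$
round-trip tolerance; the replicated synthetic study runs at 96 × 48
pixels over the 20 mm × 8 mm field of view, 11 concentrations × 5
replicates; the demo uses 128 × 64. Monte-Carlo parameter recovery uses
100 repeats of 1 % noise on 5 replicates. All randomness is seeded; the
acceptance script threads a single `--seed` through every stage.

## Known limitations

* The near-field shapes are parametric stand-ins; absolute intensities
  and the tube-coupling resonance are phenomenological.
* Periodic thermoelastic boundaries; no absolute calibration of $C$.
* Single-Debye dielectrics with linear concentration laws; no mixtures,
  no temperature dependence.
* The 16-bit frame format quantizes intensities to $2^{-16}$ of full
  scale; reconstructed maps are stored as float32 TIFF losslessly.
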