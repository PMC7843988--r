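# teoim

Simulation and analysis toolkit for **thermo-elastic optical indicator
microscopy (TEOIM)** of microwave near fields around aqueous solutions.

TEOIM images the magnetic microwave near field (H-MWNF) around a sample
without scanning: a glass slide coated with a thin conductive (ITO) film is
placed in the field, the film absorbs magnetic-field energy through induced
surface currents and heats the glass, and the resulting thermoelastic
stresses are read out photoelastically with circularly polarized light and
an analyzer at two orientations (0° and 45°). Because a lossy solution
(NaCl, glucose) attenuates the microwave field that reaches the indicator,
the imaged intensity falls as solute concentration rises — which turns the
microscope into a contact-free concentration sensor for ionic and
non-ionic solutes in the 0–100 mg/ml range. The package is aimed at
researchers developing or validating such polarimetric near-field imaging
pipelines: it provides a physics-based synthetic data generator with known
ground truth, the inverse reconstruction, and the full concentration
calibration analysis.

## What it computes

**Heat-source reconstruction.** The two linear-birefringence images
β₁ (normal-stress channel) and β₂ (shear channel), extracted from
baseline-subtracted analyzer frames, determine the heat-source density
deposited in the indicator film:

    q(x, y) = C ( ∂²β₁/∂x² − ∂²β₁/∂y² + 2 ∂²β₂/∂x∂y )

implemented with second-order central stencils or exact spectral
derivatives (`reconstruct_heat_source()`). On the package's own forward
model this operator is an exact discrete inverse.

**Dielectric absorption.** Solutions are modelled by a single-Debye +
conductivity permittivity ε\*(c, ω) (`complex_permittivity()`); microwave
power decays into a lossy medium as

    P(l) = P₀ exp(−2 l / Dp),
    Dp = c / ( ω √(2ε′) √( √(1 + (ε″/ε′)²) − 1 ) )

(`power_density_profile()`, `penetration_depth()`).

**Calibration and sensitivity.** ROI intensities across a replicated
concentration series are fitted with the saturating model
I(c) = B + A·exp(−c/c₀) (`fit_exponential()`), and the minimum detectable
concentration follows from the fitted curve:

    Cmin(c) = | ΔEmax · (dI/dc)⁻¹ | = (ΔEmax · c₀ / A) · exp(c/c₀)

with ΔEmax the maximum replicate fluctuation
(`min_detectable_concentration()`, `delta_e_max_from_series()`).

**Forward simulation.** `simulate_measurement()` composes a parametric
microwave near field (circular background lobe + tube-localized mode
attenuated by exp(−2L/Dp(c))), the heat source, a periodic spectral
plane-stress thermoelastic solve, and a circular-input Mueller polariscope
with frame-averaged camera noise — yielding analyzer frame sets with the
statistical structure the analysis assumes and a known ground-truth q.

## Worked example

Simulate the replicated NaCl concentration experiment (0–100 mg/ml,
5 replicates, 12 GHz), reconstruct the heat source in each image, and run
the calibration analysis:

```r
library(teoim)

ds <- generate_concentration_dataset(
  permittivity_spec("nacl"), seq(0, 100, 10), replicates = 5,
  noise = noise_config(seed = 42), grid = grid_spec(96, 48, 20 / 96))
series <- measure_roi_series(ds)   # solute, concentration, replicate, roi_mean
fit <- fit_exponential(series)
fit
#> <teoim_calfit: nacl> I(c) = B + A exp(-c/c0)
#>   A = 0.28578, c0 = 52.608 mg/ml, B = 0.20353 (residual sigma 0.000845, n = 11)

tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 A        0.286   0.00159
#> 2 c0      52.6     0.733
#> 3 B        0.204   0.00178

de <- delta_e_max_from_series(series)          # max replicate sd = 0.003987
min_detectable_concentration(fit, de, at_concentrations = c(0, 10, 20))
#> # A tibble: 3 × 2
#>   concentration_mg_ml cmin_mg_ml
#>                 <dbl>      <dbl>
#> 1                   0      0.734
#> 2                  10      0.888
#> 3                  20      1.07
```

The ROI intensity falls monotonically and saturates with concentration
(decay scale c₀ ≈ 53 mg/ml for NaCl), and the minimum detectable NaCl
concentration at low c is below 1 mg/ml, rising with concentration as the
calibration curve flattens. `autoplot(fit)` draws the calibration curve
with replicate error bars; `run_demo(seed, out_dir)` (or the `demo` CLI
subcommand) runs the whole study — frequency sweep, both solutes, fits and
sensitivity curves — and writes CSV/JSON outputs.

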