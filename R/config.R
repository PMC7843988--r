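#' Measurement scene configuration
#'
#' Describes one microwave exposure scene: the frequency, the orientation of
#' the E-field polarization relative to the sample tube, the tube geometry,
#' and the parametric near-field shape parameters (a circularly symmetric
#' background lobe from the waveguide aperture plus a tube-elongated coupled
#' mode whose amplitude follows a Lorentzian resonance and the dielectric
#' attenuation across the liquid column).
#'
#' @param frequency_GHz Operating frequency in GHz.
#' @param polarization `"parallel"` (E-field along the tube) or
#'   `"perpendicular"`.
#' @param tube_inner_diameter_mm,tube_outer_diameter_mm Tube bore and outer
#'   diameter in mm (defaults 1.0 and 1.5).
#' @param tube_filled Logical; `FALSE` models the empty (background-only)
#'   tube.
#' @param background_amplitude Peak of the circular background field
#'   intensity pattern (arbitrary units).
#' @param background_width_mm Gaussian width (sd) of the background lobe, mm.
#' @param tube_coupling_amplitude Peak coupling amplitude of the tube mode at
#'   resonance before dielectric attenuation.
#' @param tube_length_scale_mm Gaussian length scale of the tube mode along
#'   the tube axis (x), mm.
#' @param resonance_center_GHz Centre of the Lorentzian coupling resonance
#'   (default 12, the optimum operating frequency).
#' @param resonance_width_GHz Half-width of the Lorentzian, GHz.
#' @param effective_path_mm Effective microwave path through the liquid used
#'   in the attenuation factor `exp(-2 path / Dp)`; defaults to the inner
#'   diameter.
#' @param perpendicular_suppression Multiplier applied to the tube-mode
#'   amplitude when the polarization is perpendicular to the tube (default
#'   0.02: the liquid then has a negligible effect on the field pattern).
#' @return A `teoim_scene` list.
#' @export
scene_config <- function(frequency_GHz = 12,
                         polarization = c("parallel", "perpendicular"),
                         tube_inner_diameter_mm = 1.0,
                         tube_outer_diameter_mm = 1.5,
                         tube_filled = TRUE,
                         background_amplitude = 0.5,
                         background_width_mm = 3.0,
                         tube_coupling_amplitude = 8.0,
                         tube_length_scale_mm = 6.0,
                         resonance_center_GHz = 12,
                         resonance_width_GHz = 1.0,
                         effective_path_mm = NULL,
                         perpendicular_suppression = 0.02) {
  polarization <- match.arg(polarization)
  effective_path_mm <- effective_path_mm %||% tube_inner_diameter_mm
  if (tube_inner_diameter_mm <= 0 || tube_outer_diameter_mm <= 0 ||
      tube_inner_diameter_mm >= tube_outer_diameter_mm)
    abort("scene_config: need 0 < inner diameter < outer diameter")
  if (resonance_width_GHz <= 0)
    abort("scene_config: resonance_width_GHz must be > 0")
  if (frequency_GHz <= 0) abort("scene_config: frequency_GHz must be > 0")
  if (background_amplitude < 0 || tube_coupling_amplitude < 0)
    abort("scene_config: amplitudes must be >= 0")
  structure(list(
    frequency_GHz = frequency_GHz, polarization = polarization,
    tube_inner_diameter_mm = tube_inner_diameter_mm,
    tube_outer_diameter_mm = tube_outer_diameter_mm,
    tube_filled = isTRUE(tube_filled),
    background_amplitude = background_amplitude,
    background_width_mm = background_width_mm,
    tube_coupling_amplitude = tube_coupling_amplitude,
    tube_length_scale_mm = tube_length_scale_mm,
    resonance_center_GHz = resonance_center_GHz,
    resonance_width_GHz = resonance_width_GHz,
    effective_path_mm = effective_path_mm,
    perpendicular_suppression = perpendicular_suppression
  ), class = "teoim_scene")
}

#' Camera noise model configuration
#'
#' Additive Gaussian read noise per frame (i.i.d. across pixels), averaged
#' over `n_frames` exposures, plus one multiplicative illumination-drift
#' factor per replicate. The defaults mirror the acquisition protocol: each
#' stored image is the average of 3000 camera frames.
#'
#' @param read_noise_sigma Per-frame read noise, as a fraction of full scale
#'   (>= 0).
#' @param n_frames Number of averaged frames (>= 1; default 3000).
#' @param replicate_drift_sigma Standard deviation of the multiplicative
#'   per-replicate illumination drift (>= 0).
#' @param seed Integer RNG seed; every simulated measurement is a pure
#'   function of its inputs and this seed.
#' @return A `teoim_noise` list.
#' @export
noise_config <- function(read_noise_sigma = 0.01, n_frames = 3000L,
                         replicate_drift_sigma = 0.005, seed = 1L) {
  if (read_noise_sigma < 0 || replicate_drift_sigma < 0)
    abort("noise_config: noise sigmas must be >= 0")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    abort("noise_config: n_frames must be an integer >= 1")
  structure(list(read_noise_sigma = read_noise_sigma, n_frames = n_frames,
                 replicate_drift_sigma = replicate_drift_sigma,
                 seed = as.integer(seed)),
            class = "teoim_noise")
}

#' Indicator and optics constants of the simulated instrument
#'
#' Scalar constants of the forward chain: conversion from field intensity to
#' deposited sheet power, thermoelastic coupling, the shared stress scale,
#' the photoelastic stress-to-retardance coefficient, and the full-scale
#' illumination level. The photoelastic coefficient default keeps peak
#' retardance well inside the linear regime (delta << 0.3 rad) for
#' default scene amplitudes.
#'
#' @param sheet_coefficient Heat-source density per unit field intensity
#'   (>= 0).
#' @param coupling Thermoelastic coupling constant.
#' @param stress_scale Shared stress scale.
#' @param photoelastic_coefficient Retardance (rad) per unit stress
#'   difference.
#' @param i_full Full-scale intensity of the illumination (frames are stored
#'   in `[0, 1]` full-scale units).
#' @param gain Dimensionless gain applied when extracting birefringence
#'   channels from frames.
#' @return A `teoim_sim_params` list.
#' @export
sim_params <- function(sheet_coefficient = 1, coupling = 1, stress_scale = 1,
                       photoelastic_coefficient = 0.06, i_full = 1, gain = 1) {
  if (sheet_coefficient < 0)
    abort("sim_params: sheet_coefficient must be >= 0")
  if (i_full <= 0) abort("sim_params: i_full must be > 0")
  structure(list(sheet_coefficient = sheet_coefficient, coupling = coupling,
                 stress_scale = stress_scale,
                 photoelastic_coefficient = photoelastic_coefficient,
                 i_full = i_full, gain = gain),
            class = "teoim_sim_params")
}

#' Reconstruction configuration
#'
#' Controls the second-derivative heat-source reconstruction: the overall
#' calibration scalar `C` (absolute heat units are not recoverable without
#' the indicator material constants, so `C` is a single user-supplied
#' scale), the differentiation stencil, optional Gaussian pre-smoothing
#' (the differential operator amplifies high-frequency noise), and the
#' interior crop margin excluded from outputs.
#'
#' @param scale_c Calibration constant `C` (nonzero).
#' @param stencil `"central"` (second-order central differences) or
#'   `"spectral"` (FFT derivatives; exact inverse of the periodic forward
#'   model).
#' @param presmooth_sigma_px Gaussian pre-smoothing width in pixels (0 = off).
#'   Applied identically to both birefringence channels. A width of 1 px is
#'   a good default for noisy inputs.
#' @param crop_margin_px Margin (pixels) cropped from the reconstruction;
#'   must cover the stencil half-width (>= 1 for central differences).
#' @return A `teoim_recon_config` list.
#' @export
recon_config <- function(scale_c = 1,
                         stencil = c("central", "spectral"),
                         presmooth_sigma_px = 0,
                         crop_margin_px = 2L) {
  stencil <- match.arg(stencil)
  if (!is.numeric(scale_c) || scale_c == 0 || !is.finite(scale_c))
    abort("recon_config: scale_c must be a nonzero finite number")
  crop_margin_px <- as.integer(crop_margin_px)
  min_margin <- if (stencil == "central") 1L else 0L
  if (is.na(crop_margin_px) || crop_margin_px < min_margin)
    abort(sprintf("recon_config: crop_margin_px must be >= %d for the %s stencil",
                  min_margin, stencil))
  if (presmooth_sigma_px < 0)
    abort("recon_config: presmooth_sigma_px must be >= 0")
  structure(list(scale_c = scale_c, stencil = stencil,
                 presmooth_sigma_px = presmooth_sigma_px,
                 crop_margin_px = crop_margin_px),
            class = "teoim_recon_config")
}

#' Reconstruction scale that inverts the forward model
#'
#' The forward chain maps `q` to birefringence channels with an overall
#' factor `gain * photoelastic_coefficient * stress_scale * (-coupling)`;
#' setting the reconstruction constant `C` to the reciprocal of that factor
#' makes the reconstruction recover `q` (minus its mean) in its original
#' units. This plays the role of an absolute calibration of `C` from known
#' indicator constants.
#'
#' @param params A [sim_params()] object.
#' @return The value of `C` for [recon_config()].
#' @export
roundtrip_scale <- function(params) {
  -1 / (params$gain * params$photoelastic_coefficient *
          params$stress_scale * params$coupling)
}
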