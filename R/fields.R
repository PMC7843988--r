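# Parametric microwave near-field model. The full-wave electromagnetic
# problem is out of scope; the field-intensity patterns are parametric
# shapes chosen to reproduce the qualitative behaviour of the measured
# distributions: a circular background lobe from the waveguide aperture,
# and a tube-elongated localized mode whose amplitude carries the physics
# (resonant coupling and dielectric attenuation in the liquid).

gaussian2d <- function(grid, amplitude, sigma_x_mm, sigma_y_mm) {
  ext <- grid_extent(grid)
  xs <- grid_x(grid) - ext["x_mm"] / 2
  ys <- grid_y(grid) - ext["y_mm"] / 2
  gx <- exp(-xs^2 / (2 * sigma_x_mm^2))
  gy <- exp(-ys^2 / (2 * sigma_y_mm^2))
  amplitude * outer(gy, gx)
}

#' Background magnetic near-field intensity pattern
#'
#' Circularly symmetric field-intensity lobe centred on the waveguide
#' aperture axis (the pattern observed with an empty tube, reflecting the
#' fundamental waveguide mode), modelled as an isotropic 2-D Gaussian with
#' peak `background_amplitude` and width `background_width_mm`.
#'
#' @param grid A [grid_spec()].
#' @param scene A [scene_config()].
#' @return A `teoim_field` with role `"field_intensity"`.
#' @export
background_field <- function(grid, scene) {
  stopifnot(inherits(grid, "teoim_grid"), inherits(scene, "teoim_scene"))
  v <- gaussian2d(grid, scene$background_amplitude,
                  scene$background_width_mm, scene$background_width_mm)
  field_map(v, grid, role = "field_intensity")
}

# Lorentzian resonance profile, 1 at the centre
lorentzian_gain <- function(f_GHz, center_GHz, width_GHz) {
  1 / (1 + ((f_GHz - center_GHz) / width_GHz)^2)
}

#' Tube-localized near-field intensity pattern
#'
#' Anisotropic field-intensity mode localized around a liquid-filled tube
#' and elongated along the tube axis (x). Its peak amplitude carries the
#' measurement physics:
#' \deqn{A = A_0 \; g(f) \; S_{pol} \; e^{-2 L_{eff} / D_p(\varepsilon)},}
#' where \eqn{g(f)} is a Lorentzian resonance peaked at
#' `resonance_center_GHz`, \eqn{S_{pol}} is the perpendicular-polarization
#' suppression factor (the liquid barely perturbs the field when the
#' E-field is perpendicular to the tube), and the exponential is the
#' dielectric power attenuation across the effective liquid path, with
#' \eqn{D_p} from [penetration_depth()]. An empty tube contributes nothing.
#'
#' @param grid A [grid_spec()].
#' @param scene A [scene_config()].
#' @param eps Either a one-row tibble from [complex_permittivity()] or a
#'   numeric `c(eps_real, eps_imag)`.
#' @return A `teoim_field` with role `"field_intensity"`.
#' @export
tube_field <- function(grid, scene, eps) {
  stopifnot(inherits(grid, "teoim_grid"), inherits(scene, "teoim_scene"))
  if (!scene$tube_filled)
    return(field_map(matrix(0, grid$ny, grid$nx), grid, "field_intensity"))
  if (is.data.frame(eps)) {
    er <- eps$eps_real[1]; ei <- eps$eps_imag[1]
  } else {
    er <- eps[[1]]; ei <- eps[[2]]
  }
  dp_mm <- penetration_depth(er, ei, scene$frequency_GHz * 1e9) * 1e3
  g <- lorentzian_gain(scene$frequency_GHz, scene$resonance_center_GHz,
                       scene$resonance_width_GHz)
  pol <- if (scene$polarization == "perpendicular")
    scene$perpendicular_suppression else 1
  amp <- scene$tube_coupling_amplitude * g * pol *
    exp(-2 * scene$effective_path_mm / dp_mm)
  v <- gaussian2d(grid, amp, scene$tube_length_scale_mm,
                  scene$tube_inner_diameter_mm / 2)
  out <- field_map(v, grid, role = "field_intensity")
  attr(out, "peak_amplitude") <- amp
  out
}

#' Heat-source density deposited in the indicator film
#'
#' The conductive film absorbs the alternating magnetic field through
#' induced surface currents, so the deposited sheet power follows the field
#' intensity pixelwise: `q = sheet_coefficient * |H|^2`.
#'
#' @param h2 A `teoim_field` with role `"field_intensity"`.
#' @param sheet_coefficient Power per unit field intensity (>= 0).
#' @return A `teoim_field` with role `"heat_source"`.
#' @export
heat_source_from_field <- function(h2, sheet_coefficient = 1) {
  if (!inherits(h2, "teoim_field") || field_role(h2) != "field_intensity")
    abort("heat_source_from_field: h2 must be a field_intensity teoim_field")
  if (!is.numeric(sheet_coefficient) || sheet_coefficient < 0)
    abort("heat_source_from_field: sheet_coefficient must be >= 0")
  field_map(sheet_coefficient * unclass(h2), field_grid(h2), "heat_source")
}
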