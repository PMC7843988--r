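#' Solute permittivity parametrization
#'
#' Single-Debye-plus-conductivity model of the complex permittivity of an
#' aqueous solution as a function of solute concentration. The pure-water
#' Debye backbone (static permittivity, high-frequency limit, relaxation
#' time) is perturbed linearly in concentration:
#' \deqn{\varepsilon_s(c) = \varepsilon_{s0} - d \, c, \quad
#'       \tau(c) = \tau_0 (1 + t \, c), \quad
#'       \sigma(c) = s \, c,}
#' with decrement `d` (per mg/ml), fractional relaxation-time slope `t`
#' (per mg/ml) and ionic conductivity slope `s` (S/m per mg/ml).
#'
#' Defaults encode water at 25 degrees C (eps_s = 78.4, eps_inf = 5.2,
#' tau = 8.27 ps) and phenomenological solute slopes: NaCl dissociates into
#' ions, contributing strong ionic conductivity (about 8.5 S/m at 100 mg/ml)
#' and a marked static decrement from hydration-shell binding of water
#' dipoles; glucose is a non-electrolyte, so its loss grows only through a
#' viscosity-driven increase of the relaxation time, giving a much weaker
#' concentration response. These stand in for solution permittivity curves
#' that are not tabulated anywhere; all parameters are user-adjustable.
#'
#' @param solute `"water"`, `"nacl"` or `"glucose"`; selects default slopes.
#' @param eps_static Static (low-frequency) relative permittivity at c = 0.
#' @param eps_inf High-frequency relative permittivity limit (>= 1).
#' @param tau_s Debye relaxation time in seconds.
#' @param static_decrement Decrease of eps_static per mg/ml.
#' @param conductivity_slope Ionic conductivity in S/m per mg/ml (>= 0).
#' @param tau_slope Fractional change of tau per mg/ml.
#' @return A `teoim_permittivity_spec`.
#' @export
#' @examples
#' permittivity_spec("nacl")
#' complex_permittivity(permittivity_spec("water"), 0, 12e9)
permittivity_spec <- function(solute = c("water", "nacl", "glucose"),
                              eps_static = 78.4, eps_inf = 5.2,
                              tau_s = 8.27e-12,
                              static_decrement = NULL,
                              conductivity_slope = NULL,
                              tau_slope = NULL) {
  solute <- match.arg(solute)
  defaults <- switch(solute,
    water   = list(static_decrement = 0,    conductivity_slope = 0,     tau_slope = 0),
    nacl    = list(static_decrement = 0.15, conductivity_slope = 0.25, tau_slope = -0.001),
    glucose = list(static_decrement = 0.05, conductivity_slope = 0,     tau_slope = 0.004)
  )
  static_decrement   <- static_decrement   %||% defaults$static_decrement
  conductivity_slope <- conductivity_slope %||% defaults$conductivity_slope
  tau_slope          <- tau_slope          %||% defaults$tau_slope
  if (!(eps_static > eps_inf && eps_inf >= 1))
    abort("permittivity_spec: need eps_static > eps_inf >= 1")
  if (tau_s <= 0) abort("permittivity_spec: tau_s must be positive")
  if (conductivity_slope < 0)
    abort("permittivity_spec: conductivity_slope must be >= 0")
  structure(list(solute = solute, eps_static = eps_static, eps_inf = eps_inf,
                 tau_s = tau_s, static_decrement = static_decrement,
                 conductivity_slope = conductivity_slope,
                 tau_slope = tau_slope),
            class = "teoim_permittivity_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.teoim_permittivity_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<teoim_permittivity_spec: %s>\n",
    "  eps_s(0) = %.3g, eps_inf = %.3g, tau = %.4g ps\n",
    "  d eps_s/dc = -%.3g /(mg/ml), sigma slope = %.3g S/m/(mg/ml), ",
    "tau slope = %.3g /(mg/ml)\n"),
    x$solute, x$eps_static, x$eps_inf, x$tau_s * 1e12,
    x$static_decrement, x$conductivity_slope, x$tau_slope))
  invisible(x)
}

#' Complex permittivity at given concentration and frequency
#'
#' Evaluates the Debye-plus-conductivity model
#' \deqn{\varepsilon' = \varepsilon_\infty +
#'       \frac{\varepsilon_s(c)-\varepsilon_\infty}{1+(\omega\tau(c))^2},\qquad
#'       \varepsilon'' = \frac{(\varepsilon_s(c)-\varepsilon_\infty)\,
#'       \omega\tau(c)}{1+(\omega\tau(c))^2} +
#'       \frac{\sigma(c)}{\omega \varepsilon_0}.}
#'
#' @param spec A [permittivity_spec()].
#' @param concentration Solute concentration(s), mg/ml, >= 0.
#' @param frequency Frequency(ies), Hz, > 0. Recycled against
#'   `concentration`.
#' @return Tibble with `concentration`, `frequency`, `eps_real`, `eps_imag`.
#' @export
complex_permittivity <- function(spec, concentration, frequency) {
  stopifnot(inherits(spec, "teoim_permittivity_spec"))
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0))
    abort("complex_permittivity: concentration must be finite and >= 0")
  if (!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0))
    abort("complex_permittivity: frequency must be finite and > 0")
  n <- max(length(concentration), length(frequency))
  cc <- rep_len(concentration, n)
  ff <- rep_len(frequency, n)

  eps_s <- spec$eps_static - spec$static_decrement * cc
  tau   <- spec$tau_s * (1 + spec$tau_slope * cc)
  sigma <- spec$conductivity_slope * cc
  if (any(eps_s <= spec$eps_inf) || any(tau <= 0))
    abort(paste("complex_permittivity: concentration outside the supported",
                "range of this parametrization (eps_s(c) <= eps_inf or tau(c) <= 0)"))
  w  <- 2 * pi * ff
  wt <- w * tau
  de <- eps_s - spec$eps_inf
  eps_real <- spec$eps_inf + de / (1 + wt^2)
  eps_imag <- de * wt / (1 + wt^2) + sigma / (w * .const$eps0)
  tibble::tibble(concentration = cc, frequency = ff,
                 eps_real = eps_real, eps_imag = eps_imag)
}

#' Microwave penetration depth in a lossy dielectric
#'
#' Depth scale of power absorption,
#' \deqn{D_p = \frac{c}{\omega\sqrt{2\varepsilon'}\,
#'   \sqrt{\sqrt{1+(\varepsilon''/\varepsilon')^2}-1}},}
#' evaluated in a numerically stable form
#' (\eqn{\sqrt{1+r^2}-1 = r^2/(\sqrt{1+r^2}+1)}) so that the small-loss
#' asymptote \eqn{D_p \to c\sqrt{\varepsilon'}/(\omega\varepsilon'')} is
#' reproduced to rounding error. A lossless medium
#' (`eps_imag = 0`) returns `Inf`.
#'
#' @param eps_real Real relative permittivity, > 0. Vectorized.
#' @param eps_imag Imaginary relative permittivity, >= 0. Vectorized.
#' @param frequency Frequency in Hz, > 0. Vectorized.
#' @return Penetration depth(s) in metres (`Inf` where `eps_imag == 0`).
#' @export
#' @examples
#' penetration_depth(77, 13, 12e9)
penetration_depth <- function(eps_real, eps_imag, frequency) {
  if (!is.numeric(eps_real) || any(!is.finite(eps_real)) || any(eps_real <= 0))
    abort("penetration_depth: eps_real must be finite and > 0")
  if (!is.numeric(eps_imag) || any(!is.finite(eps_imag)) || any(eps_imag < 0))
    abort("penetration_depth: eps_imag must be finite and >= 0")
  if (!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0))
    abort("penetration_depth: frequency must be finite and > 0")
  n <- max(length(eps_real), length(eps_imag), length(frequency))
  er <- rep_len(eps_real, n); ei <- rep_len(eps_imag, n)
  f  <- rep_len(frequency, n)
  w <- 2 * pi * f
  r <- ei / er
  # sqrt(1 + r^2) - 1, stable for r -> 0
  s <- r^2 / (sqrt(1 + r^2) + 1)
  dp <- .const$speed_of_light / (w * sqrt(2 * er) * sqrt(s))
  dp[ei == 0] <- Inf
  dp
}

#' Absorbed power density versus depth
#'
#' Exponential attenuation of the volume power density inside a lossy
#' dielectric, \eqn{P_l = P_0 \exp(-2 l / D_p)}, evaluated at the requested
#' depths. An infinite penetration depth (lossless medium) gives a constant
#' profile.
#'
#' @param p0 Surface volume power density, W/m^3, >= 0.
#' @param dp Penetration depth in metres, > 0 (may be `Inf`).
#' @param depths Depths `l` in metres, >= 0.
#' @return A `teoim_propagation` tibble with `depth_m` and
#'   `power_density_w_m3`; attributes `penetration_depth_m` and
#'   `surface_power_density`.
#' @export
#' @examples
#' power_density_profile(1e6, 1e-3, c(0, 5e-4, 1e-3))
power_density_profile <- function(p0, dp, depths) {
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) || p0 < 0)
    abort("power_density_profile: p0 must be a single number >= 0")
  if (!is.numeric(dp) || length(dp) != 1L || is.na(dp) || dp <= 0)
    abort("power_density_profile: dp must be positive (possibly Inf)")
  if (!is.numeric(depths) || any(!is.finite(depths)) || any(depths < 0))
    abort("power_density_profile: depths must be finite and >= 0")
  pl <- if (is.infinite(dp)) rep(p0, length(depths)) else p0 * exp(-2 * depths / dp)
  out <- tibble::tibble(depth_m = as.numeric(depths), power_density_w_m3 = pl)
  structure(out, penetration_depth_m = dp, surface_power_density = p0,
            class = c("teoim_propagation", class(out)))
}
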