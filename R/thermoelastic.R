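# Spectral plane-stress thermoelastic solver.
#
# The indicator glass responds to a deposited heat-source density q(x, y)
# with in-plane stresses derived from an Airy-type potential phi obeying a
# biharmonic equation, here posed on a periodic domain and inverted exactly
# in Fourier space. This closure is what makes the second-derivative
# reconstruction operator an exact discrete inverse of the forward model.

ifft2_real <- function(X) Re(fft(X, inverse = TRUE)) / length(X)

# spectral wavenumber grids (rad/mm) for an ny x nx array; `d1` variants
# carry the Nyquist-zeroed wavenumbers used for odd-order derivatives
k_grids <- function(grid) {
  kx <- k_angular(grid$nx, grid$pitch_mm)
  ky <- k_angular(grid$ny, grid$pitch_mm)
  kx1 <- k_angular(grid$nx, grid$pitch_mm, nyquist_zero = TRUE)
  ky1 <- k_angular(grid$ny, grid$pitch_mm, nyquist_zero = TRUE)
  list(kx = matrix(kx, grid$ny, grid$nx, byrow = TRUE),
       ky = matrix(ky, grid$ny, grid$nx),
       kx1 = matrix(kx1, grid$ny, grid$nx, byrow = TRUE),
       ky1 = matrix(ky1, grid$ny, grid$nx))
}

# spectral partial derivative of a real ny x nx matrix; orders dx, dy.
# Odd orders use the Nyquist-zeroed wavenumbers so the multiplier keeps the
# Hermitian symmetry of a real field.
spectral_derivative <- function(values, grid, dx = 0L, dy = 0L) {
  kk <- k_grids(grid)
  mx <- if (dx %% 2L == 1L) kk$kx1 else kk$kx
  my <- if (dy %% 2L == 1L) kk$ky1 else kk$ky
  mult <- (1i * mx)^dx * (1i * my)^dy
  ifft2_real(mult * fft(values))
}

#' Thermoelastic stress field
#'
#' Container for the in-plane stress components and the generating
#' potential produced by [solve_thermoelastic()].
#'
#' @name stress_field
#' @format A `teoim_stress` list with matrices `sigma_xx`, `sigma_yy`,
#'   `sigma_xy`, `phi`, the `grid`, and attributes `coupling`,
#'   `stress_scale`, `subtracted_mean`.
NULL

#' Solve the plane-stress thermoelastic problem for a heat source
#'
#' Computes the stress response of the indicator to a heat-source density
#' map by inverting the biharmonic potential equation
#' \eqn{\nabla^4 \phi = -\kappa\, q} spectrally on a periodic domain
#' (\eqn{\hat\phi = -\kappa \hat q / |k|^4}, zero mode removed) and forming
#' \deqn{\sigma_{xx} = -s\,\partial^2\phi/\partial y^2,\quad
#'       \sigma_{yy} = -s\,\partial^2\phi/\partial x^2,\quad
#'       \sigma_{xy} = s\,\partial^2\phi/\partial x \partial y.}
#' The mean of `q` (not representable on a periodic domain) is subtracted
#' before the solve and reported in the result. Stresses are in arbitrary
#' consistent units; one shared scale `stress_scale` and the coupling
#' \eqn{\kappa} multiply the whole field.
#'
#' @param q A `teoim_field` with role `"heat_source"` (finite values).
#' @param coupling Thermoelastic coupling constant \eqn{\kappa} (> 0).
#' @param stress_scale Shared stress scale `s`.
#' @return A `teoim_stress` object; `attr(, "subtracted_mean")` records the
#'   removed constant.
#' @export
solve_thermoelastic <- function(q, coupling = 1, stress_scale = 1) {
  if (!inherits(q, "teoim_field"))
    abort("solve_thermoelastic: q must be a teoim_field")
  if (!all(is.finite(q))) abort("solve_thermoelastic: q must be finite")
  grid <- field_grid(q)
  qm <- mean(q)
  qc <- unclass(q) - qm
  kk <- k_grids(grid)
  k2 <- kk$kx^2 + kk$ky^2
  k4 <- k2^2
  Q <- fft(qc)
  phihat <- -coupling * Q / k4
  phihat[1, 1] <- 0 + 0i  # zero mode: potential defined up to a constant
  phi_yy <- ifft2_real((1i * kk$ky)^2 * phihat)
  phi_xx <- ifft2_real((1i * kk$kx)^2 * phihat)
  phi_xy <- ifft2_real((1i * kk$kx1) * (1i * kk$ky1) * phihat)
  structure(list(
    sigma_xx = -stress_scale * phi_yy,
    sigma_yy = -stress_scale * phi_xx,
    sigma_xy =  stress_scale * phi_xy,
    phi = ifft2_real(phihat),
    grid = grid
  ), coupling = coupling, stress_scale = stress_scale, subtracted_mean = qm,
     class = "teoim_stress")
}

#' @export
print.teoim_stress <- function(x, ...) {
  cat(sprintf(
    "<teoim_stress> %d x %d px; max |sxx - syy| = %.4g, max |sxy| = %.4g\n",
    x$grid$ny, x$grid$nx, max(abs(x$sigma_xx - x$sigma_yy)),
    max(abs(x$sigma_xy))))
  invisible(x)
}
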