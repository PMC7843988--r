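# Independent oracles used across the suite. None of these call the
# package's FFT-based code paths.

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Dense materialization of the periodic spectral biharmonic inverse:
# explicit 1-D DFT matrices, Kronecker product, SVD pseudo-inverse.
dense_biharmonic_phi <- function(q, grid, coupling = 1) {
  nx <- grid$nx; ny <- grid$ny; d <- grid$pitch_mm
  dft <- function(n) {
    j <- 0:(n - 1)
    exp(-2i * pi * outer(j, j) / n)
  }
  Wx <- dft(nx); Wy <- dft(ny)
  F2 <- kronecker(Wx, Wy)                      # vec is column-major, iy fast
  F2inv <- kronecker(Conj(Wx) / nx, Conj(Wy) / ny)
  kx <- 2 * pi * c(0:(ceiling(nx / 2) - 1), -(floor(nx / 2)):-1) / (nx * d)
  ky <- 2 * pi * c(0:(ceiling(ny / 2) - 1), -(floor(ny / 2)):-1) / (ny * d)
  k4 <- as.vector(outer(ky^2, kx^2, `+`)^2)    # [iy, ix], iy fast
  M <- Re(F2inv %*% (k4 * F2))                 # real operator
  qc <- as.vector(q - mean(q))
  phi <- MASS::ginv(M) %*% (-coupling * qc)
  matrix(phi, ny, nx)
}

# Debye + conductivity permittivity via complex arithmetic (independent of
# the package's real-valued formulas).
debye_complex_oracle <- function(eps_s, eps_inf, tau, sigma, f) {
  w <- 2 * pi * f
  eps <- eps_inf + (eps_s - eps_inf) / (1 + 1i * w * tau)
  c(eps_real = Re(eps),
    eps_imag = -Im(eps) + sigma / (w * 8.8541878128e-12))
}

# Step-by-step penetration-depth evaluation following the printed formula
# literally (no algebraic rearrangement).
dp_literal_oracle <- function(eps_r, eps_i, f) {
  w <- 2 * pi * f
  ratio <- eps_i / eps_r
  inner <- sqrt(1 + ratio^2) - 1
  299792458 / (w * sqrt(2 * eps_r) * sqrt(inner))
}

# Direct Mueller-chain intensity at analyzer angle A (radians)
mueller_intensity <- function(delta, theta, A, i_full = 1) {
  i_full / 2 * (1 + sin(delta) * sin(2 * (A - theta)))
}

# Build a stress object by hand (bypasses the solver)
make_stress <- function(sxx, syy, sxy, grid) {
  structure(list(sigma_xx = sxx, sigma_yy = syy, sigma_xy = sxy,
                 phi = matrix(0, grid$ny, grid$nx), grid = grid),
            coupling = 1, stress_scale = 1, subtracted_mean = 0,
            class = "teoim_stress")
}

# Small grids used throughout
test_grid <- function(n = 32L, pitch = 0.5) grid_spec(n, n, pitch)
demo_grid <- function() grid_spec(96L, 48L, 20 / 96)

noise_free <- function(seed = 1L)
  noise_config(read_noise_sigma = 0, replicate_drift_sigma = 0, seed = seed)
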