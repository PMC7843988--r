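test_that("background field is an isotropic lobe centred on the aperture", {
  g <- test_grid(40L)
  sc <- scene_config(background_amplitude = 0)
  expect_true(all(background_field(g, sc) == 0))
  sc2 <- scene_config(background_amplitude = 2, background_width_mm = 3)
  bg <- unclass(background_field(g, sc2))
  # rotational symmetry on a square grid
  expect_lt(max(abs(bg - t(bg)[nrow(bg):1, ])), 1e-12)
  expect_lt(max(abs(bg - bg[nrow(bg):1, ncol(bg):1])), 1e-12)
  # peak at the four centre pixels (even grid), value just below the peak
  pk <- which(bg == max(bg), arr.ind = TRUE)
  expect_setequal(pk[, 1], c(20L, 21L))
  expect_setequal(pk[, 2], c(20L, 21L))
})

test_that("tube field: empty tube, polarization suppression, closed-form amplitude", {
  g <- default_grid()
  eps <- complex_permittivity(permittivity_spec("water"), 0, 12e9)
  sc <- scene_config(tube_filled = FALSE)
  expect_true(all(tube_field(g, sc, eps) == 0))

  par <- tube_field(g, scene_config(polarization = "parallel"), eps)
  perp <- tube_field(g, scene_config(polarization = "perpendicular"), eps)
  expect_lte(max(perp) / max(par), 0.05)

  # at the resonance centre the Lorentzian is 1, so the amplitude equals
  # A0 * exp(-2 L / Dp) with Dp from the dielectric module
  sc12 <- scene_config(frequency_GHz = 12, resonance_center_GHz = 12)
  dp_mm <- dp_literal_oracle(eps$eps_real, eps$eps_imag, 12e9) * 1e3
  want <- sc12$tube_coupling_amplitude * exp(-2 * sc12$effective_path_mm / dp_mm)
  expect_equal(attr(tube_field(g, sc12, eps), "peak_amplitude"), want,
               tolerance = 1e-12)
})

test_that("heat source is quadratic in the field amplitude", {
  g <- test_grid()
  sc <- scene_config()
  h <- background_field(g, sc)
  expect_true(all(heat_source_from_field(field_map(matrix(0, g$ny, g$nx), g,
                                                   "field_intensity")) == 0))
  q1 <- heat_source_from_field(h, 2)
  expect_equal(unclass(q1), 2 * unclass(h), ignore_attr = TRUE)
  # doubling the H amplitude quadruples |H|^2 hence q
  h4 <- field_map(4 * unclass(h), g, "field_intensity")
  expect_equal(unclass(heat_source_from_field(h4, 2)), 4 * unclass(q1),
               ignore_attr = TRUE)
  u <- field_map(matrix(1, g$ny, g$nx), g, "field_intensity")
  expect_equal(unclass(heat_source_from_field(u, 3)),
               matrix(3, g$ny, g$nx), ignore_attr = TRUE)
  expect_error(heat_source_from_field(h, -1), "sheet_coefficient")
})

test_that("thermoelastic solve: zero source, single-mode closed form", {
  g <- test_grid(32L, pitch = 0.5)
  z <- field_map(matrix(0, 32, 32), g, "heat_source")
  st0 <- solve_thermoelastic(z)
  expect_true(all(st0$sigma_xx == 0) && all(st0$sigma_xy == 0))

  # single Fourier mode: nabla^4 phi = -coupling q gives
  # phi = -coupling q / |k|^4 with the continuous wavenumbers
  L <- 32 * 0.5
  m <- 3L; n <- 2L
  xs <- (seq_len(32) - 0.5) * 0.5
  q <- outer(sin(2 * pi * n * xs / L), sin(2 * pi * m * xs / L))  # [y, x]
  qf <- field_map(q, g, "heat_source")
  coupling <- 1.7
  st <- solve_thermoelastic(qf, coupling = coupling, stress_scale = 1)
  k2 <- (2 * pi * m / L)^2 + (2 * pi * n / L)^2
  phi_want <- -coupling * q / k2^2
  expect_lt(max(abs(st$phi - phi_want)), 1e-10 * max(abs(phi_want)))
  # sigma_yy = -s d2phi/dx2 = -s * (-(kx)^2 phi) for this mode
  kx2 <- (2 * pi * m / L)^2
  expect_lt(max(abs(st$sigma_yy - (-kx2 * phi_want * -1))), 1e-9)
})

test_that("spectral solve matches the dense DFT-matrix oracle on 16x16", {
  g <- grid_spec(16L, 16L, 1.0)
  set.seed(4)
  q <- matrix(rnorm(256), 16, 16)
  st <- solve_thermoelastic(field_map(q, g, "heat_source"), coupling = 1.3)
  phi_dense <- dense_biharmonic_phi(q, g, coupling = 1.3)
  expect_lt(max(abs(st$phi - phi_dense)), 1e-8)
})

test_that("stresses satisfy the discrete source identity", {
  # (d2/dx2 - d2/dy2)(sxx - syy) + 4 d2/dxdy sxy = -s*coupling*(q - mean q)
  g <- test_grid(24L, 0.8)
  # band-limited random source (no content at the unpaired Nyquist modes)
  set.seed(7)
  xs <- (seq_len(24) - 0.5) * 0.8
  L <- 24 * 0.8
  q <- matrix(0, 24, 24)
  for (m in 1:5) for (n in 1:5)
    q <- q + rnorm(1) * outer(sin(2 * pi * n * xs / L + rnorm(1)),
                              sin(2 * pi * m * xs / L + rnorm(1)))
  st <- solve_thermoelastic(field_map(q, g, "heat_source"),
                            coupling = 2, stress_scale = 1.5)
  d <- st$sigma_xx - st$sigma_yy
  lhs <- teoim:::spectral_derivative(d, g, dx = 2L) -
    teoim:::spectral_derivative(d, g, dy = 2L) +
    4 * teoim:::spectral_derivative(st$sigma_xy, g, dx = 1L, dy = 1L)
  rhs <- -1.5 * 2 * (q - mean(q))
  expect_lt(max(abs(lhs - rhs)), 1e-8 * max(abs(rhs)))
})

test_that("Mueller rendering matches direct evaluation", {
  g <- test_grid(24L)
  zero <- make_stress(matrix(0, 24, 24), matrix(0, 24, 24),
                      matrix(0, 24, 24), g)
  fr0 <- render_analyzer_frames(zero, i_full = 1, noise = noise_free())
  expect_equal(fr0$i0, matrix(0.5, 24, 24))
  expect_equal(fr0$i45, matrix(0.5, 24, 24))

  # uniform delta = 0.1, theta = 0: i0 = i_full/2, i45 = i_full/2 (1 + sin 0.1)
  delta <- 0.1
  st <- make_stress(matrix(delta, 24, 24), matrix(0, 24, 24),
                    matrix(0, 24, 24), g)
  fr <- render_analyzer_frames(st, photoelastic_coefficient = 1,
                               i_full = 1, noise = noise_free())
  expect_equal(fr$i0, matrix(mueller_intensity(delta, 0, 0), 24, 24),
               tolerance = 1e-12)
  expect_equal(fr$i45, matrix(mueller_intensity(delta, 0, pi / 4), 24, 24),
               tolerance = 1e-12)
  expect_equal(fr$i45[1, 1], 0.5 * (1 + sin(0.1)), tolerance = 1e-12)

  big <- make_stress(matrix(1, 24, 24), matrix(0, 24, 24),
                     matrix(0, 24, 24), g)
  expect_warning(render_analyzer_frames(big, photoelastic_coefficient = 0.5,
                                        noise = noise_free()),
                 "linearization")
})

test_that("frame averaging scales the noise as 1/sqrt(N)", {
  g <- grid_spec(64L, 64L, 0.3)
  zero <- make_stress(matrix(0, 64, 64), matrix(0, 64, 64),
                      matrix(0, 64, 64), g)
  nz <- noise_config(read_noise_sigma = 0.01, n_frames = 1e4,
                     replicate_drift_sigma = 0, seed = 21L)
  fr <- render_analyzer_frames(zero, i_full = 1, noise = nz)
  got <- sd(fr$i45 - 0.5)
  expect_lt(abs(got - 1e-4) / 1e-4, 0.10)
})

test_that("simulation is deterministic and composes the stages", {
  g <- demo_grid()
  nz <- noise_config(seed = 33L)
  a <- simulate_measurement(noise = nz, grid = g)
  b <- simulate_measurement(noise = nz, grid = g)
  expect_identical(a$i0, b$i0)
  expect_identical(a$i45, b$i45)

  # empty tube: frames independent of what would be in the tube
  sc <- scene_config(tube_filled = FALSE)
  w <- simulate_measurement(sc, permittivity_spec("water"), 0, nz, g)
  n <- simulate_measurement(sc, permittivity_spec("nacl"), 80, nz, g)
  expect_identical(w$i45, n$i45)

  # attenuation: reconstructed ROI intensity larger at c = 0 than c = 100
  r0 <- measure_roi(simulate_measurement(
    scene_config(), permittivity_spec("nacl"), 0, noise_free(5L), g))
  r100 <- measure_roi(simulate_measurement(
    scene_config(), permittivity_spec("nacl"), 100, noise_free(5L), g))
  expect_gt(r0, r100)
})

test_that("concentration datasets: shape, monotone response, solute ordering", {
  g <- demo_grid()
  one <- generate_concentration_dataset(permittivity_spec("nacl"), 50, 1L,
                                        noise = noise_free(), grid = g)
  expect_equal(nrow(one), 1L)
  expect_error(generate_concentration_dataset(concentrations = numeric(0)),
               "empty")

  nacl <- generate_concentration_dataset(
    permittivity_spec("nacl"), seq(0, 100, 10), 1L,
    noise = noise_free(9L), grid = g)
  m_nacl <- measure_roi_series(nacl)
  expect_true(all(diff(m_nacl$roi_mean) < 0))

  glu50 <- generate_concentration_dataset(
    permittivity_spec("glucose"), 50, 1L, noise = noise_free(9L), grid = g)
  m_glu <- measure_roi_series(glu50)
  expect_lt(m_nacl$roi_mean[m_nacl$concentration_mg_ml == 50],
            m_glu$roi_mean)
})

test_that("frequency sweep: pairing, resonance peak, width response", {
  g <- demo_grid()
  single <- generate_frequency_sweep(frequencies_GHz = 12,
                                     noise = noise_free(), grid = g)
  expect_equal(nrow(single), 2L)
  expect_setequal(single$condition, c("background", "sample"))

  sw <- generate_frequency_sweep(noise = noise_free(3L), grid = g)
  ms <- measure_roi_series(sw)
  cv <- sweep_difference_curve(ms[ms$condition == "background", ],
                               ms[ms$condition == "sample", ])
  expect_equal(sweep_peak(cv), 12)

  narrow <- scene_config(resonance_width_GHz = 0.5)
  sw2 <- generate_frequency_sweep(narrow, noise = noise_free(3L), grid = g)
  ms2 <- measure_roi_series(sw2)
  cv2 <- sweep_difference_curve(ms2[ms2$condition == "background", ],
                                ms2[ms2$condition == "sample", ])
  off <- function(curve) curve$difference[curve$frequency_GHz == 11] /
    curve$difference[curve$frequency_GHz == 12]
  expect_lt(off(cv2), off(cv))  # narrower resonance drops faster off-peak
})
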