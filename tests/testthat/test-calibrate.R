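test_that("replicate statistics: mean and n-1 sd per concentration", {
  s <- tibble::tibble(concentration_mg_ml = c(0, 0, 10, 10),
                      replicate = c(1, 2, 1, 2),
                      roi_mean = c(0, 2, 1, 1))
  st <- replicate_stats(s)
  expect_equal(st$mean, c(1, 1))
  expect_equal(st$sd, c(sqrt(2), 0))
  st5 <- replicate_stats(tibble::tibble(concentration_mg_ml = 0,
                                        replicate = 1:5,
                                        roi_mean = rep(1, 5)))
  expect_equal(st5$mean, 1); expect_equal(st5$sd, 0)
  expect_warning(
    replicate_stats(tibble::tibble(concentration_mg_ml = 0, replicate = 1,
                                   roi_mean = 1)),
    "single-replicate")
})

test_that("exponential fit recovers exact model data", {
  conc <- seq(0, 100, 10)
  y <- 0.2 + 1 * exp(-conc / 30)
  s <- tibble::tibble(concentration_mg_ml = conc, replicate = 1L, roi_mean = y)
  fit <- fit_exponential(s)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$decay_scale, 30, tolerance = 1e-6)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
  td <- tidy(fit)
  expect_equal(td$term, c("A", "c0", "B"))
  expect_true(glance(fit)$converged)

  expect_error(fit_exponential(s[1:2, ]), "3 distinct")
  const <- tibble::tibble(concentration_mg_ml = conc, replicate = 1L,
                          roi_mean = 1)
  expect_error(fit_exponential(const), "degenerate")
})

test_that("fit is equivariant under intensity rescaling", {
  conc <- seq(0, 100, 10)
  set.seed(2)
  y <- 0.2 + exp(-conc / 40) + rnorm(11, sd = 0.005)
  s <- tibble::tibble(concentration_mg_ml = conc, replicate = 1L, roi_mean = y)
  f1 <- fit_exponential(s)
  s2 <- dplyr::mutate(s, roi_mean = 7 * roi_mean)
  f2 <- fit_exponential(s2)
  expect_equal(f2$amplitude, 7 * f1$amplitude, tolerance = 1e-6)
  expect_equal(f2$offset, 7 * f1$offset, tolerance = 1e-6)
  expect_equal(f2$decay_scale, f1$decay_scale, tolerance = 1e-6)
})

test_that("noisy replicate fits recover the decay scale", {
  conc <- seq(0, 100, 10)
  errs <- withr::with_seed(31L, replicate(20, {
    s <- tibble::tibble(
      concentration_mg_ml = rep(conc, each = 5),
      replicate = rep(1:5, times = 11),
      roi_mean = 0.2 + exp(-rep(conc, each = 5) / 30) +
        rnorm(55, sd = 0.01))
    abs(fit_exponential(s)$decay_scale - 30) / 30
  }))
  expect_lt(median(errs), 0.10)
})

test_that("pooled and weighted fits run and agree on clean data", {
  conc <- seq(0, 100, 20)
  s <- tibble::tibble(
    concentration_mg_ml = rep(conc, each = 3),
    replicate = rep(1:3, times = length(conc)),
    roi_mean = 0.1 + exp(-rep(conc, each = 3) / 25) +
      withr::with_seed(5L, rnorm(18, sd = 1e-4)))
  fp <- fit_exponential(s, pooled = TRUE)
  fw <- fit_exponential(s, weighted = TRUE)
  fu <- fit_exponential(s)
  expect_equal(fp$decay_scale, fu$decay_scale, tolerance = 1e-2)
  expect_equal(fw$decay_scale, fu$decay_scale, tolerance = 1e-2)
})

test_that("Cmin: direct substitution, numeric-derivative oracle, monotonicity", {
  conc <- seq(0, 100, 10)
  y <- 0 + 1 * exp(-conc / 30)
  fit <- fit_exponential(tibble::tibble(concentration_mg_ml = conc,
                                        replicate = 1L, roi_mean = y))
  cm <- min_detectable_concentration(fit, 0.1, at_concentrations = c(0, 30))
  expect_equal(cm$cmin_mg_ml[1], 3.0, tolerance = 1e-5)
  expect_equal(cm$cmin_mg_ml[2], 3.0 * exp(1), tolerance = 1e-5)

  # numeric differentiation of the fitted curve as an independent oracle
  withr::with_seed(9L, for (i in 1:5) {
    A <- runif(1, 0.3, 3); c0 <- runif(1, 15, 80); B <- runif(1, -1, 1)
    yy <- B + A * exp(-conc / c0)
    f <- fit_exponential(tibble::tibble(concentration_mg_ml = conc,
                                        replicate = 1L, roi_mean = yy))
    de <- 0.05
    at <- c(5, 40, 90)
    cm2 <- min_detectable_concentration(f, de, at)
    h <- 1e-4 * f$decay_scale
    slope <- (predict(f, at + h) - predict(f, at - h)) / (2 * h)
    expect_equal(cm2$cmin_mg_ml, abs(de / slope), tolerance = 1e-6)
    # strictly increasing for a saturating decreasing fit
    dense <- min_detectable_concentration(f, de, seq(0, 100, 5))
    expect_true(all(diff(dense$cmin_mg_ml) > 0))
  })
  expect_error(min_detectable_concentration(fit, -1), "delta_e_max")
})

test_that("delta-E-max rules and their ordering", {
  s0 <- tibble::tibble(concentration_mg_ml = rep(c(0, 10), each = 3),
                       replicate = rep(1:3, 2), roi_mean = rep(1, 6))
  expect_equal(as.numeric(delta_e_max_from_series(s0, "max_sd")), 0)
  expect_equal(as.numeric(delta_e_max_from_series(s0, "max_half_range")), 0)

  s1 <- tibble::tibble(concentration_mg_ml = rep(c(0, 10), each = 2),
                       replicate = rep(1:2, 2),
                       roi_mean = c(0.9, 1.1, 1.0, 1.01))
  hr <- delta_e_max_from_series(s1, "max_half_range")
  expect_equal(as.numeric(hr), 0.1)
  expect_identical(attr(hr, "rule"), "max_half_range")

  # enumeration: max_sd <= max_half_range * sqrt(n/(n-1)) always
  withr::with_seed(17L, for (i in 1:50) {
    n <- sample(2:6, 1); k <- sample(3:6, 1)
    s <- tibble::tibble(
      concentration_mg_ml = rep(seq_len(k), each = n),
      replicate = rep(seq_len(n), times = k),
      roi_mean = rnorm(n * k))
    msd <- as.numeric(delta_e_max_from_series(s, "max_sd"))
    mhr <- as.numeric(delta_e_max_from_series(s, "max_half_range"))
    expect_lte(msd, mhr * sqrt(n / (n - 1)) + 1e-12)
  })

  single <- tibble::tibble(concentration_mg_ml = 0, replicate = 1, roi_mean = 1)
  expect_error(delta_e_max_from_series(single), "2 replicates")
})

test_that("sweep difference curve and its tie rule", {
  a <- tibble::tibble(frequency_GHz = 7:15, roi_mean = rep(1, 9))
  cv <- sweep_difference_curve(a, a)
  expect_true(all(cv$difference == 0))
  expect_equal(sweep_peak(cv), 7)  # ties break toward the lowest frequency
  b <- tibble::tibble(frequency_GHz = 8:15, roi_mean = rep(1, 8))
  expect_error(sweep_difference_curve(a, b), "frequency grids")
})
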