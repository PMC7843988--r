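#' Per-concentration replicate statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' ROI intensities at each concentration, the quantities plotted as points
#' and error bars on a calibration curve.
#'
#' @param series Tibble with columns `concentration_mg_ml` and `roi_mean`
#'   (and optionally `solute`, which is kept as a grouping column).
#' @return Tibble with `concentration_mg_ml`, `n`, `mean`, `sd` and a
#'   `single_replicate` flag (sd is reported as 0 with a warning when only
#'   one replicate is present).
#' @export
replicate_stats <- function(series) {
  check_series(series)
  keys <- intersect(c("solute", "concentration_mg_ml"), names(series))
  out <- series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$roi_mean),
      sd = if (dplyr::n() > 1L) sd(.data$roi_mean) else 0,
      .groups = "drop") |>
    dplyr::mutate(single_replicate = .data$n == 1L)
  if (any(out$single_replicate))
    warn("replicate_stats: single-replicate concentrations; sd reported as 0")
  out
}

check_series <- function(series, need_replicate = FALSE) {
  need <- c("concentration_mg_ml", "roi_mean", if (need_replicate) "replicate")
  missing <- setdiff(need, names(series))
  if (length(missing))
    abort(paste("series is missing column(s):", paste(missing, collapse = ", ")))
  if (any(!is.finite(series$roi_mean)))
    abort("series has non-finite roi_mean values (missing cells are not allowed)")
  invisible(TRUE)
}

#' Fit the exponential calibration model to a concentration series
#'
#' Least-squares fit of the saturating intensity model
#' \deqn{I(c) = B + A \exp(-c / c_0)}
#' to the per-concentration mean intensities (matching the plotted points;
#' set `pooled = TRUE` to fit all replicates instead). The initialization
#' is a fixed deterministic rule: `B0` = minimum mean, `A0` = range,
#' `c00` = half the concentration span. Optionally weighted by inverse
#' replicate variance.
#'
#' @param series Tibble with `concentration_mg_ml`, `roi_mean` and (for
#'   weighting) `replicate`.
#' @param weighted Weight by `1 / sd^2` of the replicates (requires >= 2
#'   replicates per concentration with nonzero scatter).
#' @param pooled Fit all replicate points rather than the means.
#' @return A `teoim_calfit` object with [tidy()], [glance()], [predict()]
#'   and [autoplot()] methods.
#' @export
fit_exponential <- function(series, weighted = FALSE, pooled = FALSE) {
  check_series(series)
  stats_tbl <- suppressWarnings(replicate_stats(
    series[setdiff(names(series), "solute")]))
  if (nrow(stats_tbl) < 3L)
    abort("fit_exponential: need at least 3 distinct concentrations")
  df <- if (pooled) {
    tibble::tibble(conc = series$concentration_mg_ml, y = series$roi_mean)
  } else {
    tibble::tibble(conc = stats_tbl$concentration_mg_ml, y = stats_tbl$mean)
  }
  if (diff(range(df$y)) < .Machine$double.eps * max(1, max(abs(df$y))) * 100)
    abort("fit_exponential: degenerate data (intensity variation below machine epsilon)")
  start <- list(B = min(df$y), A = diff(range(df$y)),
                c0 = diff(range(df$conc)) / 2)
  wts <- NULL
  if (weighted) {
    if (any(stats_tbl$sd <= 0))
      abort("fit_exponential: weighting requires nonzero replicate sd at every concentration")
    wts <- if (pooled) {
      1 / stats_tbl$sd[match(df$conc, stats_tbl$concentration_mg_ml)]^2
    } else 1 / stats_tbl$sd^2
  }
  sw <- if (is.null(wts)) rep(1, nrow(df)) else sqrt(wts)
  # internal parametrization uses log(c0): c0 stays positive without a box
  # boundary (where the c0 gradient degenerates); same initialization rule
  model_u <- function(p) p[["B"]] + p[["A"]] * exp(-df$conc / exp(p[["u"]]))
  resid_fn <- function(p) sw * (df$y - model_u(p))
  start_u <- list(B = start$B, A = start$A, u = log(start$c0))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start_u, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      abort(paste("fit_exponential: fit failed to converge:",
                  conditionMessage(e))))
  if (!(fit$info %in% 1:4))
    abort(sprintf("fit_exponential: fit failed to converge (%s)", fit$message))
  cf <- c(B = fit$par[["B"]], A = fit$par[["A"]], c0 = exp(fit$par[["u"]]))
  if (!is.finite(cf[["c0"]]) || cf[["c0"]] <= 0)
    abort(sprintf(
      "fit_exponential: fitted decay scale c0 = %.3g is not a saturating decay",
      cf[["c0"]]))
  res <- df$y - (cf[["B"]] + cf[["A"]] * exp(-df$conc / cf[["c0"]]))
  dof <- max(1, nrow(df) - 3)
  sigma2 <- sum((sw * res)^2) / dof
  e <- exp(-df$conc / cf[["c0"]])
  J <- -sw * cbind(B = rep(1, nrow(df)), A = e,
                   c0 = cf[["A"]] * e * df$conc / cf[["c0"]]^2)
  vc <- tryCatch(sigma2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(c("B", "A", "c0"), c("B", "A", "c0"))
  structure(list(
    amplitude = cf[["A"]], decay_scale = cf[["c0"]], offset = cf[["B"]],
    vcov = vc[c("A", "c0", "B"), c("A", "c0", "B")], residuals = res,
    sigma = sqrt(sum(res^2) / dof),
    data = df, stats = stats_tbl, weighted = weighted, pooled = pooled,
    converged = TRUE,
    solute = if ("solute" %in% names(series)) series$solute[1] else NA_character_
  ), class = "teoim_calfit")
}

#' @export
print.teoim_calfit <- function(x, ...) {
  cat(sprintf(paste0(
    "<teoim_calfit%s> I(c) = B + A exp(-c/c0)\n",
    "  A = %.5g, c0 = %.5g mg/ml, B = %.5g (residual sigma %.3g, n = %d)\n"),
    if (is.na(x$solute)) "" else paste0(": ", x$solute),
    x$amplitude, x$decay_scale, x$offset, x$sigma, nrow(x$data)))
  invisible(x)
}

#' @export
coef.teoim_calfit <- function(object, ...) {
  c(A = object$amplitude, c0 = object$decay_scale, B = object$offset)
}

#' @rdname fit_exponential
#' @param x,object A `teoim_calfit`.
#' @param ... Unused.
#' @export
tidy.teoim_calfit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(term = c("A", "c0", "B"),
                 estimate = unname(coef(x)),
                 std.error = unname(se))
}

#' @rdname fit_exponential
#' @export
glance.teoim_calfit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, nobs = nrow(x$data),
                 converged = x$converged, weighted = x$weighted,
                 pooled = x$pooled)
}

#' Predict fitted intensity at new concentrations
#' @param object A `teoim_calfit`.
#' @param concentration Concentrations (mg/ml) to evaluate.
#' @param ... Unused.
#' @return Numeric fitted intensities.
#' @export
predict.teoim_calfit <- function(object, concentration = object$data$conc, ...) {
  object$offset + object$amplitude * exp(-concentration / object$decay_scale)
}

#' @rdname fit_exponential
#' @export
autoplot.teoim_calfit <- function(object, ...) {
  grid <- tibble::tibble(
    conc = seq(min(object$data$conc), max(object$data$conc), length.out = 200))
  grid$fit <- predict(object, grid$conc)
  st <- object$stats
  ggplot2::ggplot(st, ggplot2::aes(.data$concentration_mg_ml, .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 1.5) +
    ggplot2::geom_point(colour = "red") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$conc, .data$fit)) +
    ggplot2::labs(x = "concentration (mg/ml)", y = "ROI intensity (arb.)")
}

#' Maximum replicate fluctuation for the sensitivity analysis
#'
#' The detection threshold used in the minimum-detectable-concentration
#' formula: the maximum over concentrations of the replicate fluctuation.
#' Two rules are provided because the margin-of-error definition is
#' ambiguous: `"max_sd"` (default) takes the largest replicate standard
#' deviation; `"max_half_range"` the largest half-range `(max - min) / 2`.
#'
#' @param series Tibble with `concentration_mg_ml`, `replicate`, `roi_mean`
#'   (>= 2 replicates per concentration).
#' @param rule `"max_sd"` or `"max_half_range"`.
#' @return The fluctuation value, with the rule recorded in
#'   `attr(, "rule")`.
#' @export
delta_e_max_from_series <- function(series, rule = c("max_sd", "max_half_range")) {
  rule <- match.arg(rule)
  check_series(series, need_replicate = TRUE)
  per <- series |>
    dplyr::group_by(.data$concentration_mg_ml) |>
    dplyr::summarise(n = dplyr::n(),
                     sd = if (dplyr::n() > 1) sd(.data$roi_mean) else NA_real_,
                     half_range = (max(.data$roi_mean) - min(.data$roi_mean)) / 2,
                     .groups = "drop")
  if (any(per$n < 2L))
    abort("delta_e_max_from_series: fluctuation rules need >= 2 replicates per concentration")
  val <- switch(rule, max_sd = max(per$sd), max_half_range = max(per$half_range))
  structure(val, rule = rule)
}

#' Minimum detectable concentration curve
#'
#' Sensitivity limit derived from the fitted calibration curve,
#' \deqn{C_{min}(c) = \left| \Delta E_{max}
#'   \left(\frac{dI}{dc}\right)^{-1} \right|
#'   = \frac{\Delta E_{max}\, c_0}{A} \, e^{c/c_0},}
#' using the analytic derivative of the fitted exponential model. For a
#' saturating decreasing fit (`A > 0`) the curve increases with
#' concentration: the system is most sensitive at low concentrations.
#'
#' @param fit A `teoim_calfit`.
#' @param delta_e_max Detection threshold (> 0), e.g. from
#'   [delta_e_max_from_series()].
#' @param at_concentrations Concentrations (mg/ml) at which to evaluate.
#' @return A `teoim_sensitivity` tibble with `concentration_mg_ml` and
#'   `cmin_mg_ml`; attributes `delta_e_max` and `rule` (if carried by
#'   `delta_e_max`).
#' @export
min_detectable_concentration <- function(fit, delta_e_max,
                                         at_concentrations = fit$data$conc) {
  stopifnot(inherits(fit, "teoim_calfit"))
  if (!is.numeric(delta_e_max) || delta_e_max <= 0)
    abort("min_detectable_concentration: delta_e_max must be > 0")
  if (fit$amplitude == 0)
    abort("min_detectable_concentration: undefined sensitivity (A = 0)")
  cmin <- abs(as.numeric(delta_e_max) * fit$decay_scale / fit$amplitude) *
    exp(at_concentrations / fit$decay_scale)
  out <- tibble::tibble(concentration_mg_ml = as.numeric(at_concentrations),
                        cmin_mg_ml = cmin)
  structure(out, delta_e_max = as.numeric(delta_e_max),
            rule = attr(delta_e_max, "rule"),
            class = c("teoim_sensitivity", class(out)))
}

#' @export
autoplot.teoim_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$concentration_mg_ml,
                                       .data$cmin_mg_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (mg/ml)",
                  y = expression(C[min] ~ "(mg/ml)"))
}

#' Background-vs-sample frequency-difference curve
#'
#' Elementwise difference of the sample and background ROI intensities
#' across a frequency sweep; the frequency maximizing the difference is
#' the optimal operating point.
#'
#' @param bg_series,sample_series Tibbles with `frequency_GHz` and
#'   `roi_mean` on identical frequency grids.
#' @return A `teoim_sweep` tibble with `frequency_GHz`, `background`,
#'   `sample`, `difference`, sorted by frequency.
#' @export
sweep_difference_curve <- function(bg_series, sample_series) {
  for (s in list(bg_series, sample_series))
    if (!all(c("frequency_GHz", "roi_mean") %in% names(s)))
      abort("sweep_difference_curve: series need frequency_GHz and roi_mean columns")
  bg <- dplyr::arrange(bg_series, .data$frequency_GHz)
  sm <- dplyr::arrange(sample_series, .data$frequency_GHz)
  if (!isTRUE(all.equal(bg$frequency_GHz, sm$frequency_GHz)))
    abort("sweep_difference_curve: frequency grids do not match")
  out <- tibble::tibble(frequency_GHz = bg$frequency_GHz,
                        background = bg$roi_mean,
                        sample = sm$roi_mean,
                        difference = sm$roi_mean - bg$roi_mean)
  structure(out, class = c("teoim_sweep", class(out)))
}

#' Peak frequency of a sweep difference curve
#'
#' Argmax of the difference; ties are broken toward the lowest frequency.
#'
#' @param curve A `teoim_sweep` from [sweep_difference_curve()].
#' @return Peak frequency in GHz.
#' @export
sweep_peak <- function(curve) {
  stopifnot(inherits(curve, "teoim_sweep"))
  curve$frequency_GHz[which.max(curve$difference)]
}

#' @export
autoplot.teoim_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("background", "sample", "difference"),
                              names_to = "signal", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency_GHz, .data$intensity,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frequency (GHz)", y = "ROI intensity (arb.)")
}
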