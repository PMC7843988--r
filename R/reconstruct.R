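#' Extract linear-birefringence images from analyzer frames
#'
#' Linearized inversion of the Mueller chain: for small retardance the
#' baseline-subtracted frames are proportional to the two stress channels,
#' so the birefringence images are
#' `beta = gain * 2 * (frame - baseline) / i_full`. The channel convention
#' is fixed by the forward model: `beta1` (normal-stress-difference
#' channel) comes from the 45-degree frame, `beta2` (shear channel) from
#' the 0-degree frame with a sign flip. A constant offset common to frame
#' and baseline cancels.
#'
#' @param frames A `teoim_frames` set (frames and baselines must share grid
#'   and full scale).
#' @param gain Dimensionless extraction gain.
#' @return A `teoim_lb` list with `beta1`, `beta2` (`teoim_field`s, role
#'   `"beta"`), the `grid` and provenance metadata.
#' @export
extract_lb <- function(frames, gain = 1) {
  if (!inherits(frames, "teoim_frames"))
    abort("extract_lb: frames must be a teoim_frames set")
  imgs <- frames[c("i0", "i45", "baseline0", "baseline45")]
  dims <- lapply(imgs, dim)
  if (length(unique(dims)) != 1L)
    abort("extract_lb: frames and baselines have mismatched grids")
  grid <- frames$grid
  beta1 <- gain * 2 * (frames$i45 - frames$baseline45) / frames$i_full
  beta2 <- -gain * 2 * (frames$i0 - frames$baseline0) / frames$i_full
  structure(list(
    beta1 = field_map(beta1, grid, "beta"),
    beta2 = field_map(beta2, grid, "beta"),
    grid = grid,
    provenance = list(gain = gain, i_full = frames$i_full,
                      scene = frames$scene, noise = frames$noise,
                      concentration = frames$concentration,
                      params = frames$params)
  ), class = "teoim_lb")
}

#' Construct a birefringence image pair directly
#'
#' @param beta1,beta2 `ny x nx` numeric matrices (normal and shear
#'   channels).
#' @param grid A [grid_spec()].
#' @return A `teoim_lb` pair.
#' @export
lb_pair <- function(beta1, beta2, grid) {
  structure(list(beta1 = field_map(beta1, grid, "beta"),
                 beta2 = field_map(beta2, grid, "beta"),
                 grid = grid, provenance = list()),
            class = "teoim_lb")
}

# periodic circular shift of a matrix by (di, dj)
circ_shift <- function(m, di = 0L, dj = 0L) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- ((seq_len(n1) - 1L + di) %% n1) + 1L
  rj <- ((seq_len(n2) - 1L + dj) %% n2) + 1L
  m[ri, rj, drop = FALSE]
}

# central finite differences (periodic wrap; interior later cropped).
# x is the column direction, y the row direction; h in mm.
d2x_central <- function(m, h) (circ_shift(m, 0L, 1L) - 2 * m + circ_shift(m, 0L, -1L)) / h^2
d2y_central <- function(m, h) (circ_shift(m, 1L, 0L) - 2 * m + circ_shift(m, -1L, 0L)) / h^2
dxy_central <- function(m, h) {
  (circ_shift(m, 1L, 1L) - circ_shift(m, 1L, -1L) -
     circ_shift(m, -1L, 1L) + circ_shift(m, -1L, -1L)) / (4 * h^2)
}

# Gaussian pre-smoothing via the periodic spectral transfer function
gaussian_presmooth <- function(m, grid, sigma_px) {
  if (sigma_px <= 0) return(m)
  kk <- k_grids(grid)
  sig_mm <- sigma_px * grid$pitch_mm
  transfer <- exp(-(kk$kx^2 + kk$ky^2) * sig_mm^2 / 2)
  ifft2_real(transfer * fft(m))
}

#' Reconstruct the heat-source distribution from birefringence images
#'
#' Second-derivative inverse of the thermoelastic imaging chain,
#' \deqn{\hat q(x,y) = C\left(\frac{\partial^2 \beta_1}{\partial x^2}
#'   - \frac{\partial^2 \beta_1}{\partial y^2}
#'   + 2\,\frac{\partial^2 \beta_2}{\partial x \partial y}\right),}
#' with derivatives in physical units (per mm^2) using the grid pitch.
#' Differentiation uses second-order central stencils (mixed derivative by
#' composed central first differences) or exact spectral derivatives; an
#' optional Gaussian pre-smoothing is applied identically to both channels
#' first (the operator amplifies high-frequency noise). A `crop_margin_px`
#' frame is removed from the output in place of one-sided boundary
#' stencils.
#'
#' @param lb A `teoim_lb` pair.
#' @param cfg A [recon_config()].
#' @return A `teoim_field` with role `"reconstruction"`, cropped to the
#'   interior; its `origin_px` attribute records the crop geometry.
#' @export
reconstruct_heat_source <- function(lb, cfg = recon_config()) {
  if (!inherits(lb, "teoim_lb"))
    abort("reconstruct_heat_source: lb must be a teoim_lb pair")
  stopifnot(inherits(cfg, "teoim_recon_config"))
  grid <- lb$grid
  m <- cfg$crop_margin_px
  if (2 * m >= grid$nx || 2 * m >= grid$ny)
    abort("reconstruct_heat_source: crop margin larger than the image")
  b1 <- gaussian_presmooth(unclass(lb$beta1), grid, cfg$presmooth_sigma_px)
  b2 <- gaussian_presmooth(unclass(lb$beta2), grid, cfg$presmooth_sigma_px)
  h <- grid$pitch_mm
  if (cfg$stencil == "central") {
    q <- cfg$scale_c * (d2x_central(b1, h) - d2y_central(b1, h) +
                          2 * dxy_central(b2, h))
  } else {
    q <- cfg$scale_c * (spectral_derivative(b1, grid, dx = 2L) -
                          spectral_derivative(b1, grid, dy = 2L) +
                          2 * spectral_derivative(b2, grid, dx = 1L, dy = 1L))
  }
  rows <- (m + 1L):(grid$ny - m)
  cols <- (m + 1L):(grid$nx - m)
  field_map(q[rows, cols, drop = FALSE], grid, "reconstruction",
            origin_px = c(m, m))
}

#' Mean over a rectangular region of interest
#'
#' Arithmetic mean of the pixels whose centres fall inside the half-open
#' physical rectangle `[x0, x1) x [y0, y1)` (mm). Cropped fields are
#' handled through their origin offset.
#'
#' @param map A `teoim_field`.
#' @param roi Numeric `c(x0, y0, x1, y1)` in mm.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, roi) {
  if (!inherits(map, "teoim_field")) abort("roi_mean: map must be a teoim_field")
  if (length(roi) != 4L || roi[3] <= roi[1] || roi[4] <= roi[2])
    abort("roi_mean: roi must be c(x0, y0, x1, y1) with x1 > x0, y1 > y0")
  g <- field_grid(map); o <- field_origin(map)
  xs <- grid_x(g, ncol(map), o[1])
  ys <- grid_y(g, nrow(map), o[2])
  cx <- xs >= roi[1] & xs < roi[3]
  cy <- ys >= roi[2] & ys < roi[4]
  if (!any(cx) || !any(cy))
    abort("roi_mean: roi does not intersect the field interior")
  mean(unclass(map)[cy, cx])
}

#' Default region of interest around the tube
#'
#' Rectangle centred on the tube: the middle half of the x extent and a
#' band of +/- 1.5 mm around the tube axis, mirroring the dashed ROI drawn
#' on the measured images.
#'
#' @param grid A [grid_spec()].
#' @param half_height_mm Half-height of the band, mm.
#' @return Numeric `c(x0, y0, x1, y1)` in mm.
#' @export
default_roi <- function(grid, half_height_mm = 1.5) {
  ext <- grid_extent(grid)
  c(ext["x_mm"] * 0.25, ext["y_mm"] / 2 - half_height_mm,
    ext["x_mm"] * 0.75, ext["y_mm"] / 2 + half_height_mm)
}

#' Reconstructed-intensity ROI mean for one measurement
#'
#' Convenience wrapper running birefringence extraction, heat-source
#' reconstruction and ROI averaging for a simulated frame set. When the
#' frame set carries its simulation constants, the reconstruction scale `C`
#' defaults to [roundtrip_scale()] so the result is in heat-source units;
#' pre-smoothing defaults to 1 px when the frames are noisy, 0 otherwise.
#'
#' @param frames A `teoim_frames` set.
#' @param roi ROI rectangle in mm (default [default_roi()]).
#' @param recon Optional [recon_config()] overriding the defaults.
#' @param gain Extraction gain.
#' @return Scalar ROI mean of the reconstructed heat source.
#' @export
measure_roi <- function(frames, roi = NULL, recon = NULL, gain = 1) {
  roi <- roi %||% default_roi(frames$grid)
  if (is.null(recon)) {
    pars <- frames$params
    if (is.null(pars))
      abort("measure_roi: supply a recon_config for frames without simulation metadata")
    noisy <- !is.null(frames$noise) && frames$noise$read_noise_sigma > 0
    recon <- recon_config(scale_c = roundtrip_scale(pars),
                          stencil = "central",
                          presmooth_sigma_px = if (noisy) 1 else 0)
  }
  lb <- extract_lb(frames, gain = gain)
  qhat <- reconstruct_heat_source(lb, recon)
  roi_mean(qhat, roi)
}

#' Measure ROI means across a dataset manifest
#'
#' Maps [measure_roi()] over the `frames` list-column of a manifest from
#' [generate_concentration_dataset()] or [generate_frequency_sweep()],
#' returning a tidy table ready for [replicate_stats()],
#' [fit_exponential()] or [sweep_difference_curve()].
#'
#' @param dataset Tibble with a `frames` list-column.
#' @param roi,recon,gain Passed to [measure_roi()].
#' @return The manifest with `roi_mean` added and `frames` dropped.
#' @export
measure_roi_series <- function(dataset, roi = NULL, recon = NULL, gain = 1) {
  if (!"frames" %in% names(dataset))
    abort("measure_roi_series: dataset must have a frames list-column")
  dataset |>
    dplyr::mutate(roi_mean = purrr::map_dbl(.data$frames, measure_roi,
                                            roi = roi, recon = recon,
                                            gain = gain)) |>
    dplyr::select(-"frames")
}
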