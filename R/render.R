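#' Render polarimetric analyzer frames from a stress field
#'
#' Circular-input Mueller chain of the polariscope: circularly polarized
#' probe light acquires a photoelastic retardance
#' \eqn{\delta = k_{pe}\sqrt{(\sigma_{xx}-\sigma_{yy})^2 + (2\sigma_{xy})^2}}
#' with fast-axis angle \eqn{\theta} given by
#' \eqn{\tan 2\theta = 2\sigma_{xy}/(\sigma_{xx}-\sigma_{yy})}, and the
#' analyzer at angle `A` transmits
#' \deqn{I(A) = \tfrac{I_{full}}{2}\bigl(1 + \sin\delta \,
#'       \sin 2(A - \theta)\bigr).}
#' Frames are recorded at `A = 0` and `A = 45` degrees; the 45-degree frame
#' carries the normal-stress-difference channel and the 0-degree frame the
#' shear channel. Unstressed baseline frames are rendered with the same
#' noise discipline. Additive Gaussian read noise averaged over
#' `noise$n_frames` exposures is sampled directly from its exact averaged
#' distribution (sd `read_noise_sigma / sqrt(n_frames)`), and intensities
#' are clipped to `[0, 1]` full scale.
#'
#' A warning is issued if the peak retardance exceeds 0.3 rad, outside the
#' linearization regime assumed downstream.
#'
#' @param stress A `teoim_stress` from [solve_thermoelastic()].
#' @param photoelastic_coefficient Retardance per unit stress difference.
#' @param i_full Full-scale intensity (> 0). Frames are stored in `[0, 1]`
#'   full-scale units (`i_full` of 1 means the camera full scale).
#' @param noise A [noise_config()].
#' @param drift Multiplicative illumination drift factor applied to this
#'   measurement (default 1; drawn per replicate by dataset generators).
#' @return A `teoim_frames` list: images `i0`, `i45`, `baseline0`,
#'   `baseline45`, plus `grid`, `i_full` (nominal), `noise`, `drift`.
#' @export
render_analyzer_frames <- function(stress, photoelastic_coefficient = 0.05,
                                   i_full = 1, noise = noise_config(),
                                   drift = 1) {
  stopifnot(inherits(stress, "teoim_stress"), inherits(noise, "teoim_noise"))
  if (!is.numeric(i_full) || i_full <= 0)
    abort("render_analyzer_frames: i_full must be > 0")
  d_sig <- stress$sigma_xx - stress$sigma_yy
  shear2 <- 2 * stress$sigma_xy
  r_raw <- sqrt(d_sig^2 + shear2^2)
  delta <- photoelastic_coefficient * r_raw
  if (max(delta) > 0.3)
    warn(sprintf(paste("render_analyzer_frames: peak retardance %.3g rad",
                       "exceeds the 0.3 rad linearization regime"), max(delta)))
  safe <- r_raw > 0
  cos2t <- ifelse(safe, d_sig / r_raw, 0)
  sin2t <- ifelse(safe, shear2 / r_raw, 0)
  sd_ <- sin(delta)
  amp <- i_full * drift / 2
  ideal <- list(
    i0         = amp * (1 - sd_ * sin2t),
    i45        = amp * (1 + sd_ * cos2t),
    baseline0  = matrix(amp, nrow(d_sig), ncol(d_sig)),
    baseline45 = matrix(amp, nrow(d_sig), ncol(d_sig))
  )
  sigma_eff <- noise$read_noise_sigma / sqrt(noise$n_frames)
  imgs <- withr::with_seed(noise$seed, {
    lapply(ideal, function(im) {
      if (sigma_eff > 0)
        im <- im + matrix(rnorm(length(im), sd = sigma_eff),
                          nrow(im), ncol(im))
      pmin(pmax(im, 0), 1)
    })
  })
  structure(c(imgs, list(grid = stress$grid, i_full = i_full, noise = noise,
                         drift = drift)),
            class = "teoim_frames")
}

#' @export
print.teoim_frames <- function(x, ...) {
  cat(sprintf(
    "<teoim_frames> %d x %d px, i_full = %.3g, n_frames = %d, seed = %d\n",
    x$grid$ny, x$grid$nx, x$i_full, x$noise$n_frames, x$noise$seed))
  invisible(x)
}
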