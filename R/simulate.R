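#' Simulate one complete polarimetric measurement
#'
#' Runs the full forward chain for a single scene: parametric near field
#' (background lobe plus tube mode attenuated by the solution's dielectric
#' loss) -> heat-source density in the indicator film -> thermoelastic
#' stress -> Mueller-chain analyzer frames with camera noise. The result is
#' a pure function of the configuration objects and the seed in `noise`.
#'
#' @param scene A [scene_config()].
#' @param spec A [permittivity_spec()] for the solution in the tube.
#' @param concentration Solute concentration, mg/ml.
#' @param noise A [noise_config()].
#' @param grid A [grid_spec()] (default 20 mm x 8 mm).
#' @param params A [sim_params()].
#' @param drift Multiplicative illumination drift factor (default 1).
#' @return A `teoim_frames` set with `scene`, `spec`, `concentration` and
#'   `params` attached as metadata.
#' @export
#' @examples
#' fr <- simulate_measurement(noise = noise_config(seed = 7, read_noise_sigma = 0))
#' range(fr$i45)
simulate_measurement <- function(scene = scene_config(),
                                 spec = permittivity_spec("water"),
                                 concentration = 0,
                                 noise = noise_config(),
                                 grid = default_grid(),
                                 params = sim_params(),
                                 drift = 1) {
  stopifnot(inherits(scene, "teoim_scene"),
            inherits(spec, "teoim_permittivity_spec"),
            inherits(params, "teoim_sim_params"))
  eps <- complex_permittivity(spec, concentration, scene$frequency_GHz * 1e9)
  h2 <- background_field(grid, scene)
  tf <- tube_field(grid, scene, eps)
  total <- field_map(unclass(h2) + unclass(tf), grid, "field_intensity")
  q <- heat_source_from_field(total, params$sheet_coefficient)
  stress <- solve_thermoelastic(q, coupling = params$coupling,
                                stress_scale = params$stress_scale)
  frames <- render_analyzer_frames(
    stress, photoelastic_coefficient = params$photoelastic_coefficient,
    i_full = params$i_full, noise = noise, drift = drift)
  frames$scene <- scene
  frames$spec <- spec
  frames$concentration <- concentration
  frames$params <- params
  frames$heat_source <- q
  frames
}

# deterministic per-cell seed derivation, kept well below 2^31
derive_seed <- function(base_seed, i, j = 0L) {
  (as.integer(base_seed) %% 100000L) * 10000L + i * 100L + j
}

#' Generate a replicated concentration series of measurements
#'
#' Simulates the concentration-response experiment: for each concentration
#' (default 0 to 100 mg/ml in 10 mg/ml steps) and each of `replicates`
#' repeats (default 5), one full measurement is generated with its own
#' derived seed and an independently drawn multiplicative illumination
#' drift. Optionally writes the frames to disk as 16-bit TIFFs with a CSV
#' manifest (see [write_dataset()]).
#'
#' @param spec A [permittivity_spec()] for the solute.
#' @param concentrations Non-negative, sorted concentrations in mg/ml.
#' @param replicates Number of replicates per concentration (>= 1).
#' @param scene A [scene_config()].
#' @param noise A [noise_config()]; its `seed` seeds the whole dataset.
#' @param grid A [grid_spec()].
#' @param params A [sim_params()].
#' @param dir Optional output directory; when given, frames are written to
#'   disk and the returned manifest contains file paths instead of in-memory
#'   frame sets.
#' @return A tibble manifest with columns `solute`, `concentration_mg_ml`,
#'   `replicate`, `frequency_GHz`, `seed` and either a `frames` list-column
#'   or the four image path columns.
#' @export
generate_concentration_dataset <- function(spec = permittivity_spec("nacl"),
                                           concentrations = seq(0, 100, by = 10),
                                           replicates = 5L,
                                           scene = scene_config(),
                                           noise = noise_config(),
                                           grid = default_grid(),
                                           params = sim_params(),
                                           dir = NULL) {
  if (length(concentrations) == 0)
    abort("generate_concentration_dataset: empty concentration list")
  if (any(concentrations < 0) || is.unsorted(concentrations))
    abort("generate_concentration_dataset: concentrations must be non-negative and sorted")
  replicates <- as.integer(replicates)
  if (replicates < 1L)
    abort("generate_concentration_dataset: replicates must be >= 1")

  cases <- tidyr::expand_grid(
    concentration_mg_ml = as.numeric(concentrations),
    replicate = seq_len(replicates)
  )
  cases$seed <- purrr::map2_int(
    match(cases$concentration_mg_ml, concentrations), cases$replicate,
    ~ derive_seed(noise$seed, .x, .y))
  drifts <- purrr::map_dbl(cases$seed, function(s)
    withr::with_seed(s + 1L,
      1 + rnorm(1, sd = noise$replicate_drift_sigma)))
  frames <- purrr::pmap(list(cases$concentration_mg_ml, cases$seed, drifts),
    function(conc, s, dr) {
      ncfg <- noise; ncfg$seed <- s
      simulate_measurement(scene, spec, conc, ncfg, grid, params, drift = dr)
    })
  out <- tibble::tibble(
    solute = spec$solute,
    concentration_mg_ml = cases$concentration_mg_ml,
    replicate = cases$replicate,
    frequency_GHz = scene$frequency_GHz,
    seed = cases$seed,
    frames = frames
  )
  if (!is.null(dir)) out <- write_dataset(out, dir) else out
}

#' Generate a paired background / DI-water frequency sweep
#'
#' For each frequency (default 7 to 15 GHz), simulates both the empty-tube
#' background scene and the water-filled scene with a shared derived seed,
#' enabling paired contrast analysis across the sweep.
#'
#' @param scene A [scene_config()] (frequency field is overridden per
#'   sweep point).
#' @param frequencies_GHz Frequencies to sweep, GHz.
#' @param spec A [permittivity_spec()] for the liquid (default water).
#' @param concentration Concentration of the filled-tube condition, mg/ml.
#' @param noise,grid,params As in [simulate_measurement()].
#' @return Tibble with `frequency_GHz`, `condition`
#'   (`"background"`/`"sample"`), `seed` and a `frames` list-column.
#' @export
generate_frequency_sweep <- function(scene = scene_config(),
                                     frequencies_GHz = 7:15,
                                     spec = permittivity_spec("water"),
                                     concentration = 0,
                                     noise = noise_config(),
                                     grid = default_grid(),
                                     params = sim_params()) {
  if (length(frequencies_GHz) == 0 || any(frequencies_GHz <= 0))
    abort("generate_frequency_sweep: frequencies must be positive")
  rows <- purrr::imap(as.numeric(frequencies_GHz), function(f, i) {
    s <- derive_seed(noise$seed, i)
    ncfg <- noise; ncfg$seed <- s
    sc_bg <- scene; sc_bg$frequency_GHz <- f; sc_bg$tube_filled <- FALSE
    sc_w  <- scene; sc_w$frequency_GHz <- f; sc_w$tube_filled <- TRUE
    tibble::tibble(
      frequency_GHz = f,
      condition = c("background", "sample"),
      seed = s,
      frames = list(
        simulate_measurement(sc_bg, spec, concentration, ncfg, grid, params),
        simulate_measurement(sc_w, spec, concentration, ncfg, grid, params))
    )
  })
  dplyr::bind_rows(rows)
}
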