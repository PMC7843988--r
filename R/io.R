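# Image, manifest and configuration IO.
#
# Analyzer frames are stored as 16-bit grayscale TIFFs in [0, 1] full-scale
# units (tiff::writeTIFF / readTIFF). Reconstructed maps are 32-bit float
# TIFFs: the tiff package reads IEEE-float TIFFs but cannot write them, so
# a minimal uncompressed little-endian float32 writer lives here. Every
# image carries a JSON sidecar with its grid geometry.

write_float_tiff <- function(values, path) {
  stopifnot(is.matrix(values), is.numeric(values))
  ny <- nrow(values); nx <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  entries <- list(  # tag, type (3 = SHORT, 4 = LONG), value
    c(256L, 4L, nx),            # ImageWidth
    c(257L, 4L, ny),            # ImageLength
    c(258L, 3L, 32L),           # BitsPerSample
    c(259L, 3L, 1L),            # Compression = none
    c(262L, 3L, 1L),            # Photometric = BlackIsZero
    c(273L, 4L, NA),            # StripOffsets (patched below)
    c(277L, 3L, 1L),            # SamplesPerPixel
    c(278L, 4L, ny),            # RowsPerStrip
    c(279L, 4L, 4L * nx * ny),  # StripByteCounts
    c(339L, 3L, 3L)             # SampleFormat = IEEE float
  )
  data_offset <- 8L + 2L + 12L * length(entries) + 4L
  entries[[6]][3] <- data_offset
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (e[2] == 3L) {  # SHORT packed into 4-byte value field
      writeBin(e[3], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[3], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("missing sidecar: expected %s", sp))
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a scalar field as a 32-bit float TIFF
#'
#' The field values are stored losslessly (IEEE float32) with a JSON
#' sidecar (`<path>.json`) carrying the grid geometry, crop origin and
#' role. Reading requires the sidecar and is bit-exact.
#'
#' @param field A `teoim_field`.
#' @param path Output `.tif` path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns the `teoim_field`.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "teoim_field"))
  g <- field_grid(field)
  write_float_tiff(unclass(field), path)
  jsonlite::write_json(
    list(nx = g$nx, ny = g$ny, pitch_mm = g$pitch_mm,
         origin_px = field_origin(field), role = field_role(field)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  meta <- read_sidecar(path)
  v <- tiff::readTIFF(path)
  if (length(dim(v)) != 2L)
    abort("read_field_tiff: expected a single-channel image")
  field_map(v, grid_spec(meta$nx, meta$ny, meta$pitch_mm),
            role = meta$role, origin_px = unlist(meta$origin_px))
}

#' Write / read an analyzer frame set as 16-bit TIFFs
#'
#' Writes the four images (`i0`, `i45`, `baseline0`, `baseline45`) as
#' 16-bit grayscale TIFFs (`<prefix>_<channel>.tif`; values rounded to the
#' nearest of 65535 levels of full scale) plus a JSON sidecar
#' (`<prefix>.json`) with the grid, full-scale level, noise settings and
#' scene metadata. Reading restores a `teoim_frames` set within the 16-bit
#' quantization (<= 2^-16 full scale per pixel).
#'
#' @param frames A `teoim_frames` set.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return `write_frame_set` returns a named list of written paths
#'   (invisible); `read_frame_set` returns the `teoim_frames`.
#' @export
write_frame_set <- function(frames, dir, prefix) {
  stopifnot(inherits(frames, "teoim_frames"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- c("i0", "i45", "baseline0", "baseline45")
  paths <- stats::setNames(
    file.path(dir, sprintf("%s_%s.tif", prefix, channels)), channels)
  for (ch in channels)
    tiff::writeTIFF(pmin(pmax(frames[[ch]], 0), 1), paths[[ch]],
                    bits.per.sample = 16L, compression = "none")
  g <- frames$grid
  meta <- list(
    images = as.list(stats::setNames(basename(paths), names(paths))),
    nx = g$nx, ny = g$ny, pitch_mm = g$pitch_mm,
    i_full = frames$i_full, drift = frames$drift,
    noise = unclass(frames$noise),
    scene = if (!is.null(frames$scene)) unclass(frames$scene),
    params = if (!is.null(frames$params)) unclass(frames$params),
    concentration = frames$concentration
  )
  sc <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(meta, sc, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, sidecar = sc))
}

rebuild_config <- function(fields, constructor) {
  if (is.null(fields)) return(NULL)
  keep <- intersect(names(fields), names(formals(constructor)))
  do.call(constructor, fields[keep])
}

#' @rdname write_frame_set
#' @param sidecar Path to the `<prefix>.json` sidecar written by
#'   `write_frame_set`.
#' @export
read_frame_set <- function(sidecar) {
  if (!file.exists(sidecar))
    abort(sprintf("missing sidecar: expected %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  grid <- grid_spec(meta$nx, meta$ny, meta$pitch_mm)
  imgs <- lapply(meta$images, function(p) {
    v <- tiff::readTIFF(file.path(dir, p))
    if (!identical(dim(v), c(grid$ny, grid$nx)))
      abort(sprintf("read_frame_set: image %s does not match the sidecar grid", p))
    v
  })
  structure(c(imgs, list(
    grid = grid, i_full = meta$i_full,
    noise = rebuild_config(meta$noise, noise_config),
    drift = meta$drift %||% 1,
    scene = rebuild_config(meta$scene, scene_config),
    params = rebuild_config(meta$params, sim_params),
    concentration = meta$concentration
  )), class = "teoim_frames")
}

#' Write / read a simulated dataset with a CSV manifest
#'
#' Writes every frame set of an in-memory manifest (from
#' [generate_concentration_dataset()] or [generate_frequency_sweep()]) to
#' `dir` and a `manifest.csv` listing the image paths and the cell
#' metadata (solute, concentration, replicate, frequency, seed).
#'
#' @param dataset Tibble with a `frames` list-column.
#' @param dir Output directory.
#' @return The on-disk manifest tibble (with path columns).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot("frames" %in% names(dataset))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap(seq_len(nrow(dataset)), function(i, ...) {
    fr <- dataset$frames[[i]]
    label <- if ("condition" %in% names(dataset))
      sprintf("%s_f%g", dataset$condition[i], dataset$frequency_GHz[i])
    else
      sprintf("%s_c%03d_r%d", dataset$solute[i],
              round(dataset$concentration_mg_ml[i]), dataset$replicate[i])
    paths <- write_frame_set(fr, dir, label)
    tibble::tibble(path_i0 = basename(paths[["i0"]]),
                   path_i45 = basename(paths[["i45"]]),
                   path_baseline0 = basename(paths[["baseline0"]]),
                   path_baseline45 = basename(paths[["baseline45"]]),
                   sidecar = basename(paths[["sidecar"]]))
  })
  manifest <- dplyr::bind_cols(
    dplyr::select(dataset, -"frames"), dplyr::bind_rows(rows))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' @rdname write_dataset
#' @param manifest_path Path to a `manifest.csv` written by
#'   `write_dataset`.
#' @return `read_dataset` returns the manifest with a restored `frames`
#'   list-column.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    abort(sprintf("read_dataset: no manifest at %s", manifest_path))
  manifest <- tibble::as_tibble(
    utils::read.csv(manifest_path, stringsAsFactors = FALSE))
  dir <- dirname(manifest_path)
  manifest$frames <- purrr::map(manifest$sidecar,
                                ~ read_frame_set(file.path(dir, .x)))
  manifest
}

# ---- YAML run configuration -------------------------------------------------

config_schema <- list(
  grid = grid_spec, scene = scene_config, noise = noise_config,
  sim = sim_params, reconstruction = recon_config
)

#' Load / save a validated run configuration
#'
#' Reads a YAML file with sections `grid`, `scene`, `noise`, `sim`,
#' `reconstruction`, a `dielectric` section of per-solute
#' [permittivity_spec()] overrides, plus `roi` (mm rectangle),
#' `output_dir` and `log_level`. Validation is strict: unknown sections or
#' keys are rejected by name, so a misspelled physics parameter can never
#' be silently replaced by its default. Missing keys take the documented
#' defaults. `save_config` writes the normalized configuration back to
#' YAML, so `save_config(load_config(x))` is a fixed point.
#'
#' @param path YAML file path.
#' @return A `teoim_run_config` list of validated configuration objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("load_config: no such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(names(config_schema), "dielectric", "roi", "output_dir", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort(sprintf("load_config: unknown section(s): %s",
                  paste(unknown, collapse = ", ")))
  cfg <- list()
  for (sec in names(config_schema)) {
    ctor <- config_schema[[sec]]
    given <- raw[[sec]] %||% list()
    bad <- setdiff(names(given), names(formals(ctor)))
    if (length(bad))
      abort(sprintf("load_config: unknown key(s) in %s: %s", sec,
                    paste(paste0(sec, ".", bad), collapse = ", ")))
    cfg[[sec]] <- do.call(ctor, given)
  }
  diel <- raw$dielectric %||% list()
  bad_sol <- setdiff(names(diel), c("water", "nacl", "glucose"))
  if (length(bad_sol))
    abort(sprintf("load_config: unknown solute(s) in dielectric: %s",
                  paste(bad_sol, collapse = ", ")))
  cfg$dielectric <- lapply(
    stats::setNames(c("water", "nacl", "glucose"),
                    c("water", "nacl", "glucose")),
    function(sol) {
      given <- diel[[sol]] %||% list()
      bad <- setdiff(names(given),
                     setdiff(names(formals(permittivity_spec)), "solute"))
      if (length(bad))
        abort(sprintf("load_config: unknown key(s) in dielectric.%s: %s", sol,
                      paste(bad, collapse = ", ")))
      do.call(permittivity_spec, c(list(solute = sol), given))
    })
  if (!is.null(raw$roi)) {
    roi <- as.numeric(unlist(raw$roi))
    if (length(roi) != 4L || roi[3] <= roi[1] || roi[4] <= roi[2])
      abort("load_config: roi must be [x0, y0, x1, y1] with x1 > x0, y1 > y0")
    ext <- grid_extent(cfg$grid)
    if (roi[1] < 0 || roi[2] < 0 || roi[3] > ext[1] || roi[4] > ext[2])
      abort("load_config: roi lies outside the grid bounds")
    cfg$roi <- roi
  } else {
    cfg$roi <- default_roi(cfg$grid)
  }
  cfg$output_dir <- raw$output_dir %||% "."
  cfg$log_level <- raw$log_level %||% "info"
  structure(cfg, class = "teoim_run_config")
}

#' @rdname load_config
#' @param config A `teoim_run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "teoim_run_config"))
  plain <- list(
    grid = unclass(config$grid),
    scene = unclass(config$scene),
    noise = unclass(config$noise),
    sim = unclass(config$sim),
    reconstruction = unclass(config$reconstruction),
    dielectric = lapply(config$dielectric,
                        function(s) unclass(s)[setdiff(names(unclass(s)), "solute")]),
    roi = as.numeric(config$roi),
    output_dir = config$output_dir,
    log_level = config$log_level
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}
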