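#' Pixel grid of the indicator image plane
#'
#' Defines the raster on which all field, stress and birefringence images
#' live. The convention is fixed package-wide: `x` runs rightward along the
#' tube axis, `y` downward; pixels are indexed 0-based with the centre of
#' pixel `(ix, iy)` at physical position `((ix + 0.5) * pitch_mm,
#' (iy + 0.5) * pitch_mm)` in millimetres. Arrays are stored as `ny x nx`
#' matrices (rows are `y`).
#'
#' The default grid spans 20 mm x 8 mm, the field of view of the visualized
#' near-field images.
#'
#' @param nx,ny Pixel counts along x and y; both at least 16.
#' @param pitch_mm Physical pixel pitch in mm, positive.
#' @return A `teoim_grid` object.
#' @export
#' @examples
#' g <- grid_spec(160, 64, 0.125)  # 20 mm x 8 mm
#' grid_extent(g)
grid_spec <- function(nx = 160L, ny = 64L, pitch_mm = 0.125) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 16L || ny < 16L)
    abort("grid_spec: nx and ny must be integers >= 16")
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || !is.finite(pitch_mm) ||
      pitch_mm <= 0)
    abort("grid_spec: pitch_mm must be a single positive number")
  structure(list(nx = nx, ny = ny, pitch_mm = pitch_mm), class = "teoim_grid")
}

#' Default 20 mm x 8 mm imaging grid
#' @return A `teoim_grid` (160 x 64 pixels, 0.125 mm pitch).
#' @export
default_grid <- function() grid_spec(160L, 64L, 0.125)

#' @export
print.teoim_grid <- function(x, ...) {
  cat(sprintf("<teoim_grid> %d x %d px, %.4g mm/px (%.3g mm x %.3g mm)\n",
              x$nx, x$ny, x$pitch_mm, x$nx * x$pitch_mm, x$ny * x$pitch_mm))
  invisible(x)
}

#' Physical extent of a grid
#' @param grid A `teoim_grid`.
#' @return Named numeric `c(x_mm =, y_mm =)`.
#' @export
grid_extent <- function(grid) {
  c(x_mm = grid$nx * grid$pitch_mm, y_mm = grid$ny * grid$pitch_mm)
}

# pixel-centre coordinates (mm); offset = 0-based origin of a cropped array
grid_x <- function(grid, n = grid$nx, offset = 0L)
  (offset + seq_len(n) - 0.5) * grid$pitch_mm
grid_y <- function(grid, n = grid$ny, offset = 0L)
  (offset + seq_len(n) - 0.5) * grid$pitch_mm

# angular spatial frequencies (rad / mm) in FFT order. For odd-order
# derivatives on an even grid the unpaired Nyquist mode has no
# Hermitian-symmetric partner, so its wavenumber is zeroed (standard
# spectral-differentiation convention); `nyquist_zero` selects that variant.
k_angular <- function(n, d, nyquist_zero = FALSE) {
  j <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k <- 2 * pi * j / (n * d)
  if (nyquist_zero && n %% 2L == 0L) k[n / 2 + 1L] <- 0
  k
}

#' Gridded scalar field image
#'
#' A 2-D real field on a [grid_spec()] raster: a heat-source density map, a
#' near-field intensity map, or a birefringence channel. Values are stored as
#' an `ny x nx` matrix; a crop offset (`origin_px`, 0-based) records where a
#' sub-image sits inside its parent grid so physical coordinates survive
#' cropping.
#'
#' @param values Numeric `ny x nx` matrix of finite values.
#' @param grid A `teoim_grid` describing the parent raster.
#' @param role One of `"heat_source"`, `"field_intensity"`, `"beta"`,
#'   `"reconstruction"`.
#' @param origin_px Integer 0-based `(ix, iy)` offset of `values[1, 1]` within
#'   the parent grid.
#' @return A `teoim_field` object (matrix with metadata).
#' @export
field_map <- function(values, grid,
                      role = c("heat_source", "field_intensity", "beta",
                               "reconstruction"),
                      origin_px = c(0L, 0L)) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    abort("field_map: values must be a numeric matrix")
  if (!all(is.finite(values)))
    abort("field_map: values must all be finite")
  if (nrow(values) + origin_px[2] > grid$ny || ncol(values) + origin_px[1] > grid$nx)
    abort("field_map: values (plus origin offset) exceed the grid")
  structure(values, grid = grid, role = role,
            origin_px = as.integer(origin_px),
            class = c("teoim_field", class(values)))
}

field_grid <- function(x) attr(x, "grid")
field_role <- function(x) attr(x, "role")
field_origin <- function(x) attr(x, "origin_px")

#' @export
print.teoim_field <- function(x, ...) {
  g <- field_grid(x)
  cat(sprintf("<teoim_field: %s> %d x %d px of %d x %d grid, range [%.4g, %.4g]\n",
              field_role(x), nrow(x), ncol(x), g$ny, g$nx, min(x), max(x)))
  invisible(x)
}

#' Convert a field image to a tidy tibble
#'
#' @param x A `teoim_field`.
#' @param ... Unused.
#' @return Tibble with `x_mm`, `y_mm` (pixel centres) and `value`.
#' @export
as_tibble.teoim_field <- function(x, ...) {
  g <- field_grid(x)
  o <- field_origin(x)
  xs <- grid_x(g, ncol(x), o[1])
  ys <- grid_y(g, nrow(x), o[2])
  tibble::tibble(
    x_mm = rep(xs, each = nrow(x)),
    y_mm = rep(ys, times = ncol(x)),
    value = as.vector(unclass(x))
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plot a field image
#'
#' @param object A `teoim_field`.
#' @param ... Unused.
#' @return A ggplot raster of the field with physical axes (mm).
#' @export
autoplot.teoim_field <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = field_role(object)) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

# shared helper: check that two images live on the same grid
check_same_grid <- function(a, b, what = "images") {
  ga <- field_grid(a); gb <- field_grid(b)
  if (!identical(unclass(ga), unclass(gb)) ||
      !identical(dim(a), dim(b)))
    abort(sprintf("%s must share the same grid and shape", what))
  invisible(TRUE)
}
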