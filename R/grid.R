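#' Build a uniform wavelength grid
#'
#' Constructs the spectral axis of the imaging spectrometer: `n_bands` band
#' centers uniformly spaced between `start_nm` and `end_nm`, both endpoints
#' included. The instrument covered here records 243 bands from 550 to
#' 1700 nm, giving a spacing of 1150/242 (about 4.75 nm); the band count and
#' the range endpoints are taken as exact and the spacing follows from them.
#'
#' @param start_nm first band center in nanometres.
#' @param end_nm last band center in nanometres; must exceed `start_nm`.
#' @param n_bands number of bands (at least 2).
#' @return A `wavelength_grid` object: list with `band_centers_nm` (numeric
#'   vector, strictly increasing, uniformly spaced) and `n_bands`.
#' @examples
#' g <- build_wavelength_grid(550, 1700, 243)
#' g$n_bands
#' diff(range(g$band_centers_nm))
#' @export
build_wavelength_grid <- function(start_nm, end_nm, n_bands) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || length(start_nm) != 1L ||
      length(end_nm) != 1L || !is.finite(start_nm) || !is.finite(end_nm)) {
    stop("start_nm and end_nm must be single finite numbers", call. = FALSE)
  }
  if (start_nm >= end_nm) {
    stop("invalid wavelength range: start_nm must be < end_nm", call. = FALSE)
  }
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2L) {
    stop("n_bands must be an integer >= 2", call. = FALSE)
  }
  centers <- seq(start_nm, end_nm, length.out = n_bands)
  structure(
    list(band_centers_nm = centers, n_bands = n_bands),
    class = "wavelength_grid"
  )
}

#' The instrument wavelength grid
#'
#' 243 bands spanning 550 to 1700 nm, the grid of the extended-VNIR
#' push-broom spectrometer the pipeline was designed around.
#'
#' @return A [build_wavelength_grid()] result with 243 bands.
#' @export
instrument_grid <- function() build_wavelength_grid(550, 1700, 243)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %.1f-%.1f nm (spacing %.4f nm)\n",
    x$n_bands, x$band_centers_nm[1L], x$band_centers_nm[x$n_bands],
    grid_spacing(x)
  ))
  invisible(x)
}

#' Grid spacing in nm
#' @param grid a `wavelength_grid`.
#' @return The (uniform) spacing between adjacent band centers.
#' @export
grid_spacing <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  (grid$band_centers_nm[grid$n_bands] - grid$band_centers_nm[1L]) /
    (grid$n_bands - 1L)
}

validate_grid <- function(grid) {
  if (!inherits(grid, "wavelength_grid")) stop("not a wavelength_grid", call. = FALSE)
  w <- grid$band_centers_nm
  if (length(w) != grid$n_bands || grid$n_bands < 2L) {
    stop("grid length inconsistent with n_bands", call. = FALSE)
  }
  d <- diff(w)
  if (any(d <= 0)) stop("band centers must be strictly increasing", call. = FALSE)
  if (max(abs(d - d[1L])) > 1e-9 * max(abs(w))) {
    stop("band centers are not uniformly spaced", call. = FALSE)
  }
  invisible(grid)
}

#' Index of the band nearest a target wavelength
#'
#' Finds the band whose center is closest to `target_nm`; a tie between two
#' equidistant centers is broken toward the lower index. Used to pick the
#' red-edge (705 nm) and NIR (750 nm) NDVI bands, which have no exact match
#' on the instrument grid.
#'
#' @param grid a `wavelength_grid`.
#' @param target_nm target wavelength in nm; must lie within one grid spacing
#'   of the grid's range.
#' @return 1-based band index.
#' @examples
#' nearest_band(instrument_grid(), 705)
#' @export
nearest_band <- function(grid, target_nm) {
  validate_grid(grid)
  stopifnot(is.numeric(target_nm), length(target_nm) == 1L, is.finite(target_nm))
  w <- grid$band_centers_nm
  sp <- grid_spacing(grid)
  if (target_nm < w[1L] - sp || target_nm > w[grid$n_bands] + sp) {
    stop(sprintf("target %.1f nm is outside the grid range [%.1f, %.1f] nm",
                 target_nm, w[1L], w[grid$n_bands]), call. = FALSE)
  }
  # which.min returns the first minimum, i.e. the lower index on ties
  which.min(abs(w - target_nm))
}

#' Cube geometry
#'
#' Spatial layout of an image cube: number of scan lines (the vertical,
#' mirror-scanned dimension of the push-broom system), detector pixels per
#' line, and the square pixel size on the chamber floor plane.
#'
#' @param n_lines scan-line count.
#' @param n_samples detector pixels per line.
#' @param pixel_size_mm ground-sample distance in mm (square pixels).
#' @return A `cube_geometry` object with the fields above plus
#'   `vertical_coverage_mm = n_lines * pixel_size_mm` and
#'   `horizontal_coverage_mm = n_samples * pixel_size_mm`.
#' @export
cube_geometry <- function(n_lines, n_samples, pixel_size_mm) {
  n_lines <- as.integer(n_lines); n_samples <- as.integer(n_samples)
  if (is.na(n_lines) || n_lines < 1L || is.na(n_samples) || n_samples < 1L) {
    stop("n_lines and n_samples must be positive integers", call. = FALSE)
  }
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("pixel_size_mm must be positive", call. = FALSE)
  }
  structure(
    list(
      n_lines = n_lines, n_samples = n_samples, pixel_size_mm = pixel_size_mm,
      vertical_coverage_mm = n_lines * pixel_size_mm,
      horizontal_coverage_mm = n_samples * pixel_size_mm
    ),
    class = "cube_geometry"
  )
}

#' The instrument chamber geometry
#'
#' 500 scan lines by 320 detector pixels at 5 mm per pixel: 2500 mm of
#' vertical coverage (chamber height) and 1600 mm horizontal (chamber width).
#'
#' @return A [cube_geometry()].
#' @export
instrument_geometry <- function() cube_geometry(500L, 320L, 5)
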