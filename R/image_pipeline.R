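#' Normalize a plant scan by its blank-chamber reference scan
#'
#' Divides the plant cube by the paired reference cube band by band,
#' converting raw digital numbers to apparent reflectance. Because both scans
#' share the lamp spectrum and the illumination field, the ratio cancels
#' them. Ratios are clipped to `[0, 1]`; voxels where the reference intensity
#' is zero carry no information and are flagged invalid rather than clipped.
#'
#' @param plant a plant-scan [raw_cube()].
#' @param reference the paired reference-scan [raw_cube()]; must share shape
#'   and wavelength grid with `plant`.
#' @return A `reflectance_cube`: list with `values` (3-D array in `[0, 1]`),
#'   `valid` (3-D logical), `grid`, `geometry`.
#' @export
normalize_by_reference <- function(plant, reference) {
  stopifnot(inherits(plant, "raw_cube"), inherits(reference, "raw_cube"))
  if (!identical(dim(plant$values), dim(reference$values)) ||
      !isTRUE(all.equal(plant$grid$band_centers_nm, reference$grid$band_centers_nm))) {
    stop("incompatible cubes: plant and reference differ in shape or wavelength grid",
         call. = FALSE)
  }
  if (!identical(reference$role, "reference-scan")) {
    stop("incompatible cubes: second argument is not a reference-scan", call. = FALSE)
  }
  ref <- reference$values
  valid <- ref > 0
  vals <- plant$values / ifelse(valid, ref, 1)
  vals[vals > 1] <- 1
  vals[vals < 0] <- 0
  vals[!valid] <- NA_real_
  structure(
    list(values = vals, valid = valid, grid = plant$grid, geometry = plant$geometry),
    class = "reflectance_cube"
  )
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reflectance_cube> %d lines x %d samples x %d bands (%.1f%% valid)\n",
              d[1L], d[2L], d[3L], 100 * mean(x$valid)))
  invisible(x)
}

#' Compute an NDVI image from a reflectance cube
#'
#' Per-pixel normalized difference vegetation index
#' `(I750 - I705) / (I750 + I705)` using the grid bands nearest 705 nm
#' (red edge) and 750 nm (NIR shoulder). Green vegetation sits well above
#' zero; pot, carrier and belt pixels near zero. Pixels whose two input
#' bands are not both valid, or whose band sum is not positive, are marked
#' ineligible for segmentation.
#'
#' @param cube a `reflectance_cube` whose grid covers 705 and 750 nm.
#' @param red_edge_nm,nir_nm band targets in nm (defaults 705 and 750).
#' @return An `ndvi_image`: list with `values` (2-D, `NA` where ineligible),
#'   `eligible` (2-D logical), `i705_band`, `i750_band`.
#' @export
compute_ndvi <- function(cube, red_edge_nm = 705, nir_nm = 750) {
  stopifnot(inherits(cube, "reflectance_cube"))
  b705 <- nearest_band(cube$grid, red_edge_nm)
  b750 <- nearest_band(cube$grid, nir_nm)
  i705 <- cube$values[, , b705, drop = TRUE]
  i750 <- cube$values[, , b750, drop = TRUE]
  ok <- cube$valid[, , b705, drop = TRUE] & cube$valid[, , b750, drop = TRUE]
  s <- i750 + i705
  eligible <- ok & !is.na(s) & s > 0
  vals <- ifelse(eligible, (i750 - i705) / s, NA_real_)
  if (is.null(dim(vals))) dim(vals) <- dim(cube$values)[1:2]
  structure(
    list(values = vals, eligible = eligible, i705_band = b705, i750_band = b750),
    class = "ndvi_image"
  )
}

#' Segment plant pixels by NDVI thresholding
#'
#' A pixel belongs to the plant mask when its NDVI strictly exceeds the
#' threshold (default 0.20, the universal value used across both species)
#' and it was eligible for NDVI computation. No morphological cleanup is
#' applied. An empty mask is a legal result.
#'
#' @param ndvi an `ndvi_image`.
#' @param threshold NDVI cut-off; membership requires `ndvi > threshold`.
#' @return A `plant_mask`: list with `member` (2-D logical) and `n_pixels`.
#' @export
segment_plant <- function(ndvi, threshold = 0.20) {
  stopifnot(inherits(ndvi, "ndvi_image"), is.numeric(threshold), length(threshold) == 1L)
  member <- !is.na(ndvi$values) & ndvi$eligible & ndvi$values > threshold
  structure(
    list(member = member, n_pixels = sum(member)),
    class = "plant_mask"
  )
}

#' Extract the mean reflectance spectrum of the masked plant
#'
#' Averages the reflectance of the masked pixels band by band, ignoring
#' invalid entries, and records the number of pixels contributing to each
#' band. A band with no valid masked pixel is reported as `NA` (flagged, not
#' imputed) and should be excluded from downstream modeling.
#'
#' @param cube a `reflectance_cube`.
#' @param mask a `plant_mask` of matching spatial shape with `n_pixels > 0`.
#' @return A `reflectance_spectrum`: list with `reflectance` (length
#'   `n_bands`), `grid`, `n_pixels` (per-band contributing counts).
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(mask, "plant_mask"))
  d <- dim(cube$values)
  if (!identical(dim(mask$member), d[1:2])) {
    stop("mask shape does not match cube", call. = FALSE)
  }
  if (mask$n_pixels == 0L) {
    stop("empty plant mask: segmentation found no vegetation pixels", call. = FALSE)
  }
  nb <- d[3L]
  flat <- matrix(cube$values, nrow = d[1L] * d[2L], ncol = nb)
  vflat <- matrix(cube$valid, nrow = d[1L] * d[2L], ncol = nb)
  sel <- as.vector(mask$member)
  sub <- flat[sel, , drop = FALSE]
  vsub <- vflat[sel, , drop = FALSE]
  counts <- colSums(vsub)
  sums <- colSums(ifelse(vsub, sub, 0))
  refl <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(
    list(reflectance = refl, grid = cube$grid, n_pixels = counts),
    class = "reflectance_spectrum"
  )
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d bands, %d plant pixels\n",
              x$grid$n_bands, max(x$n_pixels)))
  invisible(x)
}

#' Process one plant scan into a mean reflectance spectrum
#'
#' Full per-plant image chain: normalize by the paired reference scan,
#' compute the NDVI image, threshold it into a plant mask, and average the
#' masked reflectance into one spectrum per plant (243 points on the
#' instrument grid).
#'
#' @param plant plant-scan [raw_cube()].
#' @param reference paired reference-scan [raw_cube()].
#' @param threshold NDVI segmentation threshold (default 0.20).
#' @param plant_id optional identifier used in error messages.
#' @return A `reflectance_spectrum`.
#' @export
process_scan <- function(plant, reference, threshold = 0.20, plant_id = NULL) {
  refl <- normalize_by_reference(plant, reference)
  ndvi <- compute_ndvi(refl)
  mask <- segment_plant(ndvi, threshold)
  if (mask$n_pixels == 0L) {
    stop("empty plant mask",
         if (!is.null(plant_id)) paste0(" for plant '", plant_id, "'") else "",
         ": no pixel exceeded NDVI ", threshold, call. = FALSE)
  }
  extract_mean_spectrum(refl, mask)
}
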