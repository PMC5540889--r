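gaussian_bump <- function(wl, center, sigma) exp(-(wl - center)^2 / (2 * sigma^2))

#' Load the trait-to-spectrum model of the simulator
#'
#' Reads the versioned loading calibration shipped with the package and
#' precomputes, on the given wavelength grid, one loading vector per trait
#' (reflectance change per trait unit) plus the trait reference levels.
#' The calibration is frozen: simulated datasets are comparable across
#' seeds and sessions as long as the version string matches.
#'
#' @param grid a [build_wavelength_grid()] result.
#' @param version calibration version (default `"1"`).
#' @param spectral_noise_sd per-band Gaussian noise added to each plant's
#'   generated spectrum (reflectance units; default 0.002).
#' @return A `spectral_model`: list with `loadings` (bands x traits matrix),
#'   `reference` (named trait reference levels), `grid`, `version`,
#'   `spectral_noise_sd`.
#' @export
spectral_model <- function(grid, version = "1", spectral_noise_sd = 0.002) {
  validate_grid(grid)
  path <- system.file("extdata", paste0("spectral_loadings_v", version, ".json"),
                      package = "hyperleaf", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  wl <- grid$band_centers_nm
  traits <- names(cfg$traits)
  L <- matrix(0, grid$n_bands, length(traits), dimnames = list(NULL, traits))
  ref <- numeric(length(traits)); names(ref) <- traits
  for (tr in traits) {
    spec <- cfg$traits[[tr]]
    ref[tr] <- spec$reference
    comps <- spec$components
    if (length(comps)) {
      for (k in seq_len(nrow(comps))) {
        L[, tr] <- L[, tr] +
          comps$amplitude[k] * gaussian_bump(wl, comps$center_nm[k], comps$sigma_nm[k])
      }
    }
  }
  structure(
    list(loadings = L, reference = ref, grid = grid, version = cfg$version,
         spectral_noise_sd = spectral_noise_sd),
    class = "spectral_model"
  )
}

#' Species baseline reflectance curve
#'
#' A smooth vegetation-like spectrum on the grid: low visible reflectance,
#' a sharp red edge between 700 and 750 nm, a NIR plateau, and Gaussian
#' water absorption troughs at 970, 1240 and 1450 nm with the 1450 nm trough
#' the deepest (the relative strengths of leaf water bands). The two species
#' differ by an offset plus a shape perturbation large enough to separate
#' them in principal-component space, as two crops with different canopy
#' structure do. Both baselines keep NDVI (705/750 nm) above the 0.20
#' segmentation threshold and stay within [0.01, 0.99].
#'
#' @param species `"maize"` or `"soybean"`.
#' @param grid a [build_wavelength_grid()] result.
#' @return Numeric reflectance vector, one value per band.
#' @export
make_species_baseline <- function(species = c("maize", "soybean"), grid) {
  species <- match.arg(species)
  validate_grid(grid)
  wl <- grid$band_centers_nm
  if (species == "maize") {
    vis <- 0.08; plateau <- 0.50; edge_center <- 715; edge_width <- 11
    troughs <- c(`970` = 0.050, `1240` = 0.090, `1450` = 0.160)
  } else {
    vis <- 0.10; plateau <- 0.45; edge_center <- 710; edge_width <- 13
    troughs <- c(`970` = 0.045, `1240` = 0.085, `1450` = 0.150)
  }
  red_edge <- 1 / (1 + exp(-(wl - edge_center) / edge_width))
  base <- vis + (plateau - vis) * red_edge
  # gentle SWIR decline past the plateau
  base <- base - 0.04 * pmax(0, (wl - 1100) / 600)
  sig <- c(`970` = 25, `1240` = 35, `1450` = 60)
  for (cn in names(troughs)) {
    base <- base - troughs[[cn]] * gaussian_bump(wl, as.numeric(cn), sig[[cn]])
  }
  if (species == "soybean") {
    # shape perturbation: slightly greener VIS, bent NIR shoulder
    base <- base + 0.015 * gaussian_bump(wl, 560, 40) -
      0.02 * gaussian_bump(wl, 1100, 120)
  }
  pmin(pmax(base, 0.01), 0.99)
}

#' Generate one plant's reflectance spectrum from its chemistry
#'
#' `reflectance = baseline(species) + L %*% (traits - reference) + noise`,
#' clipped to [0.01, 0.99]. Linear in the traits by construction (pre-noise,
#' pre-clip), so a linear calibration model can recover them. Traits at
#' their reference levels with zero noise reproduce the species baseline
#' exactly.
#'
#' @param chem_row single-row data frame from [sample_chemistry()].
#' @param model a [spectral_model()].
#' @param seed integer seed for the per-band spectral noise.
#' @return Numeric reflectance vector on the model's grid.
#' @export
chem_to_spectrum <- function(chem_row, model, seed = 1L) {
  stopifnot(inherits(model, "spectral_model"), nrow(chem_row) == 1L)
  traits <- colnames(model$loadings)
  x <- vapply(traits, function(tr) as.numeric(chem_row[[tr]]), numeric(1L))
  refl <- make_species_baseline(chem_row$species, model$grid) +
    drop(model$loadings %*% (x - model$reference))
  if (model$spectral_noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))
    refl <- refl + stats::rnorm(length(refl), 0, model$spectral_noise_sd)
  }
  pmin(pmax(refl, 0.01), 0.99)
}

# ---- scene rendering ------------------------------------------------------

#' Plant silhouette template
#'
#' Deterministic plant-shaped boolean template: an elliptical canopy over a
#' vertical stem, centered in the frame.
#'
#' @param geometry a [cube_geometry()].
#' @return Logical matrix `[line, sample]`.
#' @export
make_silhouette <- function(geometry) {
  L <- geometry$n_lines; S <- geometry$n_samples
  li <- matrix(seq_len(L), L, S)
  si <- matrix(seq_len(S), L, S, byrow = TRUE)
  canopy <- ((li - 0.42 * L) / (0.28 * L))^2 + ((si - 0.5 * S) / (0.30 * S))^2 <= 1
  stem <- abs(si - 0.5 * S) <= max(1, 0.03 * S) & li >= 0.42 * L & li <= 0.85 * L
  canopy | stem
}

#' Smooth non-uniform illumination field
#'
#' Strictly positive multiplicative gain over the chamber: a broad central
#' hot spot over a base level, emulating the banked halogen lamps.
#'
#' @param geometry a [cube_geometry()].
#' @param variation peak-over-base gain excess (default 0.3; 0 = flat field).
#' @return Numeric matrix `[line, sample]`, all entries > 0.
#' @export
make_illumination <- function(geometry, variation = 0.3) {
  L <- geometry$n_lines; S <- geometry$n_samples
  li <- matrix(seq_len(L), L, S)
  si <- matrix(seq_len(S), L, S, byrow = TRUE)
  0.8 + variation * exp(-(((li - 0.4 * L) / (0.6 * L))^2 +
                            ((si - 0.5 * S) / (0.6 * S))^2))
}

# Halogen-lamp relative spectral output: Planck curve at the lamp color
# temperature, normalized to peak 1 on the grid.
lamp_spectrum <- function(grid, temperature_k = 2600) {
  wl_m <- grid$band_centers_nm * 1e-9
  h <- 6.62607015e-34; c <- 2.99792458e8; kb <- 1.380649e-23
  b <- 1 / (wl_m^5 * (exp(h * c / (wl_m * kb * temperature_k)) - 1))
  b / max(b)
}

#' Scene specification for the renderer
#'
#' @param silhouette logical plant template (`[line, sample]`).
#' @param illumination positive gain field of the same shape.
#' @param noise_sd detector noise SD in digital numbers (default 30).
#' @param background_reflectance flat reflectance of pot/carrier/belt pixels
#'   (default 0.05; NDVI of a flat reflector is 0, so the background never
#'   survives segmentation). Synthetic invention: the real chamber background
#'   is not characterized quantitatively.
#' @param full_scale digital number of a perfect diffuse reflector under
#'   unit gain at the lamp peak (default 40000).
#' @param seed integer seed for the detector noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(silhouette, illumination, noise_sd = 30,
                       background_reflectance = 0.05, full_scale = 40000,
                       seed = 1L) {
  stopifnot(is.logical(silhouette), is.matrix(silhouette),
            identical(dim(silhouette), dim(illumination)))
  if (any(illumination <= 0)) {
    stop("illumination field must be strictly positive", call. = FALSE)
  }
  structure(
    list(silhouette = silhouette, illumination = illumination,
         noise_sd = noise_sd, background_reflectance = background_reflectance,
         full_scale = full_scale, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Render a plant scan and its paired reference scan
#'
#' Builds the two 16-bit cubes the instrument would record:
#' `reference DN = round(gain * lamp * full_scale)` and
#' `plant DN = round(gain * lamp * full_scale * reflectance + noise)`, with
#' the input spectrum inside the plant silhouette and the flat background
#' reflectance elsewhere. Both cubes share the illumination field and lamp
#' spectrum, so dividing plant by reference recovers the reflectance up to
#' rounding and detector noise.
#'
#' @param spectrum per-band reflectance of the plant (length = grid bands).
#' @param scene a [scene_spec()].
#' @param grid a [build_wavelength_grid()] result.
#' @param geometry a [cube_geometry()] matching the scene shape.
#' @return List with `plant` and `reference`, both [raw_cube()]s.
#' @export
render_scene <- function(spectrum, scene, grid, geometry) {
  stopifnot(inherits(scene, "scene_spec"))
  validate_grid(grid)
  if (length(spectrum) != grid$n_bands) {
    stop("spectrum length does not match the grid", call. = FALSE)
  }
  if (!identical(dim(scene$silhouette),
                 c(geometry$n_lines, geometry$n_samples))) {
    stop("scene shape does not match geometry", call. = FALSE)
  }
  lamp <- lamp_spectrum(grid)
  gain <- scene$illumination
  # [line, sample, band] = gain[l,s] * lamp[b] * full_scale
  ref_field <- outer(gain, lamp) * scene$full_scale
  if (max(ref_field) > 65535) {
    stop("scaling error: reference digital numbers overflow 16 bits", call. = FALSE)
  }
  refl <- array(scene$background_reflectance,
                dim = c(geometry$n_lines, geometry$n_samples, grid$n_bands))
  sil <- which(scene$silhouette)
  npx <- geometry$n_lines * geometry$n_samples
  for (b in seq_len(grid$n_bands)) {
    refl[sil + (b - 1L) * npx] <- spectrum[b]
  }
  plant_field <- ref_field * refl
  if (scene$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(scene$seed)
    plant_field <- plant_field + stats::rnorm(length(plant_field), 0, scene$noise_sd)
  }
  plant_dn <- pmin(pmax(round(plant_field), 0), 65535)
  ref_dn <- round(ref_field)
  list(
    plant = raw_cube(plant_dn, grid, geometry, "plant-scan"),
    reference = raw_cube(ref_dn, grid, geometry, "reference-scan")
  )
}

#' Generate a complete simulated imaging bundle
#'
#' The simulator's end product: a chemistry table for the full study design,
#' one rendered plant/reference cube pair per plant on disk, and a
#' ground-truth manifest (per-plant generating spectrum, loadings version,
#' seed). Fully reproducible: the same config and seed give a byte-identical
#' bundle.
#'
#' @param config a [run_config()]; its `$sim` block sets the design counts,
#'   cube size, noise levels and loadings version.
#' @param seed master integer seed; per-plant seeds are derived from it.
#' @param force overwrite an existing bundle directory (default `FALSE`).
#' @return Invisibly, a list with `chem`, `manifest`, and the output paths.
#' @export
make_dataset <- function(config, seed = 1L, force = FALSE) {
  sim <- config$sim
  out_dir <- config$out_dir
  cube_dir <- file.path(out_dir, "cubes")
  if (dir.exists(cube_dir) && length(dir(cube_dir))) {
    if (!force) {
      stop("bundle already exists at ", cube_dir, "; use force = TRUE to overwrite",
           call. = FALSE)
    }
    unlink(cube_dir, recursive = TRUE)
  }
  dir.create(cube_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- build_wavelength_grid(sim$start_nm, sim$end_nm, sim$n_bands)
  geometry <- cube_geometry(sim$n_lines, sim$n_samples, sim$pixel_size_mm)
  model <- spectral_model(grid, version = sim$loadings_version,
                          spectral_noise_sd = sim$spectral_noise_sd)
  design <- default_design(sim$n_water, sim$n_nutrient)
  chem <- sample_chemistry(design, seed = seed)
  sil <- make_silhouette(geometry)
  illum <- make_illumination(geometry, sim$illumination_variation)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  plant_seeds <- sample.int(.Machine$integer.max - 1L, 2L * nrow(chem))
  manifest_plants <- vector("list", nrow(chem))
  for (i in seq_len(nrow(chem))) {
    id <- chem$id[i]
    spectrum <- chem_to_spectrum(chem[i, , drop = FALSE], model,
                                 seed = plant_seeds[2L * i - 1L])
    scene <- scene_spec(sil, illum, noise_sd = sim$detector_noise_sd,
                        background_reflectance = sim$background_reflectance,
                        full_scale = sim$full_scale,
                        seed = plant_seeds[2L * i])
    cubes <- render_scene(spectrum, scene, grid, geometry)
    plant_path <- file.path(cube_dir, paste0(id, "_plant.bil"))
    ref_path <- file.path(cube_dir, paste0(id, "_ref.bil"))
    write_bil(cubes$plant, plant_path)
    write_bil(cubes$reference, ref_path)
    manifest_plants[[i]] <- list(
      id = id, plant_bil = basename(plant_path), reference_bil = basename(ref_path),
      true_spectrum = round(spectrum, 8)
    )
  }
  chem_path <- file.path(out_dir, "chemistry.csv")
  utils::write.csv(chem, chem_path, row.names = FALSE)
  manifest <- list(
    seed = as.integer(seed),
    loadings_version = model$version,
    n_plants = nrow(chem),
    grid = list(start_nm = sim$start_nm, end_nm = sim$end_nm, n_bands = sim$n_bands),
    geometry = list(n_lines = sim$n_lines, n_samples = sim$n_samples,
                    pixel_size_mm = sim$pixel_size_mm),
    background = "synthetic flat low-NDVI reflector (invented; not instrument-characterized)",
    plants = manifest_plants
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(chem = chem, manifest = manifest,
                 paths = list(out_dir = out_dir, cube_dir = cube_dir,
                              chemistry_csv = chem_path, manifest_json = manifest_path)))
}
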