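# Fixture builders and naive per-pixel loop oracles. The oracles are written
# deliberately slowly (explicit loops, no vectorization) so they share no
# code path with the implementation they check.

rand_grid <- function(n_bands, start = 550, end = 1700) {
  build_wavelength_grid(start, end, n_bands)
}

rand_raw_cube <- function(n_lines, n_samples, n_bands, role = "plant-scan",
                          grid = rand_grid(n_bands), max_dn = 65535L) {
  vals <- array(sample(0:max_dn, n_lines * n_samples * n_bands, replace = TRUE),
                dim = c(n_lines, n_samples, n_bands))
  raw_cube(vals, grid, cube_geometry(n_lines, n_samples, 5), role)
}

# reflectance_cube built directly from a values array (all entries valid)
make_refl_cube <- function(vals, grid = rand_grid(dim(vals)[3])) {
  structure(
    list(values = vals, valid = array(TRUE, dim(vals)), grid = grid,
         geometry = cube_geometry(dim(vals)[1], dim(vals)[2], 5)),
    class = "reflectance_cube"
  )
}

oracle_normalize <- function(plant, reference) {
  d <- dim(plant$values)
  vals <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (l in seq_len(d[1])) for (s in seq_len(d[2])) for (b in seq_len(d[3])) {
    r <- reference$values[l, s, b]
    if (r > 0) {
      valid[l, s, b] <- TRUE
      v <- plant$values[l, s, b] / r
      vals[l, s, b] <- min(max(v, 0), 1)
    }
  }
  list(values = vals, valid = valid)
}

oracle_ndvi <- function(refl, b705, b750) {
  d <- dim(refl$values)
  out <- matrix(NA_real_, d[1], d[2])
  elig <- matrix(FALSE, d[1], d[2])
  for (l in seq_len(d[1])) for (s in seq_len(d[2])) {
    if (refl$valid[l, s, b705] && refl$valid[l, s, b750]) {
      a <- refl$values[l, s, b750]; b <- refl$values[l, s, b705]
      if (a + b > 0) {
        elig[l, s] <- TRUE
        out[l, s] <- (a - b) / (a + b)
      }
    }
  }
  list(values = out, eligible = elig)
}

oracle_mask_count <- function(ndvi_values, eligible, threshold) {
  m <- 0L
  for (i in seq_along(ndvi_values)) {
    if (eligible[i] && !is.na(ndvi_values[i]) && ndvi_values[i] > threshold) {
      m <- m + 1L
    }
  }
  m
}

oracle_mean_spectrum <- function(refl, member) {
  d <- dim(refl$values)
  out <- numeric(d[3]); counts <- integer(d[3])
  for (b in seq_len(d[3])) {
    acc <- 0; k <- 0L
    for (l in seq_len(d[1])) for (s in seq_len(d[2])) {
      if (member[l, s] && refl$valid[l, s, b]) {
        acc <- acc + refl$values[l, s, b]
        k <- k + 1L
      }
    }
    counts[b] <- k
    out[b] <- if (k > 0) acc / k else NA_real_
  }
  list(reflectance = out, n_pixels = counts)
}

# small chemistry row with every trait at a given level
chem_row_at <- function(model, species = "maize", overrides = list()) {
  row <- as.list(model$reference)
  row$species <- species
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  as.data.frame(row, stringsAsFactors = FALSE)
}

# tiny run_config in a fresh temp dir
mini_config <- function(n_water = 2L, n_nutrient = 2L, n_lines = 16L,
                        n_samples = 16L, n_bands = 243L, seed = 1L,
                        sim_extra = list(), ...) {
  run_config(
    out_dir = tempfile("bundle"),
    seed = seed,
    sim = c(list(n_water = n_water, n_nutrient = n_nutrient, n_lines = n_lines,
                 n_samples = n_samples, n_bands = n_bands), sim_extra),
    ...
  )
}
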