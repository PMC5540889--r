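test_that("the water-content identity holds exactly for every generated row", {
  chem <- sample_chemistry(seed = 7)
  expect_identical(nrow(chem), 120L)
  expect_equal(chem$wc, (chem$w_fresh - chem$w_dry) / chem$w_fresh * 100)
  expect_true(all(chem$w_dry <= chem$w_fresh))
  traits <- c("n", "p", "k", "mg", "ca", "s", "na", "fe", "mn", "b", "cu", "zn")
  expect_true(all(as.matrix(chem[traits]) >= 0))
  # formula check at round numbers
  expect_equal((10 - 2) / 10 * 100, 80)
})

test_that("pooled ranges stay inside the study envelope for any seed", {
  for (seed in c(1, 99, 2026)) {
    chem <- sample_chemistry(seed = seed)
    expect_true(all(chem$wc[chem$species == "maize"] >= 79.6))
    expect_true(all(chem$wc[chem$species == "maize"] <= 91.0))
    expect_true(all(chem$wc[chem$species == "soybean"] >= 68.2))
    expect_true(all(chem$wc[chem$species == "soybean"] <= 81.9))
    expect_true(all(chem$n >= 0.96 & chem$n <= 5.68))
  }
})

test_that("a large draw approaches the nitrogen range endpoints", {
  chem <- sample_chemistry(default_design(135L, 90L), seed = 11) # 1080 plants
  expect_gte(min(chem$n), 0.96)
  expect_lte(max(chem$n), 5.68)
  expect_lt(min(chem$n), 0.96 + 0.3)
  expect_gt(max(chem$n), 5.68 - 0.3)
})

test_that("nutrient treatments order responsive traits and spare Na/B", {
  chem <- sample_chemistry(default_design(5L, 60L), seed = 13)
  nut <- chem[chem$experiment == "nutrient", ]
  mean_by <- function(tr) tapply(nut[[tr]], nut$treatment, mean)[c("low", "medium", "high")]
  for (tr in c("n", "p", "k", "mg", "ca", "s", "fe", "mn", "cu", "zn")) {
    m <- mean_by(tr)
    expect_true(all(diff(m) > 0), label = paste("ordered means for", tr))
  }
  for (tr in c("na", "b")) {
    m <- mean_by(tr)
    expect_lt(max(m) - min(m), 0.2 * stats::sd(nut[[tr]]))
  }
})

test_that("invalid designs are rejected", {
  bad <- default_design()
  bad$n[1] <- 0L
  expect_error(sample_chemistry(bad), "counts must be >= 1")
})

test_that("species baselines are segmentable, bounded and water-banded", {
  g <- instrument_grid()
  for (sp in c("maize", "soybean")) {
    base <- make_species_baseline(sp, g)
    expect_true(all(base >= 0.01 & base <= 0.99))
    i705 <- base[nearest_band(g, 705)]
    i750 <- base[nearest_band(g, 750)]
    expect_gt((i750 - i705) / (i750 + i705), 0.2)
    # water trough depth below the local continuum: 1450 deeper than 970
    depth <- function(center, shoulders) {
      sh <- vapply(shoulders, function(w) base[nearest_band(g, w)], numeric(1))
      mean(sh) - base[nearest_band(g, center)]
    }
    d970 <- depth(970, c(900, 1060))
    d1450 <- depth(1450, c(1300, 1660))
    expect_gt(d1450, d970)
    expect_gt(d970, 0)
  }
  # the two species differ enough to matter spectrally
  expect_gt(max(abs(make_species_baseline("maize", g) -
                      make_species_baseline("soybean", g))), 0.02)
})

test_that("chemistry at reference levels reproduces the baseline exactly", {
  g <- instrument_grid()
  model <- spectral_model(g, spectral_noise_sd = 0)
  row <- chem_row_at(model, "maize")
  expect_equal(chem_to_spectrum(row, model), make_species_baseline("maize", g))
})

test_that("raising water content deepens the 1450 nm trough", {
  g <- instrument_grid()
  model <- spectral_model(g, spectral_noise_sd = 0)
  lo <- chem_to_spectrum(chem_row_at(model, overrides = list(wc = 70)), model)
  hi <- chem_to_spectrum(chem_row_at(model, overrides = list(wc = 90)), model)
  b1450 <- nearest_band(g, 1450)
  expect_lt(hi[b1450], lo[b1450])
})

test_that("sodium and boron are spectrally silent", {
  g <- instrument_grid()
  model <- spectral_model(g, spectral_noise_sd = 0)
  s1 <- chem_to_spectrum(chem_row_at(model, overrides = list(na = 0.002, b = 15)), model)
  s2 <- chem_to_spectrum(chem_row_at(model, overrides = list(na = 0.019, b = 75)), model)
  expect_identical(s1, s2)
})

test_that("generated spectra are linear in the traits", {
  g <- instrument_grid()
  model <- spectral_model(g, spectral_noise_sd = 0)
  base_row <- chem_row_at(model)
  s0 <- chem_to_spectrum(base_row, model)
  for (tr in c("wc", "n", "ca", "cu")) {
    delta <- model$reference[[tr]] * 0.05 + 0.01
    row2 <- base_row; row2[[tr]] <- row2[[tr]] + delta
    fd <- (chem_to_spectrum(row2, model) - s0) / delta
    expect_equal(fd, unname(model$loadings[, tr]), tolerance = 1e-8)
  }
})

test_that("rendering inverts through the pipeline and respects the gain field", {
  g <- instrument_grid()
  geo <- cube_geometry(24, 20, 5)
  model <- spectral_model(g, spectral_noise_sd = 0)
  spectrum <- chem_to_spectrum(chem_row_at(model), model)
  sil <- make_silhouette(geo)
  flat <- scene_spec(sil, matrix(1, 24, 20), noise_sd = 0)
  got <- process_scan(render_scene(spectrum, flat, g, geo)$plant,
                      render_scene(spectrum, flat, g, geo)$reference)
  expect_lt(max(abs(got$reflectance - spectrum)), 2e-4)

  # a background-only scene has no vegetation signal
  empty_scene <- scene_spec(matrix(FALSE, 24, 20), matrix(1, 24, 20), noise_sd = 0)
  cubes <- render_scene(spectrum, empty_scene, g, geo)
  nd <- compute_ndvi(normalize_by_reference(cubes$plant, cubes$reference))
  expect_identical(segment_plant(nd)$n_pixels, 0L)
})

test_that("scene validation catches bad illumination and overflow", {
  geo <- cube_geometry(8, 8, 5)
  sil <- make_silhouette(geo)
  expect_error(scene_spec(sil, matrix(0, 8, 8)), "strictly positive")
  g <- build_wavelength_grid(550, 1700, 10)
  sc <- scene_spec(sil, matrix(2, 8, 8), noise_sd = 0, full_scale = 60000)
  expect_error(render_scene(rep(0.5, 10), sc, g, geo), "overflow")
})

test_that("a mini bundle has the right structure and is byte-reproducible", {
  cfg <- mini_config(n_water = 2L, n_nutrient = 1L, n_lines = 12L,
                     n_samples = 10L, n_bands = 24L)
  res <- suppressMessages(cmd_simulate(cfg))
  n_plants <- 2L * (2L * 2L + 1L * 3L) # species x (water cells + nutrient cells)
  expect_identical(res$manifest$n_plants, n_plants)
  cube_files <- dir(file.path(cfg$out_dir, "cubes"))
  expect_identical(sum(grepl("_plant\\.bil$", cube_files)), n_plants)
  expect_identical(sum(grepl("_ref\\.bil$", cube_files)), n_plants)
  expect_true(file.exists(file.path(cfg$out_dir, "chemistry.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "manifest.json")))

  # same seed, fresh directory: byte-identical bundle
  cfg2 <- cfg; cfg2$out_dir <- tempfile("bundle2")
  suppressMessages(make_dataset(cfg2, seed = cfg$seed))
  for (f in c(file.path("cubes", cube_files), "chemistry.csv", "manifest.json")) {
    expect_identical(
      unname(tools::md5sum(file.path(cfg$out_dir, f))),
      unname(tools::md5sum(file.path(cfg2$out_dir, f))),
      label = paste("md5 of", f)
    )
  }
  # overwrite guard
  expect_error(make_dataset(cfg, seed = cfg$seed), "force = TRUE")
})
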