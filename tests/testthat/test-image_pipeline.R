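test_that("self-normalization gives all-ones and zero references flag invalid", {
  g <- rand_grid(4)
  geo <- cube_geometry(3, 3, 5)
  set.seed(1)
  v <- array(sample(1:60000, 36, TRUE), c(3, 3, 4))
  plant <- raw_cube(v, g, geo, "plant-scan")
  ref <- raw_cube(v, g, geo, "reference-scan")
  rc <- normalize_by_reference(plant, ref)
  expect_true(all(rc$values == 1))
  expect_true(all(rc$valid))

  v0 <- v; v0[2, 2, 3] <- 0L
  ref0 <- raw_cube(v0, g, geo, "reference-scan")
  rc0 <- normalize_by_reference(plant, ref0)
  expect_false(rc0$valid[2, 2, 3])
  expect_true(is.na(rc0$values[2, 2, 3]))
  keep <- rc0$valid
  expect_equal(rc0$values[keep], rc$values[keep] * (v / v0)[keep])
})

test_that("normalization matches the per-voxel ratio-then-clip oracle", {
  set.seed(11)
  for (rep in 1:10) {
    plant <- rand_raw_cube(4, 4, 5)
    ref <- rand_raw_cube(4, 4, 5, role = "reference-scan", max_dn = 40000L)
    # sprinkle zero reference voxels
    z <- sample(length(ref$values), 5)
    ref$values[z] <- 0L
    rc <- normalize_by_reference(plant, ref)
    orc <- oracle_normalize(plant, ref)
    expect_equal(rc$values, orc$values)
    expect_identical(rc$valid, orc$valid)
    expect_true(all(rc$values[rc$valid] >= 0 & rc$values[rc$valid] <= 1))
  }
})

test_that("mismatched cubes and wrong roles are refused", {
  a <- rand_raw_cube(2, 2, 3)
  b <- rand_raw_cube(2, 3, 3, role = "reference-scan")
  expect_error(normalize_by_reference(a, b), "incompatible")
  c2 <- rand_raw_cube(2, 2, 3, role = "plant-scan")
  expect_error(normalize_by_reference(a, c2), "not a reference-scan")
})

test_that("NDVI reproduces hand values and the per-pixel loop oracle", {
  g <- instrument_grid()
  b705 <- nearest_band(g, 705); b750 <- nearest_band(g, 750)
  vals <- array(0.3, c(2, 2, 243))
  vals[1, 1, b705] <- 0.5; vals[1, 1, b750] <- 0.5   # -> 0
  vals[1, 2, b705] <- 0.2; vals[1, 2, b750] <- 0.6   # -> 0.5
  rc <- make_refl_cube(vals, g)
  nd <- compute_ndvi(rc)
  expect_equal(nd$values[1, 1], 0)
  expect_equal(nd$values[1, 2], 0.5)
  expect_identical(nd$i705_band, b705)
  expect_identical(nd$i750_band, b750)

  set.seed(5)
  for (rep in 1:8) {
    rc <- make_refl_cube(array(runif(4 * 5 * 243), c(4, 5, 243)), g)
    rc$valid[sample(length(rc$valid), 20)] <- FALSE
    rc$values[!rc$valid] <- NA_real_
    nd <- compute_ndvi(rc)
    orc <- oracle_ndvi(rc, b705, b750)
    expect_equal(nd$values, orc$values)
    expect_identical(nd$eligible, orc$eligible)
  }
})

test_that("NDVI requires the grid to cover both target bands", {
  rc <- make_refl_cube(array(0.5, c(2, 2, 100)), build_wavelength_grid(900, 1700, 100))
  expect_error(compute_ndvi(rc), "outside the grid")
})

test_that("NDVI is invariant to positive scaling of the cube", {
  g <- instrument_grid()
  set.seed(9)
  vals <- array(runif(3 * 3 * 243, 0.01, 0.25), c(3, 3, 243))
  nd1 <- compute_ndvi(make_refl_cube(vals, g))
  nd2 <- compute_ndvi(make_refl_cube(vals * 3.7, g)) # stays below clip range? no: 0.925 max, fine
  expect_equal(nd1$values, nd2$values)
})

test_that("segmentation thresholds strictly and counts exactly", {
  mk <- function(v) {
    structure(list(values = v, eligible = !is.na(v), i705_band = 1L, i750_band = 2L),
              class = "ndvi_image")
  }
  full <- segment_plant(mk(matrix(0.5, 4, 4)))
  expect_identical(full$n_pixels, 16L)
  empty <- segment_plant(mk(matrix(0.1, 4, 4)))
  expect_identical(empty$n_pixels, 0L)
  # exactly-threshold pixels are excluded (strict inequality)
  at <- segment_plant(mk(matrix(c(0.20, 0.2000001, NA, 0.9), 2, 2)))
  expect_identical(at$n_pixels, 2L)

  set.seed(13)
  for (rep in 1:10) {
    v <- matrix(runif(30, -0.2, 0.6), 5, 6)
    v[sample(30, 3)] <- NA
    m <- segment_plant(mk(v), threshold = 0.2)
    expect_identical(m$n_pixels, oracle_mask_count(v, !is.na(v), 0.2))
    expect_identical(m$n_pixels, sum(m$member))
  }
})

test_that("mean spectrum extraction matches constant, two-pixel and loop oracles", {
  g <- rand_grid(6)
  S <- runif(6)
  vals <- array(rep(S, each = 12), c(3, 4, 6))
  rc <- make_refl_cube(vals, g)
  mask <- structure(list(member = matrix(TRUE, 3, 4), n_pixels = 12L),
                    class = "plant_mask")
  expect_equal(extract_mean_spectrum(rc, mask)$reflectance, S)

  # two pixels with spectra a and b -> (a+b)/2
  a <- runif(6); b <- runif(6)
  vals2 <- array(0, c(1, 2, 6)); vals2[1, 1, ] <- a; vals2[1, 2, ] <- b
  rc2 <- make_refl_cube(vals2, g)
  mask2 <- structure(list(member = matrix(TRUE, 1, 2), n_pixels = 2L),
                     class = "plant_mask")
  expect_equal(extract_mean_spectrum(rc2, mask2)$reflectance, (a + b) / 2)

  set.seed(17)
  for (rep in 1:10) {
    rc3 <- make_refl_cube(array(runif(5 * 4 * 6), c(5, 4, 6)), g)
    rc3$valid[sample(length(rc3$valid), 10)] <- FALSE
    member <- matrix(runif(20) > 0.4, 5, 4)
    if (!any(member)) member[1, 1] <- TRUE
    mask3 <- structure(list(member = member, n_pixels = sum(member)),
                       class = "plant_mask")
    got <- extract_mean_spectrum(rc3, mask3)
    orc <- oracle_mean_spectrum(rc3, member)
    expect_equal(got$reflectance, orc$reflectance)
    expect_equal(got$n_pixels, orc$n_pixels)
  }
})

test_that("empty masks are an error at extraction", {
  rc <- make_refl_cube(array(0.5, c(2, 2, 3)), rand_grid(3))
  mask <- structure(list(member = matrix(FALSE, 2, 2), n_pixels = 0L),
                    class = "plant_mask")
  expect_error(extract_mean_spectrum(rc, mask), "empty plant mask")
})

test_that("mean spectrum is permutation-invariant and monotone under mask growth", {
  g <- rand_grid(5)
  set.seed(23)
  vals <- array(runif(4 * 4 * 5), c(4, 4, 5))
  rc <- make_refl_cube(vals, g)
  member <- matrix(runif(16) > 0.5, 4, 4); member[1, 1] <- TRUE
  mask <- structure(list(member = member, n_pixels = sum(member)), class = "plant_mask")
  base <- extract_mean_spectrum(rc, mask)$reflectance

  # permute pixel order consistently in cube and mask
  perm <- sample(16)
  vals_p <- array(0, c(4, 4, 5))
  flat <- matrix(vals, 16, 5)[perm, ]
  for (b in 1:5) vals_p[, , b] <- matrix(flat[, b], 4, 4)
  member_p <- matrix(as.vector(member)[perm], 4, 4)
  mask_p <- structure(list(member = member_p, n_pixels = sum(member_p)), class = "plant_mask")
  expect_equal(extract_mean_spectrum(make_refl_cube(vals_p, g), mask_p)$reflectance, base)

  # add pixels with uniformly higher reflectance: no band mean can drop
  vals_hi <- vals
  add <- which(!member)[1:3]
  for (b in 1:5) {
    plane <- vals_hi[, , b]
    plane[add] <- max(vals[, , b]) + 0.01
    vals_hi[, , b] <- plane
  }
  member_hi <- member; member_hi[add] <- TRUE
  mask_hi <- structure(list(member = member_hi, n_pixels = sum(member_hi)), class = "plant_mask")
  grown <- extract_mean_spectrum(make_refl_cube(vals_hi, g), mask_hi)$reflectance
  expect_true(all(grown >= base - 1e-12))
})

test_that("process_scan composes the chain and reports empty vegetation", {
  cfg_grid <- instrument_grid()
  geo <- cube_geometry(20, 16, 5)
  model <- spectral_model(cfg_grid, spectral_noise_sd = 0)
  spectrum <- chem_to_spectrum(chem_row_at(model), model)
  scene <- scene_spec(make_silhouette(geo), make_illumination(geo, 0.3),
                      noise_sd = 0)
  cubes <- render_scene(spectrum, scene, cfg_grid, geo)
  spec <- process_scan(cubes$plant, cubes$reference)
  expect_length(spec$reflectance, 243L)

  # plant identical to reference: NDVI == 0 everywhere, below threshold
  expect_error(
    process_scan(cubes$reference, cubes$reference, plant_id = "px7"),
    "empty plant mask.*px7"
  )
})

test_that("reference division cancels the illumination field", {
  g <- instrument_grid()
  geo <- cube_geometry(20, 16, 5)
  model <- spectral_model(g, spectral_noise_sd = 0)
  spectrum <- chem_to_spectrum(chem_row_at(model, "soybean"), model)
  sil <- make_silhouette(geo)
  flat <- scene_spec(sil, matrix(1, 20, 16), noise_sd = 0, full_scale = 30000)
  steep <- scene_spec(sil, make_illumination(geo, 1.0), noise_sd = 0,
                      full_scale = 30000) # gain spans a 2x range
  s_flat <- process_scan(render_scene(spectrum, flat, g, geo)$plant,
                         render_scene(spectrum, flat, g, geo)$reference)
  s_steep <- process_scan(render_scene(spectrum, steep, g, geo)$plant,
                          render_scene(spectrum, steep, g, geo)$reference)
  # both recover the generating spectrum up to DN rounding
  expect_lt(max(abs(s_flat$reflectance - spectrum)), 2e-4)
  expect_lt(max(abs(s_steep$reflectance - spectrum)), 2e-4)
  expect_lt(max(abs(s_steep$reflectance - s_flat$reflectance)), 2e-4)
})
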