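test_that("PCA basis recovers an exact low-rank construction", {
  # 24 spectra built from exactly 2 basis functions: cumulative explained
  # variance at k = 2 must be 1 and the residual rank collapses
  refl2 <- gen_reflectances_span(24, seed = 9, k = 2)
  b2 <- fit_basis(refl2, k = 2)
  expect_equal(sum(b2$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_error(fit_basis(refl2, k = 5), "rank 2")
})

test_that("PCA basis satisfies its structural invariants", {
  refl <- gen_reflectances(24, seed = 1)
  b <- fit_basis(refl, k = 6)
  # orthonormal columns
  expect_lt(max(abs(crossprod(b$EV) - diag(6))), 1e-8)
  # nonincreasing per-component variance, nondecreasing cumulative
  expect_true(all(diff(b$explained_variance_ratio) <= 1e-12))
  expect_true(all(b$explained_variance_ratio >= 0))
  expect_lte(sum(b$explained_variance_ratio), 1 + 1e-12)
  # sign convention: dominant element of each column is positive
  for (j in 1:6) expect_gt(b$EV[which.max(abs(b$EV[, j])), j], 0)
  # training scores reproduce the centered spectra at full rank
  rough <- withr::with_seed(4, as_spectra(matrix(runif(10 * 401), 10),
                                          spectral_grid()))
  b_full <- fit_basis(rough, k = 9)
  sc <- sweep(unclass(rough), 2, b_full$mean_spectrum) %*% b_full$EV
  back <- sweep(sc %*% t(b_full$EV), 2, b_full$mean_spectrum, `+`)
  expect_equal(unname(back), unname(unclass(rough)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(b_full$explained_variance_ratio), 1, tolerance = 1e-10)
})

test_that("identical spectra are rejected as a degenerate basis input", {
  flat <- as_spectra(matrix(0.5, 10, 401), spectral_grid())
  expect_error(fit_basis(flat, k = 1), "rank 0")
})

test_that("the exact world is reconstructed to machine precision", {
  world <- make_exact_world()
  models <- fit_world_models(world)
  rmse <- spectrum_rmse(models$recon, world$refl)
  expect_lt(max(rmse), 1e-8)
})

test_that("spectra already in the basis span are reproduced through the full pipeline", {
  # projection idempotence: a fresh spectrum drawn from the same span,
  # pushed through camera -> correction -> mapping, comes back unchanged
  world <- make_exact_world()
  models <- fit_world_models(world)
  probe <- gen_reflectances_span(5, seed = 77, k = 3)
  xyz <- spectrum_to_xyz(probe)
  # same capture session as the calibration: reuse its exposure gain
  rgb <- camera_capture(world$cam, xyz,
                        gain = attr(world$wli$patch_rgb, "gain"))
  rec <- reconstruct_spectrum(models$mapping, models$basis,
                              apply_correction(models$correction, camera_xyz(rgb)))
  expect_lt(max(spectrum_rmse(rec, probe)), 1e-6)
})

test_that("noiseless end-to-end recovery holds across seeds", {
  rmses <- vapply(1:10, function(s) {
    world <- make_exact_world(refl_seed = s, cam_seed = s + 30)
    models <- fit_world_models(world)
    mean(spectrum_rmse(models$recon, world$refl))
  }, numeric(1))
  expect_lt(mean(rmses), 1e-6)
})

test_that("permuting patch order leaves the fitted mapping unchanged", {
  world <- make_default_world()
  models <- fit_world_models(world, k = 6)
  perm <- withr::with_seed(8, sample(24))
  rgb <- world$wli$patch_rgb[perm, ]
  cal_p <- patch_calibration_set(rgb, as_spectra(unclass(world$refl)[perm, ],
                                                 spectral_grid()))
  m_p <- fit_correction(cal_p)
  mp_p <- fit_mapping(models$basis, cal_p, m_p)
  expect_equal(mp_p$M, models$mapping$M, tolerance = 1e-8)
})

test_that("hypercube reconstruction matches the scalar path pixel for pixel", {
  world <- make_default_world()
  models <- fit_world_models(world, k = 6)
  img <- world$wli$img
  cube <- image_to_hypercube(img, models$correction, models$mapping,
                             models$basis)
  expect_equal(dim(cube$values), c(128, 192, 401))
  withr::with_seed(13, {
    for (i in 1:100) {
      r <- sample(128, 1); c <- sample(192, 1)
      scalar <- reconstruct_spectrum(
        models$mapping, models$basis,
        apply_correction(models$correction, camera_xyz(img[r, c, ]))
      )
      expect_lt(max(abs(cube$values[r, c, ] - scalar[1, ])), 1e-10)
    }
  })
  # 1x1 image equals the scalar path; uniform images give uniform cubes
  one <- array(img[1, 1, ], dim = c(1, 1, 3))
  cube1 <- image_to_hypercube(one, models$correction, models$mapping,
                              models$basis)
  expect_equal(cube1$values[1, 1, ], cube$values[1, 1, ], tolerance = 1e-12)
  expect_error(image_to_hypercube(img[, , 1], models$correction,
                                  models$mapping, models$basis), "RGB")
})

test_that("reconstruction clamps nonphysical reflectance and logs the count", {
  world <- make_default_world()
  models <- fit_world_models(world, k = 6)
  # an extreme corrected color pushes the linear model outside [0, 1.2]
  wild <- reconstruct_spectrum(models$mapping, models$basis,
                               c(500, 500, 500))
  expect_true(all(wild >= 0 & wild <= 1.2))
  expect_gt(attr(wild, "n_clamped"), 0)
  free <- reconstruct_spectrum(models$mapping, models$basis,
                               c(500, 500, 500), clamp = NULL)
  expect_gt(max(abs(free)), 1.2)
})

test_that("spectrum RMSE matches its closed forms and a direct oracle", {
  g <- spectral_grid()
  a <- as_spectra(runif(401), g)
  expect_equal(spectrum_rmse(a, a), 0)
  b <- as_spectra(unclass(a) + 0.07, g)
  expect_equal(spectrum_rmse(a, b), 0.07, tolerance = 1e-12)
  withr::with_seed(21, {
    x <- as_spectra(matrix(runif(3 * 401), 3), g)
    y <- as_spectra(matrix(runif(3 * 401), 3), g)
    oracle <- sqrt(rowMeans((unclass(x) - unclass(y))^2))
    expect_equal(spectrum_rmse(x, y), oracle, tolerance = 1e-14)
  })
})

test_that("spectral models survive JSON and hypercubes survive ENVI round trips", {
  world <- make_exact_world()
  models <- fit_world_models(world)
  path <- withr::local_tempfile(fileext = ".json")
  write_spectral_model(models$basis, models$mapping, path)
  back <- read_spectral_model(path)
  xyz <- models$xyzc[1:3, ]
  expect_equal(
    reconstruct_spectrum(back$mapping, back$basis, xyz),
    reconstruct_spectrum(models$mapping, models$basis, xyz),
    ignore_attr = TRUE, tolerance = 1e-12
  )

  small <- gen_scene(gen_reflectances_span(4, seed = 2, k = 2),
                     rows = 2, cols = 2, patch_px = 3)
  cube <- image_to_hypercube(render_wli(small, world$cam)$img,
                             models$correction, models$mapping, models$basis)
  base <- withr::local_tempfile()
  write_envi(cube, base)
  cube2 <- read_envi(base)
  expect_equal(cube2$values, cube$values, tolerance = 1e-6)
  expect_identical(cube2$grid, cube$grid)
})
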