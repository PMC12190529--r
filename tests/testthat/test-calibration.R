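test_that("feature expansion evaluates monomials in declared order", {
  spec <- feature_expansion()
  expect_equal(unname(expand_features(c(1, 1, 1), spec)[1, ]),
               rep(1, 14))
  f0 <- expand_features(c(0, 0, 0), spec)[1, ]
  expect_equal(f0[1], 1)          # constant slot
  expect_true(all(f0[-1] == 0))

  custom <- feature_expansion(terms = rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 1)
  ))
  expect_equal(unname(expand_features(c(2, 1, 3), custom)[1, ]),
               c(1, 2, 1, 3, 6))
})

test_that("feature expansion rejects malformed term tables", {
  expect_error(feature_expansion(terms = cbind(1, 2)), "n x 3")
  expect_error(feature_expansion(terms = rbind(c(1, 0, 0))), "constant term")
  expect_error(feature_expansion(terms = rbind(c(0, 0, 0), c(0, 0, 0))),
               "exactly once")
  expect_error(feature_expansion(terms = rbind(c(0, 0, 0), c(-1, 0, 0))),
               "nonnegative")
})

test_that("an already-colorimetric camera fits to the identity correction", {
  # camera RGB encodes exactly the target XYZ: affine spec must find
  # zero offset + identity and drive the error to zero
  world <- make_exact_world()
  xyz <- spectrum_to_xyz(world$refl)
  rgb <- xyz_to_srgb(xyz)
  cal <- patch_calibration_set(rgb, world$refl)
  m <- fit_correction(cal, feature_expansion(terms = rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)
  )))
  expect_equal(unname(m$C), cbind(c(0, 0, 0), diag(3)), tolerance = 1e-7)
  expect_lt(mean(m$report$de_post), 1e-7)
})

test_that("a quadratic camera is corrected to machine precision by the degree-3 fit", {
  world <- make_default_world()
  m <- fit_correction(world$cal)
  target <- spectrum_to_xyz(world$refl)
  corrected <- apply_correction(m, camera_xyz(world$wli$patch_rgb))
  expect_lt(max(abs(corrected - target)), 1e-7)
  rep <- calibration_report(m)
  expect_lt(attr(rep, "mean_post"), 1e-6)
  expect_lt(attr(rep, "mean_post"), attr(rep, "mean_pre"))
  expect_equal(attr(rep, "mean_post"), mean(rep$de_post))
})

test_that("least-squares residuals are orthogonal to the feature row space", {
  for (s in 1:5) {
    world <- make_default_world(refl_seed = s, cam_seed = s + 50, noise_sd = 0.01)
    m <- fit_correction(world$cal)
    target <- t(spectrum_to_xyz(world$refl))                      # 3 x n
    V <- t(expand_features(camera_xyz(cal_rgb <- cbind(world$cal$r, world$cal$g, world$cal$b)),
                           m$spec))                               # terms x n
    resid <- target - m$C %*% V
    expect_lt(max(abs(resid %*% t(V))) / max(abs(target %*% t(V))), 1e-8)
  }
})

test_that("duplicating every patch leaves the fitted correction unchanged", {
  world <- make_default_world()
  m1 <- fit_correction(world$cal)
  rgb <- cbind(world$cal$r, world$cal$g, world$cal$b)
  cal2 <- patch_calibration_set(rbind(rgb, rgb),
                                as_spectra(rbind(unclass(world$refl),
                                                 unclass(world$refl)),
                                           spectral_grid()))
  m2 <- fit_correction(cal2)
  expect_equal(m1$C, m2$C, tolerance = 1e-10)
})

test_that("calibration never increases the mean color error across random worlds", {
  for (s in 1:10) {
    world <- make_default_world(refl_seed = 100 + s, cam_seed = 200 + s,
                                noise_sd = 0.005)
    rep <- calibration_report(fit_correction(world$cal))
    expect_lte(attr(rep, "mean_post"), attr(rep, "mean_pre"))
  }
})

test_that("degenerate calibration inputs warn or error as contracted", {
  world <- make_default_world()
  rgb <- cbind(world$cal$r, world$cal$g, world$cal$b)
  # identical patches -> rank-deficient feature matrix
  one <- as_spectra(matrix(rep(unclass(world$refl)[1, ], 24), 24, byrow = TRUE),
                    spectral_grid())
  cal_flat <- patch_calibration_set(rgb[rep(1, 24), ], one)
  expect_warning(fit_correction(cal_flat), "rank")
  # fewer patches than expansion terms
  cal_small <- patch_calibration_set(
    rgb[1:6, ], as_spectra(unclass(world$refl)[1:6, ], spectral_grid())
  )
  expect_warning(fit_correction(cal_small), "underdetermined")
  expect_error(
    patch_calibration_set(rgb[1:3, ], one),
    "one RGB triple per patch"
  )
})

test_that("correction models survive a JSON round trip", {
  world <- make_default_world()
  m <- fit_correction(world$cal)
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_model(m, path)
  m2 <- read_correction_model(path)
  xyz <- camera_xyz(world$wli$patch_rgb)
  expect_equal(apply_correction(m, xyz), apply_correction(m2, xyz),
               tolerance = 1e-12)
  expect_error(read_correction_model(
    withr::local_tempfile(lines = "{\"type\": \"other\"}", fileext = ".json")
  ), "not a correction_model")
})

test_that("tidiers expose the per-patch report and summary means", {
  world <- make_default_world()
  m <- fit_correction(world$cal)
  td <- generics::tidy(m)
  gl <- generics::glance(m)
  expect_named(td, c("patch", "de_pre", "de_post"))
  expect_equal(nrow(td), 24)
  expect_equal(gl$mean_de_post, mean(td$de_post))
  expect_equal(gl$n_terms, 14)
})
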