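test_that("the Lorentzian band profile has the analytic peak, HWHM and mass", {
  expect_equal(cauchy_lorentz(415, 415, 10), 1 / (pi * 10), tolerance = 1e-14)
  expect_equal(cauchy_lorentz(425, 415, 10), 0.5 / (pi * 10), tolerance = 1e-14)
  expect_equal(cauchy_lorentz(405, 415, 10), cauchy_lorentz(425, 415, 10))
  expect_equal(cauchy_lorentz(500, 500, 5, amplitude = 2), 2 / (pi * 5))
  # fine-grid quadrature over a wide support recovers the amplitude
  x <- seq(415 - 2000, 415 + 2000, by = 0.1)
  expect_equal(sum(cauchy_lorentz(x, 415, 5, amplitude = 0.7)) * 0.1, 0.7,
               tolerance = 2e-3)
  expect_error(cauchy_lorentz(400, 415, -1), "gamma")
  expect_error(cauchy_lorentz(400, 415, 5, amplitude = -1), "amplitude")
})

test_that("band illuminants sample the profile on the grid", {
  spec <- nbi_band_spec(amplitudes = c(0, 1, 1, 1, 1))
  g <- spectral_grid()
  expect_equal(max(abs(build_illuminant(spec, 1, g))), 0)
  band2 <- build_illuminant(spec, 2, g)
  wl <- wavelengths(g)
  expect_equal(band2[1, wl == 540], cauchy_lorentz(540, 540, 10))
  # in-grid mass approaches the amplitude once gamma >> step, wide support
  wide <- spectral_grid(-19660, 20740, 1)
  mass <- sum(build_illuminant(nbi_band_spec(centers = c(415, 540)), 1, wide))
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_error(build_illuminant(spec, 9, g), "out of range")
})

test_that("band spec construction enforces its invariants", {
  expect_error(nbi_band_spec(centers = 415), "at least 2")
  expect_error(nbi_band_spec(gammas = -2), "gammas")
  expect_error(nbi_band_spec(mix = matrix(0, 3, 5)), "nonzero total weight")
  expect_error(nbi_band_spec(mix = matrix(-1, 3, 5)), ">= 0")
  spec <- nbi_band_spec()
  expect_equal(dim(spec$mix), c(3L, 5L))
})

test_that("band rendering maps the perfect reflector to the band amplitude", {
  g <- spectral_grid()
  white <- structure(list(values = array(1, dim = c(2, 3, 401)), grid = g,
                          n_clamped = 0L), class = "hypercube")
  black <- structure(list(values = array(0, dim = c(2, 3, 401)), grid = g,
                          n_clamped = 0L), class = "hypercube")
  spec <- nbi_band_spec(amplitudes = c(1, 0.5, 1, 1, 1))
  expect_equal(render_band_image(white, spec, 1), matrix(1, 2, 3),
               tolerance = 1e-12)
  expect_equal(render_band_image(white, spec, 2), matrix(0.5, 2, 3),
               tolerance = 1e-12)
  expect_equal(render_band_image(black, spec, 1), matrix(0, 2, 3))
})

test_that("a known Gaussian reflectance renders to the quadrature value", {
  g <- spectral_grid()
  reflect <- function(wl) 0.9 * exp(-0.5 * ((wl - 430) / 50)^2)
  cube <- structure(
    list(values = array(reflect(wavelengths(g)), dim = c(1, 1, 401)),
         grid = g, n_clamped = 0L),
    class = "hypercube"
  )
  spec <- nbi_band_spec()
  got <- render_band_image(cube, spec, 1)[1, 1]
  # independent fine-grid quadrature of r * lorentzian * ybar
  fine <- seq(380, 780, by = 0.1)
  cmf_f <- cie1931_cmf(spectral_grid(380, 780, 0.1))
  lor <- (1 / pi) * 10 / ((fine - 415)^2 + 10^2)
  oracle <- sum(reflect(fine) * lor * cmf_f$ybar) / sum(lor * cmf_f$ybar)
  expect_equal(got, oracle, tolerance = 2e-3)
})

test_that("composition is consistent between image and patch paths", {
  world <- make_default_world()
  models <- fit_world_models(world, k = 6)
  cube <- image_to_hypercube(world$wli$img, models$correction,
                             models$mapping, models$basis)
  spec <- nbi_band_spec()
  img <- compose_nbi(cube, spec)
  cols <- compose_nbi_colors(models$recon, spec)
  got <- patch_means(img, world$scene)
  expect_equal(unname(got), unname(cols), tolerance = 1e-9)
})

test_that("amplitude and mix rescale to the same composed image", {
  # doubling every band amplitude while halving every mix weight must not
  # change the composition: amplitudes are pure gains
  world <- make_exact_world()
  models <- fit_world_models(world)
  s1 <- nbi_band_spec()
  s2 <- nbi_band_spec(amplitudes = 2, mix = s1$mix / 2)
  c1 <- compose_nbi_colors(models$recon, s1)
  c2 <- compose_nbi_colors(models$recon, s2)
  expect_lt(max(abs(c1 - c2)), 1e-10)
  expect_equal(compose_nbi_colors(models$recon,
                                  nbi_band_spec(mix = matrix(1e-30, 3, 5))),
               matrix(0, 24, 3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("narrow bands concentrate their power near the center", {
  # Lorentzian tails: (2/pi) atan(a / gamma) of the mass lies within
  # +/- a, so 95% needs a ~ 12.7 gamma (= 64 nm at gamma 5) while
  # +/- 32 nm holds about 90%
  g <- spectral_grid()
  wl <- wavelengths(g)
  spec <- nbi_band_spec(gammas = 5)
  for (b in seq_along(spec$centers)) {
    p <- as.vector(build_illuminant(spec, b, g))
    p <- p / sum(p)
    expect_gte(sum(p[abs(wl - spec$centers[b]) <= 64]), 0.95)
    expect_gte(sum(p[abs(wl - spec$centers[b]) <= 32]), 0.88)
  }
})

test_that("band optimization is a no-op when targets come from the start point", {
  world <- make_exact_world()
  models <- fit_world_models(world)
  spec <- nbi_band_spec()
  targets <- srgb_to_lab(compose_nbi_colors(models$recon, spec))
  opt <- optimize_bands(models$recon, targets, init = spec, seed = 1,
                        max_evals = 400)
  expect_equal(opt$objective_initial, 0, tolerance = 1e-10)
  expect_lt(opt$objective_final, 1e-10)
  expect_lt(max(abs(opt$spec$centers - spec$centers)), 1)
})

test_that("perturbed band centers are recovered from known-truth targets", {
  world <- make_default_world()
  models <- fit_world_models(world, k = 6)
  truth <- nbi_band_spec()
  targets <- srgb_to_lab(compose_nbi_colors(models$recon, truth))
  init <- nbi_band_spec(centers = truth$centers + c(8, 8, 0, 0, 0))
  for (s in 1:3) {
    opt <- optimize_bands(models$recon, targets, init = init, seed = s,
                          optimize_mix = FALSE, max_evals = 6000)
    expect_lt(opt$objective_final, 1e-3)
    expect_lt(max(abs(opt$spec$centers[1:2] - truth$centers[1:2])), 1)
  }
})

test_that("the optimized objective never exceeds the initial one", {
  world <- make_exact_world()
  models <- fit_world_models(world)
  truth <- nbi_band_spec()
  targets <- srgb_to_lab(compose_nbi_colors(models$recon, truth))
  for (s in 1:20) {
    init <- withr::with_seed(1000 + s, nbi_band_spec(
      centers = truth$centers + runif(5, -9, 9),
      gammas = runif(5, 2, 30),
      amplitudes = runif(5, 0.3, 1.8)
    ))
    opt <- optimize_bands(models$recon, targets, init = init, seed = s,
                          max_evals = 250)
    expect_lte(opt$objective_final, opt$objective_initial)
    expect_lte(opt$n_evaluations, 250)
  }
})

test_that("optimization rejects inconsistent bounds and non-finite objectives", {
  world <- make_exact_world()
  models <- fit_world_models(world)
  targets <- srgb_to_lab(compose_nbi_colors(models$recon, nbi_band_spec()))
  bad <- band_par_bounds(nbi_band_spec())
  bad$upper[1] <- bad$lower[1]
  expect_error(
    optimize_bands(models$recon, targets, seed = 1, bounds = bad),
    "invalid bounds"
  )
  expect_error(optimize_bands(models$recon, targets), "seed")
  expect_error(
    dual_annealing(function(x) NaN, 0, 1, seed = 1),
    "non-finite objective"
  )
})

test_that("band specs survive a JSON round trip", {
  spec <- nbi_band_spec(centers = c(412, 543, 601, 698, 777),
                        gammas = c(8, 11, 9, 10, 12),
                        amplitudes = c(1, 0.9, 0.1, 0.05, 0.02))
  path <- withr::local_tempfile(fileext = ".json")
  write_band_spec(spec, path)
  spec2 <- read_band_spec(path)
  expect_equal(spec2$centers, spec$centers)
  expect_equal(spec2$mix, spec$mix, ignore_attr = TRUE)
})
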