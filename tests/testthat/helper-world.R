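# Shared synthetic worlds for the module tests.

# default-difficulty world: smooth random patches, quadratic camera
make_default_world <- function(refl_seed = 1, cam_seed = 2, noise_sd = 0,
                               grid = spectral_grid()) {
  refl <- gen_reflectances(24, seed = refl_seed, grid = grid)
  cam <- gen_camera(seed = cam_seed, noise_sd = noise_sd, grid = grid)
  scene <- gen_scene(refl)
  wli <- render_wli(scene, cam, seed = if (noise_sd > 0) refl_seed + 100 else NULL)
  # calibration sees what the camera recorded: per-patch means of the
  # (possibly noisy) rendered image
  cam_rgb <- if (noise_sd > 0) patch_means(wli$img, scene) else wli$patch_rgb
  cal <- patch_calibration_set(cam_rgb, refl)
  list(refl = refl, cam = cam, scene = scene, wli = wli, cal = cal)
}

# exact world: rank-3 reflectances (so PC scores are a linear function of
# color), quadratic-but-exactly-correctable camera, no noise -> the whole
# pipeline reconstructs training spectra to machine precision
make_exact_world <- function(refl_seed = 1, cam_seed = 2, k = 3,
                             grid = spectral_grid()) {
  refl <- gen_reflectances_span(24, seed = refl_seed, k = k, grid = grid)
  cam <- gen_camera(seed = cam_seed, grid = grid)
  scene <- gen_scene(refl)
  wli <- render_wli(scene, cam)
  cal <- patch_calibration_set(wli$patch_rgb, refl)
  list(refl = refl, cam = cam, scene = scene, wli = wli, cal = cal, k = k)
}

fit_world_models <- function(world, k = NULL) {
  m <- fit_correction(world$cal)
  kk <- if (is.null(k)) min(6, world$k %||% 6) else k
  b <- fit_basis(world$refl, k = kk)
  mp <- fit_mapping(b, world$cal, m)
  xyzc <- apply_correction(m, camera_xyz(world$wli$patch_rgb))
  recon <- reconstruct_spectrum(mp, b, xyzc)
  list(correction = m, basis = b, mapping = mp, xyzc = xyzc, recon = recon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
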