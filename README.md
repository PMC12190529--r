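# nbisim

Simulated narrow-band imaging (NBI) from white-light endoscopy (WLI), via
spectral reconstruction.

## The problem

Narrow-band imaging illuminates tissue at 415 nm (blue) and 540 nm (green),
where hemoglobin absorbs strongly, to enhance vascular and mucosal contrast
during endoscopy — but many endoscopy systems lack NBI hardware. `nbisim`
implements a software route from an ordinary white-light RGB frame to a
simulated NBI image, for imaging scientists and endoscopy-analysis
pipelines:

1. **Colorimetric calibration.** Camera sRGB values of a 24-patch color
   target are linearized (IEC 61966-2-1), mapped to camera XYZ, and
   corrected towards spectrometer-derived XYZ with a polynomial regression:
   the correction matrix is `C = XYZ_spectrum · pinv(V)` where the columns
   of `V` are monomial feature vectors (degree ≤ 3 by default, 14 terms) of
   the camera XYZ, and corrected colors are `XYZ_correct = C · V`.
2. **Spectral reconstruction.** The 24 patch reflectance spectra
   (380–780 nm, 1 nm grid) are compressed by mean-centered PCA into k = 6
   principal components; the mapping from color features to PC scores is
   `M = Score · pinv(V_color)`, so any corrected pixel color reconstructs a
   full reflectance spectrum `s = mean + EV · M · V_color` — a hyperspectral
   cube from a single RGB image.
3. **Narrow-band synthesis.** Band illuminants are Cauchy–Lorentz profiles
   `f(x; x0, γ) = (1/π) · γ / ((x − x0)² + γ²)` centered at 415 and 540 nm
   (plus small auxiliary bands at 600/700/780 nm). The cube is integrated
   against each band, band images are mixed into display RGB (415 → G,B;
   540 → R), and all band parameters and the mixing matrix can be tuned by
   a dual-annealing global optimizer against per-patch target colors,
   minimizing mean CIEDE2000.
4. **Validation.** CIEDE2000 patch errors, SSIM, PSNR and histogram-entropy
   difference between the simulated NBI and a reference.

A fully seeded synthetic world (smooth patch reflectances, a polynomial-
distortion camera, tiled color-checker scenes, and an independent oracle
NBI renderer that never touches the pipeline's code paths) provides ground
truth for every stage, so the whole system is testable offline.

## Worked example

```r
library(nbisim)

# synthetic study: 24 smooth patches, quadratic-distortion camera
refl  <- gen_reflectances(24, seed = 1)
cam   <- gen_camera(seed = 2)
scene <- gen_scene(refl)                      # 4 x 6 patches, 192 x 128 px
wli   <- render_wli(scene, cam)

# 1. calibrate the camera against the patch spectra
cal <- patch_calibration_set(wli$patch_rgb, refl)
correction <- fit_correction(cal)
correction
#> <correction_model> 14 terms, 24 patches; mean dE de2000 19.1088 -> 0.0000

# 2. fit the spectral basis and the color -> score mapping
basis <- fit_basis(refl, k = 6)
basis
#> <spectral_basis> k = 6 on 380:780:1; cumulative variance 99.9975%
mapping <- fit_mapping(basis, cal, correction)
recon <- reconstruct_spectrum(mapping, basis,
  apply_correction(correction, camera_xyz(wli$patch_rgb)))
mean(spectrum_rmse(recon, refl))
#> [1] 0.0157

# 3. tune the narrow bands against oracle NBI targets
oracle <- oracle_nbi(scene)
opt <- optimize_bands(recon, oracle$patch_lab, seed = 3)
opt
#> <nbi_optimization> mean dE00 0.0240 -> 0.0236 (2000 evaluations, seed 3)

# 4. convert the scene image and score it against the oracle render
cube <- image_to_hypercube(wli$img, correction, mapping, basis)
cube
#> <hypercube> 128 x 192 px, 401 bands on 380:780:1 (0 clamped values)
nbi <- compose_nbi(cube, opt$spec)
quality_report(nbi, oracle$img)
#> <quality_report>
#>   n images          1
#>   SSIM              1.0000
#>   PSNR              60.6835 dB
#>   entropy ref/test  4.3035 / 4.3035 bits
#>   entropy diff      0.0000 %
```

Reading the numbers: calibration drives the mean patch color error from
19.1 ΔE00 to numerically zero (the synthetic camera's distortion is exactly
representable by the degree-3 correction); six principal components carry
99.9975 % of the spectral variance; spectra reconstructed from single
colors have a mean RMSE of 0.016 reflectance units against the truth; and
the composed NBI scene is essentially indistinguishable from the
independent oracle render (SSIM ≈ 1, PSNR ≈ 61 dB).

Fitted models round-trip through JSON (`write_correction_model()`,
`write_spectral_model()`, `write_band_spec()`), hypercubes through ENVI
(`write_envi()`), and each result type has `tidy()` / `glance()` /
`autoplot()` methods.

## Command line

A thin launcher is installed at `exec/nbisim`:

```sh
nbisim simulate     --out-dir fixtures --seed 1
nbisim calibrate    --rgb fixtures/patch_rgb.csv --spectra fixtures/patch_spectra.csv \
                    --out-model model.json --out-report report.csv
nbisim fit-spectral --rgb fixtures/patch_rgb.csv --spectra fixtures/patch_spectra.csv \
                    --model model.json --out spectral.json
nbisim convert      --wli fixtures/wli.png --model model.json \
                    --spectral spectral.json --out nbi.png
nbisim evaluate     --test nbi.png --reference fixtures/oracle_nbi.png --out quality.json
```

Exit status is 0 on success, 2 on malformed input or configuration, 1 on
internal error; every run is deterministic for fixed inputs.

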