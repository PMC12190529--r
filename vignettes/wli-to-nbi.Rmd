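---
title: "From white-light endoscopy to simulated narrow-band imaging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From white-light endoscopy to simulated narrow-band imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbisim)
```

`nbisim` converts a white-light endoscopic RGB image into a 380–780 nm
reflectance hypercube and from it a simulated narrow-band image (NBI).
This vignette is the package's own account of the model, its assumptions,
the synthetic world used to validate it, and the numerical choices made
where the design was genuinely open.

## The pipeline

### Colorimetric foundation

All spectra live on a common `spectral_grid()` (default 380–780 nm at
1 nm, 401 bands; spectrometer input on other grids is resampled by linear
interpolation, zero outside the tabulated support). Spectra are integrated
to CIE 1931 XYZ with

$$X = k \sum_\lambda r(\lambda)\, I(\lambda)\, \bar{x}(\lambda)\, \Delta\lambda,$$

and likewise $Y, Z$, with $k$ normalizing a perfect reflector to $Y = 100$.
The CIE 1931 2° observer curves are generated from the multi-lobe
piecewise-Gaussian analytic representation (Wyman, Sloan & Shirley 2013),
clamped at zero. This reproduces the tabulated observer to about one part
in a hundred of peak, and — more importantly for a self-contained pipeline —
every consumer of the curves (calibration targets, reconstruction, band
rendering, the synthetic oracle) uses the *same* curves, so colorimetric
comparisons inside the package are exact.

The default integration illuminant is the equal-energy illuminant E. A
daylight SPD could be substituted through `illuminant_spectrum()`'s CSV
path; E is the default because it is exactly defined on any grid, and the
calibration step absorbs any fixed linear discrepancy between the assumed
and the physical lamp. Display-side conversions (encoded sRGB ↔ XYZ ↔ Lab)
use the standard sRGB (D65) matrices and white point, since the camera and
the composed NBI image are sRGB objects. CIEDE2000 is implemented with
$k_L = k_C = k_H = 1$ and the standard hue-rotation and compensation
terms; the plain CIE76 distance is available via `delta_e_ab()` because
reports of "chromatic aberration" do not always name their formula.

### Camera calibration

Encoded sRGB is linearized with the IEC 61966-2-1 transfer function and
mapped through the sRGB→XYZ matrix to *camera XYZ* — the color the device
claims. The correction to colorimeter ground truth is a linear map on
polynomial features:

$$C = \mathrm{XYZ}_{\mathrm{spectrum}} \cdot \mathrm{pinv}(V), \qquad
  \mathrm{XYZ}_{\mathrm{correct}} = C\,V,$$

where each column of $V$ is the feature vector of one patch's camera XYZ.
The default expansion is the degree-3 family
$\{1, X, Y, Z, XY, XZ, YZ, X^2, Y^2, Z^2, XYZ, X^3, Y^3, Z^3\}$ — 14 terms,
deliberately fewer than the 24 patches so the fit stays overdetermined; the
expansion is fully configurable (including expanding over linear RGB by
supplying custom terms). The pseudo-inverse is computed by SVD with a
relative singular-value cutoff of $10^{-10}$; rank deficiency warns with
the effective rank rather than failing, since a degenerate target set is
diagnosable from the report.

### Spectral reconstruction

The 24 measured patch reflectances are compressed by mean-centered PCA.
Six components suffice for smooth natural reflectances; the basis records
per-component explained variance so this claim is checkable on any input.
Eigenvector signs are fixed (largest-magnitude element positive) for
reproducible serialization. The mapping from color to spectrum is again a
regression on color features, $M = \mathrm{Score} \cdot
\mathrm{pinv}(V_{\mathrm{color}})$, and reconstruction is

$$\hat{s} = \bar{s} + EV \cdot M \cdot V_{\mathrm{color}}.$$

$V_{\mathrm{color}}$ defaults to the calibration's expansion but is
independently configurable. Reconstructed reflectance is clamped to
$[0, 1.2]$ — slight overshoot above 1 is legitimate for a regression, 1.2
bounds nonphysical blow-up — and the clamp count is logged on the result.

A structural point worth stating plainly: a pixel color is 3-dimensional,
so the reconstructed spectrum is a *function of color*. Two metameric
surfaces (different spectra, same XYZ) reconstruct identically. Exact
recovery through the pipeline is therefore only possible when the true
reflectance family has intrinsic dimension ≤ 3; the test suite's
machine-precision recovery tests use a rank-3 world for exactly this
reason, and the 6-component default should be read as "enough basis
freedom to place the 3-parameter color manifold well", not as recovering
six independent degrees of freedom per pixel.

### Narrow-band synthesis

Band illuminants are Cauchy–Lorentz (Lorentzian) profiles

$$f(x; x_0, \gamma) = \frac{1}{\pi}\,\frac{\gamma}{(x - x_0)^2 + \gamma^2},$$

with $x_0$ the center, $\gamma$ the half-width at half maximum, scaled by a
band amplitude. Defaults: centers 415, 540, 600, 700, 780 nm, $\gamma =
10$ nm, amplitude 1. A band image is the luminance-weighted integral of
reflectance against the band, normalized by the *unit-amplitude* band's
white-reflector response: a perfect reflector maps to the band's
amplitude, so amplitudes act as pure gains and doubling every amplitude
while halving every mixing weight leaves the composed image unchanged (a
tested invariant). The mixing matrix follows the NBI display convention —
the 415 nm band drives display G and B, the 540 nm band drives display R —
with the three auxiliary red/NIR bands entering the red channel at weight
0.05 as a stand-in for vendor post-processing; the whole matrix is
optimizable. A full-XYZ band rendering (weighting by all three observer
curves instead of luminance only) was considered and not implemented: the
band images are single-channel by construction and the mixing matrix
already owns the chromatic placement.

Note one distributional fact with practical consequences: Lorentzian tails
are heavy. At $\gamma = 5$ nm, the closed form $(2/\pi)\arctan(a/\gamma)$
puts only ~90 % of band power within $x_0 \pm 32$ nm; 95 % needs
$\pm 64$ nm. Simulated narrow bands therefore leak more spectral
neighborhood than a hard-edged filter of the same nominal width would.

### Band optimization

`optimize_bands()` minimizes the mean CIEDE2000 between composed patch
colors and per-patch target Lab colors over band centers, widths,
amplitudes and (optionally) the mixing matrix, within physical bounds
(centers ±10 nm of their initial values, $\gamma \in [1, 40]$ nm,
amplitudes $\in [0, 2]$, mix weights $\in [0, 1.5]$), under a hard budget
of 2000 objective evaluations by default. The optimizer is a
dual-annealing scheme written for this package: all parameters are
box-normalized to $[0,1]$ (centers near 500 and amplitudes near 1 would
otherwise wreck any step-size choice), heavy-tailed Cauchy visiting steps
with a budget-adaptive geometric temperature schedule explore, and
restarted Nelder-Mead simplex polishes exploit. The simplex — rather than
a quasi-Newton method — is deliberate: the objective's parameters
compensate each other (a shifted center can be partly mimicked by a wider
$\gamma$ and a gain change), producing long curved valleys on which
finite-difference line searches stall; restarted simplexes keep moving
along such valleys, and in the known-truth tests recover band centers
perturbed by +8 nm to within 1 nm. A budget guard wraps every evaluation,
tracking the best point ever seen, so `objective_final ≤
objective_initial` holds unconditionally and the evaluation budget is
never exceeded. Seeds are mandatory wherever randomness exists — there is
no hidden default seed anywhere in the package.

### Quality metrics

SSIM uses the standard 11×11 Gaussian window ($\sigma = 1.5$), $K_1 =
0.01$, $K_2 = 0.03$, Gaussian-weighted moments, reflect padding, computed
on the ITU-R BT.601 luma of the 8-bit-quantized encoded image; PSNR is
$10\log_{10}(255^2/\mathrm{MSE})$ over 8-bit RGB with identical images
flagged as infinite; entropy is Shannon entropy of the 256-bin luma
histogram, with the percent difference normalized by the *reference*
image's entropy. Reports record `n`, the number of image pairs summarized,
so a single-exemplar figure is never mistaken for a mean over a set.

## The synthetic world

No endoscopic or spectrometer data ship with the package; a seeded
synthetic world generates every fixture with known ground truth.

* **Reflectances** (`gen_reflectances()`): each spectrum is a logistic
  squash of a baseline plus 4 Gaussian bumps with centers anywhere in the
  band, widths 60–150 nm and amplitudes within ±1.2. The squash keeps
  values strictly inside (0, 1); the width floor keeps spectra about as
  smooth as measured color-checker / Munsell patches, which is what makes
  a 6-component basis essentially exhaustive (≥ 99.6 % variance at the
  defaults — asserted in tests, not assumed). A companion generator
  (`gen_reflectances_span()`) draws spectra from an exact k-dimensional
  affine family for machine-precision recovery tests.
* **Camera** (`gen_camera()`): the default camera is colorimetric (its
  effective sensitivities are the XYZ→sRGB combination of the observer
  curves, with the small negative lobes that implies), with a quadratic
  distortion in XYZ space constructed *backwards*: the camera reports the
  Newton-inverted image of a random quadratic map, so that true XYZ is an
  exactly quadratic polynomial of camera XYZ and a degree ≥ 2 correction
  can undo it to machine precision. The coefficient range (±0.08) was
  chosen so the quadratic map stays globally invertible over the whole
  color box across coefficient draws while still producing double-digit
  pre-calibration ΔE00. A nonnegative Gaussian-primaries mode exists for
  studying non-ideal (non-Luther) cameras, which no color-only correction
  can fix exactly. Captures are auto-exposed — a per-session linear gain
  places the brightest channel at 0.95, as a real calibration capture is
  exposed — because clipping, not noise, is what destroys polynomial
  correctability; a pure gain is absorbed exactly by the correction.
  Optional Gaussian sensor noise on linear RGB is available and off by
  default.
* **Scenes** (`gen_scene()`, `render_wli()`): 24 patches tiled 4×6 at
  32 px (192×128), the desk-scale analogue of photographing a color
  checker.
* **Oracle renderer** (`oracle_nbi()`): the ground-truth NBI render
  integrates the *true* reflectances against the band profiles with its
  own inlined Lorentzian, integration, mixing and transfer-function code —
  no shared code path with the pipeline under test. In the exact (rank-3,
  noiseless) world the pipeline's composed image must and does match the
  oracle image to under $10^{-6}$.

What the synthetic world does *not* emulate: spatial structure (vessels,
specular highlights, shading), wavelength-dependent scattering and
absorption physics, demosaicing, or compression. Passing tests demonstrate
the correctness of the calibration/reconstruction/synthesis machinery
under its stated assumptions — smooth low-dimensional reflectances, a
polynomially correctable camera — not clinical image quality.

## Numerical choices and degenerate inputs

* SVD pseudo-inverse cutoff $10^{-10}$ (relative); rank deficiency warns.
* PCA on identical spectra (rank 0) errors, naming the achievable rank;
  requesting more components than the rank does the same.
* Out-of-range sRGB values error naming the offending value; 8-bit input
  is divided by 255 before decoding.
* Newton inversion of the camera distortion is damped (step-halving) and
  verified in tests to return residuals below $10^{-12}$.
* Reconstruction clamps to $[0, 1.2]$ and logs the clamp count.
* Grids must match exactly (after declared resampling) or operations fail
  structurally rather than guessing.

## Problem sizes

The default study — 24 patches at 401 bands, a 192×128 scene (24,576
reconstructed spectra), and two 2000-evaluation band optimizations — runs
end to end in well under a minute on one CPU; the full test suite in
about forty seconds. These sizes were chosen as the smallest at which
every stage (overdetermined calibration, 6-component PCA, scene-level
SSIM) is meaningfully exercised.

## Known limitations

* Reconstruction is color-driven: metamers are indistinguishable, and
  accuracy off the calibration manifold (e.g. strongly shaded or saturated
  colors) degrades with polynomial extrapolation.
* On flat-patch scenes the histogram-entropy comparison is a discrete
  statistic: ~24 occupied luma bins of mass 1/24 mean entropy changes in
  jumps of $(1/12)\log_2 2$ bits (≈ 2 % of the total) when two patch lumas
  merge into or split out of one 8-bit bin, which is decided by rounding
  boundaries rather than by pipeline quality. Entropy differences on such
  scenes are meaningful only at that granularity; on textured images the
  statistic behaves continuously.
* The analytic observer curves are a close but not exact reproduction of
  the tabulated CIE 1931 observer; absolute colorimetry against external
  instruments should load measured curves onto the grid instead.
* The auxiliary 600/700/780 nm bands model vendor post-processing only
  through the mixing matrix; no claim is made about any specific vendor's
  processing chain.
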