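#' Generate smooth synthetic patch reflectances
#'
#' Emulates the reflectance spectra of a 24-patch color target: each
#' spectrum is a logistic-squashed sum of a few broad Gaussian bumps, so
#' spectra are smooth, strictly inside (0, 1), and of low intrinsic
#' dimension — the same property that lets a handful of principal
#' components describe measured patch sets. Deterministic per seed.
#'
#' Defaults (4 bumps, widths 60--150 nm, bump amplitudes within +/- 1.2
#' before the squash) are chosen to mirror the smoothness of ColorChecker /
#' Munsell reflectances.
#'
#' @param n Number of spectra (24 for a standard target).
#' @param seed Integer seed.
#' @param n_gaussians Bumps per spectrum (0 gives constant mid-gray 0.5).
#' @param width_range Bump standard-deviation range in nm (>= 40).
#' @param amp_range Bump amplitude range before the logistic squash.
#' @param grid Spectral grid.
#' @return n x n_bands spectra matrix with a grid attribute.
#' @export
gen_reflectances <- function(n = 24, seed, n_gaussians = 4,
                             width_range = c(60, 150),
                             amp_range = c(-1.2, 1.2),
                             grid = spectral_grid()) {
  stopifnot(n >= 1, n_gaussians >= 0)
  if (missing(seed)) rlang::abort("gen_reflectances requires an explicit seed")
  wl <- wavelengths(grid)
  if (n_gaussians == 0) {
    return(as_spectra(matrix(0.5, n, length(wl)), grid))
  }
  withr::with_seed(seed, {
    out <- matrix(0, n, length(wl))
    for (i in seq_len(n)) {
      z <- stats::runif(1, -0.5, 0.5) + 0.2
      for (j in seq_len(n_gaussians)) {
        a <- stats::runif(1, amp_range[1], amp_range[2])
        mu <- stats::runif(1, grid$start_nm, grid$end_nm)
        w <- stats::runif(1, width_range[1], width_range[2])
        z <- z + a * exp(-0.5 * ((wl - mu) / w)^2)
      }
      out[i, ] <- stats::plogis(z)
    }
    as_spectra(out, grid)
  })
}

#' Generate reflectances inside an exact low-dimensional span
#'
#' Companion generator for exact-recovery tests: spectra are affine
#' combinations `0.5 + sum_j c_j B_j` of `k` fixed broad Gaussian basis
#' functions, with coefficients scaled so values stay well inside (0, 1).
#' The centered set has rank exactly `k`, and for k <= 3 the PC scores are
#' a linear function of tristimulus color, so the full reconstruction
#' pipeline can recover every spectrum to machine precision.
#'
#' @inheritParams gen_reflectances
#' @param k Dimension of the spanning basis.
#' @export
gen_reflectances_span <- function(n = 24, seed, k = 3, grid = spectral_grid()) {
  stopifnot(n >= k + 1, k >= 1)
  if (missing(seed)) rlang::abort("gen_reflectances_span requires an explicit seed")
  wl <- wavelengths(grid)
  centers <- seq(430, 730, length.out = k)
  B <- sapply(centers, function(mu) exp(-0.5 * ((wl - mu) / 90)^2))  # bands x k
  withr::with_seed(seed, {
    coef <- matrix(stats::runif(n * k, -1, 1) * 0.45 / k, n, k)
    as_spectra(0.5 + coef %*% t(B), grid)
  })
}

#' Synthetic patch-grid scene
#'
#' Arranges `n = rows * cols` patch reflectances in a grid of square
#' patches, the synthetic analogue of photographing a color checker. The
#' default 4 x 6 layout at 32 px gives a 192 x 128 image.
#'
#' @param reflectances n-row spectra matrix.
#' @param rows,cols Patch layout.
#' @param patch_px Patch side length in pixels.
#' @return An object of class `synthetic_scene`.
#' @export
gen_scene <- function(reflectances, rows = 4, cols = 6, patch_px = 32) {
  n <- nrow(unclass_spectra(reflectances))
  if (n != rows * cols) {
    rlang::abort(sprintf("%d reflectances cannot fill a %d x %d layout",
                         n, rows, cols))
  }
  idx <- matrix(0L, rows * patch_px, cols * patch_px)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      p <- (r - 1L) * cols + c
      idx[(r - 1L) * patch_px + seq_len(patch_px),
          (c - 1L) * patch_px + seq_len(patch_px)] <- p
    }
  }
  structure(
    list(reflectances = reflectances, rows = rows, cols = cols,
         patch_px = patch_px, patch_index = idx),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d patches @ %d px (%d x %d image)\n",
              x$rows, x$cols, x$patch_px, nrow(x$patch_index),
              ncol(x$patch_index)))
  invisible(x)
}

# tile per-patch colors (n x 3) into an H x W x 3 image
tile_patches <- function(colors, scene) {
  idx <- scene$patch_index
  array(colors[cbind(as.vector(idx), rep(1:3, each = length(idx)))],
        dim = c(nrow(idx), ncol(idx), 3))
}

#' Per-patch mean colors of a patch-grid image
#'
#' @param img H x W x 3 array.
#' @param scene The `synthetic_scene` that produced the layout.
#' @return n x 3 matrix of per-patch channel means.
#' @export
patch_means <- function(img, scene) {
  idx <- as.vector(scene$patch_index)
  n <- scene$rows * scene$cols
  sapply(1:3, function(ch) {
    tapply(as.vector(img[, , ch]), idx, mean)[as.character(seq_len(n))]
  })
}

#' Synthetic camera
#'
#' A camera model with a declared polynomial nonlinearity in XYZ space.
#' The default `"colorimetric"` camera satisfies the Luther condition (its
#' effective sensitivities are the XYZ-to-sRGB combination of the CMFs,
#' which carries small negative lobes), so the only discrepancy between
#' camera color and colorimeter color is the distortion itself — which is
#' constructed so that the true XYZ is an exact quadratic polynomial of
#' the camera XYZ, i.e. a polynomial correction of degree >= 2 can undo it
#' completely. A `"gaussian"` mode with nonnegative Gaussian sensitivities
#' at declared peaks is available for non-ideal-camera studies.
#'
#' @param seed Integer seed for the distortion coefficients.
#' @param distortion_degree 1 for an identity (linear) camera, 2 for the
#'   quadratic distortion.
#' @param distortion_scale Coefficient range of the quadratic terms.
#' @param primaries `"colorimetric"` or `"gaussian"`.
#' @param peaks,widths Gaussian sensitivity parameters (gaussian mode).
#' @param noise_sd Gaussian noise s.d. on linear RGB at render time.
#' @param grid Spectral grid.
#' @return An object of class `synthetic_camera`.
#' @export
gen_camera <- function(seed, distortion_degree = 2, distortion_scale = 0.08,
                       primaries = c("colorimetric", "gaussian"),
                       peaks = c(600, 540, 450), widths = c(70, 60, 50),
                       noise_sd = 0, grid = spectral_grid()) {
  if (missing(seed)) rlang::abort("gen_camera requires an explicit seed")
  primaries <- match.arg(primaries)
  stopifnot(distortion_degree %in% c(1, 2))
  cmf <- cie1931_cmf(grid)
  A <- matrix(0, 3, 6)
  if (distortion_degree == 2) {
    A <- withr::with_seed(seed, {
      matrix(stats::runif(18, -distortion_scale, distortion_scale), 3, 6)
    })
  }
  sens <- if (primaries == "colorimetric") {
    xyz_to_srgb_matrix() %*% rbind(cmf$xbar, cmf$ybar, cmf$zbar)
  } else {
    wl <- wavelengths(grid)
    t(sapply(seq_len(3), function(i) exp(-0.5 * ((wl - peaks[i]) / widths[i])^2)))
  }
  structure(
    list(A = A, primaries = primaries, sens = sens, noise_sd = noise_sd,
         grid = grid, seed = seed),
    class = "synthetic_camera"
  )
}

#' @export
print.synthetic_camera <- function(x, ...) {
  cat(sprintf("<synthetic_camera> %s primaries, %s distortion, noise_sd %g\n",
              x$primaries,
              if (all(x$A == 0)) "identity" else "quadratic", x$noise_sd))
  invisible(x)
}

quad_monomials <- function(u) {
  cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
        u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3])
}

# the quadratic map Q on normalized tristimulus (XYZ / 100)
camera_q <- function(u, A) u + quad_monomials(u) %*% t(A)

# damped Newton inversion of Q, row-wise: full steps while they shrink the
# residual, backtracking otherwise; converges for the mild default scale
camera_q_inv <- function(u, A, tol = 1e-13, maxit = 100) {
  resid <- function(vi, target) as.vector(camera_q(matrix(vi, 1), A)) - target
  v <- u
  for (i in seq_len(nrow(u))) {
    vi <- u[i, ]
    Fv <- resid(vi, u[i, ])
    for (it in seq_len(maxit)) {
      if (max(abs(Fv)) < tol) break
      Dm <- rbind(
        c(2 * vi[1], 0, 0), c(0, 2 * vi[2], 0), c(0, 0, 2 * vi[3]),
        c(vi[2], vi[1], 0), c(vi[3], 0, vi[1]), c(0, vi[3], vi[2])
      )
      J <- diag(3) + A %*% Dm
      step <- tryCatch(solve(J, Fv), error = function(e) Fv)
      lambda <- 1
      repeat {
        cand <- vi - lambda * step
        Fc <- resid(cand, u[i, ])
        if (max(abs(Fc)) < max(abs(Fv)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      vi <- cand
      Fv <- Fc
    }
    v[i, ] <- vi
  }
  v
}

# linear sRGB response of the camera with session exposure: by default a
# per-session linear gain keeps the brightest channel at `headroom`, the
# way a real calibration capture is exposed so no patch clips; captures
# belonging to the same session pass the session's gain explicitly. A pure
# gain is linear in XYZ and therefore exactly absorbed by the polynomial
# correction.
camera_linear <- function(cam, xyz_true, gain = NULL, headroom = 0.95) {
  u <- rbind3(xyz_true) / 100
  v <- if (all(cam$A == 0)) u else camera_q_inv(u, cam$A)
  lin <- v %*% t(xyz_to_srgb_matrix())
  if (is.null(gain)) gain <- min(1, headroom / max(lin))
  list(lin = lin * gain, gain = gain)
}

#' Simulate the camera's encoded sRGB response to scene colors
#'
#' True tristimulus -> distorted camera XYZ (`XYZ_true = 100 Q(XYZ_cam /
#' 100)` by construction) -> linear sRGB with auto-exposure (a per-capture
#' gain exposing the brightest channel at 0.95, as a real calibration
#' capture would be exposed) -> optional Gaussian noise -> clip to
#' \[0, 1\] -> sRGB encode. Uses the session RNG only when `noise_sd > 0`.
#'
#' @param cam A [gen_camera()] result.
#' @param xyz_true n x 3 true tristimulus (Y-of-white = 100).
#' @param noise_sd Overrides the camera's noise level.
#' @param gain Fixed exposure gain for captures in an existing session
#'   (`NULL` = auto-expose this capture; the applied gain is returned in
#'   the `"gain"` attribute so later captures can reuse it).
#' @return n x 3 encoded sRGB matrix; clipped-value count in attribute
#'   `"n_clipped"`, exposure gain in `"gain"`.
#' @export
camera_capture <- function(cam, xyz_true, noise_sd = cam$noise_sd,
                           gain = NULL) {
  cl <- camera_linear(cam, xyz_true, gain = gain)
  lin <- cl$lin
  if (noise_sd > 0) lin <- lin + stats::rnorm(length(lin), 0, noise_sd)
  n_clipped <- sum(lin < 0 | lin > 1)
  out <- srgb_encode(pmin(pmax(lin, 0), 1))
  attr(out, "n_clipped") <- n_clipped
  attr(out, "gain") <- cl$gain
  out
}

#' Render the white-light image of a synthetic scene
#'
#' Integrates each patch reflectance under the illuminant, captures it
#' with the synthetic camera, and tiles the patch colors into the scene
#' image. Ground-truth tristimulus is returned alongside. Noiseless
#' renders are deterministic; with `noise_sd > 0` a seed is required and
#' noise is drawn per pixel.
#'
#' @param scene A [gen_scene()] result.
#' @param cam A [gen_camera()] result.
#' @param illuminant Scene illuminant SPD.
#' @param cmf Color matching functions.
#' @param noise_sd Per-pixel Gaussian noise on linear RGB.
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @return List: `img` (H x W x 3 encoded sRGB), `patch_rgb` (n x 3,
#'   noiseless patch colors), `patch_xyz_true` (n x 3).
#' @export
render_wli <- function(scene, cam,
                       illuminant = illuminant_spectrum("E", spectra_grid(scene$reflectances)),
                       cmf = cie1931_cmf(spectra_grid(scene$reflectances)),
                       noise_sd = cam$noise_sd, seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(cam, "synthetic_camera"))
  xyz_true <- spectrum_to_xyz(scene$reflectances, illuminant, cmf)
  patch_rgb <- camera_capture(cam, xyz_true, noise_sd = 0)
  if (noise_sd > 0) {
    if (is.null(seed)) rlang::abort("render_wli with noise_sd > 0 requires a seed")
    lin_img <- tile_patches(camera_linear(cam, xyz_true)$lin, scene)
    img <- withr::with_seed(seed, {
      noisy <- lin_img + stats::rnorm(length(lin_img), 0, noise_sd)
      array(srgb_encode(pmin(pmax(noisy, 0), 1)), dim = dim(lin_img))
    })
  } else {
    img <- tile_patches(patch_rgb, scene)
  }
  list(img = img, patch_rgb = patch_rgb, patch_xyz_true = xyz_true)
}

#' Independent oracle narrow-band render
#'
#' The ground-truth renderer the simulated-NBI pipeline is judged against:
#' it integrates the TRUE patch reflectances (never reconstructed ones)
#' against the Cauchy-Lorentz band profiles and mixes them into display
#' RGB under the same rendering contract as [compose_nbi()], but with its
#' own inlined Lorentzian, integration, mixing and transfer-function code
#' so it shares no code path with the pipeline under test.
#'
#' @param scene A [gen_scene()] result.
#' @param spec An [nbi_band_spec()].
#' @param cmf Color matching functions.
#' @return List: `img` (H x W x 3 encoded sRGB), `patch_rgb` (n x 3),
#'   `patch_lab` (n x 3 Lab targets under the D65 white).
#' @export
oracle_nbi <- function(scene, spec = nbi_band_spec(),
                       cmf = cie1931_cmf(spectra_grid(scene$reflectances))) {
  stopifnot(inherits(scene, "synthetic_scene"))
  g <- spectra_grid(scene$reflectances)
  wl <- wavelengths(g)
  R <- unclass_spectra(scene$reflectances)
  nb <- length(spec$centers)
  # inlined Lorentzian band responses, normalized to unit white response
  resp <- sapply(seq_len(nb), function(b) {
    shape <- (1 / pi) * spec$gammas[b] /
      ((wl - spec$centers[b])^2 + spec$gammas[b]^2)
    w <- shape * cmf$ybar
    spec$amplitudes[b] * as.vector(R %*% w) / sum(w)
  })
  lin <- resp %*% t(spec$mix)
  lin <- pmin(pmax(lin, 0), 1)
  # inlined IEC 61966-2-1 forward transfer
  enc <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  dim(enc) <- dim(lin)
  list(
    img = tile_patches(enc, scene),
    patch_rgb = enc,
    patch_lab = srgb_to_lab(enc)
  )
}
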