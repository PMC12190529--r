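#' Cauchy-Lorentz narrow-band profile
#'
#' Narrow-band illuminants are modelled as scaled Lorentzian (Cauchy)
#' densities, `amplitude * (1/pi) * gamma / ((x - x0)^2 + gamma^2)`:
#' `x0` is the peak wavelength, `gamma` the half-width at half maximum, and
#' the profile integrates to `amplitude` over an unbounded axis.
#'
#' @param x Wavelengths (nm).
#' @param x0 Center wavelength (nm).
#' @param gamma HWHM scale (nm), > 0.
#' @param amplitude Nonnegative relative power multiplier.
#' @return Density values at `x`.
#' @examples
#' cauchy_lorentz(415, 415, 10)         # peak = 1 / (pi * 10)
#' cauchy_lorentz(425, 415, 10)         # half the peak at x0 + gamma
#' @export
cauchy_lorentz <- function(x, x0, gamma, amplitude = 1) {
  if (any(gamma <= 0)) rlang::abort(sprintf("gamma must be > 0, got %g", min(gamma)))
  if (any(amplitude < 0)) rlang::abort("amplitude must be >= 0")
  amplitude * (1 / (pi * gamma)) * gamma^2 / ((x - x0)^2 + gamma^2)
}

#' Narrow-band illumination specification
#'
#' The set of Cauchy-Lorentz bands used to simulate narrow-band imaging,
#' plus the 3 x n_bands mixing matrix that maps band images onto display
#' R, G, B. Defaults follow the NBI convention: the 415 nm (blue) band
#' drives the display G and B channels and the 540 nm (green) band drives
#' display R; auxiliary bands at 600, 700 and 780 nm enter the red channel
#' at small weight to emulate vendor post-processing. Every parameter is
#' optimizable via [optimize_bands()].
#'
#' @param centers Band center wavelengths (nm).
#' @param gammas HWHM scales (nm), recycled.
#' @param amplitudes Band gains, recycled.
#' @param mix 3 x n_bands nonnegative matrix (rows = display R, G, B).
#' @return An object of class `nbi_band_spec`.
#' @export
nbi_band_spec <- function(centers = c(415, 540, 600, 700, 780),
                          gammas = 10,
                          amplitudes = 1,
                          mix = NULL) {
  nb <- length(centers)
  if (nb < 2) rlang::abort("at least 2 bands required")
  gammas <- rep_len(gammas, nb)
  amplitudes <- rep_len(amplitudes, nb)
  if (any(gammas <= 0)) rlang::abort("gammas must be > 0")
  if (any(amplitudes < 0)) rlang::abort("amplitudes must be >= 0")
  if (is.null(mix)) {
    mix <- matrix(0, 3, nb, dimnames = list(c("R", "G", "B"), NULL))
    mix[1, 2] <- 1                      # green band -> display red
    mix[2, 1] <- 1                      # blue band -> display green
    mix[3, 1] <- 1                      # blue band -> display blue
    if (nb > 2) mix[1, 3:nb] <- 0.05    # auxiliary red/NIR bands
  }
  mix <- as.matrix(mix)
  if (nrow(mix) != 3 || ncol(mix) != nb) {
    rlang::abort(sprintf("mix must be 3 x %d", nb))
  }
  if (any(mix < 0)) rlang::abort("mix entries must be >= 0")
  if (any(rowSums(mix) == 0)) {
    rlang::abort("each display channel must receive nonzero total weight")
  }
  structure(
    list(centers = centers, gammas = gammas, amplitudes = amplitudes, mix = mix),
    class = "nbi_band_spec"
  )
}

#' @export
print.nbi_band_spec <- function(x, ...) {
  cat(sprintf(
    "<nbi_band_spec> %d bands at %s nm (gamma %s)\n",
    length(x$centers), paste(round(x$centers, 1), collapse = "/"),
    paste(round(x$gammas, 1), collapse = "/")
  ))
  invisible(x)
}

#' Sample one band's illuminant on a grid
#'
#' @param spec An [nbi_band_spec()].
#' @param band_index Which band.
#' @param grid A [spectral_grid()].
#' @return 1-row spectra matrix of the band's density on the grid.
#' @export
build_illuminant <- function(spec, band_index, grid = spectral_grid()) {
  stopifnot(inherits(spec, "nbi_band_spec"))
  if (band_index < 1 || band_index > length(spec$centers)) {
    rlang::abort(sprintf("band_index %d out of range", band_index))
  }
  v <- cauchy_lorentz(wavelengths(grid), spec$centers[band_index],
                      spec$gammas[band_index], spec$amplitudes[band_index])
  as_spectra(v, grid)
}

# normalized luminance-weighted band weights: w(lambda) such that a
# perfect reflector under the unit-amplitude band maps to 1; the band's
# amplitude then acts as a pure gain.
band_weights <- function(spec, grid, cmf) {
  wl <- wavelengths(grid)
  sapply(seq_along(spec$centers), function(b) {
    shape <- cauchy_lorentz(wl, spec$centers[b], spec$gammas[b], 1)
    w <- shape * cmf$ybar
    spec$amplitudes[b] * w / sum(w)
  })   # n_bands(grid) x n_bands(spec)
}

#' Render one narrow-band image from a hypercube
#'
#' Per pixel, the luminance-weighted integral of reflectance against the
#' band illuminant, normalized by the band shape's white-reflector response:
#' a perfect reflector maps to the band amplitude (1 at default).
#'
#' @param cube A `hypercube`.
#' @param spec An [nbi_band_spec()].
#' @param band_index Which band to render.
#' @param cmf Color matching functions on the cube grid.
#' @return H x W matrix of band responses.
#' @export
render_band_image <- function(cube, spec, band_index,
                              cmf = cie1931_cmf(cube$grid)) {
  stopifnot(inherits(cube, "hypercube"))
  check_same_grid(cube$grid, cmf$grid, what = "cube and cmf")
  w <- band_weights(spec, cube$grid, cmf)[, band_index]
  d <- dim(cube$values)
  matrix(matrix(cube$values, d[1] * d[2], d[3]) %*% w, d[1], d[2])
}

# band responses of spectra rows: n_spectra x n_bands(spec)
band_responses <- function(spectra, spec, cmf) {
  g <- spectra_grid(spectra)
  unclass_spectra(spectra) %*% band_weights(spec, g, cmf)
}

#' Compose the simulated NBI image
#'
#' Renders every band of `spec` from the hypercube, mixes the band images
#' into display R, G, B with `spec$mix`, clips to \[0, 1\] and sRGB-encodes.
#'
#' @inheritParams render_band_image
#' @return H x W x 3 array of encoded sRGB.
#' @export
compose_nbi <- function(cube, spec = nbi_band_spec(),
                        cmf = cie1931_cmf(cube$grid)) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  resp <- matrix(cube$values, d[1] * d[2], d[3]) %*%
    band_weights(spec, cube$grid, cmf)              # npx x n_bands
  rgb <- pmin(pmax(resp %*% t(spec$mix), 0), 1)
  array(srgb_encode(rgb), dim = c(d[1], d[2], 3))
}

#' Compose NBI display colors for a set of spectra
#'
#' The patch-level fast path used by the band optimizer: same contract as
#' [compose_nbi()] but acting on spectra rows instead of a full cube.
#'
#' @param spectra n x n_bands spectra matrix with a grid attribute.
#' @param spec An [nbi_band_spec()].
#' @param cmf Color matching functions.
#' @return n x 3 matrix of encoded sRGB colors.
#' @export
compose_nbi_colors <- function(spectra, spec = nbi_band_spec(),
                               cmf = cie1931_cmf(spectra_grid(spectra))) {
  resp <- band_responses(spectra, spec, cmf)
  srgb_encode(pmin(pmax(resp %*% t(spec$mix), 0), 1))
}
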