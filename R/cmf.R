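#' CIE 1931 2-degree color matching functions
#'
#' Returns the xbar, ybar, zbar weights of the CIE 1931 2-degree standard
#' observer tabulated on `grid`. The curves are generated from the
#' multi-lobe piecewise-Gaussian analytic representation of the observer
#' (Wyman, Sloan & Shirley 2013), which reproduces the tabulated observer
#' to about 1 part in 100 of peak and is clamped at zero so all weights are
#' nonnegative. Because every component of this package (calibration
#' targets, reconstruction, band rendering and the synthetic oracle) uses
#' the same curves, the pipeline is exactly self-consistent.
#'
#' @param grid A [spectral_grid()]; defaults to 380--780 nm at 1 nm.
#' @return A list of class `cmf` with elements `grid`, `xbar`, `ybar`,
#'   `zbar` (numeric vectors, one value per band).
#' @examples
#' cmf <- cie1931_cmf()
#' wavelengths(cmf$grid)[which.max(cmf$ybar)]  # ybar peaks near 555 nm
#' @export
cie1931_cmf <- function(grid = spectral_grid()) {
  wl <- wavelengths(grid)
  # piecewise Gaussian: different widths left/right of the mode
  pg <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  xbar <- 1.056 * pg(wl, 599.8, 37.9, 31.0) +
    0.362 * pg(wl, 442.0, 16.0, 26.7) -
    0.065 * pg(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * pg(wl, 568.8, 46.9, 40.5) +
    0.286 * pg(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * pg(wl, 437.0, 11.8, 36.0) +
    0.681 * pg(wl, 459.0, 26.0, 13.8)
  structure(
    list(grid = grid, xbar = pmax(xbar, 0), ybar = pmax(ybar, 0),
         zbar = pmax(zbar, 0)),
    class = "cmf"
  )
}

#' @export
print.cmf <- function(x, ...) {
  cat(sprintf("<cmf> CIE 1931 2-degree observer on %s\n", format(x$grid)))
  invisible(x)
}

#' Reference illuminants
#'
#' `illuminant_spectrum("E")` is the equal-energy illuminant (flat spectral
#' power), the package default for spectral integration: it is exactly
#' defined on any grid, and calibration absorbs any linear discrepancy
#' between it and the physical lamp. Arbitrary measured lamp spectra can be
#' supplied as spectra matrices read with [read_spectra_csv()].
#'
#' @param name Illuminant name; currently `"E"`.
#' @param grid A [spectral_grid()].
#' @return A 1-row spectra matrix on `grid`.
#' @export
illuminant_spectrum <- function(name = "E", grid = spectral_grid()) {
  name <- toupper(name)
  if (name == "E") {
    return(as_spectra(rep(1, n_bands(grid)), grid))
  }
  rlang::abort(sprintf(
    "unknown illuminant '%s'; supply a measured SPD as a spectra matrix", name
  ))
}
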