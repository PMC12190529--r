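#' Integrate reflectance spectra to CIE XYZ
#'
#' Computes X = k * sum(r * I * xbar) * dl (and likewise Y, Z) over the
#' shared wavelength grid, with the normalization k chosen so that a
#' perfect reflector (r = 1 everywhere) under the given illuminant has
#' Y = 100. This is the colorimetric anchor of the calibration: patch
#' reflectance spectra measured by the spectrometer become the XYZ targets
#' the camera is corrected towards.
#'
#' @param reflectance Spectra matrix (rows = spectra) with a grid attribute.
#' @param illuminant Illuminant spectral power, 1-row spectra matrix on the
#'   same grid (resampled otherwise).
#' @param cmf Color matching functions from [cie1931_cmf()] on the same grid.
#' @return n x 3 matrix of tristimulus values (columns X, Y, Z).
#' @examples
#' g <- spectral_grid()
#' spectrum_to_xyz(as_spectra(rep(1, n_bands(g)), g))  # Y = 100
#' @export
spectrum_to_xyz <- function(reflectance,
                            illuminant = illuminant_spectrum("E", spectra_grid(reflectance)),
                            cmf = cie1931_cmf(spectra_grid(reflectance))) {
  g <- spectra_grid(reflectance)
  illuminant <- resample_spectra(illuminant, g)
  if (!grids_equal(cmf$grid, g)) cmf <- cie1931_cmf(g)
  check_same_grid(g, spectra_grid(illuminant), cmf$grid, what = "spectrum_to_xyz inputs")
  r <- unclass_spectra(reflectance)
  ii <- as.vector(unclass_spectra(illuminant))
  k <- 100 / sum(ii * cmf$ybar)
  w <- cbind(X = ii * cmf$xbar, Y = ii * cmf$ybar, Z = ii * cmf$zbar)
  out <- k * (r %*% w)
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' CIE XYZ to CIELAB
#'
#' Standard CIELAB with the cube-root/linear split, relative to a white
#' point whose Y is 100. The white itself maps to (100, 0, 0).
#'
#' @param xyz n x 3 matrix (or length-3 vector) of tristimulus values.
#' @param white Length-3 white point with `white[2] == 100`.
#' @return n x 3 matrix with columns L, a, b.
#' @export
xyz_to_lab <- function(xyz, white = d65_white()) {
  xyz <- rbind3(xyz)
  if (any(white <= 0)) rlang::abort("white point tristimulus must be positive")
  if (abs(white[2] - 100) > 1e-6) {
    rlang::abort(sprintf("white point must have Y = 100, got %.4f", white[2]))
  }
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz[, 1] / white[1])
  fy <- f(xyz[, 2] / white[2])
  fz <- f(xyz[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  colnames(out) <- c("L", "a", "b")
  out
}

#' @rdname xyz_to_lab
#' @param lab n x 3 matrix with columns L, a, b.
#' @export
lab_to_xyz <- function(lab, white = d65_white()) {
  lab <- rbind3(lab)
  finv <- function(t) {
    d <- 6 / 29
    ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
  }
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  out <- cbind(X = white[1] * finv(fx), Y = white[2] * finv(fy),
               Z = white[3] * finv(fz))
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Color differences in CIELAB
#'
#' `ciede2000()` implements the CIEDE2000 formula (kL = kC = kH = 1) with
#' the chroma-dependent G compensation, hue rotation term and the standard
#' discontinuity handling of the mean hue; `delta_e_ab()` is the plain
#' Euclidean CIE76 difference. Both are vectorized over rows.
#'
#' @param lab1,lab2 n x 3 matrices (or length-3 vectors) of Lab colors on
#'   the same white point.
#' @return Numeric vector of color differences, one per row.
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # ~2.0425
#' @export
ciede2000 <- function(lab1, lab2) {
  lab1 <- rbind3(lab1); lab2 <- rbind3(lab2)
  if (nrow(lab1) != nrow(lab2)) rlang::abort("lab1 and lab2 must have the same rows")
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  deg <- function(r) r * 180 / pi
  rad <- function(d) d * pi / 180

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (deg(atan2(b1, a1p)) + 360) %% 360)
  h2p <- ifelse(C2p == 0, 0, (deg(atan2(b2, a2p)) + 360) %% 360)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh,
         ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(rad(dhp) / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos(rad(hbp - 30)) + 0.24 * cos(rad(2 * hbp)) +
    0.32 * cos(rad(3 * hbp + 6)) - 0.20 * cos(rad(4 * hbp - 63))
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(rad(2 * dtheta)) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

#' @rdname ciede2000
#' @export
delta_e_ab <- function(lab1, lab2) {
  lab1 <- rbind3(lab1); lab2 <- rbind3(lab2)
  sqrt(rowSums((lab1 - lab2)^2))
}
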