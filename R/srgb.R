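#' sRGB transfer functions
#'
#' The IEC 61966-2-1 piecewise transfer function ("gamma function") between
#' encoded sRGB values and linear-light values, both on \[0, 1\]. 8-bit
#' pixel data should be divided by 255 before decoding. The pair round-trips
#' to better than 1e-12.
#'
#' @param x Numeric vector/array of values in \[0, 1\].
#' @return Values in \[0, 1\], same shape as `x`.
#' @examples
#' srgb_decode(c(0, 0.5, 1))
#' srgb_encode(srgb_decode(0.42))  # 0.42
#' @export
srgb_decode <- function(x) {
  check_unit_range(x, "srgb_decode")
  out <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  keep_shape(out, x)
}

#' @rdname srgb_decode
#' @export
srgb_encode <- function(x) {
  check_unit_range(x, "srgb_encode")
  out <- ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  keep_shape(out, x)
}

check_unit_range <- function(x, fn) {
  if (!all(is.finite(x))) {
    rlang::abort(sprintf("%s: input contains non-finite values", fn))
  }
  bad <- x < 0 | x > 1
  if (any(bad)) {
    v <- x[which(bad)[1]]
    rlang::abort(sprintf("%s: value %.6g outside [0, 1]", fn, v))
  }
  invisible(x)
}

keep_shape <- function(out, x) {
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Standard sRGB (D65) primaries: linear RGB on [0,1] <-> XYZ with Y of the
# display white = 1. Rows X, Y, Z.
srgb_to_xyz_matrix <- function() {
  matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), nrow = 3, byrow = TRUE)
}

xyz_to_srgb_matrix <- function() solve(srgb_to_xyz_matrix())

#' D65 white point
#'
#' Tristimulus of the sRGB display white (Y = 100 scale), used when
#' converting display colors to CIELAB.
#'
#' @return Named numeric vector (X, Y, Z).
#' @export
d65_white <- function() {
  w <- rowSums(srgb_to_xyz_matrix())
  w <- w / w[2] * 100
  names(w) <- c("X", "Y", "Z")
  w
}

#' Convert between encoded sRGB and XYZ / Lab
#'
#' `srgb_to_xyz()` linearizes encoded sRGB and applies the standard
#' sRGB-to-XYZ (D65) matrix on the Y-of-white = 100 scale. `srgb_to_lab()`
#' continues to CIELAB under the D65 white point. Inputs are n x 3 matrices
#' (or length-3 vectors); outputs keep the row count.
#'
#' @param rgb Encoded sRGB values in \[0, 1\], n x 3.
#' @return n x 3 matrix of XYZ (or Lab) values.
#' @export
srgb_to_xyz <- function(rgb) {
  rgb <- rbind3(rgb)
  lin <- srgb_decode(rgb)
  t(srgb_to_xyz_matrix() %*% t(lin)) * 100
}

#' @rdname srgb_to_xyz
#' @export
srgb_to_lab <- function(rgb) {
  xyz_to_lab(srgb_to_xyz(rgb), white = d65_white())
}

#' @rdname srgb_to_xyz
#' @param xyz n x 3 matrix of tristimulus values on the Y-of-white = 100
#'   scale.
#' @param clip Clip linear RGB into \[0, 1\] before encoding (out-of-gamut
#'   colors are otherwise an error in `srgb_encode`).
#' @export
xyz_to_srgb <- function(xyz, clip = TRUE) {
  xyz <- rbind3(xyz)
  lin <- t(xyz_to_srgb_matrix() %*% t(xyz / 100))
  if (clip) lin <- pmin(pmax(lin, 0), 1)
  srgb_encode(lin)
}

rbind3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    x <- matrix(x, nrow = 1)
  }
  stopifnot(ncol(x) == 3)
  x
}
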