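#' Spectral grid
#'
#' A uniform wavelength axis on which all spectra, illuminants and color
#' matching functions in the package live. The default covers the visible
#' range 380--780 nm at 1 nm steps (401 bands), the working range of the
#' reconstruction pipeline.
#'
#' @param start_nm First wavelength in nanometres.
#' @param end_nm Last wavelength in nanometres (inclusive).
#' @param step_nm Step between bands in nanometres; must divide
#'   `end_nm - start_nm` exactly.
#' @return An object of class `spectral_grid`.
#' @examples
#' g <- spectral_grid()
#' n_bands(g)      # 401
#' head(wavelengths(g))
#' @export
spectral_grid <- function(start_nm = 380, end_nm = 780, step_nm = 1) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || !is.numeric(step_nm)) {
    rlang::abort("spectral_grid bounds must be numeric")
  }
  if (start_nm >= end_nm) {
    rlang::abort(sprintf("start_nm (%g) must be < end_nm (%g)", start_nm, end_nm))
  }
  if (step_nm <= 0) {
    rlang::abort(sprintf("step_nm must be > 0, got %g", step_nm))
  }
  span <- end_nm - start_nm
  if (abs(span / step_nm - round(span / step_nm)) > 1e-9) {
    rlang::abort(sprintf(
      "(end_nm - start_nm) = %g is not divisible by step_nm = %g", span, step_nm
    ))
  }
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm),
    class = "spectral_grid"
  )
}

#' @rdname spectral_grid
#' @param grid A `spectral_grid`.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @rdname spectral_grid
#' @export
n_bands <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  as.integer(round((grid$end_nm - grid$start_nm) / grid$step_nm)) + 1L
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf(
    "<spectral_grid> %g-%g nm @ %g nm (%d bands)\n",
    x$start_nm, x$end_nm, x$step_nm, n_bands(x)
  ))
  invisible(x)
}

#' @export
format.spectral_grid <- function(x, ...) {
  sprintf("%g:%g:%g", x$start_nm, x$end_nm, x$step_nm)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

check_same_grid <- function(..., what = "spectra") {
  grids <- list(...)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!grids_equal(ref, g)) {
      rlang::abort(sprintf(
        "grid mismatch between %s: %s vs %s", what,
        format(ref), format(g)
      ))
    }
  }
  invisible(ref)
}

#' Spectra as matrices
#'
#' Spectra are stored as numeric vectors (one spectrum) or matrices with one
#' row per spectrum and one column per band, carrying their `spectral_grid`
#' in the `"grid"` attribute. `as_spectra()` attaches a grid and validates
#' the band count; `spectra_grid()` retrieves it.
#'
#' @param x Numeric vector or matrix of reflectance / relative power values.
#' @param grid The `spectral_grid` the columns live on.
#' @return `x` as a matrix with a `"grid"` attribute.
#' @export
as_spectra <- function(x, grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != n_bands(grid)) {
    rlang::abort(sprintf(
      "spectrum has %d bands but grid %s has %d",
      ncol(x), format(grid), n_bands(grid)
    ))
  }
  if (!all(is.finite(x))) rlang::abort("spectra must be finite")
  attr(x, "grid") <- grid
  x
}

#' @rdname as_spectra
#' @export
spectra_grid <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) rlang::abort("object carries no spectral grid")
  g
}

#' Resample spectra onto a new grid
#'
#' Linear interpolation between tabulated points; zero outside the tabulated
#' support. This is the resampling convention used throughout the package
#' when spectrometer data arrive on a coarser grid than the working grid.
#'
#' @param x Spectra matrix (rows = spectra) with a `"grid"` attribute.
#' @param grid Target `spectral_grid`.
#' @return Spectra matrix on `grid`.
#' @export
resample_spectra <- function(x, grid) {
  from <- spectra_grid(x)
  if (grids_equal(from, grid)) return(as_spectra(unclass_spectra(x), grid))
  wl_from <- wavelengths(from)
  wl_to <- wavelengths(grid)
  out <- t(apply(unclass_spectra(x), 1, function(v) {
    stats::approx(wl_from, v, xout = wl_to, method = "linear",
                  yleft = 0, yright = 0)$y
  }))
  as_spectra(out, grid)
}

unclass_spectra <- function(x) {
  attr(x, "grid") <- NULL
  if (is.vector(x)) matrix(x, nrow = 1) else x
}

#' Tidy view of a spectra matrix
#'
#' @param x Spectra matrix with a grid attribute.
#' @param names Optional spectrum names (defaults to rownames or `s01`...).
#' @return A tibble with columns `spectrum`, `wavelength_nm`, `value`.
#' @export
spectra_tbl <- function(x, names = NULL) {
  g <- spectra_grid(x)
  m <- unclass_spectra(x)
  if (is.null(names)) {
    names <- rownames(m) %||% sprintf("s%02d", seq_len(nrow(m)))
  }
  tibble::tibble(
    spectrum = rep(names, each = ncol(m)),
    wavelength_nm = rep(wavelengths(g), times = nrow(m)),
    value = as.vector(t(m))
  )
}

#' Read / write spectra CSV tables
#'
#' Long or wide layout. `write_spectra_csv()` writes a wide table with a
#' `wavelength_nm` column followed by one column per spectrum;
#' `read_spectra_csv()` accepts the same layout (any numeric columns beside
#' `wavelength_nm`) and resamples onto `grid` when given.
#'
#' @param x Spectra matrix with a grid attribute.
#' @param path File path.
#' @param grid Optional target grid for reading.
#' @return `read_spectra_csv()` returns a spectra matrix (rows = spectra).
#' @export
write_spectra_csv <- function(x, path) {
  g <- spectra_grid(x)
  m <- unclass_spectra(x)
  nm <- rownames(m) %||% sprintf("s%02d", seq_len(nrow(m)))
  df <- tibble::as_tibble(stats::setNames(as.data.frame(t(m)), nm))
  df <- dplyr::bind_cols(tibble::tibble(wavelength_nm = wavelengths(g)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, grid = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    rlang::abort("spectra CSV must have a 'wavelength_nm' column")
  }
  wl <- df$wavelength_nm
  vals <- as.matrix(df[setdiff(names(df), "wavelength_nm")])
  step <- unique(round(diff(wl), 9))
  if (length(step) != 1) rlang::abort("wavelength_nm must be uniformly spaced")
  src <- spectral_grid(min(wl), max(wl), step)
  out <- as_spectra(t(vals), src)
  rownames(out) <- colnames(vals)
  if (!is.null(grid)) out <- resample_spectra(out, grid)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
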