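#' Plot a set of spectra
#'
#' One line per spectrum over wavelength; reflectance or relative power on
#' the y axis.
#'
#' @param x Spectra matrix with a grid attribute.
#' @param names Optional spectrum labels.
#' @return A ggplot object.
#' @export
plot_spectra <- function(x, names = NULL) {
  df <- spectra_tbl(x, names)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value,
                                   color = .data$spectrum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "value", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectral_basis <- function(object, ...) {
  g <- object$grid
  df <- tibble::tibble(
    wavelength_nm = rep(wavelengths(g), object$k + 1),
    value = c(object$mean_spectrum, as.vector(object$EV)),
    component = rep(c("mean", sprintf("PC%d", seq_len(object$k))),
                    each = n_bands(g))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = NULL,
                  title = sprintf("Spectral basis (%.2f%% cumulative variance)",
                                  100 * sum(object$explained_variance_ratio))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.correction_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report, c("de_pre", "de_post"),
                            names_to = "stage", values_to = "de")
  df$stage <- factor(df$stage, c("de_pre", "de_post"),
                     c("before calibration", "after calibration"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$patch), .data$de,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "patch", y = sprintf("color difference (%s)", object$metric),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nbi_band_spec <- function(object, ..., grid = spectral_grid()) {
  wl <- wavelengths(grid)
  df <- purrr::map_dfr(seq_along(object$centers), function(b) {
    tibble::tibble(
      wavelength_nm = wl,
      power = cauchy_lorentz(wl, object$centers[b], object$gammas[b],
                             object$amplitudes[b]),
      band = sprintf("%.0f nm", object$centers[b])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$power,
                                   color = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "relative power", color = "band") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quality_report <- function(object, ...) {
  df <- tidy.quality_report(object)
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
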