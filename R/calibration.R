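#' Patch calibration set
#'
#' Pairs the camera's encoded sRGB values for each color-target patch with
#' the reflectance spectrum measured for that patch by a spectrometer. A
#' standard 24-patch color checker is the expected target, but any n >= 4
#' patches work; with fewer patches than expansion terms the fit is
#' underdetermined and a warning is raised at fit time.
#'
#' @param camera_rgb n x 3 matrix of encoded sRGB values in \[0, 1\]
#'   (divide 8-bit data by 255 first).
#' @param reflectance n-row spectra matrix (one spectrum per patch) with a
#'   grid attribute.
#' @return A tibble of class `patch_calibration_set` with columns `patch`,
#'   `r`, `g`, `b` and the list-column `reflectance`; the grid is carried in
#'   the `"grid"` attribute.
#' @export
patch_calibration_set <- function(camera_rgb, reflectance) {
  camera_rgb <- rbind3(camera_rgb)
  g <- spectra_grid(reflectance)
  m <- unclass_spectra(reflectance)
  if (nrow(camera_rgb) != nrow(m)) {
    rlang::abort(sprintf(
      "one RGB triple per patch required: %d RGB rows vs %d spectra",
      nrow(camera_rgb), nrow(m)
    ))
  }
  check_unit_range(camera_rgb, "patch_calibration_set")
  out <- tibble::tibble(
    patch = seq_len(nrow(m)),
    r = camera_rgb[, 1], g = camera_rgb[, 2], b = camera_rgb[, 3],
    reflectance = lapply(seq_len(nrow(m)), function(i) m[i, ])
  )
  attr(out, "grid") <- g
  class(out) <- c("patch_calibration_set", class(out))
  out
}

cal_spectra <- function(cal) {
  as_spectra(do.call(rbind, cal$reflectance), attr(cal, "grid"))
}

cal_rgb <- function(cal) cbind(cal$r, cal$g, cal$b)

#' Camera XYZ from encoded sRGB
#'
#' The pre-correction camera color: encoded sRGB is linearized with the
#' inverse transfer function and pushed through the standard sRGB-to-XYZ
#' (D65) matrix, Y-of-white = 100 scale. Whatever the real device did on
#' top of this idealization is exactly what the polynomial correction is
#' fitted to undo.
#'
#' @inheritParams srgb_to_xyz
#' @return n x 3 matrix of camera XYZ.
#' @export
camera_xyz <- function(rgb) srgb_to_xyz(rgb)

#' Fit the camera-to-colorimeter polynomial correction
#'
#' The 3 x n_terms coefficient matrix C is the minimum-norm least-squares
#' solution of `XYZ_spectrum = C V`, where V stacks the polynomial feature
#' vectors of the camera XYZ of each patch (one column per patch) and
#' `XYZ_spectrum` holds the spectrally integrated patch colors. The
#' pseudo-inverse is computed by SVD with a relative cutoff of 1e-10, so
#' C = XYZ_spectrum pinv(V). Per-patch color error (CIEDE2000 by default)
#' before and after correction is recorded in the fit report.
#'
#' @param cal A [patch_calibration_set()].
#' @param spec A [feature_expansion()]; default degree-3, 14 terms.
#' @param illuminant Illuminant SPD used to integrate the patch spectra.
#' @param cmf Color matching functions.
#' @param metric `"de2000"` (default) or `"deab"` for the fit report.
#' @return An object of class `correction_model` with elements `spec`, `C`
#'   (3 x n_terms), `white`, `report` (per-patch tibble), `metric`.
#' @seealso [apply_correction()], [calibration_report()]
#' @export
fit_correction <- function(cal,
                           spec = feature_expansion(),
                           illuminant = illuminant_spectrum("E", attr(cal, "grid")),
                           cmf = cie1931_cmf(attr(cal, "grid")),
                           metric = c("de2000", "deab")) {
  stopifnot(inherits(cal, "patch_calibration_set"))
  metric <- match.arg(metric)
  n <- nrow(cal)
  if (n < 4) rlang::abort("at least 4 calibration patches required")
  if (n < n_terms(spec)) {
    rlang::warn(sprintf(
      "underdetermined fit: %d patches < %d expansion terms", n, n_terms(spec)
    ))
  }
  refl <- cal_spectra(cal)
  target <- spectrum_to_xyz(refl, illuminant, cmf)      # n x 3
  cam <- camera_xyz(cal_rgb(cal))                       # n x 3
  V <- t(expand_features(cam, spec))                    # n_terms x n
  C <- t(target) %*% pinv(V, warn_rank = TRUE)          # 3 x n_terms

  white <- spectrum_to_xyz(
    as_spectra(rep(1, n_bands(attr(cal, "grid"))), attr(cal, "grid")),
    illuminant, cmf
  )[1, ]
  corrected <- t(C %*% V)
  de_fun <- if (metric == "de2000") ciede2000 else delta_e_ab
  lab_t <- xyz_to_lab(target, white)
  report <- tibble::tibble(
    patch = cal$patch,
    de_pre = de_fun(xyz_to_lab(cam, white), lab_t),
    de_post = de_fun(xyz_to_lab(corrected, white), lab_t)
  )
  structure(
    list(spec = spec, C = C, white = white, metric = metric,
         report = report, cal = cal, illuminant = illuminant, cmf = cmf),
    class = "correction_model"
  )
}

#' Apply a fitted color correction
#'
#' `XYZ_correct = C * features(XYZ_camera)`; vectorized over rows, so a
#' whole image flattened to n x 3 goes through in one call.
#'
#' @param model A fitted `correction_model`.
#' @param xyz n x 3 matrix (or length-3 vector) of camera XYZ.
#' @return n x 3 matrix of corrected XYZ.
#' @export
apply_correction <- function(model, xyz) {
  stopifnot(inherits(model, "correction_model"))
  out <- expand_features(rbind3(xyz), model$spec) %*% t(model$C)
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Per-patch calibration error report
#'
#' Re-evaluates the stored calibration set through the fitted model and
#' returns per-patch color differences before and after correction, plus
#' summary means. The paper-facing quantity is the post-correction mean.
#'
#' @param model A fitted `correction_model`.
#' @return A tibble with columns `patch`, `de_pre`, `de_post`; the means are
#'   in attributes `mean_pre` / `mean_post` and in [glance.correction_model()].
#' @export
calibration_report <- function(model) {
  stopifnot(inherits(model, "correction_model"))
  rep <- model$report
  attr(rep, "mean_pre") <- mean(rep$de_pre)
  attr(rep, "mean_post") <- mean(rep$de_post)
  rep
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> %d terms, %d patches; mean dE %s %.4f -> %.4f\n",
    n_terms(x$spec), nrow(x$report), x$metric,
    mean(x$report$de_pre), mean(x$report$de_post)
  ))
  invisible(x)
}

#' Tidiers for correction models
#'
#' `tidy()` returns the per-patch pre/post color error table; `glance()`
#' a one-row summary with the mean errors.
#'
#' @param x A `correction_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.correction_model <- function(x, ...) x$report

#' @rdname tidy.correction_model
#' @export
glance.correction_model <- function(x, ...) {
  tibble::tibble(
    n_patches = nrow(x$report),
    n_terms = n_terms(x$spec),
    metric = x$metric,
    mean_de_pre = mean(x$report$de_pre),
    mean_de_post = mean(x$report$de_post)
  )
}

#' Serialize / restore a correction model as JSON
#'
#' Matrices are written row-major with declared shapes so the file is
#' self-describing and byte-stable for identical fits.
#'
#' @param model A `correction_model`.
#' @param path Output file.
#' @export
write_correction_model <- function(model, path) {
  obj <- list(
    type = "correction_model",
    terms = model$spec$terms,
    C = list(shape = dim(model$C), data = as.vector(t(model$C))),
    white = unname(model$white),
    metric = model$metric
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "correction_model") {
    rlang::abort(sprintf("%s is not a correction_model JSON", path))
  }
  C <- matrix(obj$C$data, nrow = obj$C$shape[1], byrow = TRUE)
  structure(
    list(spec = feature_expansion(terms = obj$terms), C = C,
         white = stats::setNames(obj$white, c("X", "Y", "Z")),
         metric = obj$metric,
         report = tibble::tibble(patch = integer(), de_pre = numeric(),
                                 de_post = numeric())),
    class = "correction_model"
  )
}
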