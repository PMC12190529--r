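#' Principal-component basis of a reflectance set
#'
#' Mean-centered PCA of the patch reflectance spectra. A handful of smooth
#' components captures almost all the variance of natural reflectances —
#' six components is the pipeline default — and each training spectrum's
#' scores are recoverable as `t(EV) %*% (r - mean)`. Eigenvector sign is
#' fixed by making each column's largest-magnitude element positive, so
#' serialized bases are reproducible.
#'
#' @param spectra n x n_bands spectra matrix with a grid attribute, n >= k + 1.
#' @param k Number of components to keep (default 6).
#' @return An object of class `spectral_basis`: `grid`, `mean_spectrum`,
#'   `EV` (n_bands x k, orthonormal columns), `explained_variance_ratio`.
#' @export
fit_basis <- function(spectra, k = 6) {
  g <- spectra_grid(spectra)
  X <- unclass_spectra(spectra)
  n <- nrow(X)
  if (n < k + 1) {
    rlang::abort(sprintf("need at least k + 1 = %d spectra, got %d", k + 1, n))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  tol <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tol)
  if (rank < k) {
    rlang::abort(sprintf(
      "requested k = %d components but the centered set has rank %d", k, rank
    ))
  }
  ev <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| element of each column positive
  for (j in seq_len(k)) {
    if (ev[which.max(abs(ev[, j])), j] < 0) ev[, j] <- -ev[, j]
  }
  var_all <- sv$d^2
  structure(
    list(grid = g, mean_spectrum = mu, EV = ev,
         explained_variance_ratio = var_all[seq_len(k)] / sum(var_all),
         k = k),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf(
    "<spectral_basis> k = %d on %s; cumulative variance %.4f%%\n",
    x$k, format(x$grid), 100 * sum(x$explained_variance_ratio)
  ))
  invisible(x)
}

basis_scores <- function(basis, spectra) {
  X <- unclass_spectra(spectra)
  sweep(X, 2, basis$mean_spectrum) %*% basis$EV   # n x k
}

#' Tidiers for spectral bases
#'
#' `tidy()` gives per-component explained variance; `glance()` the k and
#' cumulative explained variance.
#'
#' @param x A `spectral_basis`.
#' @param ... Unused.
#' @export
tidy.spectral_basis <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' @rdname tidy.spectral_basis
#' @export
glance.spectral_basis <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_bands = length(x$mean_spectrum),
    cumulative_variance = sum(x$explained_variance_ratio)
  )
}

#' Fit the color-feature-to-score mapping
#'
#' The bridge from corrected camera color to spectral shape: training PC
#' scores are regressed on polynomial features of the corrected patch XYZ,
#' `M = Score pinv(V_color)` with the same SVD pseudo-inverse as the
#' colorimetric correction. The color expansion defaults to the
#' calibration's but is independently configurable.
#'
#' @param basis A [fit_basis()] result.
#' @param cal The [patch_calibration_set()] the correction was fitted on.
#' @param correction The fitted [fit_correction()] model.
#' @param spec Color-feature expansion (`V_color`); defaults to the
#'   correction's expansion.
#' @return An object of class `spectral_mapping`: `spec`, `M` (k x n_terms).
#' @export
fit_mapping <- function(basis, cal, correction, spec = correction$spec) {
  stopifnot(inherits(basis, "spectral_basis"),
            inherits(cal, "patch_calibration_set"),
            inherits(correction, "correction_model"))
  if (!grids_equal(basis$grid, attr(cal, "grid"))) {
    rlang::abort("basis and calibration set live on different grids")
  }
  score <- t(basis_scores(basis, cal_spectra(cal)))          # k x n
  corrected <- apply_correction(correction, camera_xyz(cal_rgb(cal)))
  Vc <- t(expand_features(corrected, spec))                  # n_terms x n
  M <- score %*% pinv(Vc)
  structure(list(spec = spec, M = M, k = basis$k), class = "spectral_mapping")
}

#' @export
print.spectral_mapping <- function(x, ...) {
  cat(sprintf("<spectral_mapping> %d scores from %d color features\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Reconstruct a reflectance spectrum from a corrected color
#'
#' `s = mean + EV M features(XYZ_correct)`, then clamped to \[0, 1.2\]:
#' reconstruction may legitimately overshoot unit reflectance slightly, but
#' 1.2 bounds nonphysical blow-up. The number of clamped values is recorded
#' in the `"n_clamped"` attribute.
#'
#' @param mapping A [fit_mapping()] result.
#' @param basis The matching [fit_basis()] result.
#' @param xyz n x 3 corrected XYZ (or length-3 vector).
#' @param clamp Clamp range, `NULL` to disable.
#' @return n-row spectra matrix on the basis grid.
#' @export
reconstruct_spectrum <- function(mapping, basis, xyz, clamp = c(0, 1.2)) {
  stopifnot(inherits(mapping, "spectral_mapping"),
            inherits(basis, "spectral_basis"))
  feats <- expand_features(rbind3(xyz), mapping$spec)        # n x n_terms
  s <- feats %*% t(mapping$M) %*% t(basis$EV)                # n x n_bands
  s <- sweep(s, 2, basis$mean_spectrum, `+`)
  n_clamped <- 0L
  if (!is.null(clamp)) {
    n_clamped <- sum(s < clamp[1] | s > clamp[2])
    s <- pmin(pmax(s, clamp[1]), clamp[2])
  }
  out <- as_spectra(s, basis$grid)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Reconstruct a full hypercube from a white-light RGB image
#'
#' Per-pixel pipeline: sRGB decode, camera XYZ, polynomial correction,
#' basis reconstruction. Vectorized over all pixels; identical to the
#' scalar [reconstruct_spectrum()] path.
#'
#' @param img H x W x 3 array of encoded sRGB in \[0, 1\].
#' @param correction Fitted `correction_model`.
#' @param mapping Fitted `spectral_mapping`.
#' @param basis Fitted `spectral_basis`.
#' @return An object of class `hypercube`: list with `values`
#'   (H x W x n_bands array), `grid`, `n_clamped`.
#' @export
image_to_hypercube <- function(img, correction, mapping, basis) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    rlang::abort("img must be an H x W x 3 RGB array")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- matrix(img, h * w, 3)
  xyzc <- apply_correction(correction, camera_xyz(rgb))
  sp <- reconstruct_spectrum(mapping, basis, xyzc)
  cube <- array(unclass_spectra(sp), dim = c(h, w, n_bands(basis$grid)))
  structure(
    list(values = cube, grid = basis$grid,
         n_clamped = attr(sp, "n_clamped")),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d px, %d bands on %s (%d clamped values)\n",
              d[1], d[2], d[3], format(x$grid), x$n_clamped))
  invisible(x)
}

#' Root-mean-square error between spectra
#'
#' Per-band RMSE in reflectance units between paired rows of two spectra
#' matrices on the same grid — the reconstruction-fidelity figure of the
#' pipeline.
#'
#' @param a,b Spectra matrices with equal shape and grid.
#' @return Numeric vector, one RMSE per row pair.
#' @export
spectrum_rmse <- function(a, b) {
  check_same_grid(spectra_grid(a), spectra_grid(b), what = "spectrum_rmse inputs")
  ma <- unclass_spectra(a); mb <- unclass_spectra(b)
  stopifnot(all(dim(ma) == dim(mb)))
  sqrt(rowMeans((ma - mb)^2))
}

#' Serialize / restore the spectral model (basis + mapping) as JSON
#'
#' @param basis A `spectral_basis`.
#' @param mapping A `spectral_mapping`.
#' @param path Output file.
#' @export
write_spectral_model <- function(basis, mapping, path) {
  obj <- list(
    type = "spectral_model",
    grid = unclass(basis$grid),
    mean_spectrum = basis$mean_spectrum,
    EV = list(shape = dim(basis$EV), data = as.vector(t(basis$EV))),
    explained_variance_ratio = basis$explained_variance_ratio,
    terms = mapping$spec$terms,
    M = list(shape = dim(mapping$M), data = as.vector(t(mapping$M)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spectral_model
#' @return `read_spectral_model()` returns `list(basis =, mapping =)`.
#' @export
read_spectral_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "spectral_model") {
    rlang::abort(sprintf("%s is not a spectral_model JSON", path))
  }
  g <- spectral_grid(obj$grid$start_nm, obj$grid$end_nm, obj$grid$step_nm)
  EV <- matrix(obj$EV$data, nrow = obj$EV$shape[1], byrow = TRUE)
  M <- matrix(obj$M$data, nrow = obj$M$shape[1], byrow = TRUE)
  basis <- structure(
    list(grid = g, mean_spectrum = obj$mean_spectrum, EV = EV,
         explained_variance_ratio = obj$explained_variance_ratio,
         k = ncol(EV)),
    class = "spectral_basis"
  )
  mapping <- structure(
    list(spec = feature_expansion(terms = obj$terms), M = M, k = nrow(M)),
    class = "spectral_mapping"
  )
  list(basis = basis, mapping = mapping)
}
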