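#' Optimize narrow-band parameters against target colors
#'
#' Tunes the Cauchy-Lorentz band parameters (centers, HWHM scales,
#' amplitudes) and optionally the band-to-display mixing matrix by dual
#' annealing, minimizing the mean CIEDE2000 between the NBI colors composed
#' from the reconstructed patch spectra and per-patch target Lab colors
#' (typically from real narrow-band captures, or from the synthetic
#' oracle renderer). Bounds default to a physical neighborhood of the
#' initial spec: centers within +/- 10 nm of their initial values, gamma in
#' \[1, 40\] nm, amplitudes in \[0, 2\], mix weights in \[0, 1.5\].
#'
#' @param spectra n x n_bands reconstructed patch spectra (grid attribute).
#' @param target_lab n x 3 matrix of target Lab colors (D65 white).
#' @param init Initial [nbi_band_spec()].
#' @param seed Integer seed for the annealer (required).
#' @param optimize_mix Also optimize the mixing matrix (default TRUE).
#' @param bounds Optional list with `lower` and `upper` parameter vectors
#'   (see [band_par_bounds()]).
#' @param max_evals Objective evaluation budget (default 2000).
#' @param cmf Color matching functions on the spectra grid.
#' @return An object of class `nbi_optimization`: `spec` (optimized),
#'   `objective_initial`, `objective_final`, `n_evaluations`, `seed`.
#' @export
optimize_bands <- function(spectra, target_lab, init = nbi_band_spec(),
                           seed, optimize_mix = TRUE, bounds = NULL,
                           max_evals = 2000,
                           cmf = cie1931_cmf(spectra_grid(spectra))) {
  stopifnot(inherits(init, "nbi_band_spec"))
  if (missing(seed)) rlang::abort("optimize_bands requires an explicit seed")
  target_lab <- rbind3(target_lab)
  if (nrow(target_lab) != nrow(unclass_spectra(spectra))) {
    rlang::abort("one target Lab color per spectrum required")
  }
  g <- spectra_grid(spectra)
  if (is.null(bounds)) bounds <- band_par_bounds(init, g, optimize_mix)
  if (any(bounds$upper <= bounds$lower)) {
    rlang::abort("invalid bounds: upper must exceed lower everywhere")
  }
  x0 <- spec_to_par(init, optimize_mix)
  if (length(x0) != length(bounds$lower)) {
    rlang::abort(sprintf("bounds length %d does not match %d parameters",
                         length(bounds$lower), length(x0)))
  }
  objective <- function(par) {
    sp <- par_to_spec(par, init, optimize_mix)
    cols <- compose_nbi_colors(spectra, sp, cmf)
    mean(ciede2000(srgb_to_lab(cols), target_lab))
  }
  res <- dual_annealing(objective, bounds$lower, bounds$upper, x0 = x0,
                        max_evals = max_evals, seed = seed)
  structure(
    list(spec = par_to_spec(res$par, init, optimize_mix),
         objective_initial = res$value_initial,
         objective_final = res$value,
         n_evaluations = res$n_evaluations,
         seed = seed, optimize_mix = optimize_mix),
    class = "nbi_optimization"
  )
}

#' Default parameter bounds for band optimization
#'
#' @param init Initial [nbi_band_spec()].
#' @param grid Spectral grid the bands must stay inside.
#' @param optimize_mix Include mixing-matrix bounds.
#' @param center_slack Allowed center excursion in nm (default 10).
#' @return List with `lower` and `upper` vectors matching the optimizer's
#'   parameter layout (per band: center, gamma, amplitude; then the mix
#'   matrix row-major if included).
#' @export
band_par_bounds <- function(init, grid = spectral_grid(),
                            optimize_mix = TRUE, center_slack = 10) {
  nb <- length(init$centers)
  lo_c <- pmax(init$centers - center_slack, grid$start_nm)
  hi_c <- pmin(init$centers + center_slack, grid$end_nm)
  lower <- as.vector(rbind(lo_c, rep(1, nb), rep(0, nb)))
  upper <- as.vector(rbind(hi_c, rep(40, nb), rep(2, nb)))
  if (optimize_mix) {
    lower <- c(lower, rep(0, 3 * nb))
    upper <- c(upper, rep(1.5, 3 * nb))
  }
  list(lower = lower, upper = upper)
}

spec_to_par <- function(spec, optimize_mix) {
  p <- as.vector(rbind(spec$centers, spec$gammas, spec$amplitudes))
  if (optimize_mix) p <- c(p, as.vector(t(spec$mix)))
  p
}

par_to_spec <- function(par, init, optimize_mix) {
  nb <- length(init$centers)
  bp <- matrix(par[seq_len(3 * nb)], nrow = 3)
  mix <- if (optimize_mix) {
    matrix(par[3 * nb + seq_len(3 * nb)], nrow = 3, byrow = TRUE)
  } else {
    init$mix
  }
  # bypass constructor validation: intermediate optimizer states may zero
  # out a display channel; the returned optimum is still a valid spec
  structure(
    list(centers = bp[1, ], gammas = pmax(bp[2, ], 1e-6),
         amplitudes = pmax(bp[3, ], 0), mix = pmax(mix, 0)),
    class = "nbi_band_spec"
  )
}

#' @export
print.nbi_optimization <- function(x, ...) {
  cat(sprintf(
    "<nbi_optimization> mean dE00 %.4f -> %.4f (%d evaluations, seed %d)\n",
    x$objective_initial, x$objective_final, x$n_evaluations, x$seed
  ))
  invisible(x)
}

#' Tidiers for band optimizations
#'
#' `tidy()` lists the optimized band parameters; `glance()` the objective
#' before/after and bookkeeping.
#'
#' @param x An `nbi_optimization`.
#' @param ... Unused.
#' @export
tidy.nbi_optimization <- function(x, ...) {
  tibble::tibble(
    band = seq_along(x$spec$centers),
    center_nm = x$spec$centers,
    gamma_nm = x$spec$gammas,
    amplitude = x$spec$amplitudes,
    mix_r = x$spec$mix[1, ],
    mix_g = x$spec$mix[2, ],
    mix_b = x$spec$mix[3, ]
  )
}

#' @rdname tidy.nbi_optimization
#' @export
glance.nbi_optimization <- function(x, ...) {
  tibble::tibble(
    objective_initial = x$objective_initial,
    objective_final = x$objective_final,
    n_evaluations = x$n_evaluations,
    seed = x$seed,
    optimize_mix = x$optimize_mix
  )
}

#' Serialize / restore a band spec as JSON
#'
#' @param spec An `nbi_band_spec`.
#' @param path Output file.
#' @export
write_band_spec <- function(spec, path) {
  obj <- list(
    type = "nbi_band_spec",
    centers = spec$centers, gammas = spec$gammas,
    amplitudes = spec$amplitudes,
    mix = list(shape = dim(spec$mix), data = as.vector(t(spec$mix)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_band_spec
#' @export
read_band_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "nbi_band_spec") {
    rlang::abort(sprintf("%s is not an nbi_band_spec JSON", path))
  }
  nbi_band_spec(
    centers = obj$centers, gammas = obj$gammas, amplitudes = obj$amplitudes,
    mix = matrix(obj$mix$data, nrow = obj$mix$shape[1], byrow = TRUE)
  )
}
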