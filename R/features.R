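#' Polynomial feature expansion of a color
#'
#' The nonlinear correlation between camera colors and colorimeter colors
#' is modelled by regression on monomials of the three color channels.
#' A `feature_expansion` is an ordered list of exponent triples over
#' (X, Y, Z) (or linear R, G, B if the camera side is expanded before the
#' matrix); the default is the full degree-3 family without mixed cubics,
#' 14 terms: 1, X, Y, Z, XY, XZ, YZ, X^2, Y^2, Z^2, XYZ, X^3, Y^3, Z^3.
#' With 24 calibration patches this keeps the regression overdetermined.
#'
#' @param terms Integer matrix, one row per term, columns = exponents of the
#'   three channels. Ignored unless `degree = NULL`.
#' @param degree Convenience constructor: `feature_expansion(degree = 2)`
#'   gives all monomials of total degree <= 2; the default `degree = 3`
#'   gives the 14-term family above.
#' @return An object of class `feature_expansion`.
#' @examples
#' feature_expansion(degree = 2)
#' @export
feature_expansion <- function(degree = 3, terms = NULL) {
  if (is.null(terms)) {
    stopifnot(degree >= 1, degree <= 3)
    terms <- rbind(
      c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)
    )
    if (degree >= 2) {
      terms <- rbind(terms,
        c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
        c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)
      )
    }
    if (degree >= 3) {
      terms <- rbind(terms, c(1, 1, 1), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
    }
  } else {
    terms <- as.matrix(terms)
    if (ncol(terms) != 3 || nrow(terms) < 1) {
      rlang::abort("terms must be an n x 3 exponent matrix with >= 1 row")
    }
    if (any(terms < 0) || any(terms != round(terms))) {
      rlang::abort("exponents must be nonnegative integers")
    }
    n_const <- sum(rowSums(terms) == 0)
    if (n_const != 1) {
      rlang::abort(sprintf(
        "expansion must contain the constant term exactly once (found %d)", n_const
      ))
    }
  }
  structure(list(terms = terms), class = "feature_expansion")
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("<feature_expansion> %d terms, max degree %d\n",
              n_terms(x), max(rowSums(x$terms))))
  invisible(x)
}

n_terms <- function(spec) nrow(spec$terms)

#' @rdname feature_expansion
#' @param xyz n x 3 matrix (or length-3 vector) of channel values.
#' @param spec A `feature_expansion`.
#' @return `expand_features()` returns an n x n_terms matrix, columns in the
#'   spec's declared term order.
#' @export
expand_features <- function(xyz, spec = feature_expansion()) {
  xyz <- rbind3(xyz)
  tm <- spec$terms
  out <- matrix(1, nrow(xyz), nrow(tm))
  for (j in seq_len(nrow(tm))) {
    e <- tm[j, ]
    out[, j] <- xyz[, 1]^e[1] * xyz[, 2]^e[2] * xyz[, 3]^e[3]
  }
  out
}

# Moore-Penrose pseudo-inverse by SVD with a relative singular-value
# cutoff; warns with the effective rank when the system is rank-deficient.
pinv <- function(A, rtol = 1e-10, warn_rank = FALSE) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d)
  if (warn_rank && sum(keep) < min(dim(A))) {
    rlang::warn(sprintf(
      "rank-deficient design: effective rank %d of %d", sum(keep), min(dim(A))
    ))
  }
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
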