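#' Image quality metrics
#'
#' The validation metrics used to score a simulated narrow-band image
#' against a reference: structural similarity (SSIM), peak signal-to-noise
#' ratio (PSNR), and the percent difference of histogram entropy. SSIM and
#' entropy operate on the ITU-R BT.601 luma of the encoded image quantized
#' to 8 bits; PSNR on the 8-bit RGB channels. SSIM uses the standard
#' 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01, K2 = 0.03, Gaussian-
#' weighted moments, reflect padding at borders.
#'
#' @param a,b Images: H x W x 3 encoded-sRGB arrays in \[0, 1\], or H x W
#'   grayscale matrices in \[0, 1\].
#' @name quality-metrics
NULL

# BT.601 luma of an encoded image, 8-bit integer scale 0..255
luma255 <- function(img) {
  if (length(dim(img)) == 3) {
    y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    y <- as.matrix(img)
  }
  round(pmin(pmax(y, 0), 1) * 255)
}

# separable Gaussian filter with reflect padding
gauss_filter <- function(m, sigma = 1.5, size = 11) {
  half <- (size - 1) / 2
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  pad_reflect <- function(x, n) {
    # mirror without repeating the edge sample
    rbind(x[(n + 1):2, , drop = FALSE], x,
          x[(nrow(x) - 1):(nrow(x) - n), , drop = FALSE])
  }
  conv_rows <- function(x) {
    xp <- pad_reflect(x, half)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(size)) {
      out <- out + k[i] * xp[i:(i + nrow(x) - 1), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' @rdname quality-metrics
#' @param sigma,size Gaussian window parameters.
#' @return `img_ssim()`: mean SSIM over the map, in \[-1, 1\].
#' @export
img_ssim <- function(a, b, sigma = 1.5, size = 11) {
  ya <- luma255(a); yb <- luma255(b)
  if (!all(dim(ya) == dim(yb))) {
    rlang::abort(sprintf("image shape mismatch: %s vs %s",
                         paste(dim(ya), collapse = "x"),
                         paste(dim(yb), collapse = "x")))
  }
  L <- 255
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_a <- gauss_filter(ya, sigma, size)
  mu_b <- gauss_filter(yb, sigma, size)
  s_aa <- gauss_filter(ya * ya, sigma, size) - mu_a^2
  s_bb <- gauss_filter(yb * yb, sigma, size) - mu_b^2
  s_ab <- gauss_filter(ya * yb, sigma, size) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + c1) * (2 * s_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2))
  mean(map)
}

#' @rdname quality-metrics
#' @param data_range Peak-to-peak data range (255 for 8-bit).
#' @return `img_psnr()`: dB; `Inf` for identical images.
#' @export
img_psnr <- function(a, b, data_range = 255) {
  qa <- round(pmin(pmax(a, 0), 1) * 255)
  qb <- round(pmin(pmax(b, 0), 1) * 255)
  if (!all(dim(qa) == dim(qb))) rlang::abort("image shape mismatch")
  mse <- mean((qa - qb)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' @rdname quality-metrics
#' @return `img_entropy()`: Shannon entropy in bits of the 256-bin
#'   grayscale histogram (0 to 8).
#' @export
img_entropy <- function(a) {
  y <- luma255(a)
  if (length(y) == 0) rlang::abort("empty image")
  p <- tabulate(y + 1, nbins = 256) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname quality-metrics
#' @return `entropy_diff()`: tibble with `entropy_ref`, `entropy_test` and
#'   `percent` = |H_test - H_ref| / H_ref x 100 (normalized by the
#'   reference image).
#' @export
entropy_diff <- function(a, b) {
  ha <- img_entropy(a)
  hb <- img_entropy(b)
  tibble::tibble(
    entropy_ref = ha, entropy_test = hb,
    percent = abs(hb - ha) / ha * 100
  )
}

#' Patchwise CIEDE2000 summary
#'
#' @param predicted,target n x 3 Lab matrices on one white point.
#' @return Tibble of per-patch `de00` plus `mean` / `max` attributes; see
#'   also the one-row summary in the returned attributes.
#' @export
patchwise_delta_e <- function(predicted, target) {
  predicted <- rbind3(predicted); target <- rbind3(target)
  if (nrow(predicted) != nrow(target)) {
    rlang::abort("predicted and target must have equal patch counts")
  }
  de <- ciede2000(predicted, target)
  out <- tibble::tibble(patch = seq_along(de), de00 = de)
  attr(out, "mean") <- mean(de)
  attr(out, "max") <- max(de)
  out
}

#' Full quality report between a test and a reference image
#'
#' Bundles SSIM, PSNR and entropy difference (and, when per-patch Lab
#' colors are supplied, the CIEDE2000 summary) into one object; `tidy()`
#' flattens it to a metric/value tibble and [write_quality_report()] saves
#' it as JSON.
#'
#' @param test,reference Encoded-sRGB image arrays of equal shape.
#' @param predicted_lab,target_lab Optional n x 3 per-patch Lab colors.
#' @param n Number of image pairs the report summarizes (recorded so a
#'   single-exemplar report is distinguishable from a mean over a set).
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(test, reference, predicted_lab = NULL,
                           target_lab = NULL, n = 1L) {
  ed <- entropy_diff(reference, test)
  rep <- list(
    n = n,
    ssim = img_ssim(test, reference),
    psnr_db = img_psnr(test, reference),
    entropy_ref = ed$entropy_ref,
    entropy_test = ed$entropy_test,
    entropy_diff_percent = ed$percent
  )
  if (!is.null(predicted_lab) && !is.null(target_lab)) {
    pd <- patchwise_delta_e(predicted_lab, target_lab)
    rep$deltaE00_mean <- attr(pd, "mean")
    rep$deltaE00_max <- attr(pd, "max")
    rep$deltaE00_per_patch <- pd$de00
  }
  structure(rep, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  n images          %d\n", x$n))
  cat(sprintf("  SSIM              %.4f\n", x$ssim))
  cat(sprintf("  PSNR              %s dB\n",
              if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.4f", x$psnr_db)))
  cat(sprintf("  entropy ref/test  %.4f / %.4f bits\n",
              x$entropy_ref, x$entropy_test))
  cat(sprintf("  entropy diff      %.4f %%\n", x$entropy_diff_percent))
  if (!is.null(x$deltaE00_mean)) {
    cat(sprintf("  dE00 mean/max     %.4f / %.4f\n",
                x$deltaE00_mean, x$deltaE00_max))
  }
  invisible(x)
}

#' @rdname quality_report
#' @param x A `quality_report`.
#' @param ... Unused.
#' @export
tidy.quality_report <- function(x, ...) {
  tibble::tibble(
    metric = c("ssim", "psnr_db", "entropy_ref_bits", "entropy_test_bits",
               "entropy_diff_percent",
               if (!is.null(x$deltaE00_mean)) c("deltaE00_mean", "deltaE00_max")),
    value = c(x$ssim, x$psnr_db, x$entropy_ref, x$entropy_test,
              x$entropy_diff_percent,
              if (!is.null(x$deltaE00_mean)) c(x$deltaE00_mean, x$deltaE00_max))
  )
}

#' @rdname quality_report
#' @param report A `quality_report`.
#' @param path Output JSON file.
#' @export
write_quality_report <- function(report, path) {
  obj <- unclass(report)
  obj$psnr_db <- if (is.infinite(obj$psnr_db)) "infinite" else obj$psnr_db
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
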