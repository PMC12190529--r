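# Independent oracles, coded separately from the package implementations.

# -- CIEDE2000, scalar, stepwise -------------------------------------------
# Written from the published formula step list, deliberately with explicit
# branching (no vectorized tricks) so it is an independent code path.
ciede2000_oracle <- function(lab1, lab2) {
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]

  C1ab <- sqrt(a1 * a1 + b1 * b1)
  C2ab <- sqrt(a2 * a2 + b2 * b2)
  Cab <- (C1ab + C2ab) / 2
  G <- 0.5 * (1 - sqrt(Cab^7 / (Cab^7 + 25^7)))
  ap1 <- (1 + G) * a1
  ap2 <- (1 + G) * a2
  Cp1 <- sqrt(ap1 * ap1 + b1 * b1)
  Cp2 <- sqrt(ap2 * ap2 + b2 * b2)

  hp <- function(ap, b) {
    if (ap == 0 && b == 0) return(0)
    h <- atan2(b, ap) * 180 / pi
    if (h < 0) h <- h + 360
    h
  }
  hp1 <- hp(ap1, b1)
  hp2 <- hp(ap2, b2)

  dLp <- L2 - L1
  dCp <- Cp2 - Cp1
  if (Cp1 * Cp2 == 0) {
    dhp <- 0
  } else if (abs(hp2 - hp1) <= 180) {
    dhp <- hp2 - hp1
  } else if (hp2 - hp1 > 180) {
    dhp <- hp2 - hp1 - 360
  } else {
    dhp <- hp2 - hp1 + 360
  }
  dHp <- 2 * sqrt(Cp1 * Cp2) * sin((dhp / 2) * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (Cp1 + Cp2) / 2
  if (Cp1 * Cp2 == 0) {
    hbp <- hp1 + hp2
  } else if (abs(hp1 - hp2) <= 180) {
    hbp <- (hp1 + hp2) / 2
  } else if (hp1 + hp2 < 360) {
    hbp <- (hp1 + hp2 + 360) / 2
  } else {
    hbp <- (hp1 + hp2 - 360) / 2
  }

  Tv <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos((2 * hbp) * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + (0.015 * (Lbp - 50)^2) / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tv
  RT <- -sin((2 * dtheta) * pi / 180) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

# -- fine-grid quadrature for spectrum -> XYZ ------------------------------
# integrates analytic reflectance/illuminant functions against the CMFs on
# a 0.1 nm grid with plain Riemann summation, independent of
# spectrum_to_xyz's matrix algebra.
quadrature_xyz <- function(reflect_fn, illum_fn = function(x) rep(1, length(x)),
                           start = 380, end = 780, step = 0.1) {
  fine <- spectral_grid(start, end, step)
  wl <- wavelengths(fine)
  cmf <- cie1931_cmf(fine)
  r <- reflect_fn(wl)
  ii <- illum_fn(wl)
  k <- 100 / sum(ii * cmf$ybar)
  c(X = k * sum(r * ii * cmf$xbar),
    Y = k * sum(r * ii * cmf$ybar),
    Z = k * sum(r * ii * cmf$zbar))
}

# -- naive SSIM -------------------------------------------------------------
# direct per-pixel window loop on BT.601 luma, same parameters and border
# convention (mirror without edge repetition) as the package contract, but
# computed with explicit loops over window offsets.
ssim_naive <- function(a, b, sigma = 1.5, size = 11) {
  to_luma <- function(img) {
    if (length(dim(img)) == 3) {
      y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      y <- as.matrix(img)
    }
    round(pmin(pmax(y, 0), 1) * 255)
  }
  ya <- to_luma(a); yb <- to_luma(b)
  h <- nrow(ya); w <- ncol(ya)
  half <- (size - 1) / 2
  k1 <- exp(-0.5 * ((-half:half) / sigma)^2)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  mirror <- function(i, n) {
    # reflect without repeating the edge: ..., 3, 2, 1, 2, 3, ...
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  total <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- mirror(i + (-half:half), h)
      cj <- mirror(j + (-half:half), w)
      wa <- ya[ri, cj]; wb <- yb[ri, cj]
      mua <- sum(K * wa); mub <- sum(K * wb)
      vaa <- sum(K * wa * wa) - mua^2
      vbb <- sum(K * wb * wb) - mub^2
      vab <- sum(K * wa * wb) - mua * mub
      total <- total + ((2 * mua * mub + c1) * (2 * vab + c2)) /
        ((mua^2 + mub^2 + c1) * (vaa + vbb + c2))
    }
  }
  total / (h * w)
}
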