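#' Colour-space conversions and the CIEDE2000 colour difference
#'
#' The white-balance algorithm does its statistics in YUV, where Y carries
#' brightness and the zero-centred U/V planes carry blue- and red-difference
#' chroma; evaluation happens in CIELAB through the CIEDE2000 metric.
#' These conversions are shared by every other layer of the package.
#'
#' @name color_core
NULL

yuv_weights <- function(standard = c("bt601", "bt709")) {
  standard <- match.arg(standard)
  if (standard == "bt601") c(r = 0.299, g = 0.587, b = 0.114)
  else c(r = 0.2126, g = 0.7152, b = 0.0722)
}

# Analog-convention chroma scales shared by both luma variants:
# U = 0.492 (B - Y), V = 0.877 (R - Y).
U_SCALE <- 0.492
V_SCALE <- 0.877

#' Convert an RGB image to YUV
#'
#' Uses the analog (BT.601 by default) convention: `Y = 0.299 R + 0.587 G +
#' 0.114 B`, `U = 0.492 (B - Y)`, `V = 0.877 (R - Y)`.  Achromatic pixels
#' (`R = G = B`) map to `U = V = 0` exactly, so a colour cast shows up as a
#' displaced chroma cloud.
#'
#' @param img an [rgb_image()] (values on their encoded scale; the chroma
#'   statistics of the estimator deliberately operate on encoded values).
#' @param standard luma weights, `"bt601"` (default) or `"bt709"`.
#' @return a `yuv_image`: list of `Y`, `U`, `V` matrices plus bookkeeping.
#' @seealso [yuv_to_rgb()]
#' @export
#' @examples
#' y <- rgb_to_yuv(rgb_image(array(128, c(2, 2, 3))))
#' range(y$U); range(y$V)  # 0 0 for gray
rgb_to_yuv <- function(img, standard = c("bt601", "bt709")) {
  img <- as_rgb_image(img)
  w <- yuv_weights(standard)
  R <- channel(img, 1); G <- channel(img, 2); B <- channel(img, 3)
  Y <- w["r"] * R + w["g"] * G + w["b"] * B
  # chroma from channel differences: B - Y = wr (B - R) + wg (B - G) and
  # R - Y = wg (R - G) + wb (R - B), so achromatic pixels give exactly 0
  structure(list(Y = unname(Y),
                 U = unname(U_SCALE * (w["r"] * (B - R) + w["g"] * (B - G))),
                 V = unname(V_SCALE * (w["g"] * (R - G) + w["b"] * (R - B))),
                 white_level = white_level_of(img),
                 standard = match.arg(standard)),
            class = "yuv_image")
}

#' @export
print.yuv_image <- function(x, ...) {
  cat(sprintf("<yuv_image %d x %d (%s)>\n", nrow(x$Y), ncol(x$Y), x$standard))
  invisible(x)
}

#' Convert a YUV image back to RGB
#'
#' Exact algebraic inverse of [rgb_to_yuv()] before clipping; values that
#' land outside `[0, white_level]` are clipped and their fraction recorded
#' in the `clipped_fraction` attribute.
#'
#' @param yuv a `yuv_image` as returned by [rgb_to_yuv()].
#' @return an [rgb_image()].
#' @export
yuv_to_rgb <- function(yuv) {
  stopifnot(inherits(yuv, "yuv_image"))
  w <- yuv_weights(yuv$standard)
  R <- yuv$Y + yuv$V / V_SCALE
  B <- yuv$Y + yuv$U / U_SCALE
  G <- (yuv$Y - w["r"] * R - w["b"] * B) / w["g"]
  px <- array(c(R, G, B), dim = c(dim(yuv$Y), 3L))
  wl <- yuv$white_level
  clipped <- mean(px < -1e-9 | px > wl + 1e-9)
  out <- rgb_image(px, white_level = wl, clip = TRUE)
  attr(out, "clipped_fraction") <- clipped
  out
}

srgb_encode_to_linear <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

# D65 reference white in XYZ (Y = 1).
D65_XYZ <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

# Column-vector matrices of the sRGB <-> XYZ transform (IEC 61966-2-1, D65).
RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                    0.2126729, 0.7151522, 0.0721750,
                    0.0193339, 0.1191920, 0.9503041),
                  nrow = 3, byrow = TRUE)
XYZ2RGB <- matrix(c( 3.2404542, -1.5371385, -0.4985314,
                    -0.9692660,  1.8760108,  0.0415560,
                     0.0556434, -0.2040259,  1.0572252),
                  nrow = 3, byrow = TRUE)

#' Convert an RGB image to a CIELAB field
#'
#' Standard sRGB chain: decode the transfer curve (skipped when the image is
#' tagged `"sRGB-linearized"`), apply the sRGB primaries matrix to XYZ, then
#' CIELAB against a D65 reference white.  This is the operand space of
#' [ciede2000()].
#'
#' @param img an [rgb_image()].
#' @param white_point reference white as an XYZ triple with `Y = 1`;
#'   defaults to D65.
#' @return an `H x W x 3` array with planes L, a, b.
#' @export
#' @examples
#' lab <- rgb_to_lab(rgb_image(array(128, c(1, 1, 3))))
#' lab[1, 1, 1]  # L* of mid-gray, ~53.59
rgb_to_lab <- function(img, white_point = D65_XYZ) {
  img <- as_rgb_image(img)
  wl <- white_level_of(img)
  rgb01 <- matrix(unclass(img), ncol = 3L) / wl
  if (attr(img, "encoding") != "sRGB-linearized")
    rgb01 <- srgb_encode_to_linear(rgb01)
  xyz <- rgb01 %*% t(RGB2XYZ)
  xr <- xyz[, 1] / white_point[1]
  yr <- xyz[, 2] / white_point[2]
  zr <- xyz[, 3] / white_point[3]
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xr); fy <- f(yr); fz <- f(zr)
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(lab, dim = c(dim(img)[1:2], 3L))
}

#' CIEDE2000 colour difference
#'
#' Full CIEDE2000 formula on CIELAB pairs, including the a' chroma
#' rescaling, the lightness/chroma/hue weighting functions SL/SC/SH and the
#' blue-region hue-rotation term RT.  When either colour has zero chroma the
#' hue difference is defined as zero, so neutral axis comparisons never
#' divide by zero.  Vectorized over rows.
#'
#' @param lab1,lab2 length-3 vectors `c(L, a, b)` or `n x 3` matrices.
#' @param kL,kC,kH strictly positive parametric weighting factors
#'   (default 1, the reference conditions).
#' @return numeric vector of nonnegative colour differences; values for
#'   in-gamut colour pairs lie in `[0, 100]` (smaller = more similar).
#' @references Sharma, G., Wu, W., Dalal, E. N. (2005). The CIEDE2000
#'   color-difference formula: implementation notes, supplementary test
#'   data, and mathematical observations. Color Res. Appl. 30(1), 21-30.
#' @export
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # 2.0425
ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  if (any(c(kL, kC, kH) <= 0)) stop("kL, kC, kH must be strictly positive")
  if (is.null(dim(lab1))) lab1 <- matrix(lab1, ncol = 3L)
  if (is.null(dim(lab2))) lab2 <- matrix(lab2, ncol = 3L)
  if (!all(is.finite(lab1)) || !all(is.finite(lab2)))
    stop("Lab inputs must be finite")
  n <- max(nrow(lab1), nrow(lab2))
  if (nrow(lab1) == 1L && n > 1L) lab1 <- lab1[rep(1L, n), , drop = FALSE]
  if (nrow(lab2) == 1L && n > 1L) lab2 <- lab2[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(lab1) == nrow(lab2))

  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hdeg <- function(b, ap) {
    h <- atan2(b, ap) * 180 / pi
    h <- ifelse(h < 0, h + 360, h)
    ifelse(b == 0 & ap == 0, 0, h)
  }
  h1p <- hdeg(b1, a1p)
  h2p <- hdeg(b2, a2p)

  dLp <- L2 - L1
  dCp <- C2p - C1p

  zero_chroma <- C1p * C2p == 0
  dh <- h2p - h1p
  dhp <- ifelse(zero_chroma, 0,
         ifelse(abs(dh) <= 180, dh,
         ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)

  Lbar <- (L1 + L2) / 2
  Cbarp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbarp <- ifelse(zero_chroma, hsum,
           ifelse(abs(h1p - h2p) <= 180, hsum / 2,
           ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos((hbarp - 30) * pi / 180) +
            0.24 * cos(2 * hbarp * pi / 180) +
            0.32 * cos((3 * hbarp + 6) * pi / 180) -
            0.20 * cos((4 * hbarp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbarp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbarp^7 / (Cbarp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbar - 50)^2 / sqrt(20 + (Lbar - 50)^2)
  SC <- 1 + 0.045 * Cbarp
  SH <- 1 + 0.015 * Cbarp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC

  tL <- dLp / (kL * SL)
  tC <- dCp / (kC * SC)
  tH <- dHp / (kH * SH)
  sqrt(pmax(tL^2 + tC^2 + tH^2 + RT * tC * tH, 0))
}
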