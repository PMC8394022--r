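# Independent scalar CIEDE2000, coded step by step from the published
# implementation notes (Sharma, Wu & Dalal 2005), kept deliberately
# separate from the vectorized package implementation.
ciede2000_scalar <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]
  rad <- pi / 180

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
    h <- atan2(b, ap) / rad
    if (h < 0) h + 360 else h
  }
  hp1 <- hp(ap1, b1)
  hp2 <- hp(ap2, b2)

  dLp <- L2 - L1
  dCp <- Cp2 - Cp1
  if (Cp1 * Cp2 == 0) {
    dhp <- 0
  } else {
    dhp <- hp2 - hp1
    if (dhp > 180) dhp <- dhp - 360
    if (dhp < -180) dhp <- dhp + 360
  }
  dHp <- 2 * sqrt(Cp1 * Cp2) * sin(dhp * rad / 2)

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

  Tv <- 1 - 0.17 * cos((hbp - 30) * rad) + 0.24 * cos(2 * hbp * rad) +
    0.32 * cos((3 * hbp + 6) * rad) - 0.20 * cos((4 * hbp - 63) * rad)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tv
  RT <- -sin(2 * dtheta * rad) * RC
  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

# The 34 published CIEDE2000 worked test pairs with their reference
# differences (implementation-notes supplementary data, 4 decimals).
sharma_pairs <- local({
  m <- matrix(c(
    50, 2.6772, -79.7751,   50, 0, -82.7485,       2.0425,
    50, 3.1571, -77.2803,   50, 0, -82.7485,       2.8615,
    50, 2.8361, -74.0200,   50, 0, -82.7485,       3.4412,
    50, -1.3802, -84.2814,  50, 0, -82.7485,       1.0000,
    50, -1.1848, -84.8006,  50, 0, -82.7485,       1.0000,
    50, -0.9009, -85.5211,  50, 0, -82.7485,       1.0000,
    50, 0, 0,               50, -1, 2,             2.3669,
    50, -1, 2,              50, 0, 0,              2.3669,
    50, 2.49, -0.001,       50, -2.49, 0.0009,     7.1792,
    50, 2.49, -0.001,       50, -2.49, 0.0010,     7.1792,
    50, 2.49, -0.001,       50, -2.49, 0.0011,     7.2195,
    50, 2.49, -0.001,       50, -2.49, 0.0012,     7.2195,
    50, -0.001, 2.49,       50, 0.0009, -2.49,     4.8045,
    50, -0.001, 2.49,       50, 0.0010, -2.49,     4.8045,
    50, -0.001, 2.49,       50, 0.0011, -2.49,     4.7461,
    50, 2.5, 0,             50, 0, -2.5,           4.3065,
    50, 2.5, 0,             73, 25, -18,          27.1492,
    50, 2.5, 0,             61, -5, 29,           22.8977,
    50, 2.5, 0,             56, -27, -3,          31.9030,
    50, 2.5, 0,             58, 24, 15,           19.4535,
    50, 2.5, 0,             50, 3.1736, 0.5854,    1.0000,
    50, 2.5, 0,             50, 3.2972, 0,         1.0000,
    50, 2.5, 0,             50, 1.8634, 0.5757,    1.0000,
    50, 2.5, 0,             50, 3.2592, 0.3350,    1.0000,
    60.2574, -34.0099, 36.2677, 60.4626, -34.1751, 39.4387, 1.2644,
    63.0109, -31.0961, -5.8663, 62.8187, -29.7946, -4.0864, 1.2630,
    61.2901, 3.7196, -5.3901,   61.4292, 2.2480, -4.9620,   1.8731,
    35.0831, -44.1164, 3.7933,  35.0232, -40.0716, 1.5901,  1.8645,
    22.7233, 20.0904, -46.6940, 23.0331, 14.9730, -42.5619, 2.0373,
    36.4612, 47.8580, 18.3852,  36.2715, 50.5065, 21.2231,  1.4146,
    90.8027, -2.0831, 1.4410,   91.1528, -1.6435, 0.0447,   1.4441,
    90.9257, -0.5406, -0.9208,  88.6381, -0.8985, -0.7239,  1.5381,
    6.7747, -0.2908, -2.4247,   5.8714, -0.0985, -2.2286,   0.6377,
    2.0776, 0.0795, -1.1350,    0.9033, -0.0636, -0.5514,   0.9082),
    ncol = 7, byrow = TRUE)
  list(lab1 = m[, 1:3], lab2 = m[, 4:6], de = m[, 7])
})

# CIELAB values for a handful of sRGB colours under D65, frozen from an
# independent reference implementation of the sRGB -> XYZ -> Lab chain.
lab_anchors <- data.frame(
  r = c(255, 0, 0, 200, 30, 250),
  g = c(0, 255, 0, 160, 60, 250),
  b = c(0, 0, 255, 120, 90, 5),
  L = c(53.240588, 87.735099, 32.295673, 68.590986, 24.467045, 95.458729),
  a = c(80.092308, -86.183030, 79.185591, 9.393949, -0.568146, -21.196443),
  bb = c(67.202751, 83.179703, -107.857300, 26.470161, -21.295996, 92.720259))

# Random in-gamut test image on the 0-255 scale.
random_image <- function(h, w, seed, lo = 0, hi = 255) {
  with_seed_test(seed, rgb_image(array(runif(h * w * 3, lo, hi),
                                       dim = c(h, w, 3))))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force re-implementation of the weights-threshold search objective:
# enumerate the outward grid, keep in-band values with enough candidates,
# score each by the mean luminance of its brightest five pixels, prefer
# the highest score and break ties towards the larger candidate set.
brute_force_wr <- function(yuv, cfg, exclude = NULL) {
  grid0 <- round(cfg$wr_init + cfg$wr_step *
                   unlist(lapply(0:(ceiling((cfg$wr_max - cfg$wr_min) /
                                              cfg$wr_step) + 1L),
                                 function(k) if (k == 0) 0 else c(k, -k))),
                 10)
  grid <- grid0[grid0 >= cfg$wr_min - 1e-9 & grid0 <= cfg$wr_max + 1e-9]
  stats <- compute_uv_stats(yuv)
  best <- NULL
  best_score <- -Inf
  best_count <- -1L
  for (wr in grid) {
    m <- select_candidates(yuv, stats, wr, exclude = exclude)
    n <- attr(m, "count")
    f <- attr(m, "fraction")
    if (n < cfg$min_candidates) next
    if (f < cfg$target_candidate_fraction_band[1] ||
        f > cfg$target_candidate_fraction_band[2]) next
    ys <- sort(yuv$Y[m], decreasing = TRUE)
    sc <- mean(ys[seq_len(min(5L, length(ys)))])
    if (sc > best_score || (sc == best_score && n > best_count)) {
      best <- wr; best_score <- sc; best_count <- n
    }
  }
  best
}

# Tiny suite shared by slower tests (built once per test run).
small_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_suite(scene_spec())
    cache
  }
})
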