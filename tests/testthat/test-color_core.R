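test_that("rgb_to_yuv reproduces the analog-convention transform", {
  yuv_of <- function(rgb) {
    y <- rgb_to_yuv(rgb_image(array(rgb, c(1, 1, 3))))
    c(y$Y, y$U, y$V)
  }
  expect_equal(yuv_of(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(yuv_of(c(128, 128, 128)), c(128, 0, 0))
  # direct evaluation of the 3x3 transform on pure red
  expect_equal(yuv_of(c(255, 0, 0)),
               c(76.245, -37.51254, 156.768135), tolerance = 1e-9)
})

test_that("achromatic pixels map to exactly zero chroma", {
  for (g in c(0, 1, 17, 128.5, 254, 255)) {
    y <- rgb_to_yuv(rgb_image(array(g, c(2, 2, 3))))
    expect_identical(max(abs(y$U)), 0)
    expect_identical(max(abs(y$V)), 0)
  }
})

test_that("yuv round-trip is the identity on in-gamut images", {
  for (seed in 1:5) {
    img <- random_image(8, 9, seed)
    for (std in c("bt601", "bt709")) {
      back <- yuv_to_rgb(rgb_to_yuv(img, std))
      expect_lt(max(abs(unclass(back) - unclass(img))), 1e-9)
      expect_equal(attr(back, "clipped_fraction"), 0)
    }
  }
  # inverse of the derived forward example
  y <- rgb_to_yuv(rgb_image(array(c(255, 0, 0), c(1, 1, 3))))
  expect_equal(as.numeric(unclass(yuv_to_rgb(y))), c(255, 0, 0),
               tolerance = 1e-6)
})

test_that("rgb_to_yuv rejects non-finite pixels", {
  px <- array(100, c(2, 2, 3))
  px[1, 1, 1] <- NaN
  expect_error(rgb_image(px), "non-finite")
})

test_that("rgb_to_lab follows the standard sRGB chain under D65", {
  lab_of <- function(rgb) as.numeric(
    rgb_to_lab(rgb_image(array(rgb, c(1, 1, 3)))))
  expect_equal(lab_of(c(255, 255, 255)), c(100, 0, 0), tolerance = 0.01)
  expect_equal(lab_of(c(0, 0, 0))[1], 0, tolerance = 1e-8)
  mid <- lab_of(c(128, 128, 128))
  expect_equal(mid[1], 53.585, tolerance = 1e-3)
  expect_lt(max(abs(mid[2:3])), 0.01)
  # frozen anchors were computed with the slightly different (older ITU)
  # matrix constants, hence the loose absolute tolerance
  for (i in seq_len(nrow(lab_anchors))) {
    got <- lab_of(c(lab_anchors$r[i], lab_anchors$g[i], lab_anchors$b[i]))
    expect_lt(max(abs(got - as.numeric(lab_anchors[i, c("L", "a", "bb")]))),
              0.005)
  }
})

test_that("rgb_to_lab roughly agrees with grDevices::convertColor", {
  # convertColor uses slightly different adaptation constants, so this is
  # a coarse cross-check, not the precision oracle.
  rgbm <- with_seed_test(11, matrix(runif(150), ncol = 3))
  ours <- matrix(rgb_to_lab(rgb_image(array(rgbm * 255, c(50, 1, 3)))),
                 ncol = 3)
  ref <- grDevices::convertColor(rgbm, from = "sRGB", to = "Lab")
  expect_lt(max(abs(ours - ref)), 0.5)
})

test_that("ciede2000 matches the published worked pairs to 1e-4", {
  got <- ciede2000(sharma_pairs$lab1, sharma_pairs$lab2)
  expect_equal(round(got, 4), sharma_pairs$de, tolerance = 1e-8)
  # and is symmetric on the same pairs
  expect_equal(ciede2000(sharma_pairs$lab2, sharma_pairs$lab1), got)
})

test_that("ciede2000 agrees with an independent scalar implementation", {
  labs <- with_seed_test(7, cbind(runif(1000, 0, 100),
                                  runif(1000, -100, 100),
                                  runif(1000, -100, 100)))
  labs2 <- with_seed_test(8, cbind(runif(1000, 0, 100),
                                   runif(1000, -100, 100),
                                   runif(1000, -100, 100)))
  got <- ciede2000(labs, labs2)
  ref <- vapply(seq_len(nrow(labs)),
                function(i) ciede2000_scalar(labs[i, ], labs2[i, ]), 0)
  expect_lt(max(abs(got - ref)), 1e-4)
  expect_true(all(got >= 0))
})

test_that("ciede2000 metric identities hold", {
  x <- c(41.3, 12.7, -30.2)
  expect_identical(ciede2000(x, x), 0)
  a <- c(55, 10, 10); b <- c(60, -4, 22)
  expect_identical(ciede2000(a, b), ciede2000(b, a))
  # neutral-axis pairs (C' = 0) must not produce NaN
  expect_false(is.nan(ciede2000(c(50, 0, 0), c(70, 0, 0))))
  expect_equal(ciede2000(c(50, 0, 0), c(50, 0, 0)), 0)
  # in-gamut image colours stay within the nominal 0-100 span
  img <- random_image(10, 10, 3)
  labs <- matrix(rgb_to_lab(img), ncol = 3)
  de <- ciede2000(labs, labs[rev(seq_len(nrow(labs))), ])
  expect_true(all(de >= 0 & de <= 100))
  expect_error(ciede2000(a, b, kL = 0), "positive")
})
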