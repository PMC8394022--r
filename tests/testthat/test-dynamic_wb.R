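# A yuv_image built directly from chroma planes, for hand-checked cases.
yuv_from_planes <- function(Y, U, V) {
  structure(list(Y = Y, U = U, V = V, white_level = 255,
                 standard = "bt601"), class = "yuv_image")
}

test_that("compute_uv_stats implements the average absolute deviation", {
  # uniform chroma: no deviation
  img <- rgb_image(array(rep(c(120, 80, 60), each = 12), c(3, 4, 3)))
  s <- compute_uv_stats(rgb_to_yuv(img))
  expect_equal(s$Du, 0)
  expect_equal(s$Dv, 0)
  # two pixels, U = {+10, -10}
  y <- yuv_from_planes(matrix(0, 1, 2), matrix(c(10, -10), 1),
                       matrix(0, 1, 2))
  s <- compute_uv_stats(y)
  expect_equal(s$Mu, 0)
  expect_equal(s$Du, 10)
  # single pixel
  y1 <- yuv_from_planes(matrix(5), matrix(3.5), matrix(-2))
  s1 <- compute_uv_stats(y1)
  expect_equal(s1$Du, 0)
  expect_equal(s1$Dv, 0)
  expect_equal(s1$Mu, 3.5)
  expect_equal(s1$Mv, -2)
  expect_equal(s1$N, 1L)
})

test_that("the three-pixel worked example selects exactly one candidate", {
  y <- yuv_from_planes(matrix(0, 1, 3),
                       matrix(c(0, 6, 20), 1),
                       matrix(c(0, -6, -20), 1))
  s <- compute_uv_stats(y)
  expect_equal(s$Mu, 26 / 3, tolerance = 1e-12)
  expect_equal(s$Du, 68 / 9, tolerance = 1e-12)
  expect_equal(s$Mv, -26 / 3, tolerance = 1e-12)
  expect_equal(s$Dv, 68 / 9, tolerance = 1e-12)
  m <- select_candidates(y, s, 1)
  expect_identical(as.vector(m), c(FALSE, FALSE, TRUE))
  expect_identical(attr(m, "count"), 1L)
})

test_that("degenerate chroma yields an empty flagged mask", {
  img <- rgb_image(array(150, c(4, 4, 3)))
  yuv <- rgb_to_yuv(img)
  m <- select_candidates(yuv, compute_uv_stats(yuv), 1.5)
  expect_identical(attr(m, "count"), 0L)
  expect_true(attr(m, "degenerate"))
})

test_that("candidate sets are nested in the weights threshold", {
  wrs <- seq(0.2, 2, by = 0.2)
  for (seed in 1:10) {
    img <- random_image(12, 14, seed)
    yuv <- rgb_to_yuv(img)
    s <- compute_uv_stats(yuv)
    masks <- lapply(wrs, function(wr) select_candidates(yuv, s, wr))
    for (i in seq_along(wrs)[-1])
      expect_true(all(masks[[i]][masks[[i - 1]]])) # subset, exactly
  }
})

test_that("search_wr equals exhaustive evaluation of the grid", {
  cfg <- wb_config()
  suite <- small_suite()
  for (ct in names(suite$images)) {
    yuv <- rgb_to_yuv(suite$images[[ct]])
    got <- search_wr(yuv, cfg, img = suite$images[[ct]])
    want <- brute_force_wr(yuv, cfg)
    if (is.null(want)) {
      expect_true(got$status != "band")
    } else {
      expect_identical(got$status, "band")
      expect_identical(got$wr, want)
    }
  }
})

test_that("search_wr reports insufficiency when no threshold has enough", {
  # 16 pixels can never reach a floor of 20 candidates
  img <- random_image(4, 4, 99)
  yuv <- rgb_to_yuv(img)
  sr <- search_wr(yuv, wb_config(min_candidates = 20))
  expect_identical(sr$status, "insufficient")
  expect_warning(res <- white_balance(img, wb_config(min_candidates = 20)),
                 "insufficient")
  expect_identical(as.numeric(res$diagnostics$gains), c(1, 1, 1))
  expect_identical(unclass(res$image), unclass(img))
})

test_that("raising the candidate floor never lowers the chosen threshold", {
  for (seed in c(3, 4, 5)) {
    suite <- build_suite(scene_spec(layout_seed = seed))
    for (ct in c("4000", "5600")) {
      yuv <- rgb_to_yuv(suite$images[[ct]])
      wr1 <- search_wr(yuv, wb_config(min_candidates = 20))$wr
      wr2 <- search_wr(yuv, wb_config(min_candidates = 40))$wr
      expect_gte(wr2, wr1)
    }
  }
})

test_that("filter_by_percentage keeps the brightest fraction", {
  img <- random_image(10, 1, 21)
  yuv <- rgb_to_yuv(img)
  full <- select_candidates(yuv, compute_uv_stats(yuv), 1e6) # everything
  expect_identical(attr(full, "count"), 10L)
  # wp = 1 is the identity
  expect_identical(which(filter_by_percentage(yuv, full, 1)), which(full))
  # top-3 by brute-force sort
  top3 <- filter_by_percentage(yuv, full, 0.3)
  expect_setequal(which(top3), order(-yuv$Y)[1:3])
  # nesting in wp
  for (pair in list(c(0.1, 0.5), c(0.2, 0.7), c(0.5, 1))) {
    a <- filter_by_percentage(yuv, full, pair[1])
    b <- filter_by_percentage(yuv, full, pair[2])
    expect_true(all(b[a]))
  }
  expect_error(filter_by_percentage(yuv, select_candidates(
    yuv, compute_uv_stats(rgb_to_yuv(rgb_image(array(9, c(10, 1, 3))))),
    0.1), 0.5), "empty")
})

test_that("compute_gains applies the luminance-reference rule", {
  # neutral reference pixels: unit gains
  img <- rgb_image(array(200, c(2, 2, 3)))
  m <- structure(matrix(TRUE, 2, 2), count = 4L,
                 class = c("candidate_mask", "matrix"))
  expect_equal(as.numeric(compute_gains(img, m, yref = "max_luminance")),
               c(1, 1, 1))
  # mask mean (200,160,120) with a (200,200,200) pixel anchoring Yref = 200
  px <- array(rep(c(200, 160, 120), each = 4), c(2, 2, 3))
  px[1, 1, ] <- 200
  img2 <- rgb_image(px)
  m2 <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)
  g <- compute_gains(img2, m2, yref = "max_luminance")
  expect_equal(as.numeric(g), c(1, 1.25, 200 / 120), tolerance = 1e-12)
  # a black channel in the reference is an error
  px0 <- px; px0[, , 3] <- 0
  expect_error(compute_gains(rgb_image(px0), m2), "black reference")
})

test_that("apply_gains multiplies, rounds and clips", {
  img <- rgb_image(array(100, c(1, 1, 3)))
  out <- apply_gains(img, c(1, 1.25, 1.6667))
  expect_equal(as.numeric(unclass(out)), c(100, 125, 167))
  clipped <- apply_gains(rgb_image(array(200, c(1, 1, 3))), c(2, 1, 1))
  expect_equal(as.numeric(unclass(clipped)), c(255, 200, 200))
  same <- apply_gains(img, c(1, 1, 1))
  expect_identical(unclass(same), unclass(img))
})

test_that("corrected reference pixels become achromatic", {
  suite <- small_suite()
  for (ct in c("4000", "4800", "5600")) {
    res <- white_balance(suite$images[[ct]])
    m <- res$diagnostics$mask
    g <- res$diagnostics$gains
    px <- unclass(suite$images[[ct]])
    means <- vapply(1:3, function(i) mean(px[, , i][m]), 0) * as.numeric(g)
    yuv <- rgb_to_yuv(rgb_image(array(rep(means, each = 1), c(1, 1, 3))))
    expect_lt(abs(yuv$U[1]), 0.5)
    expect_lt(abs(yuv$V[1]), 0.5)
  }
})

test_that("white balance is deterministic and neutral-safe", {
  suite <- small_suite()
  img <- suite$images[["4800"]]
  r1 <- white_balance(img)
  r2 <- white_balance(img)
  expect_identical(unclass(r1$image), unclass(r2$image))
  expect_identical(r1$diagnostics$gains, r2$diagnostics$gains)
  # a noiseless gray card passes through untouched
  gray <- rgb_image(array(180, c(20, 30, 3)))
  res <- suppressWarnings(white_balance(gray))
  expect_identical(as.numeric(res$diagnostics$gains), c(1, 1, 1))
  expect_lt(mean(abs(unclass(res$image) - unclass(gray))), 1)
})

test_that("a noisy but neutral scene is corrected by less than one level", {
  spec <- scene_spec(noise_sd = 2)
  sc <- render_scene(spec, gain_triple(c(1, 1, 1)))
  res <- white_balance(sc$image)
  shift <- vapply(1:3, function(i)
    mean(unclass(res$image)[, , i] - unclass(sc$image)[, , i]), 0)
  expect_lt(max(abs(shift)), 1)
})

test_that("configuration validation rejects inconsistent ranges", {
  expect_error(wb_config(wr_init = 2))            # above wr_max
  expect_error(wb_config(wp_min = 0.5))           # above wp_init
  expect_error(wb_config(target_candidate_fraction_band = c(0.5, 0.1)))
  expect_error(wb_config(gain_cap = -1))
  expect_silent(wb_config(wr_fixed = 1.5, wp_fixed = 0.1))
})
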