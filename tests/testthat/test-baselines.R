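uniform_img <- function(rgb, h = 4, w = 5)
  rgb_image(array(rep(rgb, each = h * w), c(h, w, 3)))

test_that("white-patch retinex anchors the reference quantile to white", {
  # image already containing white at the reference quantile: unchanged
  px <- array(rep(c(180, 160, 140), each = 25), c(5, 5, 3))
  px[1, 1, ] <- 255
  wp <- white_patch(rgb_image(px), percentile = 100)
  expect_equal(as.numeric(wp$diagnostics$gains), c(1, 1, 1))
  expect_equal(unclass(wp$image), px, ignore_attr = TRUE)
  # uniform image, literal max
  g <- white_patch(uniform_img(c(200, 160, 120)), 100)$diagnostics$gains
  expect_equal(as.numeric(g), c(255 / 200, 255 / 160, 255 / 120))
  # reference pixels are driven to the white level
  out <- white_patch(uniform_img(c(200, 160, 120)), 100)$image
  expect_true(all(unclass(out) == 255))
  expect_error(white_patch(uniform_img(c(10, 10, 0)), 100), "black")
})

test_that("gray-world estimation equalizes channel means", {
  # achromatic image: nothing to do
  g0 <- gray_world_edge(uniform_img(c(140, 140, 140)), norm_p = 1,
                        deriv_order = 0)$diagnostics$gains
  expect_equal(as.numeric(g0), c(1, 1, 1))
  # plain mean estimate on a uniform cast
  g <- gray_world_edge(uniform_img(c(200, 160, 120)), norm_p = 1,
                       deriv_order = 0)$diagnostics$gains
  expect_equal(as.numeric(g), c(0.8, 1, 160 / 120), tolerance = 1e-12)
  # post-correction channel means agree within rounding
  img <- random_image(16, 16, 5, lo = 30, hi = 220)
  out <- gray_world_edge(img, norm_p = 1, deriv_order = 0)$image
  means <- vapply(1:3, function(i) mean(unclass(out)[, , i]), 0)
  expect_lt(max(means) - min(means), 1)
})

test_that("gray-edge runs on gradients and stays deterministic", {
  img <- random_image(20, 20, 9, lo = 10, hi = 240)
  r1 <- gray_world_edge(img)
  r2 <- gray_world_edge(img)
  expect_identical(unclass(r1$image), unclass(r2$image))
  expect_true(all(as.numeric(r1$diagnostics$gains) > 0))
  # a constant image has zero gradients everywhere: estimation must fail
  expect_error(gray_world_edge(uniform_img(c(100, 100, 100)),
                               deriv_order = 1), "zero")
})

test_that("the pinned configuration reproduces the classic method exactly", {
  suite <- small_suite()
  cfg <- wb_config(wr_fixed = 1.5, wp_fixed = 0.1, stats_mode = "block",
                   yref = "max_luminance", gain_cap = Inf,
                   refine_reference = FALSE, exclude_saturated = FALSE)
  for (ct in c("4000", "4800", "6500")) {
    a <- dh_reference(suite$images[[ct]])
    b <- white_balance(suite$images[[ct]], cfg)
    expect_identical(unclass(a$image), unclass(b$image))
    expect_identical(as.numeric(a$diagnostics$gains),
                     as.numeric(b$diagnostics$gains))
  }
})

test_that("the classic method recovers a plain white-patch scene", {
  # white patch + gray background only, the scene family it was built for
  spec <- scene_spec(skin_tones = list(), bright_objects = list(),
                     layout_seed = 14)
  sc <- render_scene(spec, 4800)
  res <- dh_reference(sc$image)
  rec <- as.numeric(res$diagnostics$gains)
  rec <- rec / rec[2]
  inv <- 1 / as.numeric(sc$ground_truth$gains_true)
  inv <- inv / inv[2]
  expect_lt(max(abs(rec / inv - 1)), 0.10)
  # neutral input: unit gains
  neutral <- suppressWarnings(dh_reference(uniform_img(c(150, 150, 150))))
  expect_equal(as.numeric(neutral$diagnostics$gains), c(1, 1, 1))
})

test_that("the method registry dispatches by name", {
  expect_identical(wb_methods(), c("OURS", "WPR", "WGE", "DH"))
  img <- small_suite()$images[["4800"]]
  for (m in wb_methods()) {
    res <- wb_correct(img, m)
    expect_s3_class(res, "wb_result")
    expect_identical(res$diagnostics$method, m)
    expect_true(all(unclass(res$image) >= 0 & unclass(res$image) <= 255))
  }
  expect_error(wb_correct(img, "NOPE"))
})
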