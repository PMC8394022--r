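#' Classical white-balance baselines
#'
#' Three reference methods behind the same method interface as the
#' dynamic-threshold estimator: white-patch retinex (WPR), gray-world /
#' gray-edge (WGE), and the fixed-threshold dynamic method (DH) that the
#' iterated estimator descends from.
#'
#' @name baselines
NULL

wb_result_of <- function(img, gains, method, extra = list()) {
  structure(list(image = apply_gains(img, gains),
                 diagnostics = c(list(method = method, neutral = FALSE,
                                      gains = gain_triple(gains)), extra)),
            class = "wb_result")
}

#' White-patch retinex
#'
#' Assumes the brightest pixels reflect the illuminant: the per-channel
#' reference is a high quantile of that channel and the gains scale each
#' reference to the white level.  A percentile slightly below 100 avoids
#' anchoring on single noisy pixels; `percentile = 100` gives the literal
#' channel maximum.
#'
#' @param img an [rgb_image()].
#' @param percentile per-channel reference quantile, in percent.
#' @return a `wb_result` (corrected image + diagnostics with gains).
#' @export
white_patch <- function(img, percentile = 99) {
  img <- as_rgb_image(img)
  stopifnot(percentile > 0, percentile <= 100)
  wl <- white_level_of(img)
  ref <- vapply(1:3, function(i)
    stats::quantile(channel(img, i), percentile / 100, names = FALSE), 0)
  if (any(ref <= 0)) stop("black reference: a channel quantile is zero")
  wb_result_of(img, wl / ref, "WPR", list(reference = ref,
                                          percentile = percentile))
}

# Separable Gaussian smoothing with edge replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  conv_cols <- function(a) {
    ap <- a[pad_idx(nrow(a)), , drop = FALSE]
    out <- matrix(0, nrow(a), ncol(a))
    for (j in seq_along(k))
      out <- out + k[j] * ap[j:(j + nrow(a) - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

# Central-difference gradient magnitude with replicated edges.
grad_magnitude <- function(m) {
  n <- nrow(m); p <- ncol(m)
  dx <- (m[pmin(seq_len(n) + 1L, n), , drop = FALSE] -
         m[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]) / 2
  dy <- (m[, pmin(seq_len(p) + 1L, p), drop = FALSE] -
         m[, pmax(seq_len(p) - 1L, 1L), drop = FALSE]) / 2
  sqrt(dx^2 + dy^2)
}

#' Gray-world / gray-edge estimation
#'
#' Estimates the illuminant as the Minkowski-`p` mean of each channel
#' (`deriv_order = 0`, the gray-world family) or of each channel's spatial
#' gradient magnitude after Gaussian smoothing (`deriv_order = 1`, the
#' gray-edge family).  Gains normalize the estimate to its own mean, so
#' overall brightness is preserved.
#'
#' @param img an [rgb_image()].
#' @param norm_p Minkowski norm order (`p = 1` is the plain mean).
#' @param deriv_order 0 for gray-world, 1 for gray-edge.
#' @param sigma Gaussian pre-smoothing standard deviation in pixels
#'   (used only for `deriv_order = 1`).
#' @return a `wb_result`.
#' @export
gray_world_edge <- function(img, norm_p = 6, deriv_order = 1, sigma = 2) {
  img <- as_rgb_image(img)
  stopifnot(norm_p >= 1, deriv_order %in% c(0, 1), sigma >= 0)
  est <- vapply(1:3, function(i) {
    m <- channel(img, i)
    if (deriv_order == 1) m <- grad_magnitude(gaussian_blur(m, sigma))
    mean(abs(m)^norm_p)^(1 / norm_p)
  }, 0)
  if (any(est <= 0)) stop("illuminant estimate has a zero channel")
  wb_result_of(img, mean(est) / est, "WGE",
               list(estimate = est, norm_p = norm_p,
                    deriv_order = deriv_order, sigma = sigma))
}

#' Fixed-threshold dynamic white balance (the classic ancestor)
#'
#' The block-statistics dynamic-threshold method with its iteration
#' disabled: per-block chroma statistics on a fixed grid, the candidate
#' rule at a pinned weights threshold of 1.5, retention of the brightest
#' 10% of candidates, and the max-luminance gain rule.  By construction it
#' coincides bit-exactly with [white_balance()] run with the equivalent
#' pinned configuration.
#'
#' @param img an [rgb_image()].
#' @param blocks block grid `c(rows, cols)`.
#' @return a `wb_result`.
#' @export
dh_reference <- function(img, blocks = c(3L, 4L)) {
  cfg <- wb_config(wr_fixed = 1.5, wp_fixed = 0.1,
                   stats_mode = "block", block_grid = blocks,
                   yref = "max_luminance", gain_cap = Inf,
                   refine_reference = FALSE, exclude_saturated = FALSE)
  out <- white_balance(img, cfg)
  out$diagnostics$method <- "DH"
  out
}

#' Names of the registered white-balance methods
#' @return character vector.
#' @export
wb_methods <- function() c("OURS", "WPR", "WGE", "DH")

#' Run a white-balance method by name
#'
#' Common entry point used by the evaluation protocol and the command-line
#' interface.
#'
#' @param img an [rgb_image()].
#' @param method one of [wb_methods()].
#' @param ... method-specific arguments (`cfg` for `"OURS"`, `percentile`
#'   for `"WPR"`, `norm_p`/`deriv_order`/`sigma` for `"WGE"`, `blocks` for
#'   `"DH"`).
#' @return a `wb_result`.
#' @export
#' @examples
#' img <- rgb_image(array(runif(300, 20, 230), c(10, 10, 3)))
#' wb_correct(img, "WPR")$diagnostics$gains
wb_correct <- function(img, method = wb_methods(), ...) {
  method <- match.arg(method)
  switch(method,
         OURS = white_balance(img, ...),
         WPR = white_patch(img, ...),
         WGE = gray_world_edge(img, ...),
         DH = dh_reference(img, ...))
}
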