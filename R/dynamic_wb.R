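#' Configuration for the dynamic-threshold white balance
#'
#' Holds the two iterated thresholds of the estimator and their search
#' ranges: the weights threshold `Wr` scales the chroma average-absolute
#' deviation that defines the near-white acceptance region (searched over
#' 0.5-1.5 starting at 1), and the percentage threshold `Wp` is the fraction
#' of accepted candidates retained as the white reference (iterated from 0.1
#' down towards 0.001, never above 0.2).
#'
#' @param wr_init,wr_min,wr_max,wr_step weights-threshold start, search
#'   range and increment.
#' @param wp_init,wp_min,wp_max percentage-threshold start and range.
#' @param wp_factor multiplicative shrink applied to `Wp` at each iteration
#'   of the gain-stabilization loop.
#' @param target_candidate_fraction_band length-2 numeric; the candidate
#'   fraction of the frame the `Wr` search accepts.  The lower edge
#'   guards against empty references; the upper edge only excludes
#'   thresholds so loose that most of the frame qualifies and the region
#'   stops discriminating (pruning within the region is the percentage
#'   threshold's job).
#' @param min_candidates absolute floor on the number of candidate pixels.
#' @param gain_tol relative per-channel change between successive `Wp`
#'   steps below which the gain estimate counts as stabilized.
#' @param neutral_policy what to do when the chroma statistics are
#'   degenerate (`Du` or `Dv` about zero) or no `Wr` yields enough
#'   candidates: `"unit"` passes the image through with unit gains and a
#'   warning, `"error"` stops.
#' @param stats_mode `"global"` computes one set of chroma statistics for
#'   the frame (default); `"block"` computes them per block of
#'   `block_grid`, the convention of the fixed-threshold ancestor method.
#' @param block_grid rows x columns of the block partition.
#' @param yuv_standard luma weights passed to [rgb_to_yuv()].
#' @param yref luminance reference of the gain rule: `"mask_luminance"`
#'   (mean luminance of the retained reference pixels, default -- it
#'   preserves overall brightness, so re-correcting a corrected image is a
#'   near no-op) or `"max_luminance"` (brightest pixel of the frame, the
#'   fixed-threshold ancestor's convention; sensitive to noise maxima).
#' @param gain_cap upper bound on each channel gain.  Beyond about two
#'   doublings the amplified 8-bit quantization noise dominates chroma
#'   fidelity, so corrections are clamped; restoration under such extreme
#'   casts is degraded either way.  `Inf` disables the bound (the
#'   fixed-threshold baseline's classic formulation).
#' @param refine_reference re-centre the final reference on the retained
#'   set's median chroma, keeping every pixel within 3 median absolute
#'   deviations of it at the retained luminance floor.  This removes the
#'   chroma bias of the off-centre acceptance region and discards content
#'   that slipped past the luminance ranking.  Disabled for the
#'   fixed-threshold baseline.
#' @param exclude_saturated bar pixels with a clipped channel from the
#'   reference set (their chroma is meaningless); when the strict pass
#'   leaves too few candidates -- scenes so heavily cast that everything
#'   bright saturates -- the pipeline falls back to admitting them, with a
#'   diagnostic flag.  The fixed-threshold baseline disables this, matching
#'   its classic formulation.
#' @param wr_fixed,wp_fixed set to a number to pin a threshold and disable
#'   its iteration (used by the fixed-threshold baseline).
#'
#' @return a `wb_config` list.
#' @export
#' @examples
#' cfg <- wb_config()
#' cfg$wr_init
wb_config <- function(wr_init = 1.0, wr_min = 0.5, wr_max = 1.5, wr_step = 0.1,
                      wp_init = 0.1, wp_min = 0.001, wp_max = 0.2,
                      wp_factor = 0.5,
                      target_candidate_fraction_band = c(0.001, 0.5),
                      min_candidates = 20L,
                      gain_tol = 0.01,
                      neutral_policy = c("unit", "error"),
                      stats_mode = c("global", "block"),
                      block_grid = c(3L, 4L),
                      yuv_standard = c("bt601", "bt709"),
                      yref = c("mask_luminance", "max_luminance"),
                      gain_cap = 4,
                      refine_reference = TRUE,
                      exclude_saturated = TRUE,
                      wr_fixed = NULL, wp_fixed = NULL) {
  cfg <- list(wr_init = wr_init, wr_min = wr_min, wr_max = wr_max,
              wr_step = wr_step,
              wp_init = wp_init, wp_min = wp_min, wp_max = wp_max,
              wp_factor = wp_factor,
              target_candidate_fraction_band = target_candidate_fraction_band,
              min_candidates = as.integer(min_candidates),
              gain_tol = gain_tol,
              neutral_policy = match.arg(neutral_policy),
              stats_mode = match.arg(stats_mode),
              block_grid = as.integer(block_grid),
              yuv_standard = match.arg(yuv_standard),
              yref = match.arg(yref),
              gain_cap = gain_cap,
              refine_reference = isTRUE(refine_reference),
              exclude_saturated = isTRUE(exclude_saturated),
              wr_fixed = wr_fixed, wp_fixed = wp_fixed)
  with(cfg, {
    stopifnot(wr_min > 0, wr_min <= wr_init, wr_init <= wr_max, wr_step > 0,
              wp_min > 0, wp_min <= wp_init, wp_init <= wp_max, wp_max <= 1,
              wp_factor > 0, wp_factor < 1,
              length(target_candidate_fraction_band) == 2L,
              target_candidate_fraction_band[1] <
                target_candidate_fraction_band[2],
              min_candidates >= 1L, gain_tol > 0, gain_cap > 0,
              length(block_grid) == 2L, all(block_grid >= 1L))
  })
  if (!is.null(cfg$wr_fixed)) stopifnot(cfg$wr_fixed > 0)
  if (!is.null(cfg$wp_fixed)) stopifnot(cfg$wp_fixed > 0, cfg$wp_fixed <= 1)
  structure(cfg, class = "wb_config")
}

# Near-zero tolerance for the chroma deviation statistics, on the 0-255
# intensity scale; below it the acceptance radius is empty for every Wr.
DEGENERATE_EPS <- 1e-9

#' Chroma statistics of the U/V planes
#'
#' Means `Mu`, `Mv` and average absolute deviations
#' `Du = (1/N) * sum(|U - Mu|)`, `Dv = (1/N) * sum(|V - Mv|)` of the chroma
#' planes; the quantities that anchor the candidate acceptance region.
#'
#' @param yuv a `yuv_image`.
#' @param blocks `NULL` for whole-frame statistics, or `c(rows, cols)` for a
#'   block partition (statistics computed independently per block).
#' @return a `uv_stats` list (`Mu`, `Mv`, `Du`, `Dv`, `N`), or a
#'   `uv_stats_blocks` list of them with row/column extents attached.
#' @export
#' @examples
#' yuv <- rgb_to_yuv(rgb_image(array(runif(48, 0, 255), c(4, 4, 3))))
#' compute_uv_stats(yuv)
compute_uv_stats <- function(yuv, blocks = NULL) {
  stopifnot(inherits(yuv, "yuv_image"))
  if (length(yuv$U) < 1L) stop("empty image")
  if (is.null(blocks)) {
    Mu <- mean(yuv$U); Mv <- mean(yuv$V)
    return(structure(list(Mu = Mu, Mv = Mv,
                          Du = mean(abs(yuv$U - Mu)),
                          Dv = mean(abs(yuv$V - Mv)),
                          N = length(yuv$U)),
                     class = "uv_stats"))
  }
  blocks <- as.integer(blocks)
  stopifnot(length(blocks) == 2L, all(blocks >= 1L))
  h <- nrow(yuv$U); w <- ncol(yuv$U)
  rb <- split_extent(h, blocks[1])
  cb <- split_extent(w, blocks[2])
  out <- list()
  for (i in seq_along(rb)) for (j in seq_along(cb)) {
    U <- yuv$U[rb[[i]], cb[[j]], drop = FALSE]
    V <- yuv$V[rb[[i]], cb[[j]], drop = FALSE]
    Mu <- mean(U); Mv <- mean(V)
    out[[length(out) + 1L]] <- structure(
      list(Mu = Mu, Mv = Mv, Du = mean(abs(U - Mu)), Dv = mean(abs(V - Mv)),
           N = length(U), rows = rb[[i]], cols = cb[[j]]),
      class = "uv_stats")
  }
  structure(out, class = "uv_stats_blocks", grid = blocks)
}

# Contiguous near-equal partition of 1:n into k runs.
split_extent <- function(n, k) {
  k <- min(k, n)
  cuts <- floor(seq(0, n, length.out = k + 1L))
  lapply(seq_len(k), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

new_candidate_mask <- function(mask, degenerate = FALSE) {
  structure(mask, count = sum(mask), fraction = mean(mask),
            degenerate = degenerate, class = c("candidate_mask", "matrix"))
}

#' Select near-white candidate pixels
#'
#' A pixel qualifies when its chroma lies strictly inside the dynamic
#' acceptance region:
#' `|U - (Mu + Du * sign(Mu))| < Wr * Du` and
#' `|V - (Mv + Dv * sign(Mv))| < Wr * Dv`.
#' The region centre is displaced from the chroma mean by one average
#' absolute deviation in the direction of the cast, which is what makes the
#' rule latch onto bright illuminant-coloured (near-white) pixels rather
#' than the scene average.  `sign(0) = 0`.
#'
#' @param yuv a `yuv_image`.
#' @param stats output of [compute_uv_stats()] (whole-frame or block form).
#' @param wr positive weights threshold.
#' @param exclude optional logical `H x W` matrix of pixels barred from
#'   candidacy (the pipeline passes the saturated-pixel mask: a clipped
#'   channel destroys a pixel's chroma, so it carries no illuminant
#'   information).
#' @return a `candidate_mask`: logical `H x W` matrix with attributes
#'   `count`, `fraction` and `degenerate` (the latter set when `Du` or `Dv`
#'   is about zero, in which case the mask is empty).
#' @export
select_candidates <- function(yuv, stats, wr, exclude = NULL) {
  stopifnot(inherits(yuv, "yuv_image"), wr > 0)
  apply_exclude <- function(mask) {
    if (!is.null(exclude)) mask & !exclude else mask
  }
  if (inherits(stats, "uv_stats_blocks")) {
    mask <- matrix(FALSE, nrow(yuv$U), ncol(yuv$U))
    degenerate <- TRUE
    for (s in stats) {
      if (s$Du <= DEGENERATE_EPS || s$Dv <= DEGENERATE_EPS) next
      degenerate <- FALSE
      U <- yuv$U[s$rows, s$cols, drop = FALSE]
      V <- yuv$V[s$rows, s$cols, drop = FALSE]
      mask[s$rows, s$cols] <-
        abs(U - (s$Mu + s$Du * sign(s$Mu))) < wr * s$Du &
        abs(V - (s$Mv + s$Dv * sign(s$Mv))) < wr * s$Dv
    }
    return(new_candidate_mask(apply_exclude(mask), degenerate = degenerate))
  }
  stopifnot(inherits(stats, "uv_stats"))
  if (stats$Du <= DEGENERATE_EPS || stats$Dv <= DEGENERATE_EPS)
    return(new_candidate_mask(matrix(FALSE, nrow(yuv$U), ncol(yuv$U)),
                              degenerate = TRUE))
  mask <- abs(yuv$U - (stats$Mu + stats$Du * sign(stats$Mu))) < wr * stats$Du &
          abs(yuv$V - (stats$Mv + stats$Dv * sign(stats$Mv))) < wr * stats$Dv
  new_candidate_mask(apply_exclude(mask))
}

# Outward scan order for the Wr grid: wr_init, then alternating +step/-step,
# staying inside [wr_min, wr_max].
wr_grid <- function(cfg) {
  kmax <- ceiling(max(cfg$wr_max - cfg$wr_init,
                      cfg$wr_init - cfg$wr_min) / cfg$wr_step + 1e-9)
  ks <- 0L
  for (k in seq_len(max(kmax, 0L))) ks <- c(ks, k, -k)
  wr <- round(cfg$wr_init + ks * cfg$wr_step, 10)
  wr[wr >= cfg$wr_min - 1e-9 & wr <= cfg$wr_max + 1e-9]
}

# Floor on the retained reference set: averaging fewer pixels than this
# would let single-pixel sensor noise into the gain estimate.
WP_MIN_RETAIN <- 5L

# The Wp ladder: shrink wp_init by wp_factor down to wp_min, dropping steps
# whose retained count would fall below the floor or repeat the previous
# count.
wp_ladder <- function(cfg, n) {
  wps <- cfg$wp_init * cfg$wp_factor^(0:100)
  wps <- wps[wps >= cfg$wp_min - 1e-12]
  if (length(wps) == 0L) wps <- cfg$wp_init
  ks <- pmax(ceiling(wps * n), 1L)
  keep <- ks >= min(WP_MIN_RETAIN, n) & !duplicated(ks)
  if (!any(keep)) keep[1] <- TRUE
  list(wp = wps[keep], k = ks[keep])
}

# Iterate Wp down the ladder and keep the largest retained set after the
# last significant change of the gain estimate (the start of the final
# plateau); if the estimate never moves, the full wp_init set.
stabilize_wp <- function(img, yuv, mask, cfg) {
  lad <- wp_ladder(cfg, attr(mask, "count"))
  sels <- lapply(lad$wp, function(wp) {
    m <- filter_by_percentage(yuv, mask, wp)
    list(mask = m, gains = compute_gains(img, m, yref = cfg$yref,
                                         yuv_standard = cfg$yuv_standard))
  })
  gmat <- t(vapply(sels, function(s) as.numeric(s$gains), numeric(3)))
  deltas <- c(NA_real_,
              if (nrow(gmat) > 1L)
                vapply(2:nrow(gmat), function(i)
                  max(abs(gmat[i, ] / gmat[i - 1L, ] - 1)), 0))
  big <- which(deltas >= cfg$gain_tol)
  chosen <- if (length(big)) max(big) else 1L
  sel <- sels[[chosen]]
  list(wp = lad$wp[chosen], mask = sel$mask, gains = sel$gains,
       mean_y = mean(yuv$Y[sel$mask]),
       trace = data.frame(wp = lad$wp, k = lad$k, gR = gmat[, 1],
                          gG = gmat[, 2], gB = gmat[, 3], delta = deltas))
}

#' Iterative search of the weights threshold
#'
#' Steps `Wr` outward from its initial value (alternating increase and
#' decrease within the configured range) and collects the grid values whose
#' candidate fraction of the frame falls inside the target band with at
#' least `min_candidates` pixels.  Among those, the returned `Wr` is the
#' one whose percentage-threshold-stabilized reference set has the highest
#' mean luminance -- the white reference is the brightest chroma cluster
#' that survives the dynamic threshold, which disambiguates scenes whose
#' average chroma is dominated by content rather than by the cast.  Ties
#' resolve to the earliest value in the outward scan.  If no grid value
#' lands in the band, the in-range value with enough candidates whose
#' fraction is closest to the band is returned (ties towards smaller
#' `Wr`); if no value reaches the candidate floor the search reports
#' `"insufficient"` and upstream code falls back to the neutral policy.
#'
#' @param yuv a `yuv_image`.
#' @param cfg a [wb_config()].
#' @param stats optional precomputed [compute_uv_stats()] result.
#' @param img the source [rgb_image()]; when omitted it is reconstructed
#'   from `yuv` (the transform is exactly invertible), at a small cost.
#' @return a `wr_search` list: `wr`, `mask`, `status`
#'   (`"band"`/`"fallback"`/`"insufficient"`), `stab` (the stabilized
#'   percentage-threshold selection for the winning `Wr`, when in band),
#'   and the full `grid`/`fractions`/`counts` traces.
#' @export
search_wr <- function(yuv, cfg = wb_config(), stats = NULL, img = NULL,
                      exclude = NULL) {
  stopifnot(inherits(yuv, "yuv_image"), inherits(cfg, "wb_config"))
  if (is.null(stats))
    stats <- compute_uv_stats(
      yuv, blocks = if (cfg$stats_mode == "block") cfg$block_grid)
  if (is.null(img)) img <- yuv_to_rgb(yuv)
  grid <- wr_grid(cfg)
  band <- cfg$target_candidate_fraction_band
  masks <- lapply(grid, function(wr)
    select_candidates(yuv, stats, wr, exclude = exclude))
  counts <- vapply(masks, attr, integer(1), "count")
  fracs <- vapply(masks, attr, numeric(1), "fraction")
  enough <- counts >= cfg$min_candidates
  in_band <- enough & fracs >= band[1] & fracs <= band[2]
  res <- function(i, status, stab = NULL)
    structure(list(wr = grid[i], mask = masks[[i]], status = status,
                   stab = stab, grid = grid, fractions = fracs,
                   counts = counts),
              class = "wr_search")
  if (any(in_band)) {
    idx <- which(in_band)
    # Brightness score at fixed depth so candidate sets of different sizes
    # compare fairly: mean luminance of each set's brightest pixels.
    score <- vapply(idx, function(i) {
      ys <- sort(yuv$Y[masks[[i]]], decreasing = TRUE)
      mean(ys[seq_len(min(WP_MIN_RETAIN, length(ys)))])
    }, 0)
    # Ties towards the larger candidate set: a larger reference pool gives
    # the percentage threshold a less noise-biased mean to stabilize on.
    top <- which(score == max(score))
    best <- idx[top[which.max(counts[idx][top])]]
    return(res(best, "band", stabilize_wp(img, yuv, masks[[best]], cfg)))
  }
  if (!any(enough))
    return(structure(list(wr = NA_real_, mask = NULL, status = "insufficient",
                          stab = NULL, grid = grid, fractions = fracs,
                          counts = counts),
                     class = "wr_search"))
  dist <- ifelse(fracs < band[1], band[1] - fracs,
          ifelse(fracs > band[2], fracs - band[2], 0))
  dist[!enough] <- Inf
  best <- which(dist == min(dist))
  best <- best[which.min(grid[best])]
  res(best, "fallback")
}

#' Retain the brightest fraction of the candidate set
#'
#' Applies the percentage threshold: of the candidate pixels, the
#' `ceiling(wp * count)` with the highest luminance Y are kept as the white
#' reference (brightness ranking; ties at the cutoff broken by scan order,
#' i.e. column-major pixel index).
#'
#' @param yuv a `yuv_image`.
#' @param mask a non-empty `candidate_mask`.
#' @param wp retained fraction in `(0, 1]`.
#' @return a `candidate_mask` with the retained pixels.
#' @export
filter_by_percentage <- function(yuv, mask, wp) {
  stopifnot(inherits(yuv, "yuv_image"), wp > 0, wp <= 1)
  if (is.null(mask) || sum(mask) == 0L) stop("candidate mask is empty")
  idx <- which(mask)
  k <- ceiling(wp * length(idx))
  keep <- idx[order(-yuv$Y[idx], idx)][seq_len(k)]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[keep] <- TRUE
  new_candidate_mask(out)
}

# Re-centre the reference on the retained set's median chroma: keep every
# pixel of the frame whose chroma lies within k MADs of that centre and
# whose luminance reaches the retained set's floor.  The acceptance region
# of the candidate rule is anchored off-centre, so the set it truncates out
# of the white cluster is chroma-biased; re-selecting symmetrically around
# the cluster removes that bias and drops content that slipped past the
# luminance ranking.
refine_reference <- function(yuv, mask, exclude = NULL, k = 3) {
  idx <- which(mask)
  if (length(idx) < 3L) return(mask)
  u <- yuv$U[idx]; v <- yuv$V[idx]
  mu <- stats::median(u); mv <- stats::median(v)
  su <- max(stats::mad(u), 0.5)
  sv <- max(stats::mad(v), 0.5)
  keep <- abs(yuv$U - mu) <= k * su & abs(yuv$V - mv) <= k * sv &
          yuv$Y >= min(yuv$Y[idx])
  if (!is.null(exclude)) keep <- keep & !exclude
  new_candidate_mask(keep)
}

#' Per-channel gains from a white reference mask
#'
#' The gain rule of the fixed-threshold lineage: the luminance reference
#' `Yref` is the maximum luminance of the frame (or, optionally, the mean
#' luminance of the reference pixels), and each channel gain is
#' `Yref / mean(channel over mask)`, so the corrected reference pixels
#' become achromatic.
#'
#' @param img the [rgb_image()] the mask refers to.
#' @param mask a non-empty `candidate_mask`.
#' @param yref `"max_luminance"` (default) or `"mask_luminance"`.
#' @param yuv_standard luma weights used for Y.
#' @return a `gain_triple`: named numeric `c(gR, gG, gB)`, all positive.
#' @export
compute_gains <- function(img, mask,
                          yref = c("max_luminance", "mask_luminance"),
                          yuv_standard = c("bt601", "bt709")) {
  img <- as_rgb_image(img)
  yref <- match.arg(yref)
  if (is.null(mask) || sum(mask) == 0L) stop("candidate mask is empty")
  w <- yuv_weights(match.arg(yuv_standard))
  R <- channel(img, 1); G <- channel(img, 2); B <- channel(img, 3)
  Y <- w["r"] * R + w["g"] * G + w["b"] * B
  means <- c(mean(R[mask]), mean(G[mask]), mean(B[mask]))
  if (any(means <= 0))
    stop("black reference: a channel mean over the mask is zero")
  yr <- if (yref == "max_luminance") max(Y) else mean(Y[mask])
  gain_triple(yr / means)
}

#' Construct a gain triple
#' @param g numeric length 3, strictly positive per-channel gains (R, G, B).
#' @return a named `gain_triple`.
#' @export
gain_triple <- function(g) {
  g <- as.numeric(g)
  stopifnot(length(g) == 3L, all(is.finite(g)), all(g > 0))
  structure(c(gR = g[1], gG = g[2], gB = g[3]), class = "gain_triple")
}

#' Apply von Kries gains to an image
#'
#' Multiplies each channel by its gain in float, clips to
#' `[0, white_level]` and quantizes to the image's bit depth.  Unit gains
#' return the input bit-identically.
#'
#' @param img an [rgb_image()].
#' @param g a [gain_triple()] (or numeric length 3).
#' @return the corrected [rgb_image()].
#' @export
apply_gains <- function(img, g) {
  img <- as_rgb_image(img)
  g <- gain_triple(unclass(g))
  px <- unclass(img)
  px[, , 1] <- px[, , 1] * g[1]
  px[, , 2] <- px[, , 2] * g[2]
  px[, , 3] <- px[, , 3] * g[3]
  quantize_image(px, white_level_of(img), attr(img, "encoding"))
}

#' Dynamic-threshold automatic white balance
#'
#' The full estimator: map to YUV, compute the chroma statistics, search the
#' weights threshold `Wr` for the candidate set with the brightest stable
#' reference (see [search_wr()]), shrink the percentage threshold `Wp` from
#' its initial value and keep the largest retained set past the last
#' significant change of the gain estimate (per-channel change at least
#' `gain_tol`), and correct the image with the resulting von Kries gains.
#' Degenerate images (no usable chroma spread, or no threshold reaching the
#' candidate floor) pass through with unit gains and a warning under the
#' default neutral policy.
#'
#' @param img an [rgb_image()] (or bare `H x W x 3` array on a 0-255 scale).
#' @param cfg a [wb_config()].
#' @return a `wb_result`: list with `image` (the corrected [rgb_image()])
#'   and `diagnostics` (chosen `wr`, `wp`, candidate counts, `gains`,
#'   status flags, and the per-step gain trace).
#' @export
#' @examples
#' img <- rgb_image(array(runif(300, 40, 220), c(10, 10, 3)))
#' res <- white_balance(img)
#' res$diagnostics$gains
white_balance <- function(img, cfg = wb_config()) {
  img <- as_rgb_image(img)
  stopifnot(inherits(cfg, "wb_config"))
  neutral <- function(reason) {
    if (cfg$neutral_policy == "error") stop(reason)
    warning(sprintf("white_balance: %s; returning image uncorrected", reason))
    structure(list(image = img,
                   diagnostics = list(method = "OURS", neutral = TRUE,
                                      reason = reason,
                                      gains = gain_triple(c(1, 1, 1)))),
              class = "wb_result")
  }

  yuv <- rgb_to_yuv(img, cfg$yuv_standard)
  stats <- compute_uv_stats(
    yuv, blocks = if (cfg$stats_mode == "block") cfg$block_grid)
  # A clipped channel voids a pixel's chroma; saturated pixels never enter
  # the reference set.
  saturated <- NULL
  if (cfg$exclude_saturated) {
    wl <- white_level_of(img)
    saturated <- channel(img, 1) >= wl | channel(img, 2) >= wl |
                 channel(img, 3) >= wl
    if (all(saturated)) saturated <- NULL
  }

  stab <- NULL
  saturated_admitted <- FALSE
  if (!is.null(cfg$wr_fixed)) {
    mask <- select_candidates(yuv, stats, cfg$wr_fixed, exclude = saturated)
    if (attr(mask, "count") == 0L && !is.null(saturated)) {
      mask <- select_candidates(yuv, stats, cfg$wr_fixed)
      saturated_admitted <- TRUE
    }
    if (attr(mask, "degenerate") || attr(mask, "count") == 0L)
      return(neutral("degenerate chroma statistics"))
    wr <- cfg$wr_fixed
    wr_status <- "fixed"
  } else {
    probe <- select_candidates(yuv, stats, cfg$wr_init)
    if (attr(probe, "degenerate"))
      return(neutral("degenerate chroma statistics"))
    sr <- search_wr(yuv, cfg, stats = stats, img = img, exclude = saturated)
    if (sr$status == "insufficient" && !is.null(saturated)) {
      # Everything chroma-informative is clipped: degraded mode, admit
      # saturated pixels rather than leave the cast uncorrected.
      sr <- search_wr(yuv, cfg, stats = stats, img = img)
      saturated_admitted <- TRUE
    }
    if (sr$status == "insufficient")
      return(neutral("insufficient candidates at every weights threshold"))
    mask <- sr$mask
    wr <- sr$wr
    wr_status <- sr$status
    stab <- sr$stab
  }

  if (!is.null(cfg$wp_fixed)) {
    m <- filter_by_percentage(yuv, mask, cfg$wp_fixed)
    g <- compute_gains(img, m, yref = cfg$yref,
                       yuv_standard = cfg$yuv_standard)
    stab <- list(wp = cfg$wp_fixed, mask = m, gains = g,
                 mean_y = mean(yuv$Y[m]),
                 trace = data.frame(wp = cfg$wp_fixed, k = sum(m),
                                    gR = g[1], gG = g[2], gB = g[3],
                                    delta = NA_real_))
  } else if (is.null(stab)) {
    stab <- stabilize_wp(img, yuv, mask, cfg)
  }

  if (cfg$refine_reference) {
    refined <- refine_reference(yuv, stab$mask,
                                exclude = if (!saturated_admitted) saturated)
    if (attr(refined, "count") >=
        min(WP_MIN_RETAIN, attr(stab$mask, "count"))) {
      stab$mask <- refined
      stab$gains <- compute_gains(img, refined, yref = cfg$yref,
                                  yuv_standard = cfg$yuv_standard)
    }
  }
  gains <- gain_triple(pmin(as.numeric(stab$gains), cfg$gain_cap))
  corrected <- apply_gains(img, gains)
  structure(list(
    image = corrected,
    diagnostics = list(method = "OURS", neutral = FALSE,
                       wr = wr, wr_status = wr_status, wp = stab$wp,
                       n_candidates = attr(mask, "count"),
                       candidate_fraction = attr(mask, "fraction"),
                       n_selected = attr(stab$mask, "count"),
                       saturated_admitted = saturated_admitted,
                       gains = gains, gains_uncapped = stab$gains,
                       gain_trace = stab$trace,
                       mask = stab$mask)),
    class = "wb_result")
}

#' @export
print.wb_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<wb_result %s%s>\n", d$method,
              if (isTRUE(d$neutral)) " (neutral pass-through)" else ""))
  if (!isTRUE(d$neutral)) {
    if (!is.null(d$wr)) cat(sprintf("  Wr = %.3g (%s), Wp = %.3g\n",
                                    d$wr, d$wr_status, d$wp))
    cat(sprintf("  gains: R %.4f  G %.4f  B %.4f\n",
                d$gains[1], d$gains[2], d$gains[3]))
  }
  invisible(x)
}
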