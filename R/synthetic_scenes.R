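#' Synthetic colour-cast scenes
#'
#' A fixture generator emulating the study design the package targets:
#' scenes with a known-white reference patch and skin-tone regions,
#' rendered under six illuminant casts at correlated colour temperatures
#' 2800-6500 K.  Illuminants are modelled as blackbody radiators and casts
#' as diagonal von Kries gains, the model all four correction methods
#' implicitly invert, so every rendered image carries exact ground truth
#' for parameter-recovery tests.
#'
#' @name synthetic_scenes
NULL

# Evaluate expr with a private RNG state so generators are deterministic
# without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Planckian-locus chromaticity (CIE 1931 xy) by the Kang et al. (2002)
# cubic approximation, valid 1667-25000 K.
planck_xy <- function(cct) {
  x <- ifelse(cct <= 4000,
              -0.2661239e9 / cct^3 - 0.2343589e6 / cct^2 +
                0.8776956e3 / cct + 0.179910,
              -3.0258469e9 / cct^3 + 2.1070379e6 / cct^2 +
                0.2226347e3 / cct + 0.240390)
  y <- ifelse(cct <= 2222,
              -1.1063814 * x^3 - 1.34811020 * x^2 +
                2.18555832 * x - 0.20219683,
              ifelse(cct <= 4000,
                     -0.9549476 * x^3 - 1.37418593 * x^2 +
                       2.09137015 * x - 0.16748867,
                     3.0817580 * x^3 - 5.87338670 * x^2 +
                       3.75112997 * x - 0.37001483))
  c(x = unname(x), y = unname(y))
}

xy_to_linear_srgb <- function(x, y) {
  xyz <- c(x / y, 1, (1 - x - y) / y)
  as.numeric(XYZ2RGB %*% xyz)
}

#' Illuminant cast gains for a colour temperature
#'
#' Chromaticity of a blackbody radiator at the given correlated colour
#' temperature (standard Planckian-locus approximation), converted to
#' linear sRGB and normalized so the green gain is 1.  Scene base colours
#' are sRGB (D65) reflectances, so even the 6500 K lamp differs slightly
#' from neutral: the Planckian locus does not pass through D65.  The red
#' gain decreases and the blue gain increases strictly with colour
#' temperature (warm light reddens, cool light blues).
#'
#' @param cct correlated colour temperature in Kelvin, in `[1000, 12000]`.
#' @return a [gain_triple()] with `gG = 1`.
#' @export
#' @examples
#' cct_to_gains(2800)  # strongly red-heavy, blue-starved
#' cct_to_gains(6500)  # close to unit
cct_to_gains <- function(cct) {
  stopifnot(is.numeric(cct), length(cct) == 1L, is.finite(cct))
  if (cct < 1000 || cct > 12000)
    stop("cct must lie in [1000, 12000] Kelvin")
  xy <- planck_xy(cct)
  rgb <- xy_to_linear_srgb(xy[1], xy[2])
  if (any(rgb <= 0)) stop("colour temperature maps outside the sRGB gamut")
  gain_triple(rgb / rgb[2])
}

#' Scene specification
#'
#' Geometry, reflectances and noise model of the synthetic scene: a
#' mid-gray background, a white reference patch, two skin-tone patches
#' (a yellower tone standing in for high-bilirubin skin and a less yellow
#' low-bilirubin tone), and two bright coloured distractor objects that
#' keep the brightest-pixel assumption of white-patch retinex from being
#' trivially true.  Patch intensities are sized so the white reference
#' stays unclipped under casts at 4000 K and above while the strong red
#' amplification at 2800-3200 K drives it into saturation, the regime in
#' which restoration is expected to degrade.
#'
#' @param height,width frame size in pixels.
#' @param white_patch_fraction area fraction of the white reference.
#' @param white_value intensity of the white reference under neutral light.
#' @param background_gray background intensity.
#' @param skin_tones named list of base RGB triples.
#' @param bright_objects named list of base RGB triples for the
#'   high-luminance distractors.
#' @param object_fraction area fraction of each skin patch and each
#'   distractor.
#' @param noise_sd additive Gaussian intensity noise, 0-255 scale.
#' @param layout_seed integer fixing patch placement (and, combined with
#'   the colour temperature, the noise stream of each rendering).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(height = 120L, width = 160L,
                       white_patch_fraction = 0.02,
                       white_value = 160,
                       background_gray = 120,
                       skin_tones = list(high_risk = c(158, 128, 95),
                                         low_risk = c(150, 126, 110)),
                       bright_objects = list(warm = c(165, 150, 70),
                                             cool = c(110, 140, 175)),
                       object_fraction = 0.06,
                       noise_sd = 2.0,
                       layout_seed = 20210816L) {
  stopifnot(height >= 8L, width >= 8L,
            white_patch_fraction > 0, white_patch_fraction < 1,
            object_fraction > 0, object_fraction < 1,
            white_value > 0, white_value <= 255,
            background_gray > 0, background_gray <= 255,
            noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 white_patch_fraction = white_patch_fraction,
                 white_value = white_value,
                 background_gray = background_gray,
                 skin_tones = skin_tones,
                 bright_objects = bright_objects,
                 object_fraction = object_fraction,
                 noise_sd = noise_sd,
                 layout_seed = as.integer(layout_seed)),
            class = "scene_spec")
}

# Place a h x w rectangle at a seeded random position that does not overlap
# `occupied`; falls back to the least-overlapping try.
place_rect <- function(occupied, h, w) {
  H <- nrow(occupied); W <- ncol(occupied)
  best <- NULL; best_overlap <- Inf
  for (try in 1:200) {
    r0 <- sample.int(H - h + 1L, 1L)
    c0 <- sample.int(W - w + 1L, 1L)
    rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
    ov <- sum(occupied[rows, cols])
    if (ov < best_overlap) {
      best <- list(rows = rows, cols = cols); best_overlap <- ov
    }
    if (ov == 0L) break
  }
  best
}

# The noise-free neutral scene (unit illuminant) and its region masks.
render_neutral <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  px <- array(spec$background_gray, dim = c(H, W, 3L))
  masks <- list()
  with_seed(spec$layout_seed, {
    occupied <- matrix(FALSE, H, W)
    patches <- c(list(white = c(spec$white_value, spec$white_value,
                                spec$white_value)),
                 spec$skin_tones, spec$bright_objects)
    fractions <- c(spec$white_patch_fraction,
                   rep(spec$object_fraction,
                       length(spec$skin_tones) + length(spec$bright_objects)))
    for (i in seq_along(patches)) {
      area <- fractions[i] * H * W
      h <- max(2L, min(H, round(sqrt(area * H / W))))
      w <- max(2L, min(W, round(area / h)))
      rect <- place_rect(occupied, h, w)
      m <- matrix(FALSE, H, W)
      m[rect$rows, rect$cols] <- TRUE
      occupied <- occupied | m
      masks[[names(patches)[i]]] <- m
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[m] <- patches[[i]][ch]
        px[, , ch] <- plane
      }
    }
  })
  list(image = rgb_image(px), masks = masks)
}

#' Render the scene under an illuminant cast
#'
#' Multiplies the neutral scene channel-wise by the cast gains (the von
#' Kries model of the lamp), adds Gaussian sensor noise, clips to the
#' 8-bit range and quantizes.  Deterministic given the layout seed and
#' colour temperature.
#'
#' @param spec a [scene_spec()].
#' @param cct correlated colour temperature of the lamp in Kelvin, or a
#'   [gain_triple()] to apply directly.
#' @return list with `image` (the rendered [rgb_image()]) and
#'   `ground_truth` (`gains_true`, `cct`, region `masks`, the noise-free
#'   `neutral` image).
#' @export
#' @examples
#' sc <- render_scene(scene_spec(height = 24, width = 32), 4800)
#' sc$ground_truth$gains_true
render_scene <- function(spec, cct) {
  stopifnot(inherits(spec, "scene_spec"))
  if (inherits(cct, "gain_triple")) {
    gains <- cct
    cct_num <- NA_real_
  } else {
    gains <- cct_to_gains(cct)
    cct_num <- cct
  }
  base <- render_neutral(spec)
  px <- unclass(base$image)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * gains[ch]
  noise_seed <- (spec$layout_seed +
                 as.integer(round(if (is.na(cct_num)) 0 else cct_num))) %%
                .Machine$integer.max
  px <- with_seed(noise_seed, px + array(stats::rnorm(length(px),
                                                      sd = spec$noise_sd),
                                         dim = dim(px)))
  list(image = quantize_image(px, 255),
       ground_truth = list(gains_true = gains, cct = cct_num,
                           masks = base$masks, neutral = base$image))
}

#' Build the six-colour-temperature suite
#'
#' One scene, shared layout, rendered under each of the six lamp colour
#' temperatures of the emulated study design.  This is the package's
#' default test fixture; the ground truth carries the true cast gains and
#' region masks for every member.
#'
#' @param spec a [scene_spec()].
#' @param ccts colour temperatures in Kelvin.
#' @return a `scene_suite`: list with `images` (named by CCT),
#'   `ground_truth` (named list per CCT), `neutral` (noise-free reference
#'   [rgb_image()]) and `spec`.
#' @export
#' @examples
#' suite <- build_suite(scene_spec(height = 24, width = 32))
#' names(suite$images)
build_suite <- function(spec = scene_spec(),
                        ccts = c(2800, 3200, 4000, 4800, 5600, 6500)) {
  stopifnot(inherits(spec, "scene_spec"), length(ccts) >= 1L)
  rendered <- lapply(ccts, function(ct) render_scene(spec, ct))
  names(rendered) <- as.character(ccts)
  structure(list(images = lapply(rendered, `[[`, "image"),
                 ground_truth = lapply(rendered, `[[`, "ground_truth"),
                 neutral = rendered[[1]]$ground_truth$neutral,
                 ccts = ccts, spec = spec),
            class = "scene_suite")
}

#' @export
print.scene_suite <- function(x, ...) {
  cat(sprintf("<scene_suite: %d x %d px, CCTs %s K, layout seed %d>\n",
              x$spec$height, x$spec$width,
              paste(x$ccts, collapse = "/"), x$spec$layout_seed))
  invisible(x)
}
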