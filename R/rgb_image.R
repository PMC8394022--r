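#' RGB image container
#'
#' Wraps an `H x W x 3` numeric array of channel intensities together with
#' its white level (255 for 8-bit, 65535 for 16-bit material) and a tag
#' saying whether the values are sRGB-encoded (the camera-native, gamma
#' encoded representation every threshold in this package operates on) or
#' already linearized.
#'
#' @param pixels numeric `H x W x 3` array, channels ordered R, G, B.
#' @param white_level positive scalar; the value of reference white.
#' @param encoding `"sRGB-encoded"` (default) or `"sRGB-linearized"`.
#' @param clip clip values into `[0, white_level]` instead of erroring.
#'
#' @return an object of class `rgb_image` (a numeric array with attributes
#'   `white_level` and `encoding`).
#' @export
#' @examples
#' img <- rgb_image(array(128, dim = c(4, 4, 3)))
#' dim(img)
rgb_image <- function(pixels, white_level = 255,
                      encoding = c("sRGB-encoded", "sRGB-linearized"),
                      clip = TRUE) {
  encoding <- match.arg(encoding)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("image contains non-finite pixel values")
  if (!is.numeric(white_level) || length(white_level) != 1L || white_level <= 0)
    stop("`white_level` must be a positive scalar")
  if (any(pixels < 0) || any(pixels > white_level)) {
    if (!clip)
      stop("pixel values outside [0, white_level]")
    pixels <- pmin(pmax(pixels, 0), white_level)
  }
  structure(pixels, white_level = white_level, encoding = encoding,
            class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, white level %s, %s>\n",
              d[1], d[2], format(attr(x, "white_level")), attr(x, "encoding")))
  invisible(x)
}

#' Test for the rgb_image class
#' @param x object to test.
#' @return logical scalar.
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

# Coerce plain arrays leniently; used at internal entry points.
as_rgb_image <- function(x, white_level = 255) {
  if (is_rgb_image(x)) return(x)
  rgb_image(x, white_level = white_level)
}

white_level_of <- function(img) {
  wl <- attr(img, "white_level")
  if (is.null(wl)) 255 else wl
}

# Channel planes as plain matrices.
channel <- function(img, i) {
  m <- unclass(img)[, , i, drop = FALSE]
  dim(m) <- dim(img)[1:2]
  m
}

# Clip and (for integer-scaled images) quantize to the stored bit depth.
# Corrections are computed in float and only quantized here.
quantize_image <- function(pixels, white_level, encoding = "sRGB-encoded") {
  pixels <- pmin(pmax(pixels, 0), white_level)
  if (white_level > 1) pixels <- round(pixels)
  rgb_image(pixels, white_level = white_level, encoding = encoding)
}
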