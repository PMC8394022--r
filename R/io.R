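#' Read an image file into an [rgb_image()]
#'
#' PNG and TIFF through the png/tiff packages; JPEG through EBImage when
#' that package is installed.  Grayscale input is promoted to three
#' channels and an alpha channel is dropped, each with a warning.  8-bit
#' material is returned on the 0-255 scale; pass `bit_depth = 16` for
#' 16-bit sources (0-65535).
#'
#' @param path file path; format inferred from the extension.
#' @param bit_depth declared bit depth of the source, 8 or 16.
#' @return an [rgb_image()].
#' @export
read_image <- function(path, bit_depth = 8) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s'", path))
  stopifnot(bit_depth %in% c(8, 16))
  wl <- 2^bit_depth - 1
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package")
      a <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path)))
  if (is.matrix(px)) {
    warning(sprintf("'%s' is grayscale; promoting to 3 channels", path))
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  }
  if (dim(px)[3] == 4L) {
    warning(sprintf("'%s' has an alpha channel; dropping it", path))
    px <- px[, , 1:3, drop = FALSE]
  }
  if (dim(px)[3] == 2L) {  # gray + alpha
    warning(sprintf("'%s' is grayscale with alpha; promoting, dropping alpha",
                    path))
    px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  }
  rgb_image(px * wl, white_level = wl)
}

#' Write an [rgb_image()] to PNG or TIFF
#'
#' Output defaults to PNG; lossy formats are deliberately not offered for
#' output because recompression would confound colour-difference
#' evaluation.
#'
#' @param img an [rgb_image()].
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_rgb_image(img)
  wl <- white_level_of(img)
  px <- unclass(img) / wl
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path,
                           bits.per.sample = if (wl > 255) 16L else 8L),
    stop(sprintf("unsupported output format '%s'", ext)))
  invisible(path)
}
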