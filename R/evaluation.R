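#' Cross-colour-temperature consistency evaluation
#'
#' CIEDE2000-based protocol: the mean per-pixel colour difference between
#' image pairs, the original-vs-corrected improvement table per colour
#' temperature, the matrix of all unordered colour-temperature pairs with
#' its per-method mean, and line-plot exports of both views.
#'
#' @name evaluation
NULL

image_lab_rows <- function(img) {
  lab <- rgb_to_lab(img)
  matrix(lab, ncol = 3L)
}

#' Mean CIEDE2000 between two images
#'
#' Converts both images to CIELAB, evaluates CIEDE2000 per pixel and
#' averages over the frame (or over `mask` if given, e.g. for skin-only
#' pooling).
#'
#' @param a,b [rgb_image()]s of identical dimensions.
#' @param mask optional logical `H x W` matrix restricting the pooling.
#' @return scalar mean colour difference.
#' @export
#' @examples
#' x <- rgb_image(array(120, c(2, 2, 3)))
#' mean_image_de2000(x, x)  # 0
mean_image_de2000 <- function(a, b, mask = NULL) {
  a <- as_rgb_image(a); b <- as_rgb_image(b)
  if (!identical(dim(a), dim(b)))
    stop("images have different dimensions")
  de <- ciede2000(image_lab_rows(a), image_lab_rows(b))
  if (is.null(mask)) mean(de) else {
    stopifnot(identical(dim(mask), dim(a)[1:2]))
    mean(de[as.vector(mask)])
  }
}

pair_label <- function(a, b) paste0(a, "vs", b)

#' Pairwise colour-difference matrix across colour temperatures
#'
#' Mean image CIEDE2000 for every unordered pair of colour temperatures
#' (15 pairs for the six-CCT suite), plus their arithmetic mean -- the
#' consistency summary reported per correction method.  Optionally also
#' the per-CCT difference against a reference image.
#'
#' @param images named list of [rgb_image()]s, one per colour temperature
#'   (names are the CCTs), all of identical dimensions.
#' @param method method label carried into the report.
#' @param reference optional [rgb_image()]; when given, the report also
#'   carries each image's mean colour difference to it.
#' @param mask optional pooling mask forwarded to [mean_image_de2000()].
#' @return a `consistency_report`: list with `method`, `ccts`, `pairwise`
#'   (data frame `ct1`, `ct2`, `de`), `mean_pairwise`, and optionally
#'   `per_ct_vs_reference`.
#' @export
cross_ct_matrix <- function(images, method = "OURS", reference = NULL,
                            mask = NULL) {
  stopifnot(is.list(images), length(images) >= 2L,
            !is.null(names(images)), all(nzchar(names(images))))
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("images have different dimensions")
  labs <- lapply(images, function(im) image_lab_rows(as_rgb_image(im)))
  keep <- if (is.null(mask)) TRUE else as.vector(mask)
  ccts <- names(images)
  pairs <- utils::combn(seq_along(images), 2L)
  de <- apply(pairs, 2L, function(ij)
    mean(ciede2000(labs[[ij[1]]], labs[[ij[2]]])[keep]))
  pairwise <- data.frame(ct1 = ccts[pairs[1, ]], ct2 = ccts[pairs[2, ]],
                         de = de,
                         label = pair_label(ccts[pairs[1, ]],
                                            ccts[pairs[2, ]]))
  per_ct <- NULL
  if (!is.null(reference)) {
    ref_lab <- image_lab_rows(as_rgb_image(reference))
    per_ct <- vapply(labs, function(l)
      mean(ciede2000(l, ref_lab)[keep]), 0)
    names(per_ct) <- ccts
  }
  structure(list(method = method, ccts = ccts, pairwise = pairwise,
                 mean_pairwise = mean(de),
                 per_ct_vs_reference = per_ct),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report %s: %d pairs, mean dE00 = %.3f>\n",
              x$method, nrow(x$pairwise), x$mean_pairwise))
  invisible(x)
}

#' Flatten consistency reports to the wide table layout
#'
#' One row per method; one column per colour-temperature pair plus a
#' `Mean` column.
#'
#' @param reports a `consistency_report` or list of them.
#' @return a data frame.
#' @export
consistency_table <- function(reports) {
  if (inherits(reports, "consistency_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    v <- c(r$pairwise$de, r$mean_pairwise)
    names(v) <- c(r$pairwise$label, "Mean")
    as.data.frame(c(list(Method = r$method), as.list(v)),
                  check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read the consistency table as CSV
#'
#' Serialization round-trips losslessly at full double precision.
#'
#' @param reports passed to [consistency_table()].
#' @param path CSV path.
#' @return `write_consistency_csv` returns the path invisibly;
#'   `read_consistency_csv` returns the data frame.
#' @export
write_consistency_csv <- function(reports, path) {
  df <- consistency_table(reports)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_consistency_csv
#' @export
read_consistency_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Original-vs-corrected improvement table
#'
#' For each colour temperature, the mean colour difference of the original
#' and of the corrected image against a reference, in the two-row layout
#' (origin row, method row) of the consistency study.  On the synthetic
#' suite the natural reference is the noise-free neutral scene, which is
#' known exactly; a CCT member of the set can be declared instead.
#'
#' @param originals,corrected named lists of [rgb_image()]s keyed by CCT,
#'   with matching names.
#' @param reference an [rgb_image()] used as reference for both rows, or a
#'   CCT name present in the lists (then each row is compared against its
#'   own image at that CCT).
#' @param method label for the corrected row.
#' @param mask optional pooling mask.
#' @return an `improvement_table` data frame: rows `origin` and `method`,
#'   one column per CCT.
#' @export
improvement_table <- function(originals, corrected, reference,
                              method = "OURS", mask = NULL) {
  stopifnot(is.list(originals), is.list(corrected),
            identical(names(originals), names(corrected)),
            length(originals) >= 1L)
  ccts <- names(originals)
  row_vs <- function(imgs, ref)
    vapply(imgs, function(im) mean_image_de2000(im, ref, mask = mask), 0)
  if (is_rgb_image(reference) ||
      (is.array(reference) && length(dim(reference)) == 3L)) {
    ref <- as_rgb_image(reference)
    origin <- row_vs(originals, ref)
    corr <- row_vs(corrected, ref)
  } else {
    reference <- as.character(reference)
    if (!reference %in% ccts)
      stop(sprintf("reference CCT '%s' is missing from the image set",
                   reference))
    origin <- row_vs(originals, originals[[reference]])
    corr <- row_vs(corrected, corrected[[reference]])
  }
  out <- as.data.frame(rbind(origin = origin, corr))
  rownames(out) <- c("origin", method)
  names(out) <- ccts
  class(out) <- c("improvement_table", "data.frame")
  out
}

#' Export consistency curves as plot files
#'
#' Line plots of the evaluation: the per-CCT colour difference to the
#' reference (one curve per method) and the colour difference of each
#' colour-temperature pair (one curve per method).  A flatter, lower curve
#' means the method renders the scene more consistently across lamps.
#'
#' @param reports list of `consistency_report`s (one per method).
#' @param dir output directory, created if missing.
#' @param which any of `"per_ct"` (needs `per_ct_vs_reference`) and
#'   `"pairwise"`.
#' @param format `"png"` or `"svg"`.
#' @return character vector of the files written (invisibly); empty, with
#'   a warning, when no reports are supplied.
#' @export
export_curves <- function(reports, dir = ".",
                          which = c("per_ct", "pairwise"),
                          format = c("png", "svg")) {
  format <- match.arg(format)
  which <- match.arg(which, several.ok = TRUE)
  if (inherits(reports, "consistency_report")) reports <- list(reports)
  if (length(reports) == 0L) {
    warning("no reports supplied; nothing to plot")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dev_open <- function(path) {
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::svg(path, width = 9, height = 6)
  }
  methods <- vapply(reports, `[[`, "", "method")
  files <- character(0)
  if ("per_ct" %in% which &&
      !is.null(reports[[1]]$per_ct_vs_reference)) {
    path <- file.path(dir, paste0("per_ct_curves.", format))
    m <- sapply(reports, `[[`, "per_ct_vs_reference")
    dev_open(path)
    graphics::matplot(as.numeric(reports[[1]]$ccts), m, type = "b",
                      pch = 19, lty = 1, xlab = "colour temperature [K]",
                      ylab = "mean dE00 vs reference",
                      main = "Colour difference by colour temperature")
    graphics::legend("topright", legend = methods, col = seq_along(reports),
                     lty = 1, pch = 19)
    grDevices::dev.off()
    files <- c(files, path)
  }
  if ("pairwise" %in% which) {
    path <- file.path(dir, paste0("pairwise_curves.", format))
    m <- sapply(reports, function(r) r$pairwise$de)
    dev_open(path)
    graphics::matplot(seq_len(nrow(m)), m, type = "b", pch = 19, lty = 1,
                      xaxt = "n", xlab = "colour-temperature pair",
                      ylab = "mean dE00",
                      main = "Pairwise colour difference across lamps")
    graphics::axis(1, at = seq_len(nrow(m)),
                   labels = reports[[1]]$pairwise$label, las = 2,
                   cex.axis = 0.7)
    graphics::legend("topright", legend = methods, col = seq_along(reports),
                     lty = 1, pch = 19)
    grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}
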