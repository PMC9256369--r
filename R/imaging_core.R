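#' vesselseg: enhancement-integrated Gabor segmentation of retinal vessels
#'
#' Fundus photographs show blood vessels as dark curvilinear structures on a
#' reddish, unevenly illuminated background. This package segments them with
#' an orientation-selective Gabor filter bank, optionally preceded by one of
#' six contrast-enhancement operators, followed by hysteresis thresholding and
#' connected-component cleaning. Pixel-level sensitivity / accuracy /
#' specificity evaluation and a seeded synthetic phantom generator are
#' included so every stage is testable without external datasets.
#'
#' Images are held as plain numeric matrices in `[0, 1]` indexed
#' `(row, column)` with row 1 at the top; colour images as [rgb_image]
#' objects. 8-bit storage uses round-half-up quantization.
#'
#' @name vesselseg-package
#' @keywords internal
"_PACKAGE"

## ---- internal numeric conventions -------------------------------------

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# map [0,1] intensities to integer levels 0..(n_levels-1)
quantize_levels <- function(img, n_levels = 256L) {
  lev <- round_half_up(img * (n_levels - 1L))
  storage.mode(lev) <- "integer"
  lev
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# min-max rescale to [0,1]; degenerate (constant) input maps to all zeros.
# When `mask` is given the min/max are taken over masked pixels only and the
# result is clipped so unmasked pixels cannot exceed [0,1].
rescale01 <- function(x, mask = NULL, eps = 1e-12) {
  vals <- if (is.null(mask)) x else x[mask]
  lo <- min(vals); hi <- max(vals)
  if (!is.finite(lo) || !is.finite(hi) || (hi - lo) < eps) {
    return(array(0, dim(x)))
  }
  clip01((x - lo) / (hi - lo))
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(img) || any(!is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(img)
}

## ---- colour image container -------------------------------------------

#' RGB fundus image
#'
#' A lightweight container for a colour image: three numeric matrices
#' (`red`, `green`, `blue`) of identical shape with values in `[0, 1]`
#' (8-bit files are loaded as `value / 255`). Indexing is `(row, column)`,
#' row 1 at the top.
#'
#' @param red,green,blue numeric matrices in `[0, 1]`, identical dimensions.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(red, green, blue) {
  assert_gray(red, "red"); assert_gray(green, "green"); assert_gray(blue, "blue")
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    stop("red, green and blue channels must share one shape", call. = FALSE)
  }
  structure(list(red = red, green = green, blue = blue), class = "rgb_image")
}

#' @export
dim.rgb_image <- function(x) dim(x$red)

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d>\n", d[1], d[2]))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

#' Extract the green channel
#'
#' Vessels have their highest contrast against the background in the green
#' plane of a fundus photograph, so the whole pipeline operates on it.
#'
#' @param img an [rgb_image].
#' @return the green plane, unchanged, as a numeric matrix in `[0, 1]`.
#' @export
extract_green_channel <- function(img) {
  stopifnot(is_rgb_image(img))
  img$green
}

#' Quantize to 8-bit levels and back
#'
#' Maps every intensity to its nearest 8-bit level (`round(255 v) / 255`,
#' round-half-up) — the value it would take after a lossless 8-bit file
#' round trip. Idempotent.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @return matrix of the same shape on the 8-bit grid.
#' @export
quantize_roundtrip <- function(img) {
  assert_gray(img)
  round_half_up(img * 255) / 255
}

## ---- file I/O ----------------------------------------------------------

#' Read a colour fundus image
#'
#' Reads PNG, TIFF or JPEG via EBImage. A grayscale file is replicated into
#' the three channels. Outputs of this package are always written lossless
#' (PNG); JPEG is accepted on input only.
#'
#' @param path image file path.
#' @return an [rgb_image].
#' @export
read_fundus_image <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) {
    g <- t(a)
    return(rgb_image(g, g, g))
  }
  # EBImage stores [x, y, channel]; transpose to (row, column)
  rgb_image(t(a[, , 1L]), t(a[, , 2L]), t(a[, , 3L]))
}

#' Read a binary mask image
#'
#' Any supported raster is binarized at half its maximum value, the usual
#' convention for ground-truth vessel and field-of-view masks.
#'
#' @param path image file path.
#' @return logical matrix (`TRUE` = foreground).
#' @export
read_mask <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- t(a)
  m >= max(m) / 2
}

#' Write an image or mask as PNG
#'
#' Grayscale matrices and [rgb_image] objects are written as 8-bit PNG;
#' logical masks as 0/255 PNG.
#'
#' @param img numeric matrix in `[0, 1]`, logical matrix, or [rgb_image].
#' @param path output path (extension decides the lossless format,
#'   `.png` recommended).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is_rgb_image(img)) {
    a <- array(0, c(ncol(img$red), nrow(img$red), 3L))
    a[, , 1L] <- t(img$red); a[, , 2L] <- t(img$green); a[, , 3L] <- t(img$blue)
    EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  } else if (is.logical(img)) {
    EBImage::writeImage(EBImage::Image(t(img * 1)), path)
  } else {
    assert_gray(img)
    EBImage::writeImage(EBImage::Image(t(img)), path)
  }
  invisible(path)
}
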