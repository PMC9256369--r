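#' Gabor filter bank configuration
#'
#' Parameters of the complex, DC-compensated Gabor kernels
#' \deqn{\psi_{u,v}(z) = \frac{\|k_{u,v}\|^2}{\sigma}
#'   \exp\!\Big(-\frac{\|k_{u,v}\|^2 \|z\|^2}{2\sigma^2}\Big)
#'   \Big[\exp(i\, k_{u,v} \cdot z) - \exp(-\sigma^2/2)\Big]}
#' with wave number \eqn{k_v = k_{max}/\lambda^v} and orientations
#' \eqn{\phi_u = \pi u / n}. The subtracted \eqn{\exp(-\sigma^2/2)} removes
#' the kernel's DC component so a constant image yields (numerically) zero
#' response. The printed prefactor \eqn{\|k\|^2/\sigma} is kept as such; the
#' final min-max rescale makes its normalisation immaterial.
#'
#' Kernel index `u` is labelled by the orientation of the line structure it
#' detects: the plane wave runs perpendicular to \eqn{\phi_u}, so a vessel
#' at angle \eqn{\phi_u} maximises response `u`. For the default uniform
#' 8-orientation grid the kernel set is identical under either labelling.
#'
#' @param k_max peak spatial frequency, radians/pixel (default `pi/2`).
#' @param lambda_spacing frequency spacing between scales (default `sqrt(2)`).
#' @param sigma Gaussian envelope width (default `pi/3`).
#' @param kernel_width,kernel_height kernel size in pixels (default 60).
#' @param n_orientations number of orientations (default 8).
#' @param scales integer scale indices `v`, wave number `k_max/lambda^v`
#'   (default `0`, a single scale).
#' @return an object of class `gabor_bank_config`.
#' @export
gabor_bank_config <- function(k_max = pi / 2, lambda_spacing = sqrt(2),
                              sigma = pi / 3, kernel_width = 60L,
                              kernel_height = 60L, n_orientations = 8L,
                              scales = 0L) {
  stopifnot(k_max > 0, lambda_spacing > 0, sigma > 0,
            kernel_width >= 3, kernel_height >= 3, n_orientations >= 1)
  structure(list(k_max = k_max, lambda_spacing = lambda_spacing,
                 sigma = sigma, kernel_width = as.integer(kernel_width),
                 kernel_height = as.integer(kernel_height),
                 n_orientations = as.integer(n_orientations),
                 scales = as.integer(scales)),
            class = "gabor_bank_config")
}

#' Build one complex Gabor kernel
#'
#' @param config a [gabor_bank_config].
#' @param u orientation index, `0 <= u < n_orientations`.
#' @param v scale index, must be one of `config$scales`.
#' @return complex matrix of size `kernel_height` x `kernel_width`, centered
#'   at the geometric center of the grid.
#' @export
build_gabor_kernel <- function(config, u = 0L, v = 0L) {
  stopifnot(inherits(config, "gabor_bank_config"))
  if (u < 0 || u >= config$n_orientations) {
    stop("orientation index `u` out of range", call. = FALSE)
  }
  if (!(v %in% config$scales)) {
    stop("scale index `v` not in config$scales", call. = FALSE)
  }
  kv <- config$k_max / config$lambda_spacing^v
  phi <- pi * u / config$n_orientations
  # wave vector perpendicular to the detected line orientation phi_u
  kx <- kv * cos(phi + pi / 2)
  ky <- kv * sin(phi + pi / 2)
  sig <- config$sigma
  # geometric center; even sizes center on half-integer coordinates
  x <- seq_len(config$kernel_width) - (config$kernel_width + 1) / 2
  y <- seq_len(config$kernel_height) - (config$kernel_height + 1) / 2
  X <- matrix(x, config$kernel_height, config$kernel_width, byrow = TRUE)
  Y <- matrix(y, config$kernel_height, config$kernel_width)
  k2 <- kv^2
  envelope <- (k2 / sig) * exp(-k2 * (X^2 + Y^2) / (2 * sig^2))
  envelope * (exp(1i * (kx * X + ky * Y)) - exp(-sig^2 / 2))
}

#' Per-orientation Gabor magnitude responses
#'
#' Convolves the image with every kernel of the bank (reflect padding) and
#' returns the raw magnitude responses, one matrix per (orientation, scale).
#' Only the magnitude is retained; the phase is discarded.
#'
#' @inheritParams build_gabor_kernel
#' @param img numeric matrix in `[0, 1]`, at least as large as the kernel.
#' @return list of numeric matrices with attributes `u` and `v` on each
#'   element.
#' @export
gabor_responses <- function(img, config = gabor_bank_config()) {
  assert_gray(img)
  if (nrow(img) < config$kernel_height || ncol(img) < config$kernel_width) {
    stop("image is smaller than the Gabor kernel", call. = FALSE)
  }
  out <- list()
  for (v in config$scales) {
    for (u in seq_len(config$n_orientations) - 1L) {
      kern <- build_gabor_kernel(config, u, v)
      r <- Mod(conv2_reflect(img, kern))
      attr(r, "u") <- u; attr(r, "v") <- v
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' Maximum multi-orientation Gabor response
#'
#' Per pixel, the maximum magnitude over all orientations (and configured
#' scales) of the convolution with the Gabor bank, min-max rescaled to
#' `[0, 1]`. A constant image gives an all-zero response (the kernels are
#' DC-compensated, and a degenerate rescale maps a constant field to zero).
#' When a field-of-view mask is supplied the rescale normalises over the
#' FOV only.
#'
#' @inheritParams gabor_responses
#' @param fov optional logical matrix restricting the min-max normalisation.
#' @return numeric matrix in `[0, 1]`, same shape as `img`.
#' @export
gabor_max_response <- function(img, config = gabor_bank_config(), fov = NULL) {
  resp <- gabor_responses(img, config)
  mx <- resp[[1L]]
  for (r in resp[-1L]) mx <- pmax(mx, r)
  rescale01(mx, mask = fov)
}

#' Orientation attaining the maximum Gabor response
#'
#' @inheritParams gabor_responses
#' @return integer matrix of orientation indices `u` (0-based) attaining the
#'   per-pixel maximum magnitude.
#' @export
gabor_orientation_map <- function(img, config = gabor_bank_config()) {
  resp <- gabor_responses(img, config)
  best <- resp[[1L]]
  arg <- matrix(attr(resp[[1L]], "u"), nrow(best), ncol(best))
  for (r in resp[-1L]) {
    upd <- r > best
    arg[upd] <- attr(r, "u")
    best[upd] <- r[upd]
  }
  arg
}

#' Export the kernel bank for inspection
#'
#' Writes the real and imaginary parts of every kernel as frames of one
#' multi-page TIFF, each frame min-max normalised for display.
#'
#' @param config a [gabor_bank_config].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
export_gabor_bank <- function(config, path) {
  planes <- list()
  for (v in config$scales) {
    for (u in seq_len(config$n_orientations) - 1L) {
      kern <- build_gabor_kernel(config, u, v)
      planes[[length(planes) + 1L]] <- rescale01(Re(kern))
      planes[[length(planes) + 1L]] <- rescale01(Im(kern))
    }
  }
  a <- array(0, c(ncol(planes[[1L]]), nrow(planes[[1L]]), length(planes)))
  for (i in seq_along(planes)) a[, , i] <- t(planes[[i]])
  EBImage::writeImage(EBImage::Image(a), path)
  invisible(path)
}
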