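## Four non-adaptive contrast enhancement operators:
## gamma correction with an adaptive weighting distribution (GCADW),
## homomorphic filtering, joint equalization of histogram (JEH), and
## unsharp masking. All operate on a single channel in [0, 1].

# Gaussian smoothing used by the unsharp variants (EBImage). The image is
# replicate-padded by the brush radius first: this keeps the full Gaussian
# support even on images smaller than the brush and replaces filter2's
# circular wrap-around with clamp-to-edge behaviour.
gaussian_smooth <- function(img, sigma) {
  rad <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  P <- replicate_pad(img, rad)
  out <- EBImage::gblur(P, sigma = sigma, radius = rad)
  out[seq_len(nrow(img)) + rad, seq_len(ncol(img)) + rad, drop = FALSE]
}

## ---- GCADW -------------------------------------------------------------

#' GCADW configuration
#'
#' Gamma correction with an adaptive weighting distribution: the per-level
#' gamma is `1 - cdf_w(l)` where `cdf_w` is the cumulative distribution of a
#' weighted histogram. The weighting exponent `a` compresses the dynamic
#' range of the probability masses before accumulation; `a = 0.5` is the
#' customary choice in the adaptive-gamma-correction literature.
#'
#' @param a weighting-distribution exponent, `> 0` (default 0.5).
#' @param n_levels histogram levels (default 256).
#' @return an object of class `gcadw_config`.
#' @export
gcadw_config <- function(a = 0.5, n_levels = 256L) {
  stopifnot(a > 0, n_levels >= 2)
  structure(list(a = a, n_levels = as.integer(n_levels)),
            class = "gcadw_config")
}

#' Weighted cumulative distribution of an intensity histogram
#'
#' Computes `pdf_w(l) = pdf_max * ((pdf(l) - pdf_min) / (pdf_max -
#' pdf_min))^a` from the histogram's own extreme probabilities, then the
#' normalised cumulative sum `cdf_w`. When the histogram is uniform
#' (`pdf_max == pdf_min`) the weighting is undefined (0/0) and the plain
#' unweighted cdf is returned instead.
#'
#' @param histogram non-negative level counts, length `n_levels`, at least
#'   one positive.
#' @param config a [gcadw_config].
#' @return numeric vector `cdf_w` of length `n_levels`, non-decreasing,
#'   ending at 1.
#' @export
compute_weighted_cdf <- function(histogram, config = gcadw_config()) {
  stopifnot(inherits(config, "gcadw_config"))
  if (length(histogram) != config$n_levels || any(histogram < 0)) {
    stop("histogram must hold n_levels non-negative counts", call. = FALSE)
  }
  if (sum(histogram) == 0) stop("all-zero histogram", call. = FALSE)
  pdf <- histogram / sum(histogram)
  p_max <- max(pdf); p_min <- min(pdf)
  if (p_max == p_min) {
    return(cumsum(pdf) / sum(pdf))
  }
  pdf_w <- p_max * ((pdf - p_min) / (p_max - p_min))^config$a
  cumsum(pdf_w) / sum(pdf_w)
}

#' Adaptive gamma correction with weighting distribution (GCADW)
#'
#' Each intensity level `l` maps to `T(l) = l_max (l / l_max)^(1 - cdf_w(l))`
#' with `l_max` the maximum occupied level. Low intensities are lifted
#' progressively while `l_max` is a fixed point, which compensates the dark
#' periphery produced by uneven fundus illumination.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param config a [gcadw_config].
#' @return enhanced matrix in `[0, 1]`.
#' @export
gcadw_enhance <- function(img, config = gcadw_config()) {
  assert_gray(img)
  n <- config$n_levels
  lev <- quantize_levels(img, n)
  h <- tabulate(lev + 1L, nbins = n)
  cdf_w <- compute_weighted_cdf(h, config)
  l_max <- max(lev)
  if (l_max == 0L) return(array(0, dim(img)))
  l <- 0:(n - 1L)
  gamma <- 1 - cdf_w
  tl <- l_max * (l / l_max)^gamma
  tl[1L] <- 0  # 0^0 convention: level 0 stays 0
  out <- matrix(tl[lev + 1L], nrow(img), ncol(img)) / (n - 1L)
  clip01(out)
}

## ---- homomorphic filtering ---------------------------------------------

#' Homomorphic filter configuration
#'
#' An image is modelled as illumination times reflectance; taking logs turns
#' the product into a sum, and a frequency-domain filter `H(u,v) =
#' (gamma_high - gamma_low) (1 - exp(-k P^2 / P0^2)) + gamma_low`
#' attenuates the slowly varying illumination (gain `gamma_low` at DC)
#' relative to reflectance detail (gain `gamma_high` at high frequency).
#' `gamma_high > gamma_low > 0` is required.
#'
#' @param gamma_high high-frequency gain (default 0.8).
#' @param gamma_low low-frequency gain (default 0.6).
#' @param steepness_k exponent constant (default 1.0).
#' @param cutoff_p0 cutoff radius in frequency-index units; `NULL` (default)
#'   means `0.05 * min(height, width)` of the image being filtered.
#' @param log_epsilon additive constant before the logarithm (default
#'   `1/255`).
#' @return an object of class `homomorphic_config`.
#' @export
homomorphic_config <- function(gamma_high = 0.8, gamma_low = 0.6,
                               steepness_k = 1.0, cutoff_p0 = NULL,
                               log_epsilon = 1 / 255) {
  stopifnot(gamma_high > gamma_low, gamma_low > 0, steepness_k > 0,
            is.null(cutoff_p0) || cutoff_p0 > 0, log_epsilon > 0)
  structure(list(gamma_high = gamma_high, gamma_low = gamma_low,
                 steepness_k = steepness_k, cutoff_p0 = cutoff_p0,
                 log_epsilon = log_epsilon),
            class = "homomorphic_config")
}

#' Homomorphic transfer function
#'
#' Filter gain at centered frequency radius `p`: `gamma_low` at `p = 0`,
#' rising monotonically towards `gamma_high`.
#'
#' @param p frequency radius (vector allowed).
#' @param config a [homomorphic_config].
#' @param cutoff_p0 cutoff radius; overrides `config$cutoff_p0`.
#' @return filter gains, same length as `p`.
#' @export
homomorphic_transfer <- function(p, config = homomorphic_config(),
                                 cutoff_p0 = config$cutoff_p0) {
  stopifnot(!is.null(cutoff_p0), cutoff_p0 > 0)
  (config$gamma_high - config$gamma_low) *
    (1 - exp(-config$steepness_k * p^2 / cutoff_p0^2)) + config$gamma_low
}

#' Homomorphic illumination correction
#'
#' `log(img + eps)` -> 2-D FFT -> multiply by the transfer function ->
#' inverse FFT -> exponentiate -> subtract `eps` -> min-max rescale to
#' `[0, 1]`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param config a [homomorphic_config].
#' @return enhanced matrix in `[0, 1]`.
#' @export
homomorphic_enhance <- function(img, config = homomorphic_config()) {
  assert_gray(img)
  H <- nrow(img); W <- ncol(img)
  p0 <- if (is.null(config$cutoff_p0)) 0.05 * min(H, W) else config$cutoff_p0
  lg <- log(img + config$log_epsilon)
  spec <- stats::fft(lg)
  # centered frequency radius on the unshifted FFT grid
  fu <- ((seq_len(H) - 1L + floor(H / 2)) %% H) - floor(H / 2)
  fv <- ((seq_len(W) - 1L + floor(W / 2)) %% W) - floor(W / 2)
  P <- sqrt(outer(fu^2, fv^2, "+"))
  Hf <- homomorphic_transfer(P, config, cutoff_p0 = p0)
  g <- Re(stats::fft(spec * Hf, inverse = TRUE)) / (H * W)
  rescale01(exp(g) - config$log_epsilon)
}

## ---- joint equalization of histogram (JEH) ------------------------------

#' Local neighborhood mean
#'
#' Per-pixel mean over a `Z x Z` window with replicate padding at the
#' borders.
#'
#' @param img numeric matrix.
#' @param window_z odd window size `>= 3` (default 3).
#' @return matrix of local means, same shape.
#' @export
neighborhood_mean <- function(img, window_z = 3L) {
  assert_gray(img)
  if (window_z %% 2 == 0 || window_z < 3) {
    stop("window_z must be odd and >= 3", call. = FALSE)
  }
  k <- (window_z - 1L) %/% 2L
  P <- replicate_pad(img, k)
  H <- nrow(img); W <- ncol(img)
  acc <- matrix(0, H, W)
  for (di in -k:k) {
    for (dj in -k:k) {
      acc <- acc + P[seq_len(H) + k + di, seq_len(W) + k + dj, drop = FALSE]
    }
  }
  acc / window_z^2
}

#' Equalized level of one pixel pair
#'
#' The scalar mapping applied to every occurring (pixel value, local mean)
#' pair: `(n_levels - 1) / (n_pixels - 1) * (cdf - cdf_min)`, converted to
#' an integer level by truncation toward zero. Truncation (rather than
#' rounding) is the package's integer-conversion convention for this map.
#'
#' @param cdf 2-D cumulative count of the pair.
#' @param cdf_min minimum cumulative count over pairs occurring in the image.
#' @param n_pixels total pixel count `M * N`.
#' @param n_levels output levels `L` (default 256).
#' @return integer equalized level in `0..(n_levels - 1)`.
#' @export
jeh_level_map <- function(cdf, cdf_min, n_pixels, n_levels = 256L) {
  stopifnot(n_pixels >= 2, cdf >= cdf_min)
  as.integer(trunc((n_levels - 1) / (n_pixels - 1) * (cdf - cdf_min)))
}

#' Joint histogram workspace
#'
#' Quantizes the image and its `Z x Z` neighborhood mean to 8-bit levels,
#' accumulates the 256 x 256 joint histogram of (pixel, mean) pairs, its
#' 2-D cumulative distribution, the minimum CDF over occurring pairs, and
#' the pair-to-level equalization mapping.
#'
#' @inheritParams neighborhood_mean
#' @return list with elements `window_z`, `joint_histogram`, `cdf2d`,
#'   `cdf_min` and `mapping` (256 x 256 integer matrix of output levels).
#' @export
jeh_workspace <- function(img, window_z = 3L) {
  C <- 256L
  f <- quantize_levels(img, C)
  g <- quantize_levels(clip01(neighborhood_mean(img, window_z)), C)
  idx <- as.integer(f) + C * as.integer(g) + 1L
  h <- matrix(tabulate(idx, nbins = C * C), C, C)  # h[a+1, b+1]
  cdf <- apply(apply(h, 2L, cumsum), 1L, cumsum)
  cdf <- t(cdf)
  cdf_min <- min(cdf[h > 0])
  mn <- length(img)
  # same map as jeh_level_map; pairs absent from the image may sit below
  # cdf_min and are never looked up, so no occurrence guard here
  mapping <- matrix(as.integer(trunc((C - 1) / (mn - 1) * (cdf - cdf_min))),
                    C, C)
  list(window_z = as.integer(window_z), joint_histogram = h, cdf2d = cdf,
       cdf_min = cdf_min, mapping = mapping, f = f, g = g)
}

#' Joint equalization of histogram (JEH)
#'
#' Histogram equalization over (pixel value, local mean) pairs: the 2-D
#' cumulative distribution of the joint histogram drives the level mapping,
#' so pixels are spread according to both their own intensity and their
#' local context. Pixels sharing a pair receive the same output level.
#'
#' @inheritParams neighborhood_mean
#' @return equalized matrix in `[0, 1]`.
#' @export
jeh_equalize <- function(img, window_z = 3L) {
  ws <- jeh_workspace(img, window_z)
  lev <- ws$mapping[cbind(as.integer(ws$f) + 1L, as.integer(ws$g) + 1L)]
  matrix(lev, nrow(img), ncol(img)) / 255
}

## ---- unsharp masking ----------------------------------------------------

#' Unsharp masking configuration
#'
#' @param gain_k scaling constant on the high-frequency residual; values
#'   between 0.2 and 0.7 give increasing sharpening (default 0.5).
#' @param smooth_sigma Gaussian standard deviation of the smoothing that
#'   produces the blurred reference (default 2.0 px).
#' @param allow_any_gain set `TRUE` to bypass the `[0.2, 0.7]` range check.
#' @return an object of class `unsharp_config`.
#' @export
unsharp_config <- function(gain_k = 0.5, smooth_sigma = 2.0,
                           allow_any_gain = FALSE) {
  if (!allow_any_gain && (gain_k < 0.2 || gain_k > 0.7)) {
    stop("gain_k outside [0.2, 0.7]; set allow_any_gain = TRUE to override",
         call. = FALSE)
  }
  stopifnot(smooth_sigma > 0)
  structure(list(gain_k = gain_k, smooth_sigma = smooth_sigma),
            class = "unsharp_config")
}

#' Unsharp masking
#'
#' Adds back a scaled high-frequency residual: `g = img - smooth(img)`;
#' `out = clip(img + gain_k * g, 0, 1)`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param config an [unsharp_config].
#' @return sharpened matrix in `[0, 1]`.
#' @export
unsharp_enhance <- function(img, config = unsharp_config()) {
  assert_gray(img)
  g <- img - gaussian_smooth(img, config$smooth_sigma)
  clip01(img + config$gain_k * g)
}
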