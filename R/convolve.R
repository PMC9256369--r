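# Internal 2-D convolution helpers.
#
# The Gabor bank needs 'same'-size true convolution with reflect padding and
# even-sized (60x60) complex kernels; EBImage::filter2 requires odd kernel
# dimensions and circular boundaries, so the FFT path lives here. Verified
# against a direct double-loop convolution oracle in the test suite.

# Reflect (mirror-with-edge) padding. Pad widths must not exceed the image.
reflect_pad <- function(mat, top, bottom, left, right) {
  n <- nrow(mat); m <- ncol(mat)
  stopifnot(top <= n, bottom <= n, left <= m, right <= m)
  ri <- c(rev(seq_len(top)), seq_len(n), n + 1L - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(m), m + 1L - seq_len(right))
  mat[ri, ci, drop = FALSE]
}

# Replicate (clamp-to-edge) padding, any width.
replicate_pad <- function(mat, pad) {
  n <- nrow(mat); m <- ncol(mat)
  ri <- pmin(pmax(seq_len(n + 2L * pad) - pad, 1L), n)
  ci <- pmin(pmax(seq_len(m + 2L * pad) - pad, 1L), m)
  mat[ri, ci, drop = FALSE]
}

# FFT size with small prime factors at or above n (prime sizes make
# stats::fft quadratic).
good_fft_size <- function(n) {
  k <- n
  repeat {
    r <- k
    for (p in c(2L, 3L, 5L, 7L)) while (r %% p == 0L) r <- r %/% p
    if (r == 1L) return(k)
    k <- k + 1L
  }
}

# 'Same'-size true convolution (kernel flipped) with reflect padding.
# Output pixel (r, c) aligns the kernel's geometric center over (r, c);
# for even kernels the center falls on the lower-right of the middle four.
# Kernel may be complex. Image must be at least as large as the kernel.
conv2_reflect <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  H <- nrow(img); W <- ncol(img)
  stopifnot(H >= kh, W >= kw)
  pt <- kh - 1L; pl <- kw - 1L
  P <- reflect_pad(img, pt, pt, pl, pl)
  FH <- good_fft_size(nrow(P) + kh - 1L)
  FW <- good_fft_size(ncol(P) + kw - 1L)
  Ai <- matrix(0, FH, FW)
  Ai[seq_len(nrow(P)), seq_len(ncol(P))] <- P
  Ak <- matrix(0i, FH, FW)
  Ak[seq_len(kh), seq_len(kw)] <- kernel
  full <- stats::fft(stats::fft(Ai) * stats::fft(Ak), inverse = TRUE) / (FH * FW)
  rows <- seq_len(H) + pt + floor(kh / 2)
  cols <- seq_len(W) + pl + floor(kw / 2)
  out <- full[rows, cols, drop = FALSE]
  if (is.complex(kernel)) out else Re(out)
}

# Direct 3x3 true convolution with reflect padding via shifted sums —
# cheap enough for the inner loop of the PSO fitness function.
conv3x3_reflect <- function(img, k) {
  stopifnot(identical(dim(k), c(3L, 3L)))
  H <- nrow(img); W <- ncol(img)
  P <- reflect_pad(img, 1L, 1L, 1L, 1L)
  out <- matrix(0, H, W)
  for (di in -1:1) {
    for (dj in -1:1) {
      out <- out + k[2L + di, 2L + dj] *
        P[seq_len(H) + 1L - di, seq_len(W) + 1L - dj, drop = FALSE]
    }
  }
  out
}
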