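test_that("FFT convolution matches direct summation with reflect padding", {
  set.seed(5)
  img <- matrix(runif(13 * 11), 13, 11)
  for (ks in c(3L, 5L)) {
    k_real <- matrix(rnorm(ks^2), ks, ks)
    expect_equal(vesselseg:::conv2_reflect(img, k_real),
                 oracle_conv2_direct(img, k_real), tolerance = 1e-10)
    k_cplx <- matrix(complex(real = rnorm(ks^2), imaginary = rnorm(ks^2)),
                     ks, ks)
    expect_equal(vesselseg:::conv2_reflect(img, k_cplx),
                 oracle_conv2_direct(img, k_cplx), tolerance = 1e-10)
  }
})

test_that("Gabor kernels have the stated symmetry, center value and near-zero sum", {
  cfg <- gabor_bank_config()
  n <- cfg$n_orientations
  for (u in 0:(n - 1)) {
    kern <- build_gabor_kernel(cfg, u, 0L)
    expect_identical(dim(kern), c(60L, 60L))
    # 180-degree symmetry of the plane wave: point reflection about the
    # geometric center conjugates the kernel
    flipped <- kern[rev(seq_len(60)), rev(seq_len(60))]
    expect_equal(flipped, Conj(kern), tolerance = 1e-12)
    # DC compensation: the compensated sum is far below the uncompensated
    # oscillatory sum and stays under 5% of the peak magnitude (the residual
    # is pure pixel-sampling aliasing of the narrow default envelope)
    kv <- cfg$k_max; sig <- cfg$sigma
    x <- seq_len(60) - 30.5
    X <- matrix(x, 60, 60, byrow = TRUE); Y <- matrix(x, 60, 60)
    phi <- pi * u / n + pi / 2
    uncomp <- sum((kv^2 / sig) * exp(-kv^2 * (X^2 + Y^2) / (2 * sig^2)) *
                    exp(1i * kv * (cos(phi) * X + sin(phi) * Y)))
    expect_lt(Mod(sum(kern)), 0.05 * max(Mod(kern)))
    expect_lt(Mod(sum(kern)), 0.1 * Mod(uncomp))
  }
  # center value of the odd-sized variant: (||k||^2/sigma)(1 - exp(-sigma^2/2))
  cfg_odd <- gabor_bank_config(kernel_width = 61L, kernel_height = 61L)
  kern <- build_gabor_kernel(cfg_odd, 0L, 0L)
  expect_equal(kern[31, 31],
               (cfg$k_max^2 / cfg$sigma) * (1 - exp(-cfg$sigma^2 / 2)) + 0i,
               tolerance = 1e-12)
  expect_error(build_gabor_kernel(cfg, 8L, 0L), "out of range")
  expect_error(build_gabor_kernel(cfg, 0L, 1L), "scales")
})

test_that("constant images give an identically zero max response", {
  cfg <- gabor_bank_config()
  resp <- gabor_max_response(matrix(0.37, 70, 70), cfg)
  expect_identical(resp, array(0, c(70, 70)))
})

test_that("response is offset-invariant and contrast-scale-invariant after rescale", {
  set.seed(6)
  cfg <- gabor_bank_config()
  img <- matrix(runif(70 * 70, 0.05, 0.45), 70, 70)
  base <- gabor_max_response(img, cfg)
  shifted <- gabor_max_response(img + 0.05, cfg)
  expect_lt(max(abs(base - shifted)), 1e-2)
  # doubling contrast doubles raw responses (linearity of convolution),
  # leaving the rescaled output unchanged
  expect_lt(max(abs(base - gabor_max_response(2 * img, cfg))), 1e-9)
  expect_true(all(base >= 0) && all(base <= 1))
  expect_identical(dim(base), dim(img))
  expect_error(gabor_max_response(matrix(0.5, 30, 30), cfg), "smaller")
})

test_that("a dark line at angle phi_u is attributed to orientation u", {
  cfg <- gabor_bank_config()
  # Gaussian-profile ridges: an aliasing-free dark line at each angle
  rr <- matrix(1:100, 100, 100) - 50.5
  cc <- matrix(1:100, 100, 100, byrow = TRUE) - 50.5
  for (u0 in 0:7) {
    phi <- pi * u0 / 8
    perp <- abs(cc * sin(phi) - rr * cos(phi))
    along <- abs(cc * cos(phi) + rr * sin(phi))
    im <- 0.8 - 0.6 * exp(-perp^2 / 2) * (along <= 45)
    om <- gabor_orientation_map(im, cfg)
    core <- perp <= 1 & along <= 40
    expect_gt(mean(om[core] == u0), 0.5)
  }
})

test_that("the kernel bank exports as a multi-page TIFF", {
  cfg <- gabor_bank_config(kernel_width = 16L, kernel_height = 16L,
                           n_orientations = 2L)
  path <- withr::local_tempfile(fileext = ".tif")
  export_gabor_bank(cfg, path)
  frames <- EBImage::readImage(path)
  expect_identical(dim(frames)[3], 4L)  # 2 orientations x (real, imag)
})
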