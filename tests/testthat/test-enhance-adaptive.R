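test_that("tanh gain maps hit their closed-form anchors and decrease", {
  expect_equal(intensity_gain_map(0.75), 0.5)
  expect_equal(edge_gain_map(1.0), 0.5)
  expect_equal(intensity_gain_map(0.5), 0.5 * (1 + tanh(3)), tolerance = 1e-6)
  expect_equal(edge_gain_map(0.5), 0.5 * (1 + tanh(3)), tolerance = 1e-6)
  g <- seq(0, 1, by = 0.1)
  expect_true(all(diff(intensity_gain_map(g)) < 0))
  expect_true(all(diff(edge_gain_map(g)) < 0))
  # gains live strictly inside (0, 1); the product never exceeds either factor
  lg <- intensity_gain_map(g); ld <- edge_gain_map(g)
  expect_true(all(lg > 0 & lg < 1 & ld > 0 & ld < 1))
  expect_true(all(lg * ld <= pmin(lg, ld)))
})

test_that("sharpness is the mean forward-difference gradient", {
  expect_equal(sharpness_measure(matrix(0.5, 4, 4)), 0)
  # horizontal ramp: per-column step c on every interior pixel
  ramp <- matrix(rep(seq(0, 0.9, by = 0.1), each = 8), 8, 10)
  G <- sharpness_measure(ramp)
  # interior pixels contribute |c| = 0.1; the last column contributes 0
  expect_equal(G, 0.1 * (10 - 1) / 10, tolerance = 1e-12)
  set.seed(14)
  img <- matrix(runif(35), 5, 7)
  loop <- 0
  for (p in 1:5) {
    for (q in 1:7) {
      dx <- if (p < 5) img[p, q] - img[p + 1, q] else 0
      dy <- if (q < 7) img[p, q] - img[p, q + 1] else 0
      loop <- loop + sqrt(dx^2 + dy^2)
    }
  }
  expect_equal(sharpness_measure(img), loop / 35, tolerance = 1e-12)
  expect_error(sharpness_measure(matrix(0.5, 1, 5)), "2 x 2")
})

test_that("colourfulness vanishes on grayscale and matches the pure-red closed form", {
  set.seed(15)
  g <- matrix(runif(64), 8, 8)
  expect_equal(colourfulness_measure(rgb_image(g, g, g)), 0)
  red <- rgb_image(matrix(1, 6, 6), matrix(0, 6, 6), matrix(0, 6, 6))
  expect_equal(colourfulness_measure(red), 0.3 * sqrt(1.25), tolerance = 1e-12)
  # pixel shuffling leaves the statistic unchanged
  r <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  img <- rgb_image(r, g, b)
  perm <- sample(64)
  shuf <- rgb_image(matrix(r[perm], 8, 8), matrix(g[perm], 8, 8),
                    matrix(b[perm], 8, 8))
  expect_equal(colourfulness_measure(img), colourfulness_measure(shuf),
               tolerance = 1e-12)
})

test_that("adaptive unsharp masking sharpens without shifting hue", {
  const <- rgb_image(matrix(0.5, 70, 70), matrix(0.4, 70, 70),
                     matrix(0.3, 70, 70))
  out <- adaptive_usm_enhance(const)
  expect_equal(out$green, const$green, tolerance = 1e-9)
  # a blurred phantom regains sharpness
  ph <- small_phantom()
  blur <- vesselseg:::clip01(vesselseg:::gaussian_smooth(ph$image$green, 2))
  enh <- adaptive_usm_enhance_gray(blur)
  expect_gte(sharpness_measure(enh), sharpness_measure(blur))
  # channel ratios preserved wherever no channel clipped
  set.seed(16)
  r <- matrix(runif(100, 0.2, 0.6), 10, 10)
  img <- rgb_image(r, r * 0.8, r * 0.5)
  out2 <- adaptive_usm_enhance(img)
  intens <- (img$red + img$green + img$blue) / 3
  i2 <- (out2$red + out2$green + out2$blue) / 3
  unclipped <- out2$red < 1 & out2$green < 1 & out2$blue < 1 &
    out2$red > 0 & i2 > 0
  ratio_in <- img$green[unclipped] / img$red[unclipped]
  ratio_out <- out2$green[unclipped] / out2$red[unclipped]
  expect_equal(ratio_out, ratio_in, tolerance = 1e-9)
})

test_that("quality report combines the three measures", {
  ph <- small_phantom()
  qr <- quality_report(ph$image)
  expect_gt(qr$sharpness, 0)
  expect_gt(qr$colourfulness, 0)
  expect_true(qr$entropy >= 0 && qr$entropy <= 8)
  qg <- quality_report(ph$image$green)
  expect_identical(qg$colourfulness, 0)
})
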