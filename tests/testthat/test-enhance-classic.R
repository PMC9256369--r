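test_that("weighted cdf handles single, double and uniform histograms", {
  cfg <- gcadw_config(n_levels = 8L)
  h1 <- c(0, 0, 5, 0, 0, 0, 0, 0)
  cdf1 <- compute_weighted_cdf(h1, cfg)
  expect_equal(cdf1, c(0, 0, rep(1, 6)))
  # two equally occupied levels: pdf - pdf_min symmetric, so 0.5 then 1.0
  h2 <- c(0, 3, 0, 0, 3, 0, 0, 0)
  cdf2 <- compute_weighted_cdf(h2, cfg)
  expect_equal(cdf2[2], 0.5)
  expect_equal(cdf2[5], 1.0)
  # uniform histogram degenerates to the unweighted cdf
  h3 <- rep(2, 8)
  expect_equal(compute_weighted_cdf(h3, cfg), cumsum(rep(1 / 8, 8)))
  expect_error(compute_weighted_cdf(rep(0, 8), cfg), "all-zero")
  expect_false(is.unsorted(compute_weighted_cdf(c(1, 5, 2, 9, 0, 0, 3, 1), cfg)))
})

test_that("gamma correction fixes constants and l_max and matches per-level oracle", {
  expect_equal(gcadw_enhance(matrix(0.4, 6, 6)), matrix(0.4, 6, 6))
  set.seed(8)
  img <- matrix(sample(c(64, 192), 64, TRUE) / 255, 8, 8)
  out <- gcadw_enhance(img)
  # independent per-level scalar evaluation
  lev <- floor(img * 255 + 0.5)
  h <- tabulate(lev + 1, 256)
  pdf <- h / sum(h)
  pw <- max(pdf) * ((pdf - min(pdf)) / (max(pdf) - min(pdf)))^0.5
  cdfw <- cumsum(pw) / sum(pw)
  l_max <- max(lev)
  expected <- matrix(0, 8, 8)
  for (i in seq_along(lev)) {
    expected[i] <- l_max * (lev[i] / l_max)^(1 - cdfw[lev[i] + 1]) / 255
  }
  expect_equal(out, expected, tolerance = 1e-12)
  # the maximum occupied level is a fixed point
  expect_equal(max(out), max(img))
  # the level mapping is non-decreasing
  set.seed(9)
  img2 <- matrix(runif(256), 16, 16)
  out2 <- gcadw_enhance(img2)
  ord <- order(img2)
  expect_false(is.unsorted(out2[ord]))
})

test_that("homomorphic transfer runs from the low gain to the high gain", {
  cfg <- homomorphic_config()
  expect_equal(homomorphic_transfer(0, cfg, 10), 0.6)
  expect_equal(homomorphic_transfer(1e9, cfg, 10), 0.8)
  p <- seq(0, 100, by = 0.5)
  expect_false(is.unsorted(homomorphic_transfer(p, cfg, 10)))
  expect_error(homomorphic_config(gamma_high = 0.5, gamma_low = 0.6))
})

test_that("homomorphic filtering maps constants to constants and stays in range", {
  out <- homomorphic_enhance(matrix(0.6, 32, 32))
  expect_equal(max(out) - min(out), 0)
  set.seed(10)
  img <- matrix(runif(48 * 40), 48, 40)
  out2 <- homomorphic_enhance(img)
  expect_identical(dim(out2), dim(img))
  expect_true(min(out2) >= 0 && max(out2) <= 1)
})

test_that("neighborhood mean uses replicate padding", {
  expect_equal(neighborhood_mean(matrix(0.3, 5, 5)), matrix(0.3, 5, 5))
  img <- matrix((1:9) / 10, 3, 3, byrow = TRUE)
  expect_equal(neighborhood_mean(img)[2, 2], 0.5)
  img2 <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(neighborhood_mean(img2)[1, 1], 1 / 3)
  expect_error(neighborhood_mean(matrix(0.5, 4, 4), 4L), "odd")
})

test_that("joint equalization reproduces its worked example and the pair oracle", {
  # the published 6x6 worked example: CDF 11, CDF_min 1, MN 36, L 256 -> 72
  expect_identical(jeh_level_map(11, 1, 36, 256), 72L)
  # constant image: single occupied pair, numerator zero
  expect_equal(jeh_equalize(matrix(0.7, 6, 6)), matrix(0, 6, 6))
  set.seed(12)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 36, TRUE) / 255, 6, 6)
    expect_equal(jeh_equalize(img), oracle_jeh(img), tolerance = 1e-12)
  }
  # pixels sharing a (value, mean) pair share an output level
  img <- matrix(sample(0:3, 100, TRUE) / 255, 10, 10)
  ws <- jeh_workspace(img)
  out <- jeh_equalize(img)
  key <- paste(ws$f, ws$g)
  expect_true(all(tapply(as.vector(out), key,
                         function(v) length(unique(v))) == 1))
})

test_that("joint histogram workspace invariants hold", {
  set.seed(13)
  img <- matrix(runif(144), 12, 12)
  ws <- jeh_workspace(img)
  expect_equal(sum(ws$joint_histogram), 144)
  expect_gte(ws$cdf_min, 1)
  expect_false(any(apply(ws$cdf2d, 1, is.unsorted)))
  expect_false(any(apply(ws$cdf2d, 2, is.unsorted)))
})

test_that("unsharp masking sharpens a step with overshoot and fixes constants", {
  img <- matrix(0.5, 8, 8)
  cfg0 <- unsharp_config(gain_k = 0, allow_any_gain = TRUE)
  expect_equal(unsharp_enhance(img, cfg0), img)
  expect_equal(unsharp_enhance(img), img, tolerance = 1e-9)
  step <- matrix(rep(c(0.3, 0.7), each = 16), 16, 32, byrow = TRUE)
  out <- unsharp_enhance(step, unsharp_config(gain_k = 0.5))
  expect_gt(max(out[, 20]), 0.7)   # overshoot above the high level
  expect_lt(min(out[, 13]), 0.3)   # undershoot below the low level
  expect_error(unsharp_config(gain_k = 0.9), "0.2")
})
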