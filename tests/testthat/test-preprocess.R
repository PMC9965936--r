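test_that("median filter removes impulses and matches the window-sort oracle", {
  # constant image is a fixed point
  expect_equal(median_filter(matrix(7, 5, 5), 3), matrix(7, 5, 5))
  # a single salt pixel in a flat image is restored
  img <- matrix(0, 8, 8); img[4, 4] <- 255
  expect_true(all(median_filter(img, 3) == 0))
  # random images against the exhaustive oracle, two window sizes
  set.seed(101)
  for (w in c(3, 5)) {
    img <- random_gray_image(16, 16)
    expect_equal(median_filter(img, w), oracle_median_filter(img, w))
  }
  expect_error(median_filter(img, 4), "odd")
  expect_error(median_filter(img, 1), "odd")
})

test_that("median output pixels are members of their input window", {
  set.seed(7)
  img <- random_gray_image(12, 12)
  out <- median_filter(img, 3)
  pad <- hhocnn:::edge_pad(img, 1)
  for (r in seq_len(12)) {
    for (c in seq_len(12)) {
      expect_true(out[r, c] %in% pad[r:(r + 2), c:(c + 2)])
    }
  }
})

test_that("median filtering reduces the impulse-corrupted pixel count", {
  spec <- phantom_spec(noise_sigma = 0, salt_pepper = 0.1, seed = 31)
  clean <- hhocnn:::phantom_template(spec)$image
  noisy <- generate_phantom(spec)$image
  filtered <- median_filter(noisy, 3)
  expect_lt(sum(filtered != clean), sum(noisy != clean))
})

test_that("histogram PDF and CDF follow the counting definitions", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)
  h <- compute_histogram(img)
  expect_equal(h$pdf[1], 0.5)
  expect_equal(h$pdf[2], 0.5)
  expect_equal(h$cdf[2], 1.0)

  const <- compute_histogram(matrix(42, 3, 3))
  expect_equal(sum(const$pdf > 0), 1L)
  expect_equal(const$pdf[43], 1)

  set.seed(5)
  img <- random_gray_image(32, 32)
  h <- compute_histogram(img)
  expect_equal(sum(h$pdf), 1, tolerance = 1e-12)
  expect_equal(h$cdf, cumsum(tabulate(img + 1, 256) / length(img)))
  expect_true(all(diff(h$cdf) >= 0))
})

test_that("split points implement the CDF-weighted mean recursion", {
  # t = 1: no interior points, single full interval
  img <- matrix(c(10, 20, 30, 40), 2, 2)
  h <- compute_histogram(img)
  s1 <- split_points(h, 1)
  expect_length(s1, 0L)
  expect_equal(attr(s1, "intervals"), matrix(c(0L, 255L), 1))

  # two-delta histogram: split equals the directly evaluated weighted mean
  img2 <- matrix(rep(c(50, 150), 8), 4, 4)
  h2 <- compute_histogram(img2)
  s2 <- split_points(h2, 2)
  lv <- which(h2$counts > 0) - 1
  x_direct <- sum(lv * h2$cdf[lv + 1]) / sum(h2$cdf[lv + 1])
  expect_equal(as.integer(s2), as.integer(floor(x_direct)))

  # t = 2 on any histogram: one interior split, both halves occupied
  set.seed(12)
  for (i in 1:5) {
    img3 <- random_gray_image(8, 8)
    h3 <- compute_histogram(img3)
    s3 <- split_points(h3, 2)
    expect_length(s3, 1L)
    occ <- which(h3$counts > 0) - 1
    expect_gt(sum(occ <= s3), 0)
    expect_gt(sum(occ > s3), 0)
  }

  expect_error(split_points(compute_histogram(matrix(9, 2, 2)), 2), "occupied")
})

test_that("equalization matches classical HE for t = 1 and fixes constants", {
  expect_equal(equalize(matrix(99, 6, 6), 2), matrix(99, 6, 6))

  # 4-level toy image: t = 1 equals the classical cdf-mapping oracle
  img <- matrix(c(rep(10, 8), rep(20, 4), rep(30, 2), rep(200, 2)), 4, 4)
  expect_equal(equalize(img, 1), oracle_global_he(img))

  set.seed(3)
  rnd <- random_gray_image(16, 16, levels = 64) * 4
  expect_equal(equalize(rnd, 1), oracle_global_he(rnd))
})

test_that("equalization stays in range and preserves intensity order", {
  ramp <- matrix(rep(seq(5, 250, length.out = 32), each = 8), 8, 32)
  ramp <- round(ramp)
  for (t in c(1, 2, 4)) {
    out <- equalize(ramp, t)
    expect_true(all(out >= 0 & out <= 255))
    # along the monotone ramp the output stays monotone nondecreasing
    expect_true(all(diff(out[1, ]) >= 0))
  }
  set.seed(23)
  for (i in 1:5) {
    img <- random_gray_image(12, 12)
    out <- equalize(img, 2)
    expect_true(all(out >= 0 & out <= 255))
    expect_true(all(diff(level_mapping(img, out)) >= 0))
  }
})
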