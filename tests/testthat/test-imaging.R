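test_that("grayscale conversion applies the BT.601 luminance weights", {
  white <- array(255, c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))

  red <- array(0, c(3, 3, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == 76))  # round(0.299 * 255)

  set.seed(1)
  img <- array(sample(0:255, 12, TRUE), c(2, 2, 3))
  manual <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  expect_equal(to_grayscale(img), manual)
  expect_equal(dim(to_grayscale(img)), c(2L, 2L))
  expect_error(to_grayscale(array(0, c(0, 2, 3))), "empty|H x W")
})

test_that("CIELAB conversion matches the CIE reference behaviour", {
  white <- to_cielab(array(255, c(1, 1, 3)))
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-3)
  expect_equal(abs(white[1, 1, 2]) < 0.01, TRUE)
  expect_equal(abs(white[1, 1, 3]) < 0.01, TRUE)

  black <- to_cielab(array(0, c(1, 1, 3)))
  expect_true(all(abs(black) < 1e-8))

  gray <- to_cielab(array(119, c(1, 1, 3)))
  expect_lt(abs(gray[1, 1, 2]), 0.01)
  expect_lt(abs(gray[1, 1, 3]), 0.01)

  set.seed(2)
  img <- array(sample(0:255, 60, TRUE), c(4, 5, 3))
  ref <- grDevices::convertColor(matrix(img, ncol = 3) / 255,
                                 from = "sRGB", to = "Lab")
  expect_equal(matrix(to_cielab(img), ncol = 3), unname(ref), tolerance = 0.5)
})

test_that("gamma correction encodes with exponent 1/gamma and fixes 0/255", {
  img <- array(sample(0:255, 27, TRUE), c(3, 3, 3))
  expect_equal(apply_gamma(img, 1), img)
  expect_equal(apply_gamma(array(128, c(1, 1, 3)), 2)[1, 1, 1], 181)
  extremes <- array(c(0, 255), c(1, 2, 3))
  for (g in c(0.3, 1, 2.5)) expect_equal(apply_gamma(extremes, g), extremes)
  expect_error(apply_gamma(img, 0), "positive")
  expect_error(apply_gamma(img, -1), "positive")
  out <- apply_gamma(img, 0.4)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("median filter matches the brute-force sort oracle", {
  const <- matrix(7, 9, 9)
  expect_equal(median_filter(const, 7), const)

  z <- matrix(0, 12, 12); z[6, 6] <- 255
  expect_true(all(median_filter(z, 7) == 0))

  set.seed(3)
  for (k in 1:10) {
    m <- matrix(as.numeric(sample(0:255, 256, TRUE)), 16, 16)
    for (w in c(3, 7)) expect_equal(median_filter(m, w),
                                    naive_median_filter(m, w))
  }
  expect_error(median_filter(const, 4), "odd")
})

test_that("median filter is idempotent on flat-boundary binary masks", {
  for (m in list(matrix(1, 20, 20),
                 {b <- matrix(0, 30, 30); b[, 10:20] <- 1; b},
                 {b <- matrix(0, 30, 30); b[8:22, ] <- 1; b},
                 {b <- matrix(0, 40, 40); b[, c(5:12, 25:36)] <- 1; b})) {
    once <- median_filter(m, 7)
    expect_equal(median_filter(once, 7), once)
  }
})

test_that("image files round-trip through 8-bit PNG", {
  img <- array(as.numeric(sample(0:255, 300, TRUE)), c(10, 10, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  expect_equal(read_image(path), img)
})
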