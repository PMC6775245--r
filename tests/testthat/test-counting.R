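test_that("binarization uses the >= threshold convention", {
  expect_true(all(binarize(matrix(0.9, 3, 3)) == 1))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5) == 1))
  set.seed(18)
  m <- matrix(runif(100), 10, 10)
  expect_equal(binarize(m, 0.3), (m >= 0.3) + 0)
  expect_error(binarize(m, 0), "threshold")
})

test_that("counting handles empty, single and multiple objects", {
  expect_equal(count_ears(matrix(0, 30, 30))$count, 0L)

  disk <- matrix(0, 40, 40)
  g <- expand.grid(y = 1:40, x = 1:40)
  disk[(g$y - 20)^2 + (g$x - 20)^2 <= 100] <- 1
  res <- count_ears(disk)
  expect_equal(res$count, 1L)
  expect_length(res$contours, 1L)

  sc <- generate_scene(sparse_scene_params(3))
  res <- count_ears(sc$ear_mask)
  expect_equal(res$count, sc$true_count)
  expect_equal(length(res$contours), res$count)
})

test_that("touching disks with distinct centers are separated", {
  res <- count_ears(two_disk_mask(0.3), min_area = 10)
  expect_equal(res$count, 2L)
})

test_that("counting is monotone under disjoint far-away additions", {
  sc <- generate_scene(sparse_scene_params(2))
  base <- count_ears(sc$ear_mask)$count
  grown <- rbind(sc$ear_mask, matrix(0, 40, ncol(sc$ear_mask)))
  g <- expand.grid(y = 1:40, x = 1:40)
  blob <- matrix(0, 40, ncol(sc$ear_mask))
  blob[cbind(g$y, g$x)[(g$y - 20)^2 + (g$x - 20)^2 <= 64, ]] <- 1
  grown[nrow(sc$ear_mask) + seq_len(40), ] <- blob
  expect_equal(count_ears(grown)$count, base + 1L)
})

test_that("counting is translation invariant", {
  sc <- generate_scene(sparse_scene_params(4))
  m <- sc$ear_mask
  big <- matrix(0, nrow(m) + 20, ncol(m) + 20)
  big[11:(10 + nrow(m)), 11:(10 + ncol(m))] <- m
  big0 <- matrix(0, nrow(m) + 20, ncol(m) + 20)
  big0[1:nrow(m), 1:ncol(m)] <- m
  expect_equal(count_ears(big)$count, count_ears(big0)$count)
})

test_that("ear density follows the ground-standard closed form", {
  gs <- ground_standard(rbind(c(0, 0), c(77, 0), c(77, 81), c(0, 81)))
  expect_equal(gs$pixel_area, 6237)
  expect_equal(ears_per_m2(500, gs, c(1000, 1000)), 50)
  expect_equal(ears_per_m2(0, gs, c(1000, 1000)), 0)

  # uniform rescaling leaves the density unchanged
  for (f in c(2, 3)) {
    gsf <- ground_standard(rbind(c(0, 0), c(77 * f, 0), c(77 * f, 81 * f),
                                 c(0, 81 * f)))
    expect_equal(ears_per_m2(500, gsf, c(1000 * f, 1000 * f)), 50)
  }
  expect_error(ground_standard(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               "degenerate")
})

test_that("the ground standard is detected within tight pixel tolerances", {
  for (s in c(1, 5, 9)) {
    sc <- generate_scene(scene_params(include_standard = TRUE, seed = s))
    gs <- detect_ground_standard(sc$image)
    tr <- sc$standard_corners
    err <- vapply(1:4, function(i)
      min(sqrt(colSums((t(gs$corners) - tr[i, ])^2))), 0)
    expect_lte(max(err), 2)
    truth <- ground_standard(tr)
    expect_lte(abs(gs$pixel_area / truth$pixel_area - 1), 0.05)
  }
  plain <- generate_scene(scene_params(seed = 2))
  expect_error(detect_ground_standard(plain$image), "manual")
})

test_that("overlays draw contours non-destructively", {
  sc <- generate_scene(sparse_scene_params(5))
  res <- count_ears(sc$ear_mask)
  before <- sc$image
  over <- render_overlay(sc$image, res)
  expect_identical(sc$image, before)
  expect_false(identical(over, before))

  empty <- structure(list(mask = sc$ear_mask * 0, contours = list(),
                          count = 0L, ears_per_m2 = NA_real_),
                     class = "count_result")
  expect_identical(render_overlay(sc$image, empty), sc$image)
})
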