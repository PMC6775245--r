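test_that("center initialization lays a near-regular grid", {
  img <- array(128, c(10, 10, 3))
  lab <- to_cielab(img)
  ctr <- initialize_centers(lab, slic_params(4))
  expect_equal(nrow(ctr), 4L)
  got <- ctr[order(ctr[, "y"], ctr[, "x"]), c("x", "y")]
  want <- rbind(c(2.5, 2.5), c(7.5, 2.5), c(2.5, 7.5), c(7.5, 7.5))
  expect_true(max(abs(got - want)) <= 1)  # uniform image: no perturbation pull

  one_per_px <- initialize_centers(lab, slic_params(100))
  expect_equal(nrow(one_per_px), 100L)
  expect_error(initialize_centers(lab, slic_params(101)), "exceeds")
})

test_that("slic partitions the image and is deterministic", {
  set.seed(5)
  img <- array(sample(0:255, 48 * 48 * 3, TRUE), c(48, 48, 3))
  p <- slic_params(9)
  a <- slic_segment(img, p)
  b <- slic_segment(img, p)
  expect_identical(a$labels, b$labels)
  expect_equal(sum(tabulate(a$labels)), 48 * 48)
  expect_gte(a$K, 1L)
  expect_true(all(sort(unique(c(a$labels))) == seq_len(a$K)))
})

test_that("uniform images yield near-square equal superpixels", {
  img <- array(128, c(64, 64, 3))
  sp <- slic_segment(img, slic_params(16))
  sizes <- tabulate(sp$labels)
  expect_equal(sp$K, 16L)
  expect_true(all(abs(sizes - 256) <= 0.2 * 256))
})

test_that("large compactness pins boundaries to the initialization grid", {
  img <- array(128, c(64, 64, 3))
  sp <- slic_segment(img, slic_params(16, compactness = 1000))
  sizes <- tabulate(sp$labels)
  expect_true(all(sizes == 256))
  for (k in seq_len(sp$K)) {  # every region is an exact 16 x 16 block
    idx <- which(sp$labels == k, arr.ind = TRUE)
    expect_equal(diff(range(idx[, 1])), 15)
    expect_equal(diff(range(idx[, 2])), 15)
  }
})

test_that("a strong color split dominates the segmentation", {
  img <- array(0, c(12, 12, 3))
  img[, 1:6, 1] <- 255
  img[, 7:12, 3] <- 255
  sp <- slic_segment(img, slic_params(2))
  expect_equal(sp$K, 2L)
  expect_equal(length(unique(c(sp$labels[, 1:6]))), 1L)
  expect_equal(length(unique(c(sp$labels[, 7:12]))), 1L)
  expect_true(sp$labels[1, 1] != sp$labels[1, 12])
})

test_that("windowed assignment equals global 5-D k-means on small images", {
  set.seed(6)
  for (case in 1:4) {
    H <- sample(10:16, 1); W <- sample(10:16, 1)
    N <- sample(2:4, 1)
    img <- array(sample(0:255, H * W * 3, TRUE), c(H, W, 3))
    p <- slic_params(N)
    oracle <- global_kmeans_slic(img, p)
    lab <- to_cielab(img)
    S <- sqrt(H * W / N)
    got <- slic_iterate_cpp(lab[, , 1], lab[, , 2], lab[, , 3],
                            initialize_centers(lab, p), S,
                            p$compactness, p$max_iterations)$labels + 1L
    expect_equal(got, oracle)
  }
})

test_that("superpixel boundaries adhere to a two-tone edge", {
  set.seed(7)
  img <- array(0, c(64, 64, 3))
  img[, 1:32, 2] <- 200
  img[, 33:64, 1] <- 180
  img[, 33:64, 3] <- 40
  img <- img + array(rnorm(64 * 64 * 3, 0, 3), c(64, 64, 3))
  img <- pmin(pmax(round(img), 0), 255)
  sp <- slic_segment(img, slic_params(16))
  b <- superpixel_boundaries(sp)
  recall <- mean(vapply(seq_len(64),
                        function(r) any(b[r, 31:33]), logical(1)))
  expect_gte(recall, 0.95)
})

test_that("connectivity enforcement absorbs islands and splits shared labels", {
  # 1-pixel island inside a large region
  labels <- matrix(1L, 10, 10)
  labels[5, 5] <- 2L
  map <- structure(list(labels = labels, K = 2L, params = slic_params(2)),
                   class = "superpixel_map")
  out <- enforce_connectivity(map)
  expect_equal(out$K, 1L)
  expect_true(all(out$labels == 1L))

  # one label in two disconnected parts: the small part is merged away
  labels <- matrix(1L, 10, 10)
  labels[, 6:10] <- 2L
  labels[9:10, 9:10] <- 1L
  map <- structure(list(labels = labels, K = 2L, params = slic_params(2)),
                   class = "superpixel_map")
  out <- enforce_connectivity(map)
  expect_equal(out$K, 2L)
  expect_equal(out$labels[10, 10], out$labels[1, 10])

  # already-connected maps only get relabeled
  labels <- matrix(rep(1:2, each = 50), 10, 10)
  map <- structure(list(labels = labels, K = 2L, params = slic_params(2)),
                   class = "superpixel_map")
  out <- enforce_connectivity(map)
  expect_equal(tabulate(out$labels), c(50, 50))
})

test_that("extracted regions tile the image exactly once", {
  img <- array(as.numeric(sample(0:255, 300, TRUE)), c(10, 10, 3))

  whole <- structure(list(labels = matrix(1L, 10, 10), K = 1L,
                          params = slic_params(1)), class = "superpixel_map")
  regions <- extract_regions(img, whole)
  expect_length(regions, 1L)
  expect_equal(regions[[1]]$crop, img)
  expect_true(all(regions[[1]]$mask))
  expect_equal(regions[[1]]$box, c(0L, 0L, 10L, 10L))

  quad <- matrix(1L, 10, 10)
  quad[1:5, 6:10] <- 2L; quad[6:10, 1:5] <- 3L; quad[6:10, 6:10] <- 4L
  qmap <- structure(list(labels = quad, K = 4L, params = slic_params(4)),
                    class = "superpixel_map")
  regions <- extract_regions(img, qmap)
  expect_length(regions, 4L)
  for (r in regions) {
    expect_equal(dim(r$crop)[1:2], c(5L, 5L))
    expect_true(all(r$mask))
  }

  # irregular region: bounding box contains foreign pixels, excluded by mask
  irr <- matrix(1L, 10, 10)
  irr[3:7, 3:7] <- 2L
  irr[5, 5] <- 1L  # hole owned by the other label
  imap <- structure(list(labels = irr, K = 2L, params = slic_params(2)),
                    class = "superpixel_map")
  regions <- extract_regions(img, imap)
  r2 <- regions[[2]]
  expect_false(r2$mask[3, 3])
  cover <- matrix(0L, 10, 10)
  for (r in regions) {
    rows <- (r$box[2] + 1):r$box[4]; cols <- (r$box[1] + 1):r$box[3]
    cover[rows, cols] <- cover[rows, cols] + r$mask
  }
  expect_true(all(cover == 1L))
})

test_that("superpixel maps round-trip through the PNG serialization", {
  set.seed(8)
  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  sp <- slic_segment(img, slic_params(6, compactness = 12))
  path <- withr::local_tempfile(fileext = ".png")
  save_superpixels(sp, path)
  back <- load_superpixels(path)
  expect_identical(back$labels, sp$labels)
  expect_equal(back$K, sp$K)
  expect_equal(back$params$compactness, 12)
})
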