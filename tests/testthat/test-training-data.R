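write_via_fixture <- function(path, wrap = TRUE) {
  regions <- list(
    list(shape_attributes = list(name = "polygon",
                                 all_points_x = list(2, 8, 8, 2),
                                 all_points_y = list(2, 2, 6, 6)),
         region_attributes = list(class = "ear")),
    list(shape_attributes = list(name = "rect", x = 10, y = 10,
                                 width = 5, height = 4),
         region_attributes = list(class = "background")),
    list(shape_attributes = list(name = "polygon",
                                 all_points_x = list(1, 6, 1),
                                 all_points_y = list(10, 14, 14)),
         region_attributes = list(class = "ear")))
  rec <- list("img1.png-123" = list(filename = "img1.png", size = 123,
                                    regions = regions))
  doc <- if (wrap) list("_via_img_metadata" = rec) else rec
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

test_that("VIA annotations parse in both dialects", {
  path <- withr::local_tempfile(fileext = ".json")
  write_via_fixture(path)
  shapes <- read_via_annotations(path)
  expect_length(shapes, 3L)
  expect_equal(vapply(shapes, `[[`, "", "kind"), c("polygon", "box", "polygon"))
  expect_equal(vapply(shapes, `[[`, "", "class_label"),
               c("ear", "background", "ear"))
  expect_equal(shapes[[2]]$vertices, rbind(c(10, 10), c(15, 14)))

  write_via_fixture(path, wrap = FALSE)
  expect_length(read_via_annotations(path), 3L)

  jsonlite::write_json(list(img = list(filename = "x.png", regions = list())),
                       path, auto_unbox = TRUE)
  expect_length(read_via_annotations(path), 0L)
})

test_that("unknown classes are skipped with a warning, bad files error", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(img = list(filename = "x.png", regions = list(
    list(shape_attributes = list(name = "polygon",
                                 all_points_x = list(1, 5, 5),
                                 all_points_y = list(1, 1, 5)),
         region_attributes = list(class = "weed")))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_warning(shapes <- read_via_annotations(path), "unknown class")
  expect_length(shapes, 0L)

  writeLines("{not json", path)
  expect_error(read_via_annotations(path), "parse")
})

test_that("patch construction rasterizes polygons and zeroes backgrounds", {
  path <- withr::local_tempfile(fileext = ".json")
  write_via_fixture(path)
  shapes <- read_via_annotations(path)
  set.seed(10)
  img <- array(as.numeric(sample(0:255, 20 * 20 * 3, TRUE)), c(20, 20, 3))
  ps <- build_patches(list(img1.png = img), shapes, margin = 0)
  expect_length(ps$patches, 3L)
  expect_equal(ps$provenance$n_ear, 2L)
  expect_equal(ps$provenance$n_background, 1L)

  # box-shaped polygon fills its bounding box
  expect_true(all(ps$patches[[1]]$mask == 1))
  # background boxes carry all-zero masks
  expect_true(all(ps$patches[[2]]$mask == 0))
  # triangle mask equals the boundary-inclusive point-in-polygon oracle
  tri_oracle <- naive_polygon_mask(shapes[[3]]$vertices, 20, 20)
  y <- 11:15; x <- 2:7  # bounding rows/cols of the triangle
  expect_equal(ps$patches[[3]]$mask, tri_oracle[y, x])
})

test_that("rasterization agrees with the oracle on random convex polygons", {
  set.seed(11)
  for (k in 1:5) {
    ang <- sort(runif(sample(3:6, 1), 0, 2 * pi))
    v <- cbind(10 + 6 * cos(ang) + runif(1), 10 + 6 * sin(ang) + runif(1))
    got <- rasterize_polygon(v, 20, 20)
    want <- naive_polygon_mask(v, 20, 20)
    expect_equal(got, want)
  }
})

test_that("out-of-bounds shapes clip with a warning, degenerate ones drop", {
  img <- array(100, c(12, 12, 3))
  shapes <- list(
    list(image_id = "a", kind = "polygon",
         vertices = rbind(c(-3, 2), c(9, 2), c(9, 8), c(-3, 8)),
         class_label = "ear"),
    list(image_id = "a", kind = "polygon",
         vertices = rbind(c(4, 4), c(4, 4), c(4, 4)), class_label = "ear"))
  expect_warning(ps <- build_patches(list(a = img), shapes), "clipped")
  expect_length(ps$patches, 1L)
})

test_that("augmentation preserves image/mask correspondence and seeds", {
  img <- array(0, c(21, 21, 3))
  img[6:16, 9:13, 1] <- 255
  patch <- list(image = img, mask = (img[, , 1] > 128) + 0,
                class_label = "ear")

  # geometric-only, always applied, exact transforms (flips + 90 degrees)
  geo <- augment_params(apply_probability = 1, rotation_range = c(90, 90),
                        zoom_range = c(1, 1), brightness_range = c(1, 1),
                        hue_shift_degrees = 0, gamma_range = c(1, 1))
  set.seed(12)
  out <- augment(patch, geo)
  expect_equal((out$image[, , 1] > 128) + 0, out$mask)
  expect_equal(sum(out$mask), sum(patch$mask))

  # identity when nothing is applied
  none <- augment_params(apply_probability = 0)
  set.seed(1)
  out <- augment(patch, none)
  expect_equal(out$image, patch$image)
  expect_equal(out$mask, patch$mask)

  # fixed seed reproduces byte-identical output
  full <- augment_params()
  set.seed(13); a <- augment(patch, full)
  set.seed(13); b <- augment(patch, full)
  expect_identical(a, b)
  expect_true(all(a$image >= 0 & a$image <= 255))

  # horizontal flip is an involution
  fl <- augment_params(apply_probability = 1,
                       rotation_range = c(0, 0), zoom_range = c(1, 1),
                       brightness_range = c(1, 1), hue_shift_degrees = 0,
                       gamma_range = c(1, 1))
  set.seed(3); once <- augment(patch, fl)
  expect_equal(sum(once$mask), sum(patch$mask))
})

test_that("train/validation split is a seeded partition", {
  patches <- lapply(1:10, function(i)
    list(image = array(i, c(4, 4, 3)), mask = matrix(0, 4, 4),
         class_label = "background"))
  set <- new_patchset(patches)
  halves <- split_train_val(set, 0.2, seed = 4)
  expect_length(halves$val$patches, 2L)
  expect_length(halves$train$patches, 8L)
  ids <- function(x) vapply(x$patches, function(p) p$image[1, 1, 1], 0)
  expect_length(intersect(ids(halves$train), ids(halves$val)), 0L)
  expect_setequal(c(ids(halves$train), ids(halves$val)), 1:10)

  again <- split_train_val(set, 0.2, seed = 4)
  expect_identical(ids(again$val), ids(halves$val))

  one <- new_patchset(patches[1])
  expect_error(split_train_val(one), "at least 2")
})
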