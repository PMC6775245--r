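tiny_config <- function() model_config(c(16L, 16L), c(2L, 3L, 3L, 4L), 4L)

test_that("model configuration enforces the four-pool geometry", {
  cfg <- model_config()
  expect_equal(cfg$input_size, c(224L, 224L))
  expect_equal(cfg$encoder_widths, c(64L, 128L, 256L, 512L))
  expect_equal(cfg$bottleneck_channels, 512L)
  expect_equal(cfg$n_pool, 4L)
  expect_error(model_config(input_size = c(100, 100)), "divisible by 16")

  small <- model_config(width_multiplier = 0.125)
  expect_equal(small$encoder_widths, c(8L, 16L, 32L, 64L))
  expect_equal(small$bottleneck_channels, 64L)
})

test_that("forward pass honours the output shape and range contract", {
  m <- build_model(tiny_config(), seed = 1)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- unet_predict_cpp(m$weights, x, 16L, 16L)
  expect_equal(dim(p), c(16L, 16L))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, unet_predict_cpp(m$weights, x, 16L, 16L))
})

test_that("width multiplier scales the parameter count quadratically", {
  n_par <- function(cfg) sum(vapply(build_model(cfg, seed = 1)$weights,
                                    function(l) length(l$W) + length(l$b), 0))
  full <- n_par(model_config(c(32L, 32L), width_multiplier = 0.5))
  eighth <- n_par(model_config(c(32L, 32L), width_multiplier = 0.125))
  expect_gt(full / eighth, 12)  # ~16x fewer weights at 1/4 the width
})

test_that("binary cross-entropy matches its closed forms and a scalar oracle", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(bce_loss(t, t), 2e-6)
  expect_equal(bce_loss(matrix(0.5, 4, 4), matrix(rbinom(16, 1, 0.5), 4, 4)),
               log(2), tolerance = 1e-12)

  set.seed(14)
  p <- matrix(runif(9, 0.01, 0.99), 3, 3)
  tt <- matrix(rbinom(9, 1, 0.5), 3, 3)
  acc <- 0
  for (i in 1:3) for (j in 1:3)
    acc <- acc - (tt[i, j] * log(p[i, j]) + (1 - tt[i, j]) * log(1 - p[i, j]))
  expect_equal(bce_loss(p, tt), acc / 9, tolerance = 1e-12)
  expect_error(bce_loss(p, matrix(0, 2, 2)), "shape")
})

test_that("analytic gradients match finite differences", {
  set.seed(15)
  m <- build_model(tiny_config(), seed = 7)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  t <- matrix(rbinom(256, 1, 0.4), 16, 16)
  res <- unet_batch_grad_cpp(m$weights, list(x), list(t))
  h <- 1e-6
  for (li in c(1L, 5L, 11L, 20L)) {
    W <- m$weights[[li]]$W
    ij <- c(sample(nrow(W), 1), sample(ncol(W), 1))
    wp <- m$weights; wp[[li]]$W[ij[1], ij[2]] <- wp[[li]]$W[ij[1], ij[2]] + h
    wm <- m$weights; wm[[li]]$W[ij[1], ij[2]] <- wm[[li]]$W[ij[1], ij[2]] - h
    g_num <- (unet_batch_eval_cpp(wp, list(x), list(t))$loss -
              unet_batch_eval_cpp(wm, list(x), list(t))$loss) / (2 * h)
    g_an <- res$grads[[li]]$W[ij[1], ij[2]]
    expect_equal(g_an, g_num, tolerance = 1e-4)
  }
})

test_that("a tiny network overfits a separable color fixture", {
  set.seed(16)
  mk_patch <- function() {
    img <- array(30 + rnorm(16 * 16 * 3, 0, 5), c(16, 16, 3))
    mask <- matrix(0, 16, 16)
    y <- sample(4:12, 1); x <- sample(4:12, 1)
    mask[(y - 3):(y + 3), (x - 3):(x + 3)] <- 1
    img[, , 1][mask == 1] <- 220 + rnorm(sum(mask), 0, 5)
    list(image = pmin(pmax(img, 0), 255), mask = mask, class_label = "ear")
  }
  patches <- replicate(10, mk_patch(), simplify = FALSE)
  set <- new_patchset(patches)
  model <- build_model(model_config(c(16L, 16L), c(4L, 8L, 8L, 8L), 8L),
                       seed = 2)
  model <- train_model(model, set, set,
                       train_config(epochs = 50, learning_rate = 3e-3,
                                    batch_size = 5, seed = 3,
                                    target_val_accuracy = 0.995))
  expect_gte(max(model$history$train_accuracy), 0.99)

  # loss trend is non-increasing in epoch-median
  l <- model$history$train_loss
  half <- floor(length(l) / 2)
  expect_lt(stats::median(l[(half + 1):length(l)]),
            stats::median(l[1:half]) + 1e-8)

  # the overfit model is confident on its own ear pixels
  p <- predict_region(model, list(crop = patches[[1]]$image))
  expect_gt(mean(p[patches[[1]]$mask == 1]), 0.9)
})

test_that("prediction requires a trained model", {
  m <- build_model(tiny_config(), seed = 1)
  expect_error(predict_region(m, list(crop = array(0, c(8, 8, 3)))),
               "trained")
})

test_that("stitching writes every pixel exactly once", {
  # single full-image region: resize round trip
  reg <- list(crop = array(0, c(8, 8, 3)), mask = matrix(TRUE, 8, 8),
              box = c(0L, 0L, 8L, 8L))
  pm <- matrix(runif(16), 4, 4)
  out <- stitch_predictions(list(reg), list(pm), c(8, 8))
  expect_equal(dim(out), c(8L, 8L))

  # 4 quadrants with constant maps give a blockwise-constant image
  regions <- list(); maps <- list(); vals <- c(0, 1, 0.25, 0.75)
  k <- 0
  for (oy in c(0L, 4L)) for (ox in c(0L, 4L)) {
    k <- k + 1
    regions[[k]] <- list(crop = array(0, c(4, 4, 3)),
                         mask = matrix(TRUE, 4, 4),
                         box = c(ox, oy, ox + 4L, oy + 4L))
    maps[[k]] <- matrix(vals[k], 4, 4)
  }
  out <- stitch_predictions(regions, maps, c(8, 8))
  expect_equal(out[1, 1], 0); expect_equal(out[1, 8], 1)
  expect_equal(out[8, 1], 0.25); expect_equal(out[8, 8], 0.75)

  # random partition: ownership verified per pixel
  set.seed(17)
  img <- array(sample(0:255, 20 * 20 * 3, TRUE), c(20, 20, 3))
  sp <- slic_segment(img, slic_params(5))
  regions <- extract_regions(img, sp)
  maps <- lapply(seq_along(regions), function(i)
    matrix(i / 10, nrow(regions[[i]]$mask), ncol(regions[[i]]$mask)))
  out <- stitch_predictions(regions, maps, c(20, 20))
  for (px in sample(400, 25)) {
    r <- (px - 1) %% 20 + 1; c <- (px - 1) %/% 20 + 1
    expect_equal(out[r, c], sp$labels[r, c] / 10)
  }

  # double coverage is rejected
  bad <- list(regions[[1]], regions[[1]])
  expect_error(stitch_predictions(bad, maps[c(1, 1)], c(20, 20)),
               "exactly once")
})

test_that("checkpoints round-trip and refuse mismatched architectures", {
  m <- build_model(tiny_config(), seed = 4)
  m$trained <- TRUE
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(unet_predict_cpp(back$weights, x, 16L, 16L),
                   unet_predict_cpp(m$weights, x, 16L, 16L))
  expect_error(load_model(path, config = model_config(c(32L, 32L))),
               "does not match")
})
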