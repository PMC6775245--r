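#' Segmentation network configuration
#'
#' A VGG-style encoder (four stages of stacked 3x3 convolutions with
#' `{2,2,3,3}` layers and channel widths `encoder_widths`, each stage followed
#' by 2x2 max-pooling) feeds a single 3x3 bottleneck convolution; the decoder
#' mirrors it with four stages of 2x nearest-neighbour upsampling, skip
#' concatenation with the matching encoder output, and two 3x3 convolutions,
#' ending in a 1x1 convolution with a sigmoid that yields a per-pixel ear
#' probability at input resolution. The defaults (224x224 input, widths
#' 64/128/256/512, 512-channel bottleneck) are the full-scale configuration;
#' `width_multiplier` scales every width down for desk-scale experiments
#' without changing the topology.
#'
#' @param input_size integer vector `c(H, W)`; both divisible by 16
#'   (four pooling stages).
#' @param encoder_widths four increasing channel widths.
#' @param bottleneck_channels bottleneck width.
#' @param width_multiplier real in (0, 1]; all widths are scaled by it
#'   (rounded, floor 1).
#' @return object of class `model_config`.
#' @export
model_config <- function(input_size = c(224L, 224L),
                         encoder_widths = c(64L, 128L, 256L, 512L),
                         bottleneck_channels = 512L,
                         width_multiplier = 1.0) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size %% 16L != 0L) ||
      any(input_size < 16L))
    stop("`input_size` must be two dimensions divisible by 16", call. = FALSE)
  if (length(encoder_widths) != 4L || any(encoder_widths < 1L))
    stop("`encoder_widths` must be four positive widths", call. = FALSE)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("`width_multiplier` must be in (0, 1]", call. = FALSE)
  w <- pmax(1L, as.integer(round(encoder_widths * width_multiplier)))
  b <- max(1L, as.integer(round(bottleneck_channels * width_multiplier)))
  structure(list(input_size = input_size, encoder_widths = w,
                 bottleneck_channels = b, n_pool = 4L,
                 width_multiplier = width_multiplier),
            class = "model_config")
}

# Conv layer shapes in the exact order the C++ pass consumes them.
layer_shapes <- function(config) {
  w <- config$encoder_widths
  convs <- c(2L, 2L, 3L, 3L)
  shapes <- list()
  prev <- 3L
  for (s in 1:4) {
    for (i in seq_len(convs[s])) {
      shapes[[length(shapes) + 1L]] <- list(k = 3L, cin = prev, cout = w[s])
      prev <- w[s]
    }
  }
  shapes[[length(shapes) + 1L]] <- list(k = 3L, cin = w[4],
                                        cout = config$bottleneck_channels)
  prev <- config$bottleneck_channels
  for (s in 4:1) {
    shapes[[length(shapes) + 1L]] <- list(k = 3L, cin = prev + w[s], cout = w[s])
    shapes[[length(shapes) + 1L]] <- list(k = 3L, cin = w[s], cout = w[s])
    prev <- w[s]
  }
  shapes[[length(shapes) + 1L]] <- list(k = 1L, cin = w[1], cout = 1L)
  shapes
}

#' Build the segmentation model
#'
#' Initializes all convolution weights (He-scaled normal draws from R's RNG,
#' so seeding via `set.seed()` before the call makes the model reproducible)
#' and returns an untrained model handle.
#'
#' @param config [model_config()].
#' @param seed optional integer; if given, `set.seed(seed)` is applied first.
#' @return object of class `earcount_model` with elements `config`, `weights`
#'   and `trained`.
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weights <- lapply(layer_shapes(config), function(s) {
    fan_in <- s$k^2 * s$cin
    list(W = matrix(stats::rnorm(fan_in * s$cout, sd = sqrt(2 / fan_in)),
                    fan_in, s$cout),
         b = rep(0, s$cout))
  })
  structure(list(config = config, weights = weights, trained = FALSE),
            class = "earcount_model")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(t log p + (1 - t) log(1 - p))`, with predictions
#' clipped to `[eps, 1 - eps]`. This is the training criterion of the
#' pixel-wise ear/background classifier.
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param target binary matrix of the same shape.
#' @param eps clipping constant, default `1e-7`.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!all(dim(pred) == dim(target)))
    stop("`pred` and `target` shapes differ", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Training configuration
#'
#' Defaults follow the full-scale training recipe: 15 epochs at a learning
#' rate of 1e-4 (Adam). `target_val_accuracy` optionally stops training as
#' soon as validation pixel accuracy reaches the given level.
#'
#' @param epochs positive integer, default 15.
#' @param learning_rate positive real, default 1e-4.
#' @param batch_size positive integer, default 16.
#' @param seed integer seed for shuffling (and weight init if the model is
#'   built inside [train_model()]).
#' @param target_val_accuracy optional early-stop level in (0, 1].
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 15L, learning_rate = 1e-4, batch_size = 16L,
                         seed = 1L, target_val_accuracy = NULL) {
  if (epochs < 1L || learning_rate <= 0 || batch_size < 1L)
    stop("epochs, learning_rate and batch_size must be positive", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 target_val_accuracy = target_val_accuracy),
            class = "train_config")
}

# Resize a patch to the network input: bilinear for the image (scaled to
# [0,1]), nearest for the mask (stays binary).
prep_patch <- function(patch, input_size) {
  list(x = resize_image(patch$image, input_size[1], input_size[2],
                        "bilinear") / 255,
       t = resize_image(patch$mask + 0, input_size[1], input_size[2],
                        "nearest"))
}

#' Train the segmentation model
#'
#' Adam optimization of the binary cross-entropy over minibatches; images are
#' resized to the configured input size (bilinear; masks nearest-neighbour).
#' Records per-epoch training and validation loss and pixel accuracy.
#'
#' @param model [build_model()] handle.
#' @param train_set,val_set patch sets (see [generate_patchset()] or
#'   [build_patches()]).
#' @param cfg [train_config()].
#' @return the trained model, with `$history` (data frame of epoch, train
#'   loss/accuracy, validation loss/accuracy) attached.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config()) {
  if (length(train_set$patches) == 0L || length(val_set$patches) == 0L)
    stop("training and validation sets must be nonempty", call. = FALSE)
  isz <- model$config$input_size
  tr <- lapply(train_set$patches, prep_patch, input_size = isz)
  va <- lapply(val_set$patches, prep_patch, input_size = isz)
  vx <- lapply(va, `[[`, "x"); vt <- lapply(va, `[[`, "t")

  w <- model$weights
  ad_m <- lapply(w, function(l) list(W = l$W * 0, b = l$b * 0))
  ad_v <- ad_m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  set.seed(cfg$seed)
  history <- NULL

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(tr))
    ep_loss <- 0; ep_acc <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      xs <- lapply(tr[idx], `[[`, "x")
      ts <- lapply(tr[idx], `[[`, "t")
      res <- unet_batch_grad_cpp(w, xs, ts)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
             call. = FALSE)
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (i in seq_along(w)) {
        g <- res$grads[[i]]
        ad_m[[i]]$W <- beta1 * ad_m[[i]]$W + (1 - beta1) * g$W
        ad_m[[i]]$b <- beta1 * ad_m[[i]]$b + (1 - beta1) * g$b
        ad_v[[i]]$W <- beta2 * ad_v[[i]]$W + (1 - beta2) * g$W^2
        ad_v[[i]]$b <- beta2 * ad_v[[i]]$b + (1 - beta2) * g$b^2
        w[[i]]$W <- w[[i]]$W - cfg$learning_rate * (ad_m[[i]]$W / bc1) /
          (sqrt(ad_v[[i]]$W / bc2) + adam_eps)
        w[[i]]$b <- w[[i]]$b - cfg$learning_rate * (ad_m[[i]]$b / bc1) /
          (sqrt(ad_v[[i]]$b / bc2) + adam_eps)
      }
      ep_loss <- ep_loss + res$loss; ep_acc <- ep_acc + res$accuracy
      nb <- nb + 1L
    }
    ev <- unet_batch_eval_cpp(w, vx, vt)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nb, train_accuracy = ep_acc / nb,
      val_loss = ev$loss, val_accuracy = ev$accuracy))
    if (!is.null(cfg$target_val_accuracy) &&
        ev$accuracy >= cfg$target_val_accuracy) break
  }
  model$weights <- w
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict the ear-probability map of one candidate region
#'
#' The region crop is resized (bilinear) to the network input size and pushed
#' through a forward pass.
#'
#' @param model trained model.
#' @param region a region as produced by [extract_regions()] (needs `$crop`).
#' @return probability matrix of the network input size, values in `[0, 1]`.
#' @export
predict_region <- function(model, region) {
  if (!isTRUE(model$trained))
    stop("model has not been trained (or loaded from a checkpoint)",
         call. = FALSE)
  isz <- model$config$input_size
  x <- resize_image(region$crop, isz[1], isz[2], "bilinear") / 255
  unet_predict_cpp(model$weights, x, isz[1], isz[2])
}

#' Stitch region predictions back into a full-image probability map
#'
#' Each region's probability map is resized back to its bounding box and only
#' the pixels owned by the region's mask are written, so the superpixel
#' partition guarantees every image pixel is written exactly once.
#'
#' @param regions list of regions ([extract_regions()]).
#' @param maps list of probability matrices, one per region.
#' @param image_shape `c(H, W)`.
#' @return `H x W` probability matrix.
#' @export
stitch_predictions <- function(regions, maps, image_shape) {
  if (length(regions) != length(maps))
    stop("need one probability map per region", call. = FALSE)
  out <- matrix(0, image_shape[1], image_shape[2])
  cover <- matrix(0L, image_shape[1], image_shape[2])
  for (i in seq_along(regions)) {
    box <- regions[[i]]$box
    h <- box[4] - box[2]; wd <- box[3] - box[1]
    m <- resize_image(maps[[i]], h, wd, "bilinear")
    rows <- (box[2] + 1L):box[4]; cols <- (box[1] + 1L):box[3]
    own <- regions[[i]]$mask
    sub <- out[rows, cols, drop = FALSE]
    sub[own] <- m[own]
    out[rows, cols] <- sub
    csub <- cover[rows, cols, drop = FALSE]
    csub[own] <- csub[own] + 1L
    cover[rows, cols] <- csub
  }
  if (any(cover != 1L))
    stop("regions do not tile the image exactly once", call. = FALSE)
  out
}

#' Save / load a model checkpoint
#'
#' Weights go to an RDS file with a JSON sidecar (`<path>.json`) recording the
#' architecture, so a checkpoint refuses to load under a mismatched
#' configuration.
#'
#' @param model trained model.
#' @param path checkpoint path (e.g. `model.rds`).
#' @param config optional [model_config()] that the checkpoint must match.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model$weights, path)
  cfgj <- model$config
  jsonlite::write_json(
    list(input_size = cfgj$input_size, encoder_widths = cfgj$encoder_widths,
         bottleneck_channels = cfgj$bottleneck_channels,
         width_multiplier = cfgj$width_multiplier, trained = model$trained),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, config = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- model_config(meta$input_size, meta$encoder_widths,
                      meta$bottleneck_channels, 1.0)
  cfg$width_multiplier <- meta$width_multiplier
  if (!is.null(config)) {
    if (!identical(config$input_size, cfg$input_size) ||
        !identical(config$encoder_widths, cfg$encoder_widths) ||
        config$bottleneck_channels != cfg$bottleneck_channels)
      stop("checkpoint architecture does not match the requested config",
           call. = FALSE)
  }
  structure(list(config = cfg, weights = readRDS(path),
                 trained = isTRUE(meta$trained)),
            class = "earcount_model")
}
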