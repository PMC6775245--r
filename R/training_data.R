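#' Read VIA annotations
#'
#' Parses a VGG Image Annotator (VIA) JSON export into a flat list of shapes.
#' Both dialects are accepted: files with the project-style
#' `_via_img_metadata` wrapper and plain exports keyed by image id. Regions
#' may be lists or dicts; `polygon` and `rect` shapes are supported, and the
#' class is read from a configurable region attribute (ears are annotated as
#' polygons, background as boxes).
#'
#' @param path VIA JSON file.
#' @param class_attribute region attribute carrying the class, default
#'   `"class"` (values `"ear"` / `"background"`).
#' @return list of shapes; each has `image_id`, `kind` (`"polygon"` or
#'   `"box"`), `vertices` (n x 2 matrix of x, y; boxes have 2 corner rows)
#'   and `class_label`. Regions with an unknown class are skipped with a
#'   warning.
#' @export
read_via_annotations <- function(path, class_attribute = "class") {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse VIA JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  shapes <- list()
  for (key in names(doc)) {
    rec <- doc[[key]]
    if (!is.list(rec) || is.null(rec$filename)) next
    regions <- rec$regions
    if (is.null(regions)) regions <- list()
    for (ri in seq_along(regions)) {
      reg <- regions[[ri]]
      sa <- reg$shape_attributes
      if (is.null(sa) || is.null(sa$name))
        stop(sprintf("malformed region %d of record '%s': no shape_attributes",
                     ri, key), call. = FALSE)
      cls <- reg$region_attributes[[class_attribute]]
      if (is.null(cls) || !cls %in% c("ear", "background")) {
        warning(sprintf("record '%s' region %d: unknown class %s; skipped",
                        key, ri, deparse(cls)), call. = FALSE)
        next
      }
      if (sa$name == "polygon") {
        v <- cbind(unlist(sa$all_points_x), unlist(sa$all_points_y))
        if (nrow(v) < 3L)
          stop(sprintf("malformed polygon in record '%s' region %d", key, ri),
               call. = FALSE)
        kind <- "polygon"
      } else if (sa$name == "rect") {
        v <- rbind(c(sa$x, sa$y), c(sa$x + sa$width, sa$y + sa$height))
        kind <- "box"
      } else {
        warning(sprintf("record '%s' region %d: unsupported shape '%s'; skipped",
                        key, ri, sa$name), call. = FALSE)
        next
      }
      shapes[[length(shapes) + 1L]] <-
        list(image_id = rec$filename, kind = kind, vertices = v,
             class_label = cls)
    }
  }
  shapes
}

# Even-odd-rule polygon rasterization at pixel centres, with the boundary
# drawn inclusively (a box-shaped polygon fills its box). vertices: n x 2
# (x, y), 0-based image coordinates; returns a binary H x W matrix.
rasterize_polygon <- function(vertices, H, W) {
  mask <- matrix(0, H, W)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  eps <- 1e-9
  for (i in seq_len(n)) {  # horizontal edges lie on a scanline: fill directly
    j <- if (i == n) 1L else i + 1L
    if (vy[i] == vy[j] && vy[i] == round(vy[i])) {
      row <- vy[i] + 1L
      if (row >= 1L && row <= H) {
        a <- max(1L, ceiling(min(vx[i], vx[j]) - eps) + 1L)
        b <- min(W, floor(max(vx[i], vx[j]) + eps) + 1L)
        if (a <= b) mask[row, a:b] <- 1
      }
    }
  }
  for (row in seq_len(H)) {
    py <- row - 1  # pixel centre y
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > py) != (vy[j] > py)) {
        xs <- c(xs, vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        a <- max(1L, ceiling(xs[k] - eps) + 1L)
        b <- min(W, floor(xs[k + 1] + eps) + 1L)
        if (a <= b) mask[row, a:b] <- 1
      }
    }
  }
  mask
}

#' Bundle patches into a patch set
#'
#' Wraps a list of patches (each a list with `image`, `mask`, `class_label`)
#' together with per-class provenance counts. Used to combine base and
#' augmented patches into one training corpus.
#'
#' @param patches nonempty list of patches.
#' @return object of class `patchset`.
#' @export
new_patchset <- function(patches) {
  counts <- table(vapply(patches, `[[`, "", "class_label"))
  structure(list(patches = patches,
                 provenance = list(n_ear = sum(unlist(counts["ear"]), na.rm = TRUE),
                                   n_background = sum(unlist(counts["background"]),
                                                      na.rm = TRUE))),
            class = "patchset")
}

#' @export
print.patchset <- function(x, ...) {
  cat(sprintf("patchset: %d patches (%d ear, %d background)\n",
              length(x$patches), x$provenance$n_ear, x$provenance$n_background))
  invisible(x)
}

#' Build labelled training patches from annotated shapes
#'
#' Ear polygons become crops of their bounding box (expanded by `margin`)
#' with the rasterized polygon interior as the pixel mask; background boxes
#' become crops with all-zero masks. Shapes reaching outside the image are
#' clipped with a warning; degenerate (zero-area) shapes are skipped.
#'
#' @param images named list of RGB arrays, keyed by the `image_id` of the
#'   shapes.
#' @param shapes list from [read_via_annotations()].
#' @param margin fractional bounding-box expansion for ear crops, default 0.1.
#' @return `patchset`: list of patches (`image`, `mask`, `class_label`) plus
#'   per-class provenance counts.
#' @export
build_patches <- function(images, shapes, margin = 0.1) {
  patches <- list()
  for (sh in shapes) {
    img <- images[[sh$image_id]]
    if (is.null(img))
      stop("no image supplied for id '", sh$image_id, "'", call. = FALSE)
    H <- dim(img)[1]; W <- dim(img)[2]
    v <- sh$vertices
    if (any(v[, 1] < 0) || any(v[, 1] > W - 1) ||
        any(v[, 2] < 0) || any(v[, 2] > H - 1)) {
      warning("shape outside image bounds clipped (", sh$image_id, ")",
              call. = FALSE)
      v[, 1] <- pmin(pmax(v[, 1], 0), W - 1)
      v[, 2] <- pmin(pmax(v[, 2], 0), H - 1)
    }
    if (diff(range(v[, 1])) < 1 || diff(range(v[, 2])) < 1) next  # degenerate
    if (sh$kind == "polygon") {
      mg <- c(diff(range(v[, 1])), diff(range(v[, 2]))) * margin
      x0 <- max(0, floor(min(v[, 1]) - mg[1])); x1 <- min(W - 1, ceiling(max(v[, 1]) + mg[1]))
      y0 <- max(0, floor(min(v[, 2]) - mg[2])); y1 <- min(H - 1, ceiling(max(v[, 2]) + mg[2]))
      full <- rasterize_polygon(v, H, W)
      mask <- full[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
      if (sum(mask) == 0) next
      crop <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
      patches[[length(patches) + 1L]] <-
        list(image = crop, mask = mask, class_label = "ear")
    } else {
      x0 <- floor(min(v[, 1])); x1 <- ceiling(max(v[, 1]))
      y0 <- floor(min(v[, 2])); y1 <- ceiling(max(v[, 2]))
      x1 <- min(x1, W - 1); y1 <- min(y1, H - 1)
      crop <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
      patches[[length(patches) + 1L]] <-
        list(image = crop, mask = matrix(0, nrow(crop), ncol(crop)),
             class_label = "background")
    }
  }
  if (!length(patches)) stop("no usable shapes", call. = FALSE)
  new_patchset(patches)
}

#' Augmentation parameters
#'
#' Each transform is applied independently with probability
#' `apply_probability` (default 0.5). Geometric transforms (flips, rotation,
#' zoom) are applied identically to image and mask; photometric transforms
#' (HSV shift, brightness, gamma) touch the image only. Defaults: rotation
#' within +-180 degrees, zoom 0.8-1.2, brightness 0.7-1.3, hue shift +-10
#' degrees, saturation/value +-20%, gamma 0.5-2.
#'
#' @param apply_probability per-transform probability in `[0, 1]`.
#' @param rotation_range degrees, `c(lo, hi)`.
#' @param zoom_range multiplicative, `c(lo, hi)`.
#' @param brightness_range multiplicative, `c(lo, hi)`.
#' @param hue_shift_degrees max absolute hue shift in degrees.
#' @param sat_shift,val_shift max relative saturation/value shift.
#' @param gamma_range `c(lo, hi)` for [apply_gamma()].
#' @param flip allow horizontal and vertical flips.
#' @return object of class `augment_params`.
#' @export
augment_params <- function(apply_probability = 0.5,
                           rotation_range = c(-180, 180),
                           zoom_range = c(0.8, 1.2),
                           brightness_range = c(0.7, 1.3),
                           hue_shift_degrees = 10,
                           sat_shift = 0.2, val_shift = 0.2,
                           gamma_range = c(0.5, 2.0),
                           flip = TRUE) {
  if (apply_probability < 0 || apply_probability > 1)
    stop("`apply_probability` must be in [0, 1]", call. = FALSE)
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!rng_ok(rotation_range) || !rng_ok(zoom_range) ||
      !rng_ok(brightness_range) || !rng_ok(gamma_range))
    stop("ranges must be ordered c(lo, hi)", call. = FALSE)
  structure(list(apply_probability = apply_probability,
                 rotation_range = rotation_range, zoom_range = zoom_range,
                 brightness_range = brightness_range,
                 hue_shift_degrees = hue_shift_degrees,
                 sat_shift = sat_shift, val_shift = val_shift,
                 gamma_range = gamma_range, flip = flip),
            class = "augment_params")
}

# Inverse-mapped rotation+zoom about the patch centre. Bilinear with edge
# replication for images; nearest with 0 fill for masks.
sample_affine <- function(img, theta, zoom, method) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  ct <- cos(-theta); st <- sin(-theta)
  sy <- ((g$y - cy) * ct - (g$x - cx) * st) / zoom + cy
  sx <- ((g$y - cy) * st + (g$x - cx) * ct) / zoom + cx
  outside <- sy < 0 | sy > H - 1 | sx < 0 | sx > W - 1
  sy <- pmin(pmax(sy, 0), H - 1); sx <- pmin(pmax(sx, 0), W - 1)
  sample_plane <- function(P) {
    if (method == "nearest") {
      v <- P[cbind(round(sy) + 1, round(sx) + 1)]
      v[outside] <- 0
    } else {
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
      wy <- sy - y0; wx <- sx - x0
      v <- (1 - wy) * (1 - wx) * P[cbind(y0 + 1, x0 + 1)] +
           (1 - wy) * wx       * P[cbind(y0 + 1, x1 + 1)] +
           wy * (1 - wx)       * P[cbind(y1 + 1, x0 + 1)] +
           wy * wx             * P[cbind(y1 + 1, x1 + 1)]
    }
    matrix(v, H, W)
  }
  if (length(d) == 3L) {
    out <- array(0, d)
    for (c in seq_len(d[3])) out[, , c] <- sample_plane(img[, , c])
    out
  } else sample_plane(img)
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); u <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, u, v)))))
  g <- ifelse(i == 0, u, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, u,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Augment a training patch
#'
#' Applies flips, rotation, zoom (identically to image and mask) and HSV
#' shift, brightness and gamma correction (image only), each independently
#' with the configured probability. Randomness comes from R's RNG, so
#' `set.seed()` makes augmentation reproducible.
#'
#' @param patch a patch (list with `image`, `mask`, `class_label`).
#' @param params [augment_params()].
#' @return augmented patch of the same shape and class.
#' @export
augment <- function(patch, params = augment_params()) {
  img <- patch$image; mask <- patch$mask
  p <- params$apply_probability
  hit <- function() stats::runif(1) < p
  if (params$flip && hit()) {  # horizontal flip
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (params$flip && hit()) {  # vertical flip
    img <- img[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  theta <- 0; zoom <- 1
  if (diff(params$rotation_range) > 0 && hit())
    theta <- stats::runif(1, params$rotation_range[1],
                          params$rotation_range[2]) * pi / 180
  if (diff(params$zoom_range) > 0 && hit())
    zoom <- stats::runif(1, params$zoom_range[1], params$zoom_range[2])
  if (theta != 0 || zoom != 1) {
    img <- pmin(pmax(sample_affine(img, theta, zoom, "bilinear"), 0), 255)
    mask <- sample_affine(mask, theta, zoom, "nearest")
  }
  if (params$hue_shift_degrees > 0 && hit()) {
    hsv <- grDevices::rgb2hsv(matrix(aperm(img, c(3, 1, 2)), nrow = 3),
                              maxColorValue = 255)
    hsv[1, ] <- (hsv[1, ] + stats::runif(1, -1, 1) *
                   params$hue_shift_degrees / 360) %% 1
    hsv[2, ] <- pmin(pmax(hsv[2, ] * (1 + stats::runif(1, -1, 1) *
                                        params$sat_shift), 0), 1)
    hsv[3, ] <- pmin(pmax(hsv[3, ] * (1 + stats::runif(1, -1, 1) *
                                        params$val_shift), 0), 1)
    rgb <- hsv_to_rgb(hsv[1, ], hsv[2, ], hsv[3, ]) * 255
    img <- aperm(array(t(rgb), dim = c(3, dim(mask))), c(2, 3, 1))
  }
  if (diff(params$brightness_range) > 0 && hit()) {
    img <- pmin(pmax(img * stats::runif(1, params$brightness_range[1],
                                        params$brightness_range[2]), 0), 255)
  }
  if (diff(params$gamma_range) > 0 && hit()) {
    img <- apply_gamma(round(img),
                       stats::runif(1, params$gamma_range[1],
                                    params$gamma_range[2]))
  }
  list(image = round(img), mask = mask, class_label = patch$class_label)
}

#' Split a patch set into training and validation parts
#'
#' Random, seeded, disjoint and exhaustive split; the validation part gets
#' `round(val_fraction * n)` patches (default 20%).
#'
#' @param set `patchset`.
#' @param val_fraction real in (0, 1), default 0.2.
#' @param seed integer seed.
#' @return list with `train` and `val` patch sets.
#' @export
split_train_val <- function(set, val_fraction = 0.2, seed = 1L) {
  n <- length(set$patches)
  if (n < 2L) stop("need at least 2 patches to split", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  n_val <- max(1L, round(val_fraction * n))
  idx <- sample.int(n)
  list(train = new_patchset(set$patches[idx[(n_val + 1):n]]),
       val = new_patchset(set$patches[idx[seq_len(n_val)]]))
}
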