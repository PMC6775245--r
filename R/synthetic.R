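#' Synthetic canopy scene parameters
#'
#' Describes an overhead canopy-like scene: a low-frequency green/brown
#' background texture, elliptical golden "spike" instances with spikelet-like
#' intensity banding and optional thin awn strokes, an illumination gradient,
#' soft shadow patches, Gaussian blur, and optionally a white A4-like
#' quadrilateral ground standard. Ears are kept fully inside the frame and
#' (when a standard is present) off the standard, so the recorded instance
#' labels and count are exact by construction.
#'
#' Default geometry mirrors overhead field images scaled to desk size: on a
#' 160 x 160 px scene, ears of 20-28 px major and 9-13 px minor axis
#' correspond to mature ears at a ground resolution a few times coarser than
#' the field cameras', and 12 ears give densities in the hundreds per square
#' metre once converted through an A4 standard.
#'
#' @param image_size `c(H, W)`, default `c(160, 160)`.
#' @param n_ears number of ear instances, default 12.
#' @param major_axis_range,minor_axis_range full axis lengths in px.
#' @param overlap_limit max fraction of a new ear's area allowed to overlap
#'   already-placed ears, default 0.3.
#' @param min_clearance minimum gap in px kept between ear instances
#'   (enforced via an enlarged placement footprint), default 0. Fixture
#'   families meant to be counted exactly use a clearance of at least 4 px so
#'   gaps survive the pipeline's 7x7 median filter.
#' @param awn_probability chance an ear carries awn strokes, default 0.5.
#' @param awn_count strokes per awned ear, default 4.
#' @param background_scale texture cell size in px, default 8.
#' @param illumination_amplitude relative amplitude of the linear
#'   illumination gradient, default 0.15.
#' @param shadow_count number of soft shadow patches, default 2.
#' @param blur_sigma Gaussian blur sigma in px (image only; ground-truth
#'   masks stay crisp), default 0.8.
#' @param include_standard draw a ground-standard quadrilateral, default
#'   FALSE.
#' @param standard_size `c(h, w)` of the standard in px (A4 portrait aspect),
#'   default `c(42, 30)`.
#' @param standard_angle rotation of the standard in degrees, default 8.
#' @param seed integer seed; identical parameters give byte-identical scenes.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_size = c(160L, 160L), n_ears = 12L,
                         major_axis_range = c(20, 28),
                         minor_axis_range = c(9, 13),
                         overlap_limit = 0.3, min_clearance = 0,
                         awn_probability = 0.5, awn_count = 4L,
                         background_scale = 8L,
                         illumination_amplitude = 0.15,
                         shadow_count = 2L, blur_sigma = 0.8,
                         include_standard = FALSE,
                         standard_size = c(42, 30), standard_angle = 8,
                         seed = 1L) {
  if (any(image_size < 16L)) stop("image too small", call. = FALSE)
  if (overlap_limit < 0 || overlap_limit >= 1)
    stop("`overlap_limit` must be in [0, 1)", call. = FALSE)
  if (n_ears < 0L) stop("`n_ears` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "scene_params")
}

ellipse_pixels <- function(cy, cx, a, b, phi, H, W) {
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r + 1)):min(H, ceiling(cy + r + 1))
  xs <- max(1, floor(cx - r + 1)):min(W, ceiling(cx + r + 1))
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - 1 - cy; dx <- g$x - 1 - cx
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(y = g$y[inside], x = g$x[inside], t = u[inside] / a)
}

rect_corners <- function(cy, cx, h, w, phi) {
  base <- rbind(c(-w, -h), c(w, -h), c(w, h), c(-w, h)) / 2
  rot <- base %*% rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  cbind(rot[, 1] + cx, rot[, 2] + cy)  # (x, y), 0-based
}

#' Generate a synthetic canopy scene
#'
#' @param params [scene_params()].
#' @return object of class `synthetic_scene`: `image` (RGB array),
#'   `ear_mask` (binary), `instance_labels` (integer matrix, 0 background),
#'   `true_count`, `standard_corners` (4 x 2 or `NULL`) and `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  set.seed(params$seed)
  H <- params$image_size[1]; W <- params$image_size[2]

  # low-frequency green/brown background
  cs <- params$background_scale
  gh <- ceiling(H / cs) + 1; gw <- ceiling(W / cs) + 1
  mix <- resize_image(matrix(stats::runif(gh * gw), gh, gw), H, W, "bilinear")
  green <- c(70, 100, 45); brown <- c(110, 90, 55)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- green[c] * (1 - mix) + brown[c] * mix
  img <- img + array(stats::rnorm(H * W * 3, 0, 4), c(H, W, 3))

  # ground standard footprint (ears avoid it so ground truth stays exact)
  standard_corners <- NULL
  std_mask <- matrix(FALSE, H, W)
  if (params$include_standard) {
    sh <- params$standard_size[1]; sw <- params$standard_size[2]
    phi <- params$standard_angle * pi / 180
    cy <- H * 0.72; cx <- W * 0.72
    standard_corners <- rect_corners(cy, cx, sh, sw, phi)
    std_mask <- rasterize_polygon(standard_corners, H, W) > 0
  }

  labels <- matrix(0L, H, W)
  placed <- 0L
  attempts <- 0L
  while (placed < params$n_ears) {
    attempts <- attempts + 1L
    if (attempts > 400L * max(1L, params$n_ears))
      stop("could not place ", params$n_ears, " ears within the overlap ",
           "limit; reduce n_ears or raise overlap_limit", call. = FALSE)
    a <- stats::runif(1, params$major_axis_range[1], params$major_axis_range[2]) / 2
    b <- stats::runif(1, params$minor_axis_range[1], params$minor_axis_range[2]) / 2
    phi <- stats::runif(1, 0, pi)
    r <- max(a, b) + 2
    cy <- stats::runif(1, r, H - 1 - r); cx <- stats::runif(1, r, W - 1 - r)
    px <- ellipse_pixels(cy, cx, a, b, phi, H, W)
    if (!length(px$y)) next
    idx <- cbind(px$y, px$x)
    if (any(std_mask[idx])) next
    overlap <- mean(labels[idx] > 0L)
    if (overlap > params$overlap_limit) next
    if (params$min_clearance > 0) {
      cl <- params$min_clearance
      fp <- ellipse_pixels(cy, cx, a + cl, b + cl, phi, H, W)
      if (any(labels[cbind(fp$y, fp$x)] > 0L)) next
    }
    placed <- placed + 1L
    labels[idx] <- placed

    # golden spike texture with banding along the major axis
    base <- c(190, 170, 100) + stats::rnorm(3, 0, 8)
    band <- 1 + 0.2 * sin(px$t * a * pi / 2)
    shade <- 1 - 0.25 * abs(px$t)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[idx] <- pmin(255, base[c] * band * shade)
      img[, , c] <- plane
    }
    if (stats::runif(1) < params$awn_probability) {
      # thin awn strokes from the ear tip, image only (removed by the
      # median filter downstream, as in real masks that exclude awns)
      for (k in seq_len(params$awn_count)) {
        ang <- phi + stats::runif(1, -0.5, 0.5)
        len <- stats::runif(1, 0.3, 0.6) * a * 2
        t0 <- stats::runif(1, 0.6, 1)
        sx <- cx + t0 * a * cos(phi); sy <- cy + t0 * a * sin(phi)
        steps <- seq(0, len, by = 0.7)
        ay <- round(sy + steps * sin(ang)); ax <- round(sx + steps * cos(ang))
        ok <- ay >= 0 & ay < H & ax >= 0 & ax < W
        aidx <- cbind(ay[ok] + 1, ax[ok] + 1)
        for (c in 1:3) {
          plane <- img[, , c]
          plane[aidx] <- pmin(255, base[c] * 0.9)
          img[, , c] <- plane
        }
      }
    }
  }

  if (params$include_standard) {
    white <- 235 + matrix(stats::rnorm(H * W, 0, 3), H, W)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[std_mask] <- white[std_mask]
      img[, , c] <- plane
    }
  }

  # illumination gradient along a random direction (image only)
  if (params$illumination_amplitude > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    proj <- outer(0:(H - 1), 0:(W - 1),
                  function(y, x) (y * sin(ang) + x * cos(ang)))
    proj <- (proj - min(proj)) / max(1e-9, diff(range(proj)))
    fac <- 1 + params$illumination_amplitude * (2 * proj - 1)
    for (c in 1:3) img[, , c] <- img[, , c] * fac
  }

  # soft elliptical shadows (image only, off the standard)
  for (s in seq_len(params$shadow_count)) {
    a <- stats::runif(1, 0.1, 0.2) * W; b <- stats::runif(1, 0.08, 0.15) * H
    px <- ellipse_pixels(stats::runif(1, 0, H - 1), stats::runif(1, 0, W - 1),
                         a, b, stats::runif(1, 0, pi), H, W)
    if (!length(px$y)) next
    idx <- cbind(px$y, px$x)
    keep <- !std_mask[idx]
    idx <- idx[keep, , drop = FALSE]
    fade <- 1 - 0.35 * (1 - abs(px$t[keep]))
    for (c in 1:3) {
      plane <- img[, , c]
      plane[idx] <- plane[idx] * fade
      img[, , c] <- plane
    }
  }

  if (params$blur_sigma > 0) {
    e <- as_ebimage(pmin(pmax(img, 0), 255))
    img <- from_ebimage(EBImage::gblur(e, sigma = params$blur_sigma))
  }
  img <- pmin(pmax(round(img), 0), 255)

  structure(list(image = img, ear_mask = (labels > 0L) + 0,
                 instance_labels = labels, true_count = placed,
                 standard_corners = standard_corners, params = params),
            class = "synthetic_scene")
}

#' Generate a labelled patch set from synthetic scenes
#'
#' Cuts ear patches around instances (bounding box + 10% margin, exact
#' instance mask) and background patches from ear-free areas (all-zero
#' masks), balanced between the classes. Scenes are generated as needed with
#' seeds derived from `seed`.
#'
#' @param params [scene_params()] used for the source scenes.
#' @param n_per_class patches per class.
#' @param seed integer seed.
#' @return `patchset` of `2 * n_per_class` patches.
#' @export
generate_patchset <- function(params = scene_params(), n_per_class = 100L,
                              seed = 1L) {
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  patches <- list()
  n_ear <- 0L; n_bg <- 0L
  scene_i <- 0L
  H <- params$image_size[1]; W <- params$image_size[2]
  while (n_ear < n_per_class || n_bg < n_per_class) {
    scene_i <- scene_i + 1L
    if (scene_i > 50L + 10L * n_per_class)
      stop("could not harvest enough patches", call. = FALSE)
    sp <- params
    sp$seed <- seed * 10000L + scene_i
    sc <- generate_scene(sp)
    for (k in seq_len(sc$true_count)) {
      if (n_ear >= n_per_class) break
      idx <- which(sc$instance_labels == k, arr.ind = TRUE)
      if (!nrow(idx)) next
      y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
      x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
      mg <- ceiling(c(y1 - y0, x1 - x0) * 0.1)
      y0 <- max(1, y0 - mg[1]); y1 <- min(H, y1 + mg[1])
      x0 <- max(1, x0 - mg[2]); x1 <- min(W, x1 + mg[2])
      patches[[length(patches) + 1L]] <- list(
        image = sc$image[y0:y1, x0:x1, , drop = FALSE],
        mask = (sc$instance_labels[y0:y1, x0:x1, drop = FALSE] > 0) + 0,
        class_label = "ear",
        origin = list(scene_seed = sp$seed, y0 = y0, x0 = x0))
      n_ear <- n_ear + 1L
    }
    set.seed(sp$seed + 5000L)
    for (try in seq_len(200L)) {
      if (n_bg >= n_per_class) break
      sz <- sample(18:30, 2L, replace = TRUE)
      y0 <- sample.int(H - sz[1], 1L); x0 <- sample.int(W - sz[2], 1L)
      ys <- y0:(y0 + sz[1]); xs <- x0:(x0 + sz[2])
      if (any(sc$ear_mask[ys, xs] > 0)) next
      patches[[length(patches) + 1L]] <- list(
        image = sc$image[ys, xs, , drop = FALSE],
        mask = matrix(0, length(ys), length(xs)),
        class_label = "background",
        origin = list(scene_seed = sp$seed, y0 = y0 + 1L, x0 = x0 + 1L))
      n_bg <- n_bg + 1L
    }
  }
  new_patchset(patches)
}

#' Write a scene to disk
#'
#' Writes the RGB image, the binary ear mask, the instance labels (16-bit
#' two-byte PNG encoding as in [save_superpixels()]) and a JSON sidecar with
#' the true count, standard corners and parameters.
#'
#' @param scene [generate_scene()] result.
#' @param prefix file prefix; writes `<prefix>.png`, `<prefix>_mask.png`,
#'   `<prefix>_labels.png`, `<prefix>.json`.
#' @return `prefix` invisibly.
#' @export
write_scene <- function(scene, prefix) {
  write_image(scene$image, paste0(prefix, ".png"))
  write_image(scene$ear_mask * 255, paste0(prefix, "_mask.png"))
  enc <- array(0, dim = c(dim(scene$instance_labels), 3L))
  enc[, , 1] <- scene$instance_labels %/% 256L
  enc[, , 2] <- scene$instance_labels %% 256L
  write_image(enc, paste0(prefix, "_labels.png"))
  p <- scene$params
  jsonlite::write_json(
    list(true_count = scene$true_count,
         standard_corners = scene$standard_corners,
         params = p[!vapply(p, is.null, TRUE)]),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Sparse non-overlapping fixture family
#'
#' The scene parameterization used for exact-count evaluation of the
#' counting stages: well-separated plain ears (no awns, no shadows) whose
#' gaps survive both the median filter and the edge baseline's dilation.
#' Clearance is set above twice the dilation growth of the default edge
#' parameters (2 iterations of a 5 px disc, plus the ~3 px reach of the
#' blurred Sobel band).
#'
#' @param seed integer seed.
#' @return [scene_params()] object.
#' @export
sparse_scene_params <- function(seed = 1L) {
  scene_params(image_size = c(224L, 224L), n_ears = 10L, overlap_limit = 0,
               min_clearance = 14, awn_probability = 0, shadow_count = 0L,
               seed = seed)
}
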