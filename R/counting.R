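#' Binarize a probability map
#'
#' Pixels with probability greater than or equal to `threshold` become ear
#' pixels (value 1). The default 0.5 is the sigmoid midpoint.
#'
#' @param map probability matrix in `[0, 1]`.
#' @param threshold real in (0, 1).
#' @return binary 0/1 matrix.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  (map >= threshold) + 0
}

# 0-based contour coordinates (x, y) of each labelled object.
trace_contours <- function(lab_matrix) {
  e <- EBImage::Image(t(lab_matrix))
  ct <- EBImage::ocontour(e)
  lapply(ct, function(m) {
    colnames(m) <- c("x", "y")
    m
  })
}

#' Count individual ears in a binary mask
#'
#' The counting pipeline: 7x7 median filter to remove speckle
#' misclassification, Euclidean distance transform, marker-based watershed to
#' split touching ears, removal of components smaller than `min_area`, then
#' contour tracing. Watershed markers are the regional maxima of the distance
#' map; flooded regions are re-merged when the ridge between them is shallow
#' (prominence below `watershed_tolerance`, which absorbs the sub-pixel
#' fluctuation of the discrete distance transform along an elongated ear's
#' ridge) or when their peaks lie closer than `min_peak_separation` (two
#' maxima inside one ear).
#'
#' By default `min_peak_separation` is 0.6 x the median equivalent diameter
#' (`2 * sqrt(area / pi)`) of the separated objects, so the floor adapts to
#' the ear size actually present in the image.
#'
#' @param mask binary 0/1 matrix.
#' @param min_area minimum object area in pixels; default 0.02% of the image.
#' @param min_peak_separation minimum distance between distinct peaks in
#'   pixels, or `NULL` to estimate it from the object sizes.
#' @param median_window median filter window (odd), default 7.
#' @param watershed_tolerance minimum ridge prominence separating two
#'   objects, default 1 (one distance-map unit).
#' @return object of class `count_result`: list with `mask` (filtered binary
#'   mask), `objects` (labelled matrix), `contours`, `count` and
#'   `ears_per_m2` (`NA` until [ears_per_m2()] is applied).
#' @export
count_ears <- function(mask, min_area = NULL, min_peak_separation = NULL,
                       median_window = 7L, watershed_tolerance = 1) {
  if (!all(mask %in% c(0, 1)))
    stop("`mask` must be binary", call. = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  if (is.null(min_area)) min_area <- max(4, round(0.0002 * H * W))
  m <- median_filter(mask, median_window)
  if (sum(m) == 0)
    return(structure(list(mask = m, objects = matrix(0L, H, W),
                          contours = list(), count = 0L, ears_per_m2 = NA_real_),
                     class = "count_result"))
  em <- EBImage::Image(t(m))
  dm <- t(EBImage::imageData(EBImage::distmap(em)))
  markers <- ws_maxima_cpp(dm)
  lab <- ws_flood_cpp(dm, markers)
  lab <- ws_merge_cpp(dm, lab, watershed_tolerance, 0)
  if (is.null(min_peak_separation)) {
    # separation floor from the separated objects' own sizes
    areas <- tabulate(lab[lab > 0L])
    areas <- areas[areas > 0]
    eq_diam <- 2 * sqrt(stats::median(areas) / pi)
    min_peak_separation <- max(1, 0.6 * eq_diam)
  }
  lab <- ws_merge_cpp(dm, lab, 0, min_peak_separation)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  contours <- if (length(keep)) trace_contours(lab) else list()
  structure(list(mask = m, objects = lab, contours = contours,
                 count = length(keep), ears_per_m2 = NA_real_),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat("count_result:", x$count, "ears")
  if (!is.na(x$ears_per_m2)) cat(sprintf(" (%.1f ears/m2)", x$ears_per_m2))
  cat("\n")
  invisible(x)
}

#' Ground standard of known physical size
#'
#' Four pixel corners of an object of known physical area placed in the scene
#' (by default an A4 sheet, 0.210 m x 0.297 m = 0.06237 m2), used to convert
#' pixel measurements into metric units.
#'
#' @param corners 4 x 2 matrix of (x, y) pixel coordinates forming a simple
#'   quadrilateral.
#' @param physical_area physical area in m2, default A4.
#' @return object of class `ground_standard` with the quadrilateral's pixel
#'   area precomputed (shoelace formula).
#' @export
ground_standard <- function(corners, physical_area = 0.210 * 0.297) {
  corners <- matrix(as.numeric(corners), 4L, 2L)
  x <- corners[, 1]; y <- corners[, 2]
  px_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (!is.finite(px_area) || px_area <= 0)
    stop("ground standard corners are degenerate", call. = FALSE)
  structure(list(corners = corners, physical_area = physical_area,
                 pixel_area = px_area),
            class = "ground_standard")
}

#' Convert an ear count into ears per square metre
#'
#' The standard's pixel area `P` and physical area give the metric scale
#' `scale^2 = physical_area / P` (m2 per pixel2); the imaged ground area is
#' `A = H * W * scale^2` and the density is `count / A`. The result is
#' invariant to uniform image rescaling.
#'
#' @param count nonnegative integer ear count.
#' @param standard [ground_standard()].
#' @param image_shape `c(H, W)` in pixels.
#' @return ears per square metre.
#' @export
ears_per_m2 <- function(count, standard, image_shape) {
  if (!inherits(standard, "ground_standard"))
    stop("`standard` must be a ground_standard", call. = FALSE)
  scale2 <- standard$physical_area / standard$pixel_area
  area_m2 <- image_shape[1] * image_shape[2] * scale2
  count / area_m2
}

#' Detect the ground standard in an image
#'
#' Finds the largest bright, low-saturation connected region, approximates it
#' by its four extreme corners (min/max of `x + y` and `x - y`) and accepts it
#' only if it is large enough and near-rectangular (pixel area within 20% of
#' the corner-quadrilateral area). Manual corner entry via [ground_standard()]
#' is always available when detection fails.
#'
#' @param img RGB array.
#' @param min_value minimum brightness (value channel, 0-1), default 0.7.
#' @param max_saturation maximum saturation, default 0.25.
#' @param min_area_fraction minimum fraction of image pixels, default 0.001.
#' @param physical_area physical area in m2, default A4.
#' @return [ground_standard()] on success; error if no candidate passes.
#' @export
detect_ground_standard <- function(img, min_value = 0.7, max_saturation = 0.25,
                                   min_area_fraction = 0.001,
                                   physical_area = 0.210 * 0.297) {
  assert_rgb(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  hsv <- grDevices::rgb2hsv(matrix(aperm(img, c(3, 1, 2)), nrow = 3),
                            maxColorValue = 255)
  bright <- matrix(hsv[3, ] >= min_value & hsv[2, ] <= max_saturation, H, W)
  # one-pixel dilation recovers the boundary ring lost to image blur
  eb <- EBImage::dilate(EBImage::Image(t(bright) + 0), EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(eb)
  labm <- t(EBImage::imageData(lab))
  if (max(labm) == 0)
    stop("no ground standard detected; supply corners manually via ",
         "ground_standard()", call. = FALSE)
  sizes <- tabulate(labm[labm > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_area_fraction * H * W)
    stop("no ground standard candidate large enough; supply corners manually",
         call. = FALSE)
  idx <- which(labm == best, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  s <- x + y; d <- x - y
  # average the pixels attaining each extreme (sub-pixel corner estimate)
  pick <- function(v, lo) {
    sel <- if (lo) v <= min(v) + 1 else v >= max(v) - 1
    c(mean(x[sel]), mean(y[sel]))
  }
  corners <- rbind(pick(s, TRUE), pick(d, FALSE), pick(s, FALSE), pick(d, TRUE))
  # the extreme-band average sits ~3/4 px inside the physical corner
  ctr <- colMeans(corners)
  dirs <- sweep(corners, 2L, ctr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  corners <- corners + 0.5 * dirs
  gs <- ground_standard(corners, physical_area)
  if (abs(gs$pixel_area - sizes[best]) > 0.2 * gs$pixel_area)
    stop("brightest region is not rectangular enough to be the ground ",
         "standard; supply corners manually", call. = FALSE)
  gs
}

# 3x5 bitmap digits for numbering contours on overlays.
digit_glyphs <- local({
  rows <- c("111101101101111", "010110010010111", "111001111100111",
            "111001111001111", "101101111001001", "111100111001111",
            "111100111101111", "111001001001001", "111101111101111",
            "111101111001111")
  lapply(rows, function(r) matrix(as.integer(strsplit(r, "")[[1]]) == 1L,
                                  nrow = 5, byrow = TRUE))
})

stamp_number <- function(img, number, x, y, col = c(255, 255, 0)) {
  digs <- as.integer(strsplit(as.character(number), "")[[1]])
  H <- dim(img)[1]; W <- dim(img)[2]
  for (i in seq_along(digs)) {
    g <- digit_glyphs[[digs[i] + 1L]]
    for (r in 1:5) for (cc in 1:3) {
      if (!g[r, cc]) next
      yy <- y + r; xx <- x + (i - 1L) * 4L + cc
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) img[yy, xx, ] <- col
    }
  }
  img
}

#' Render a counting overlay
#'
#' Draws each detected ear's contour in red and stamps its sequential index
#' near the contour on a copy of the input image.
#'
#' @param img RGB array.
#' @param result [count_ears()] result.
#' @return RGB array (the input is not modified).
#' @export
render_overlay <- function(img, result) {
  assert_rgb(img)
  out <- img
  H <- dim(img)[1]; W <- dim(img)[2]
  for (i in seq_along(result$contours)) {
    ct <- result$contours[[i]]
    ys <- pmin(pmax(ct[, "y"] + 1L, 1L), H)
    xs <- pmin(pmax(ct[, "x"] + 1L, 1L), W)
    for (c in 1:3) out[cbind(ys, xs, c)] <- c(255, 0, 0)[c]
    out <- stamp_number(out, i, round(mean(xs)) - 2L, round(mean(ys)) - 3L)
  }
  out
}
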