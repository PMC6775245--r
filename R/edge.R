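#' Parameters of the handcrafted edge-counting baseline
#'
#' The comparison method: grayscale conversion, Sobel gradient magnitude,
#' thresholding (Otsu by default), morphological dilation to join broken edge
#' fragments, hole filling, removal of small objects, erosion to smooth
#' boundaries, and contour counting. Structuring elements are elliptical
#' (discs), matching the rounded-elongated shape prior of wheat ears.
#'
#' @param magnitude_threshold `"otsu"` or a fixed value in gradient-magnitude
#'   units (0-255 scale).
#' @param dilation_size disc diameter for dilation (odd), default 5.
#' @param dilation_iter dilation repetitions, default 2.
#' @param min_object_area small-object removal threshold in pixels; default
#'   0.05% of the image.
#' @param erosion_size disc diameter for erosion (odd), default 5.
#' @param erosion_iter erosion repetitions, default 1.
#' @return object of class `edge_params`.
#' @export
edge_params <- function(magnitude_threshold = "otsu",
                        dilation_size = 5L, dilation_iter = 2L,
                        min_object_area = NULL,
                        erosion_size = 5L, erosion_iter = 1L) {
  if (dilation_size %% 2L == 0L || erosion_size %% 2L == 0L)
    stop("structuring element sizes must be odd", call. = FALSE)
  if (dilation_iter < 0L || erosion_iter < 0L)
    stop("iteration counts must be >= 0", call. = FALSE)
  structure(list(magnitude_threshold = magnitude_threshold,
                 dilation_size = as.integer(dilation_size),
                 dilation_iter = as.integer(dilation_iter),
                 min_object_area = min_object_area,
                 erosion_size = as.integer(erosion_size),
                 erosion_iter = as.integer(erosion_iter)),
            class = "edge_params")
}

sobel_magnitude <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  e <- EBImage::Image(t(gray))
  gx <- EBImage::filter2(e, kx, boundary = "replicate")
  gy <- EBImage::filter2(e, ky, boundary = "replicate")
  t(EBImage::imageData(sqrt(gx^2 + gy^2)))
}

#' Count ears with the Sobel-edge baseline
#'
#' Runs the full handcrafted pipeline and returns the same kind of result as
#' [count_ears()]. All intermediate stages are attached under `$stages`
#' (grayscale, gradient magnitude, binary edges, dilated, filled, cleaned,
#' eroded) for inspection: dilation is a superset of its input foreground,
#' erosion a subset, and filling a superset.
#'
#' @param img RGB array.
#' @param params [edge_params()].
#' @return `count_result` with a `$stages` list attached.
#' @export
edge_count <- function(img, params = edge_params()) {
  assert_rgb(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  gray <- to_grayscale(img)
  mag <- sobel_magnitude(gray)
  thr <- params$magnitude_threshold
  if (identical(thr, "otsu")) {
    norm <- mag / max(mag, 1e-12)
    thr <- EBImage::otsu(EBImage::Image(t(norm)), range = c(0, 1)) *
      max(mag, 1e-12)
  }
  edges <- (mag >= thr) + 0

  brush_d <- EBImage::makeBrush(params$dilation_size, "disc")
  brush_e <- EBImage::makeBrush(params$erosion_size, "disc")
  cur <- EBImage::Image(t(edges))
  for (i in seq_len(params$dilation_iter)) cur <- EBImage::dilate(cur, brush_d)
  dilated <- t(EBImage::imageData(cur)) + 0
  cur <- EBImage::fillHull(cur)
  filled <- t(EBImage::imageData(cur)) + 0

  min_area <- params$min_object_area
  if (is.null(min_area)) min_area <- max(9, round(5e-4 * H * W))
  labi <- EBImage::bwlabel(cur)
  sizes <- tabulate(as.integer(labi[labi > 0]))
  small <- which(sizes < min_area)
  cleaned_m <- t(EBImage::imageData(labi))
  cleaned_m[cleaned_m %in% small] <- 0L
  cleaned <- (cleaned_m > 0) + 0

  cur <- EBImage::Image(t(cleaned))
  for (i in seq_len(params$erosion_iter)) cur <- EBImage::erode(cur, brush_e)
  eroded <- t(EBImage::imageData(cur)) + 0

  labf <- EBImage::bwlabel(EBImage::Image(t(eroded)))
  labm <- t(EBImage::imageData(labf))
  # erosion can leave sub-threshold slivers; keep the area rule after it too
  sizes_f <- tabulate(labm[labm > 0])
  keep <- which(sizes_f >= min_area)
  relab <- integer(length(sizes_f)); relab[keep] <- seq_along(keep)
  labm[labm > 0] <- relab[labm[labm > 0]]
  contours <- if (length(keep)) trace_contours(labm) else list()

  res <- structure(list(mask = eroded, objects = labm, contours = contours,
                        count = length(keep), ears_per_m2 = NA_real_),
                   class = "count_result")
  res$stages <- list(gray = gray, magnitude = mag, edges = edges,
                     dilated = dilated, filled = filled, cleaned = cleaned,
                     eroded = eroded)
  res
}
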