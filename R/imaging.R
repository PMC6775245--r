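#' @useDynLib earcount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal validation helpers ------------------------------------------

assert_rgb <- function(img, arg = deparse(substitute(img))) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` must have channel values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_gray <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must be a nonempty H x W matrix", arg), call. = FALSE)
  invisible(img)
}

#' Convert an RGB image to grayscale
#'
#' Luminance-weighted conversion using the ITU-R BT.601 weights
#' 0.299 R + 0.587 G + 0.114 B, rounded to integers.
#'
#' Images throughout the package are base arrays indexed `[row, col]`
#' (row = y, growing downward), `H x W x 3` with channel values in
#' `[0, 255]` for RGB and `H x W` matrices for grayscale.
#'
#' @param img `H x W x 3` array with values in `[0, 255]`.
#' @return `H x W` numeric matrix of rounded luminance values.
#' @export
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' to_grayscale(img)  # all 255
to_grayscale <- function(img) {
  assert_rgb(img)
  round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Convert an sRGB image to CIELAB
#'
#' Standard sRGB (D65 white point) -> XYZ -> CIELAB conversion. L is in
#' `[0, 100]`; a and b are the opponent colour channels. The CIELAB space is
#' perceptually approximately uniform, which is why the superpixel clustering
#' measures colour distance in it.
#'
#' @param img `H x W x 3` array, values in `[0, 255]`.
#' @return `H x W x 3` array of (L, a, b) values.
#' @export
to_cielab <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  v <- img / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(lin, ncol = 3L)  # columns R, G, B (linear)
  xyz <- m %*% t(matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041), nrow = 3L, byrow = TRUE))
  white <- c(0.95047, 1.0, 1.08883)
  t3 <- sweep(xyz, 2L, white, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  array(c(L, a, b), dim = d)
}

#' Gamma-correct an image
#'
#' Gamma encoding: `out = round(255 * (in/255)^(1/gamma))` per channel.
#' `gamma > 1` brightens mid-tones, `gamma < 1` darkens them; 0 and 255 are
#' fixed points. Used by the augmentation stage to emulate exposure and
#' luminance-encoding differences between cameras.
#'
#' @param img RGB array or grayscale matrix with values in `[0, 255]`.
#' @param gamma positive real.
#' @return image of the same shape and type.
#' @export
apply_gamma <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0)
    stop("`gamma` must be a positive number", call. = FALSE)
  if (length(dim(img)) == 3L) assert_rgb(img) else assert_gray(img)
  out <- round(255 * (img / 255)^(1 / gamma))
  dim(out) <- dim(img)
  out
}

#' Sliding-window median filter
#'
#' Each output pixel is the median of the `window x window` neighbourhood of
#' the input pixel; borders are handled by reflection. This is the denoising
#' step applied to the binary segmentation mask before watershed counting
#' (default window of seven pixels), and it is deliberately implemented as the
#' literal sort-the-window operation it is described as.
#'
#' @param img grayscale matrix (or 0/1 binary mask).
#' @param window odd integer window side length, default 7.
#' @return filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 7L) {
  assert_gray(img)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  median_filter_cpp(img, window)
}

# ---- file I/O --------------------------------------------------------------

# EBImage stores images [x, y(, channel)] with values in [0, 1]; the package
# convention is [row = y, col = x] in [0, 255]. These two adapters own the
# transpose so no other code has to think about it.
as_ebimage <- function(img) {
  if (length(dim(img)) == 3L) {
    EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
  } else {
    EBImage::Image(t(img) / 255, colormode = "Grayscale")
  }
}

from_ebimage <- function(eimg) {
  d <- dim(eimg)
  px <- EBImage::imageData(eimg)
  if (length(d) == 3L && d[3] == 3L) {
    round(255 * aperm(px, c(2L, 1L, 3L)))
  } else {
    if (length(d) == 3L) px <- px[, , 1L]
    round(255 * t(px))
  }
}

#' Read an image file
#'
#' Reads PNG, JPEG or TIFF into the package's `H x W x 3` (RGB) or `H x W`
#' (grayscale) 8-bit convention.
#'
#' @param path file path.
#' @return RGB array or grayscale matrix with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  e <- EBImage::readImage(path)
  d <- dim(e)
  if (length(d) == 3L && d[3] >= 3L) {
    from_ebimage(e[, , 1:3])
  } else {
    from_ebimage(e)
  }
}

#' Write an image file
#'
#' @param img RGB array or grayscale matrix in `[0, 255]`.
#' @param path destination; format from extension (png/jpg/tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  EBImage::writeImage(as_ebimage(pmin(pmax(img, 0), 255)), path)
  invisible(path)
}
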