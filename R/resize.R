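#' Resize an image, mask or probability map
#'
#' Bilinear interpolation for continuous data (images, probability maps) and
#' nearest-neighbour for label data (binary masks stay binary). Sampling uses
#' half-pixel-centre alignment with edge clamping.
#'
#' @param img matrix or `H x W x C` array.
#' @param out_h,out_w output dimensions.
#' @param method `"bilinear"` or `"nearest"`.
#' @return resized matrix/array.
#' @export
resize_image <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (length(dim(img)) == 3L) {
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (c in seq_len(dim(img)[3]))
      out[, , c] <- resize_image(img[, , c], out_h, out_w, method)
    return(out)
  }
  H <- nrow(img); W <- ncol(img)
  sy <- H / out_h; sx <- W / out_w
  ys <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), H - 1)
  xs <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), W - 1)
  if (method == "nearest") {
    return(img[round(ys) + 1L, round(xs) + 1L, drop = FALSE])
  }
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- ys - y0; wx <- xs - x0
  i0 <- y0 + 1L; i1 <- y1 + 1L; j0 <- x0 + 1L; j1 <- x1 + 1L
  a <- img[i0, j0, drop = FALSE]; b <- img[i0, j1, drop = FALSE]
  d <- img[i1, j0, drop = FALSE]; e <- img[i1, j1, drop = FALSE]
  top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
  bot <- d * outer(rep(1, out_h), 1 - wx) + e * outer(rep(1, out_h), wx)
  top * outer(1 - wy, rep(1, out_w)) + bot * outer(wy, rep(1, out_w))
}
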