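#' SLIC parameters
#'
#' Parameters of the superpixel partition. `n_superpixels` is the requested
#' number of roughly equal-sized regions; the pipeline default of 3000 suits
#' full-resolution canopy images and avoids oversegmentation, while desk-scale
#' fixtures use far fewer. `compactness` (m) weights spatial against colour
#' distance: larger values give squarer superpixels, smaller values better
#' boundary adherence. `min_region_fraction` is the size threshold, relative
#' to the average superpixel area, below which a connected fragment is merged
#' into an adjacent region.
#'
#' @param n_superpixels positive integer, default 3000.
#' @param compactness positive real, default 10.
#' @param max_iterations positive integer, default 10.
#' @param min_region_fraction real in (0, 1), default 0.25.
#' @return object of class `slic_params`.
#' @export
slic_params <- function(n_superpixels = 3000L, compactness = 10,
                        max_iterations = 10L, min_region_fraction = 0.25) {
  n_superpixels <- as.integer(n_superpixels)
  if (is.na(n_superpixels) || n_superpixels < 1L)
    stop("`n_superpixels` must be a positive integer", call. = FALSE)
  if (!is.numeric(compactness) || compactness <= 0)
    stop("`compactness` must be positive", call. = FALSE)
  if (max_iterations < 1L)
    stop("`max_iterations` must be >= 1", call. = FALSE)
  if (min_region_fraction <= 0 || min_region_fraction >= 1)
    stop("`min_region_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(n_superpixels = n_superpixels, compactness = compactness,
                 max_iterations = as.integer(max_iterations),
                 min_region_fraction = min_region_fraction),
            class = "slic_params")
}

# Squared-gradient magnitude of the L channel (central differences, edges
# clamped); used only to nudge seeds off edges.
lab_gradient <- function(lab) {
  L <- lab[, , 1]
  H <- nrow(L); W <- ncol(L)
  right <- L[, c(2:W, W), drop = FALSE]; left <- L[, c(1, 1:(W - 1)), drop = FALSE]
  down <- L[c(2:H, H), , drop = FALSE]; up <- L[c(1, 1:(H - 1)), , drop = FALSE]
  (right - left)^2 + (down - up)^2
}

#' Initialize SLIC cluster centers
#'
#' Places centers on a regular grid with spacing `S = sqrt(H * W / N)`, then
#' perturbs each to the lowest-gradient position in its 3x3 neighbourhood so
#' seeds avoid edges. Center colours are sampled from the image at the
#' perturbed position.
#'
#' @param lab `H x W x 3` CIELAB array (see [to_cielab()]).
#' @param params [slic_params()].
#' @return numeric matrix with one row per center and columns
#'   `l, a, b, x, y` (x = column, y = row, 0-based).
#' @export
initialize_centers <- function(lab, params) {
  H <- dim(lab)[1]; W <- dim(lab)[2]
  N <- params$n_superpixels
  if (N > H * W)
    stop("`n_superpixels` exceeds the pixel count", call. = FALSE)
  nx <- min(W, max(1L, as.integer(ceiling(sqrt(N * W / H)))))
  ny <- min(H, max(1L, as.integer(round(N / nx))))
  xs <- (seq_len(nx) - 0.5) * (W / nx) - 0.5
  ys <- (seq_len(ny) - 0.5) * (H / ny) - 0.5
  grid <- expand.grid(x = xs, y = ys)  # row-major over the grid
  grad <- lab_gradient(lab)
  centers <- matrix(0, nrow(grid), 5L,
                    dimnames = list(NULL, c("l", "a", "b", "x", "y")))
  for (k in seq_len(nrow(grid))) {
    cx <- min(max(as.integer(round(grid$x[k])), 0L), W - 1L)
    cy <- min(max(as.integer(round(grid$y[k])), 0L), H - 1L)
    best <- c(cy, cx); bestg <- grad[cy + 1L, cx + 1L]  # ties keep the seed
    for (dy in -1:1) for (dx in -1:1) {
      yy <- cy + dy; xx <- cx + dx
      if (yy < 0L || yy >= H || xx < 0L || xx >= W) next
      g <- grad[yy + 1L, xx + 1L]
      if (g < bestg) { bestg <- g; best <- c(yy, xx) }
    }
    # keep the continuous grid position, shifted by the perturbation offset,
    # so an unperturbed seed lattice stays symmetric between pixels
    centers[k, ] <- c(lab[best[1] + 1L, best[2] + 1L, ],
                      grid$x[k] + (best[2] - cx), grid$y[k] + (best[1] - cy))
  }
  centers
}

#' Segment an image into SLIC superpixels
#'
#' Localized k-means over the 5-D `(l, a, b, x, y)` space: each pixel is
#' assigned to the nearest center under
#' `D^2 = d_lab^2 + (m/S)^2 d_xy^2`, each center searching only a `2S x 2S`
#' window around itself; centers are then updated to the mean of their pixels.
#' After `max_iterations` rounds, connectivity is enforced
#' ([enforce_connectivity()]) so every region is 4-connected and no small
#' islands remain.
#'
#' @param img RGB array (`H x W x 3`, values in `[0, 255]`).
#' @param params [slic_params()].
#' @return object of class `superpixel_map`: list with `labels` (`H x W`
#'   integer matrix, values `1..K`), `K`, and `params`.
#' @export
slic_segment <- function(img, params = slic_params()) {
  assert_rgb(img)
  lab <- to_cielab(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  S <- sqrt(H * W / params$n_superpixels)
  centers <- initialize_centers(lab, params)
  res <- slic_iterate_cpp(lab[, , 1], lab[, , 2], lab[, , 3], centers,
                          S, params$compactness, params$max_iterations)
  labels <- res$labels + 1L
  map <- structure(list(labels = labels, K = max(labels), params = params),
                   class = "superpixel_map")
  enforce_connectivity(map, params)
}

#' Enforce 4-connectivity of a superpixel map
#'
#' Splits labels into 4-connected components, merges every component smaller
#' than `min_region_fraction * (H * W / n_superpixels)` into the adjacent
#' component with which it shares the longest boundary (ties broken toward
#' the lower label), and relabels the result `1..K` in row-major order of
#' first occurrence.
#'
#' @param map `superpixel_map` (possibly with disconnected labels).
#' @param params [slic_params()]; defaults to the map's own.
#' @return `superpixel_map` whose regions are all 4-connected.
#' @export
enforce_connectivity <- function(map, params = map$params) {
  labels <- map$labels
  H <- nrow(labels); W <- ncol(labels)
  comp <- connected_components_cpp(labels)
  nc <- max(comp)
  sizes <- tabulate(comp, nbins = nc)
  thresh <- params$min_region_fraction * (H * W / params$n_superpixels)

  # adjacency counts between horizontally/vertically touching components
  a <- c(comp[-H, ], comp[, -W]); b <- c(comp[-1, ], comp[, -1])
  keep <- a != b
  pair_lo <- pmin(a[keep], b[keep]); pair_hi <- pmax(a[keep], b[keep])
  adj <- if (length(pair_lo))
    stats::aggregate(rep(1L, length(pair_lo)),
                     by = list(lo = pair_lo, hi = pair_hi), FUN = sum)
  else data.frame(lo = integer(), hi = integer(), x = integer())

  # union-find so mutual merges between two small components cannot cycle
  parent <- seq_len(nc)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  small <- which(sizes < thresh)
  for (s in small) {
    rows <- adj$lo == s | adj$hi == s
    if (!any(rows)) next  # single-component image
    nb <- ifelse(adj$lo[rows] == s, adj$hi[rows], adj$lo[rows])
    cnt <- adj$x[rows]
    best <- nb[order(-cnt, nb)][1]
    rs <- find(s); rb <- find(best)
    if (rs != rb) parent[rs] <- rb
  }
  roots <- vapply(seq_len(nc), find, 1L)
  comp[] <- roots[comp]

  # row-major relabel to 1..K
  flat <- as.integer(t(comp))  # row-major order
  first <- !duplicated(flat)
  newid <- integer(max(comp)); newid[flat[first]] <- seq_len(sum(first))
  out <- matrix(newid[as.integer(comp)], H, W)
  structure(list(labels = out, K = max(out), params = params),
            class = "superpixel_map")
}

#' Extract per-superpixel candidate regions
#'
#' One region per label: the tight bounding-box crop of the RGB image, the
#' label's ownership mask within that box, and the box in image coordinates.
#' The union of all ownership masks tiles the image exactly once, which is
#' what lets region-wise network predictions be stitched back losslessly.
#'
#' @param img RGB array.
#' @param map `superpixel_map` matching the image shape.
#' @return list of regions; each is a list with `crop` (RGB array), `mask`
#'   (logical matrix), `box` (`c(x0, y0, x1, y1)`, 0-based half-open) and
#'   `label`.
#' @export
extract_regions <- function(img, map) {
  assert_rgb(img)
  labels <- map$labels
  if (!all(dim(labels) == dim(img)[1:2]))
    stop("superpixel map does not match image shape", call. = FALSE)
  lapply(seq_len(map$K), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    list(crop = img[y0:y1, x0:x1, , drop = FALSE],
         mask = labels[y0:y1, x0:x1, drop = FALSE] == k,
         box = c(x0 - 1L, y0 - 1L, x1, y1),
         label = k)
  })
}

#' Boundary pixels of a superpixel map
#'
#' A pixel is a boundary pixel if its label differs from its right or lower
#' 4-neighbour. Used for boundary-recall checks against known edges.
#'
#' @param map `superpixel_map` or a label matrix.
#' @return logical `H x W` matrix.
#' @export
superpixel_boundaries <- function(map) {
  labels <- if (inherits(map, "superpixel_map")) map$labels else map
  H <- nrow(labels); W <- ncol(labels)
  b <- matrix(FALSE, H, W)
  b[, -W] <- labels[, -W] != labels[, -1]
  b[-H, ] <- b[-H, ] | (labels[-H, ] != labels[-1, ])
  b
}

#' Save / load a superpixel map
#'
#' The label image is stored as an RGB PNG encoding each 16-bit label as a
#' high byte (red) and low byte (green), with a plain-text sidecar recording
#' `K` and the parameters, so the round trip is exact.
#'
#' @param map `superpixel_map`.
#' @param path PNG path; the sidecar is `<path>.meta`.
#' @return `path` invisibly; `load_superpixels()` returns the map.
#' @export
save_superpixels <- function(map, path) {
  lab <- map$labels
  if (max(lab) > 65535L) stop("more than 65535 labels", call. = FALSE)
  enc <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  enc[, , 1] <- lab %/% 256L
  enc[, , 2] <- lab %% 256L
  write_image(enc, path)
  p <- map$params
  writeLines(c(paste0("K=", map$K),
               paste0("n_superpixels=", p$n_superpixels),
               paste0("compactness=", p$compactness),
               paste0("max_iterations=", p$max_iterations),
               paste0("min_region_fraction=", p$min_region_fraction)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname save_superpixels
#' @export
load_superpixels <- function(path) {
  enc <- read_image(path)
  lab <- matrix(as.integer(enc[, , 1] * 256L + enc[, , 2]),
                nrow = dim(enc)[1])
  meta <- strsplit(readLines(paste0(path, ".meta")), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(meta, `[`, "", 2L), vapply(meta, `[`, "", 1L))
  params <- slic_params(as.integer(vals[["n_superpixels"]]),
                        as.numeric(vals[["compactness"]]),
                        as.integer(vals[["max_iterations"]]),
                        as.numeric(vals[["min_region_fraction"]]))
  structure(list(labels = lab, K = as.integer(vals[["K"]]), params = params),
            class = "superpixel_map")
}
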