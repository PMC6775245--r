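# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's own code paths.

# Brute-force sliding-window median with half-sample symmetric reflection.
naive_median_filter <- function(m, w) {
  H <- nrow(m); W <- ncol(m); r <- w %/% 2
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j] <- stats::median(m[refl((i - r):(i + r), H),
                                   refl((j - r):(j + r), W)])
    }
  }
  out
}

# Global (unwindowed) 5-D k-means with the SLIC distance, run from the same
# initialization the package uses. Ties go to the lowest center index.
global_kmeans_slic <- function(img, params) {
  lab <- to_cielab(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  S <- sqrt(H * W / params$n_superpixels)
  centers <- initialize_centers(lab, params)
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  feats <- cbind(matrix(lab, ncol = 3)[g$y + 1 + H * g$x, , drop = FALSE],
                 g$x, g$y)
  w2 <- (params$compactness / S)^2
  assign <- integer(nrow(feats))
  for (iter in seq_len(params$max_iterations)) {
    d <- sapply(seq_len(nrow(centers)), function(k) {
      (feats[, 1] - centers[k, 1])^2 + (feats[, 2] - centers[k, 2])^2 +
        (feats[, 3] - centers[k, 3])^2 +
        w2 * ((feats[, 4] - centers[k, 4])^2 + (feats[, 5] - centers[k, 5])^2)
    })
    assign <- apply(d, 1, which.min)
    for (k in seq_len(nrow(centers))) {
      sel <- assign == k
      if (any(sel)) centers[k, ] <- colMeans(feats[sel, , drop = FALSE])
    }
  }
  matrix(assign[order(g$x * H + g$y)], H, W)  # feats are already in col order
}

# Boundary-inclusive point-in-polygon at pixel centres (crossing number +
# on-segment test).
naive_polygon_mask <- function(vertices, H, W) {
  vx <- vertices[, 1]; vy <- vertices[, 2]; n <- length(vx)
  on_seg <- function(px, py) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      dx <- vx[j] - vx[i]; dy <- vy[j] - vy[i]
      len2 <- dx^2 + dy^2
      if (len2 == 0) next
      t <- ((px - vx[i]) * dx + (py - vy[i]) * dy) / len2
      if (t < -1e-9 || t > 1 + 1e-9) next
      qx <- vx[i] + t * dx; qy <- vy[i] + t * dy
      if ((px - qx)^2 + (py - qy)^2 < 1e-12) return(TRUE)
    }
    FALSE
  }
  mask <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      px <- c - 1; py <- r - 1
      cross <- 0
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        if ((vy[i] > py) != (vy[j] > py)) {
          xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
          if (px < xint) cross <- cross + 1
        }
      }
      if (cross %% 2 == 1 || on_seg(px, py)) mask[r, c] <- 1
    }
  }
  mask
}

# Two-disk mask with the given overlap fraction of the radius.
two_disk_mask <- function(overlap, r = 10, size = 80, angle = 0.3) {
  d <- 2 * r * (1 - overlap)
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  m <- matrix(0, size, size)
  cx1 <- 25; cy1 <- 40
  m[(g$y - cy1)^2 + (g$x - cx1)^2 <= r^2] <- 1
  m[(g$y - cy1 - d * sin(angle))^2 + (g$x - cx1 - d * cos(angle))^2 <= r^2] <- 1
  m
}
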