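# Shared fixture builders; everything is generated in code.

# flat interface of given half-width on y = 0
flat_interface <- function(half_width = 2500) {
  cbind(x = c(-half_width, half_width), y = c(0, 0))
}

# semicircular source outline of radius r above the interface (y <= 0)
semicircle_outline <- function(r = 745, n = 37) {
  th <- seq(0, pi, length.out = n)
  cbind(x = r * cos(th), y = -r * sin(th))
}

std_geometry <- function(r = 745, half_width = 2500) {
  source_geometry(outline = semicircle_outline(r),
                  interface = flat_interface(half_width),
                  contact_length = 2 * r)
}

# binary image with filled disks stamped at (row, col) centers
disk_image <- function(nrow_px, ncol_px, centers, radius) {
  img <- matrix(FALSE, nrow_px, ncol_px)
  for (k in seq_len(nrow(centers))) {
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        r <- centers[k, 1] + dr; c <- centers[k, 2] + dc
        if (r >= 1 && r <= nrow_px && c >= 1 && c <= ncol_px)
          img[r, c] <- TRUE
      }
    }
  }
  img
}

# independent O(n*m) oracle for min point-to-polyline distance
brute_min_distance <- function(pts, verts) {
  apply(pts, 1, function(p) {
    best <- Inf
    for (i in seq_len(nrow(verts) - 1)) {
      a <- verts[i, ]; b <- verts[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else
        max(0, min(1, sum((p - a) * ab) / len2))
      best <- min(best, sqrt(sum((p - (a + t * ab))^2)))
    }
    best
  })
}

# exhaustive enumeration of the threshold-ROI rule: try every index and
# keep the deepest that satisfies both conditions literally
enumerate_threshold_roi <- function(column, threshold) {
  k <- length(column)
  best <- NA_integer_
  for (i in seq_len(k)) {
    if (column[i] < threshold) next
    deeper1 <- if (i + 1 <= k) column[i + 1] else 0
    deeper2 <- if (i + 2 <= k) column[i + 2] else 0
    if (deeper1 < threshold && deeper2 < threshold) best <- i
  }
  best
}

# exhaustive Otsu: maximize between-class variance over every split level
exhaustive_otsu <- function(v, levels = 256) {
  v <- round(v)
  best_t <- NA_real_; best_var <- -Inf
  for (t in 1:(levels - 1)) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bv > best_var) { best_var <- bv; best_t <- t }
  }
  best_t
}

# sample m points on the upper half of an axis-aligned ellipse centered on y=0
half_ellipse_points <- function(a, b, cx = 0, m = 40) {
  th <- seq(0.05, pi - 0.05, length.out = m)
  cbind(cx + a * cos(th), b * sin(th))
}
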