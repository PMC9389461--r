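#' Construct a projection image
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = image
#'   rows, columns = image columns).
#' @param pixel_size Pixel edge length in um/pixel.
#' @param n_projected_planes Number of focal planes combined into this image.
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, pixel_size, n_projected_planes = 1L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 n_projected_planes = as.integer(n_projected_planes)),
            class = "projection_image")
}

#' Maximum-intensity projection of consecutive focal planes
#'
#' Collapses `n` consecutive planes of a confocal stack into one image by
#' the per-pixel maximum, the projection used before nucleus segmentation.
#'
#' @param stack List of `projection_image` planes with identical shape.
#' @param start 1-based index of the first plane.
#' @param n Number of consecutive planes (>= 1).
#' @return A `projection_image` with `n_projected_planes = n`.
#' @export
max_project <- function(stack, start = 1L, n = length(stack)) {
  if (n < 1L || start < 1L || start + n - 1L > length(stack))
    stop("plane range [start, start + n - 1] outside the stack", call. = FALSE)
  planes <- lapply(stack[start:(start + n - 1L)], function(p) p$pixels)
  d <- dim(planes[[1L]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("planes differ in shape", call. = FALSE)
  out <- Reduce(pmax, planes)
  projection_image(out, stack[[start]]$pixel_size, n_projected_planes = n)
}

#' Global Otsu threshold of an integer-valued image
#'
#' Maximizes the between-class variance over all candidate gray levels
#' (256 levels for 8-bit data). The returned level t assigns foreground to
#' intensities >= t.
#'
#' @param pixels Numeric matrix of intensities.
#' @param levels Number of gray levels assumed (default 256).
#' @return The threshold as a gray level.
#' @export
otsu_threshold <- function(pixels, levels = 256L) {
  v <- round(as.vector(pixels))
  if (max(v) == min(v))
    stop("constant image: automatic threshold is degenerate", call. = FALSE)
  levels <- max(levels, max(v) + 1L)   # accommodate >8-bit data
  h <- tabulate(v + 1L, nbins = levels)
  p <- h / sum(h)
  g <- seq_len(levels) - 1
  omega <- cumsum(p)              # class-0 probability for threshold at g+1
  mu <- cumsum(p * g)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # split after level k maximizing sigma_b; foreground = intensities >= k + 1
  g[which.max(sigma_b)] + 1
}

#' Binarize a projection image
#'
#' @param img A `projection_image`.
#' @param threshold Numeric intensity, or `"auto"` for a histogram-based
#'   global threshold (Otsu criterion). The mask is TRUE where intensity
#'   >= threshold.
#' @return Logical matrix of the same shape, with attribute `"threshold"`.
#' @export
binarize <- function(img, threshold = "auto") {
  px <- img$pixels
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(px)
  } else {
    threshold <- as.numeric(threshold)
    if (threshold > max(px) || threshold < min(px))
      warning("threshold ", threshold, " lies outside the intensity range [",
              min(px), ", ", max(px), "]", call. = FALSE)
  }
  structure(px >= threshold, threshold = threshold)
}

# 8-connected component labeling of a logical mask. Returns an integer
# matrix with 0 = background and labels 1..k.
.label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- matrix(0L, d[1L], d[2L])
  if (length(idx) == 0L) return(lab)
  pos <- seq_along(idx)
  lut <- integer(prod(d)); lut[idx] <- pos
  row <- ((idx - 1L) %% d[1L]) + 1L
  col <- ((idx - 1L) %/% d[1L]) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    ok <- r2 >= 1L & r2 <= d[1L] & c2 >= 1L & c2 <= d[2L]
    nb <- (c2[ok] - 1L) * d[1L] + r2[ok]
    hit <- lut[nb] > 0L
    edges <- rbind(edges, cbind(pos[ok][hit], lut[nb][hit]))
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(pos, pos)),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[pos]
  lab[idx] <- as.integer(match(comp, unique(comp)))
  lab
}

# Marching-squares perimeter of one component given as a logical matrix:
# total length of the 0.5-level contour(s) of the (zero-padded) mask.
.ms_perimeter <- function(sub) {
  padded <- matrix(0, nrow(sub) + 2L, ncol(sub) + 2L)
  padded[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                y = seq_len(ncol(padded)),
                                z = padded, levels = 0.5)
  sum(vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)) +
      sqrt((cc$x[1] - cc$x[length(cc$x)])^2 +
           (cc$y[1] - cc$y[length(cc$y)])^2)
  }, numeric(1)))
}

#' Detect nuclei as filtered connected components
#'
#' Particle identification on a binary mask: 8-connected components are
#' measured (area, marching-squares perimeter, circularity = 4 pi A / P^2,
#' clamped to \[0, 1\]) and filtered by area and circularity. Components
#' touching the image border are retained. Centroids are unweighted means of
#' member pixel centers, converted to um; pixel (row i, col j) has its
#' center at x = (j - 0.5) * pixel_size, y = (i - 0.5) * pixel_size.
#'
#' @param mask Logical matrix (from [binarize()]).
#' @param pixel_size um/pixel.
#' @param min_area,max_area Area filter in um2.
#' @param min_circularity Minimum circularity.
#' @return A data.frame of class `detected_particles` with columns
#'   `x`, `y` (um), `area` (um2), `circularity`.
#' @export
detect_nuclei <- function(mask, pixel_size, min_area = 20, max_area = 500,
                          min_circularity = 0.3) {
  stopifnot(is.logical(mask), pixel_size > 0, min_area >= 0,
            min_area < max_area, min_circularity >= 0)
  lab <- .label_components(mask)
  k <- max(lab)
  empty <- data.frame(x = numeric(), y = numeric(), area = numeric(),
                      circularity = numeric())
  class(empty) <- c("detected_particles", "data.frame")
  if (k == 0L) return(empty)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  row <- ((idx - 1L) %% nrow(lab)) + 1L
  col <- ((idx - 1L) %/% nrow(lab)) + 1L
  npx <- tabulate(comp, nbins = k)
  cx <- (tapply(col, comp, mean) - 0.5) * pixel_size
  cy <- (tapply(row, comp, mean) - 0.5) * pixel_size
  area <- npx * pixel_size^2
  per <- vapply(seq_len(k), function(i) {
    sel <- comp == i
    r <- range(row[sel]); c <- range(col[sel])
    sub <- matrix(0, r[2] - r[1] + 1L, c[2] - c[1] + 1L)
    sub[cbind(row[sel] - r[1] + 1L, col[sel] - c[1] + 1L)] <- 1
    .ms_perimeter(sub) * pixel_size
  }, numeric(1))
  circ <- pmin(1, 4 * pi * area / per^2)
  keep <- area >= min_area & area <= max_area & circ >= min_circularity
  out <- data.frame(x = as.numeric(cx)[keep], y = as.numeric(cy)[keep],
                    area = area[keep], circularity = circ[keep])
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detected_particles", "data.frame")
  out
}

#' Full image-based nucleus detection
#'
#' Convenience wrapper: maximum projection (optional), binarization and
#' particle filtering, returning a [nucleus_set()].
#'
#' @param stack List of `projection_image` planes (or a single one).
#' @param sample_id Sample label.
#' @param config An [analysis_config()] supplying threshold and filters.
#' @return A `nucleus_set` of detected centroids.
#' @export
detect_sample <- function(stack, sample_id, config = analysis_config()) {
  if (inherits(stack, "projection_image")) stack <- list(stack)
  img <- max_project(stack)
  mask <- binarize(img, config$binarization_threshold)
  parts <- detect_nuclei(mask, img$pixel_size, config$min_area,
                         config$max_area, config$min_circularity)
  nucleus_set(sample_id, parts$x, parts$y, pixel_size = img$pixel_size)
}
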